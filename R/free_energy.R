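# Multistate reweighting (MBAR) over umbrella-sampled windows.
#
# Conventions: k_B = 1 (temperatures in model energy units), reduced
# potential u_k(x) = [E(x) + kappa_k (Q(x) - Q0_k)^2] / T_k. Free energies
# in the output tables are in units of k_B*T at the table's own temperature.

#' Construct a window of umbrella samples
#'
#' @param window_id Identifier for the window.
#' @param bias_center Center Q0 of the harmonic bias on global Q.
#' @param bias_strength Spring constant kappa (energy / Q^2); 0 = unbiased.
#' @param temperature Simulation temperature (model units, k_B = 1).
#' @param frames Data frame with at least columns `energy` and `global_q`;
#'   per-foldon columns `q_1`..`q_N` are carried through if present.
#' @return A `window_samples` object.
#' @export
window_samples <- function(window_id, bias_center, bias_strength,
                           temperature, frames) {
  stopifnot(nrow(frames) >= 1L, bias_strength >= 0, temperature > 0)
  if (!all(c("energy", "global_q") %in% names(frames))) {
    stop("frames need 'energy' and 'global_q' columns", call. = FALSE)
  }
  structure(list(window_id = window_id, bias_center = bias_center,
                 bias_strength = bias_strength, temperature = temperature,
                 frames = frames),
            class = "window_samples")
}

#' @noRd
reduced_potential <- function(energy, global_q, temperature,
                              bias_strength = 0, bias_center = 0) {
  (energy + bias_strength * (global_q - bias_center)^2) / temperature
}

# Convex MBAR objective and gradient in the free energies f (gauge f[1]=0
# applied outside). logNf = log(N_k) + f_k.
#' @noRd
mbar_obj <- function(f, u, logN) {
  ell <- col_logsumexp(logN + f - u)          # length n
  sum(ell) - sum(exp(logN) * f)
}

#' @noRd
mbar_grad <- function(f, u, logN) {
  ell <- col_logsumexp(logN + f - u)
  W <- exp(sweep(f - u, 2L, ell, "-"))        # K x n, rows sum to e^{-f}...
  exp(logN) * (rowSums(W) - 1)
}

#' Solve the MBAR self-consistent equations
#'
#' Pools the frames of all windows, solves for the window free energies
#' f_k (gauge f_1 = 0) by minimizing the convex MBAR objective (BFGS with
#' analytic gradient) followed by self-consistent iteration until the
#' maximum per-iteration change in any f_k falls below `tol`, and exposes
#' normalized per-frame weights at any target (unbiased) temperature.
#'
#' @param windows List of `window_samples`.
#' @param tol Convergence tolerance on max |delta f| (default 1e-8).
#' @param max_iter Maximum self-consistent iterations (default 10000).
#' @param n_boot Number of block-bootstrap resamples for standard errors
#'   (default 0 = none; resamples are warm-started from the converged
#'   solution, blocks drawn within windows).
#' @param seed Seed for the bootstrap resampling.
#' @return An `mbar_fit` with window free energies `f` (dimensionless),
#'   pooled frame data, and bootstrap machinery used by
#'   [macrobasin_free_energies()].
#' @export
mbar_solve <- function(windows, tol = 1e-8, max_iter = 10000L,
                       n_boot = 0L, seed = 1L) {
  stopifnot(length(windows) >= 1L)
  K <- length(windows)
  Nk <- vapply(windows, function(w) nrow(w$frames), integer(1))
  energy <- unlist(lapply(windows, function(w) w$frames$energy))
  gq <- unlist(lapply(windows, function(w) w$frames$global_q))
  n <- length(energy)
  if (any(!is.finite(energy)) || any(!is.finite(gq))) {
    stop("non-finite energy or global_q in window frames", call. = FALSE)
  }
  u <- matrix(0, K, n)  # u[k, n]: reduced potential of frame n in state k
  for (k in seq_len(K)) {
    w <- windows[[k]]
    u[k, ] <- reduced_potential(energy, gq, w$temperature,
                                w$bias_strength, w$bias_center)
  }
  logN <- log(Nk)

  solve_f <- function(u, logN, f0) {
    free <- seq_along(logN)[-1L]  # gauge: f[1] = 0
    if (length(free) > 0L) {
      fn <- function(ff) mbar_obj(c(0, ff), u, logN)
      gr <- function(ff) mbar_grad(c(0, ff), u, logN)[free]
      opt <- stats::optim(f0[free], fn, gr, method = "BFGS",
                          control = list(maxit = 500L, reltol = 1e-14))
      f <- c(0, opt$par)
    } else f <- 0
    # self-consistent polish: f_k <- -log sum_n exp(-u_kn) / D_n
    for (it in seq_len(max_iter)) {
      ell <- col_logsumexp(logN + f - u)
      fnew <- -apply(-u - matrix(ell, nrow(u), length(ell), byrow = TRUE),
                     1L, logsumexp)
      fnew <- fnew - fnew[1L]
      delta <- max(abs(fnew - f))
      f <- fnew
      if (delta < tol) return(list(f = f, residual = delta, iter = it))
    }
    stop(sprintf(
      "MBAR failed to converge in %d iterations (residual %.3e > tol %.3e)",
      max_iter, delta, tol), call. = FALSE)
  }

  sol <- solve_f(u, logN, rep(0, K))
  f <- sol$f
  ell <- col_logsumexp(logN + f - u)  # log denominator per frame

  # overlap diagnostic: the MBAR overlap matrix O_kl = sum_n W_kn W_ln N_l
  # (W_kn the normalized weight of frame n in state k). Windows whose
  # overlap graph is disconnected yield large-variance relative free
  # energies, so warn (not error).
  W <- exp(sweep(f - u, 2L, ell, "-"))  # rows sum to 1 at the solution
  O <- W %*% (t(W) * Nk)
  conn <- (O + t(O)) / 2 > 1e-3
  reach <- conn | diag(TRUE, K)
  for (i in seq_len(K)) reach <- reach | (reach %*% reach) > 0
  if (K > 1L && !all(reach)) {
    warning("poor overlap: umbrella windows form ",
            "disconnected groups; free-energy differences between them ",
            "have large variance", call. = FALSE)
  }

  boot <- NULL
  if (n_boot > 0L) {
    set.seed(seed)
    win_of <- rep(seq_len(K), Nk)
    starts <- c(0L, cumsum(Nk)[-K])
    boot <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(seq_len(K), function(k) {
        nk <- Nk[k]
        blk <- max(1L, floor(sqrt(nk)))
        nblk <- ceiling(nk / blk)
        st <- sample.int(nk - blk + 1L, nblk, replace = TRUE)
        (starts[k] + unlist(lapply(st, function(s) s:(s + blk - 1L))))[1:nk]
      }))
      sb <- solve_f(u[, idx, drop = FALSE], logN, f)
      boot[[b]] <- list(idx = idx, f = sb$f,
                        ell = col_logsumexp(logN + sb$f -
                                            u[, idx, drop = FALSE]))
    }
  }

  structure(list(f = f, ell = ell, energy = energy, global_q = gq,
                 Nk = Nk, windows = windows, residual = sol$residual,
                 iterations = sol$iter, overlap = O, boot = boot),
            class = "mbar_fit")
}

#' Normalized frame weights at a target temperature
#'
#' Weights of the pooled frames in the unbiased ensemble at temperature
#' `temperature`; they sum to 1.
#'
#' @param fit An `mbar_fit`.
#' @param temperature Target temperature (model units).
#' @return Numeric vector of weights, one per pooled frame.
#' @export
mbar_weights <- function(fit, temperature) {
  lw <- -fit$energy / temperature - fit$ell
  w <- exp(lw - logsumexp(lw))
  w / sum(w)
}

#' Macrobasin free energies from MBAR weights
#'
#' F_a = -ln(sum of weights of frames labelled a), in units of k_B*T at the
#' target temperature, shifted so the gauge label has F = 0. Only labels
#' with nonzero weight appear.
#'
#' @param fit An `mbar_fit`, or a bare numeric vector of normalized weights.
#' @param labels Character vector of macrobasin labels aligned with the
#'   pooled frames (or with the weight vector).
#' @param temperature Target temperature (used to compute weights when `fit`
#'   is an `mbar_fit`; recorded in the table either way).
#' @param gauge Reference label set to F = 0: `"unfolded"` (the all-zeros
#'   label when present, else the lowest-F label), `"min"`, or an explicit
#'   label string.
#' @return A `free_energy_table`: data frame with columns `label`, `F_kT`,
#'   `stderr_kT`; attributes `temperature` and `gauge`.
#' @export
macrobasin_free_energies <- function(fit, labels, temperature,
                                     gauge = "unfolded") {
  if (inherits(fit, "mbar_fit")) {
    w <- mbar_weights(fit, temperature)
  } else {
    w <- as.numeric(fit)
    if (abs(sum(w) - 1) > 1e-8) stop("weights must be normalized",
                                     call. = FALSE)
  }
  if (length(labels) != length(w)) {
    stop("labels not aligned with weights", call. = FALSE)
  }
  check_labels(labels)
  mass <- vapply(split(w, labels), sum, numeric(1))
  mass <- mass[mass > 0]
  F <- -log(mass)
  F <- F[order(names(F))]
  gl <- resolve_gauge(gauge, names(F), F)
  F <- F - F[[gl]]

  se <- rep(NA_real_, length(F))
  if (inherits(fit, "mbar_fit") && !is.null(fit$boot)) {
    bF <- sapply(fit$boot, function(b) {
      lw <- -fit$energy[b$idx] / temperature - b$ell
      wb <- exp(lw - logsumexp(lw))
      mb <- vapply(split(wb, labels[b$idx]), sum, numeric(1))
      Fb <- -log(mb[names(F)])
      Fb - Fb[[gl]]
    })
    se <- apply(matrix(bF, nrow = length(F)), 1L, stats::sd)
  }

  out <- data.frame(label = names(F), F_kT = unname(F), stderr_kT = se,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "temperature") <- temperature
  attr(out, "gauge") <- gl
  class(out) <- c("free_energy_table", "data.frame")
  out
}

#' @noRd
resolve_gauge <- function(gauge, labels, F) {
  unfolded <- strrep("0", nchar(labels[1L]))
  if (identical(gauge, "unfolded")) {
    if (unfolded %in% labels) unfolded else labels[which.min(F)]
  } else if (identical(gauge, "min")) {
    labels[which.min(F)]
  } else {
    if (!gauge %in% labels) {
      stop("gauge label '", gauge, "' has zero weight / is unsampled",
           call. = FALSE)
    }
    gauge
  }
}

#' Folded-unfolded stability from a free-energy table
#'
#' Returns F(all-ones) - F(all-zeros) in k_B*T: negative values mean the
#' fully folded macrobasin is more stable.
#'
#' @param table A `free_energy_table`.
#' @return Stability in k_B*T.
#' @export
stability <- function(table) {
  n <- nchar(table$label[1L])
  folded <- strrep("1", n); unfolded <- strrep("0", n)
  missing <- setdiff(c(folded, unfolded), table$label)
  if (length(missing) > 0L) {
    stop("endpoint macrobasin(s) unsampled: ",
         paste(missing, collapse = ", "),
         " - chevron point undefined", call. = FALSE)
  }
  table$F_kT[table$label == folded] - table$F_kT[table$label == unfolded]
}

#' Write / read free-energy tables as TSV
#'
#' Columns: `temperature`, `label`, `F_kT`, `stderr_kT`.
#' @param table A `free_energy_table`.
#' @param path File path.
#' @export
write_free_energy_table <- function(table, path) {
  df <- data.frame(temperature = attr(table, "temperature"),
                   label = table$label, F_kT = table$F_kT,
                   stderr_kT = table$stderr_kT)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_free_energy_table
#' @export
read_free_energy_table <- function(path) {
  df <- utils::read.delim(path, colClasses = c(label = "character"))
  out <- data.frame(label = df$label, F_kT = df$F_kT,
                    stderr_kT = df$stderr_kT, stringsAsFactors = FALSE)
  attr(out, "temperature") <- df$temperature[1L]
  attr(out, "gauge") <- out$label[which(out$F_kT == 0)[1L]]
  class(out) <- c("free_energy_table", "data.frame")
  out
}
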