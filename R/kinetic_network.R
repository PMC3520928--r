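# Locally connected master equation over sampled macrobasins.
#
# Index convention (stated everywhere): entry K[b, a] (row b, column a) is
# the rate of the transition a -> b; every column sums to zero so that
# dP/dt = K %*% P conserves probability.

#' Hamming-1 connectivity between sampled macrobasins
#'
#' Edges join exactly those label pairs differing in a single foldon bit;
#' unsampled labels contribute no nodes or edges.
#'
#' @param labels Character vector (or set) of macrobasin labels of common
#'   length.
#' @return Data frame of undirected edges `from`, `to` with `from < to`
#'   lexicographically.
#' @export
build_connectivity <- function(labels) {
  labels <- sort(unique(as.character(labels)))
  check_labels(labels)
  n <- length(labels)
  bits <- do.call(rbind, strsplit(labels, ""))
  from <- character(0); to <- character(0)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      d <- rowSums(bits[(a + 1L):n, , drop = FALSE] !=
                   matrix(bits[a, ], n - a, ncol(bits), byrow = TRUE))
      hit <- which(d == 1L) + a
      from <- c(from, rep(labels[a], length(hit)))
      to <- c(to, labels[hit])
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Build the master-equation rate matrix
#'
#' For each Hamming-1 connected pair a -> b the rate is the universal
#' downhill rate k0 when the move is downhill or flat in free energy
#' (F_b - F_a <= 0) and k0 * exp(-(F_b - F_a)) otherwise, with free energies
#' in k_B*T. Diagonal entries are minus the column sums, conserving
#' probability. The construction satisfies detailed balance with respect to
#' pi ~ exp(-F).
#'
#' @param table A `free_energy_table`.
#' @param k0 Universal downhill rate in 1/s (default 1e6, the folding speed
#'   limit).
#' @return A `rate_matrix`: square matrix with `dimnames` the sorted labels,
#'   attributes `k0` and `temperature`.
#' @export
build_rate_matrix <- function(table, k0 = 1e6) {
  stopifnot(nrow(table) >= 1L, k0 > 0)
  labels <- sort(table$label)
  F <- stats::setNames(table$F_kT, table$label)[labels]
  K <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  edges <- build_connectivity(labels)
  for (e in seq_len(nrow(edges))) {
    a <- edges$from[e]; b <- edges$to[e]
    dF <- F[[b]] - F[[a]]
    K[b, a] <- if (dF <= 0) k0 else k0 * exp(-dF)   # a -> b
    K[a, b] <- if (-dF <= 0) k0 else k0 * exp(dF)   # b -> a
  }
  diag(K) <- 0
  diag(K) <- -colSums(K)
  attr(K, "k0") <- k0
  attr(K, "temperature") <- attr(table, "temperature")
  attr(K, "F_kT") <- F
  class(K) <- c("rate_matrix", "matrix")
  K
}

#' @noRd
stationary_distribution <- function(K) {
  F <- attr(K, "F_kT")
  if (!is.null(F)) {
    p <- exp(-(F - min(F)))
  } else {
    ev <- eigen(unclass(K))
    p <- abs(Re(ev$vectors[, which.min(abs(ev$values))]))
  }
  p / sum(p)
}

#' Spectral decomposition of the rate matrix
#'
#' Diagonalizes K through the detailed-balance symmetrization
#' S = diag(pi^-1/2) K diag(pi^1/2), which is symmetric and therefore has a
#' real spectrum; eigenvalues are sorted descending with the zero mode
#' first, and its eigenvector is proportional to the Boltzmann weights.
#' If K violates detailed balance beyond tolerance a general (possibly
#' complex) eigensolver is used with a warning.
#'
#' @param K A `rate_matrix`.
#' @param P0 Optional initial population vector (named or in label order);
#'   when given, mode coefficients `c = V^-1 P0` are attached.
#' @return A `spectral_decomposition`: list with `values` (eigenvalues,
#'   descending), `vectors` (columns = modes), `vectors_inv`, `pi`
#'   (stationary distribution), `labels`, `coefficients` (or NULL).
#' @export
spectral_solve <- function(K, P0 = NULL) {
  labels <- rownames(K)
  Km <- unclass(K)
  p <- stationary_distribution(K)
  db <- Km * rep(p, each = nrow(Km))  # K[b,a] * pi_a
  if (max(abs(db - t(db))) > 1e-8 * max(abs(Km))) {
    warning("rate matrix violates detailed balance; using general solver",
            call. = FALSE)
    ev <- eigen(Km)
    ord <- order(Re(ev$values), decreasing = TRUE)
    V <- ev$vectors[, ord, drop = FALSE]
    lam <- ev$values[ord]
    Vinv <- solve(V)
  } else {
    s <- sqrt(p)
    S <- Km * outer(1 / s, s)          # symmetric under detailed balance
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)   # already sorted descending
    lam <- es$values
    V <- es$vectors * s                # back-transform: V = D^{1/2} U
    Vinv <- t(es$vectors) * rep(1 / s, each = length(s))
  }
  co <- NULL
  if (!is.null(P0)) {
    P0 <- normalize_populations(P0, labels)
    co <- as.numeric(Vinv %*% P0)
  }
  structure(list(values = lam, vectors = V, vectors_inv = Vinv,
                 pi = p, labels = labels, coefficients = co,
                 k0 = attr(K, "k0") %||% 1),
            class = "spectral_decomposition")
}

#' @noRd
normalize_populations <- function(P0, labels) {
  if (!is.null(names(P0))) {
    v <- stats::setNames(rep(0, length(labels)), labels)
    v[names(P0)] <- P0
    P0 <- v
  }
  if (length(P0) != length(labels)) {
    stop("initial populations do not match the label set", call. = FALSE)
  }
  if (any(P0 < -1e-12) || abs(sum(P0) - 1) > 1e-8) {
    stop("initial populations must be nonnegative and sum to 1",
         call. = FALSE)
  }
  as.numeric(P0)
}

#' Propagate populations in time
#'
#' P(t) = sum_n c_n V_n exp(lambda_n t): the spectral solution of the
#' master equation. Populations stay normalized and converge to the
#' Boltzmann distribution.
#'
#' @param decomp A `spectral_decomposition`.
#' @param P0 Initial population vector (named or in label order).
#' @param times Numeric vector of times (same units as 1/rates).
#' @return Matrix of populations: rows = times, columns = labels.
#' @export
propagate <- function(decomp, P0, times) {
  P0 <- normalize_populations(P0, decomp$labels)
  co <- as.numeric(decomp$vectors_inv %*% P0)
  out <- vapply(times, function(t) {
    as.numeric(Re(decomp$vectors %*% (co * exp(decomp$values * t))))
  }, numeric(length(decomp$labels)))
  out <- t(matrix(out, nrow = length(decomp$labels)))
  colnames(out) <- decomp$labels
  rownames(out) <- as.character(times)
  if (any(out < -1e-6)) {
    stop("propagation produced negative populations beyond tolerance",
         call. = FALSE)
  }
  out
}

#' Observed relaxation rate
#'
#' The magnitude of the largest eigenvalue strictly below zero; the spectral
#' gap ratio lambda_1 / lambda_2 is attached to flag multi-exponential
#' regimes (values near 1 mean several comparable slow modes).
#'
#' @param decomp A `spectral_decomposition`.
#' @return `k_obs` (1/s) with attribute `gap_ratio`.
#' @export
relaxation_rate <- function(decomp) {
  lam <- Re(decomp$values)
  tol <- 1e-10 * decomp$k0
  zero <- sum(lam > -tol)
  if (zero > 1L) {
    stop(zero, " zero modes: sampled network is disconnected", call. = FALSE)
  }
  nz <- lam[lam <= -tol]
  if (length(nz) == 0L) stop("need >= 2 states for a relaxation rate",
                             call. = FALSE)
  k <- abs(nz[1L])
  attr(k, "gap_ratio") <- if (length(nz) >= 2L) nz[1L] / nz[2L] else NA_real_
  k
}

#' Thermal chevron scan
#'
#' For each free-energy table (one per temperature) with both the fully
#' folded and fully unfolded macrobasins sampled, computes the
#' folded-unfolded stability and the log10 relaxation rate of the rate
#' matrix built from that table. Temperatures whose endpoints are unsampled
#' are skipped and reported.
#'
#' @param tables List of `free_energy_table`s.
#' @param k0 Universal downhill rate (1/s).
#' @return A `chevron_curve`: data frame `temperature`, `stability_kT`,
#'   `log10_rate`, sorted by stability; skipped temperatures in attribute
#'   `skipped`.
#' @export
chevron_scan <- function(tables, k0 = 1e6) {
  stopifnot(length(tables) >= 1L)
  rows <- list(); skipped <- numeric(0)
  for (tab in tables) {
    temp <- attr(tab, "temperature")
    ok <- tryCatch({
      st <- stability(tab)
      K <- build_rate_matrix(tab, k0)
      kobs <- relaxation_rate(spectral_solve(K))
      rows[[length(rows) + 1L]] <-
        data.frame(temperature = temp, stability_kT = st,
                   log10_rate = log10(as.numeric(kobs)))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) skipped <- c(skipped, temp)
  }
  if (length(rows) < 2L) {
    stop("need >= 2 temperatures with both endpoints sampled", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$stability_kT), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("chevron_curve", "data.frame")
  out
}

#' Write a rate matrix as an edge-list TSV
#'
#' Columns: `from_label`, `to_label`, `rate_per_s` (off-diagonal entries
#' only, sorted).
#' @param K A `rate_matrix`.
#' @param path File path.
#' @export
write_rate_matrix <- function(K, path) {
  labels <- rownames(K)
  idx <- which(unclass(K) > 0 & row(K) != col(K), arr.ind = TRUE)
  df <- data.frame(from_label = labels[idx[, 2L]],
                   to_label = labels[idx[, 1L]],
                   rate_per_s = K[idx])
  df <- df[order(df$from_label, df$to_label), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
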