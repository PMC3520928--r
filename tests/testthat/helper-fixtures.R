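# Fixtures and independent oracles, all built in code.

# Minimal PDB text from a coordinate matrix (CA-only, chain A by default).
make_pdb <- function(coords, chain = "A", resnames = NULL, skip_ca = integer(0),
                     altloc_rows = NULL) {
  n <- nrow(coords)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    if (i %in% skip_ca) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CB  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, resnames[i], chain, i, coords[i, 1], coords[i, 2], coords[i, 3]))
      next
    }
    alts <- if (!is.null(altloc_rows) && i %in% altloc_rows) {
      list(c("A", 0.4, 99), c("B", 0.6, 0))  # B wins on occupancy
    } else list(c(" ", 1.0, 0))
    for (a in alts) {
      serial <- serial + 1L
      off <- as.numeric(a[3])
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA %s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
        serial, a[1], resnames[i], chain, i,
        coords[i, 1] + off, coords[i, 2], coords[i, 3], as.numeric(a[2])))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# Collinear CA trace spaced `d` Angstrom apart along x.
collinear_coords <- function(n, d = 3.8) {
  cbind(x = d * (seq_len(n) - 1), y = 0, z = 0)
}

# A compact 3D fold: points on a coarse helix so that non-trivial contacts
# exist at moderate sequence separation.
helix_coords <- function(n, radius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  t <- seq_len(n)
  cbind(radius * cos(turn * t), radius * sin(turn * t), rise * t)
}

# Random free-energy table over all 2^n labels (k_BT units, gauge 0...0).
random_fe_table <- function(n, spread = 3, temperature = 1) {
  labels <- sort(vapply(0:(2^n - 1), function(s) {
    paste(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L), collapse = "")
  }, character(1)))
  F <- stats::runif(length(labels), -spread, spread)
  F <- F - F[labels == strrep("0", n)]
  out <- data.frame(label = labels, F_kT = F, stderr_kT = 0,
                    stringsAsFactors = FALSE)
  attr(out, "temperature") <- temperature
  attr(out, "gauge") <- strrep("0", n)
  class(out) <- c("free_energy_table", "data.frame")
  out
}

# Independent ODE oracle: fixed-step classical RK4 for dP/dt = K P.
rk4_propagate <- function(K, P0, times, dt = NULL) {
  K <- unclass(K)
  if (is.null(dt)) dt <- 0.02 / max(abs(diag(K)))
  deriv <- function(P) as.numeric(K %*% P)
  out <- matrix(NA_real_, length(times), length(P0))
  ord <- order(times)
  t_cur <- 0
  P <- as.numeric(P0)
  for (ti in ord) {
    target <- times[ti]
    while (t_cur < target - 1e-15) {
      h <- min(dt, target - t_cur)
      k1 <- deriv(P)
      k2 <- deriv(P + h / 2 * k1)
      k3 <- deriv(P + h / 2 * k2)
      k4 <- deriv(P + h * k3)
      P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t_cur <- t_cur + h
    }
    out[ti, ] <- P
  }
  out
}

# Exhaustive widest-bottleneck path oracle over positive-flux edges.
brute_bottleneck_path <- function(J, source, sink) {
  labels <- rownames(J)
  best <- list(width = -Inf, path = NULL)
  recurse <- function(node, visited, width) {
    if (node == sink) {
      key_new <- paste(c(visited), collapse = ",")
      if (width > best$width ||
          (width == best$width &&
           key_new < paste(best$path, collapse = ","))) {
        best <<- list(width = width, path = visited)
      }
      return(invisible())
    }
    for (v in labels[J[, node] > 0]) {
      if (!(v %in% visited)) {
        recurse(v, c(visited, v), min(width, J[v, node]))
      }
    }
  }
  recurse(source, source, Inf)
  best
}

# Small random synthetic landscape with heterogeneous parameters.
random_landscape <- function(n, seed) {
  set.seed(seed)
  synthetic_landscape(n,
                      epsilon = stats::runif(n, 0.5, 3),
                      entropy = stats::runif(n, 0.5, 2.5),
                      coupling = if (n > 1) stats::runif(n - 1, 0, 2) else 0,
                      seed = seed)
}
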