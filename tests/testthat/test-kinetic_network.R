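test_that("connectivity is exactly the Hamming-1 graph", {
  expect_equal(nrow(build_connectivity(c("0000", "0001"))), 1L)
  expect_equal(nrow(build_connectivity(c("0101", "1010"))), 0L)
  labs3 <- vapply(0:7, function(s) {
    paste(bitwAnd(bitwShiftR(s, 0:2), 1L), collapse = "")
  }, character(1))
  edges <- build_connectivity(labs3)
  expect_equal(nrow(edges), 3 * 2^2)  # N * 2^(N-1)
  # brute-force pairwise Hamming oracle
  brute <- 0L
  for (a in 1:7) for (b in (a + 1):8) {
    if (sum(strsplit(labs3[a], "")[[1]] != strsplit(labs3[b], "")[[1]]) == 1) {
      brute <- brute + 1L
    }
  }
  expect_equal(nrow(edges), brute)
  expect_error(build_connectivity(c("01", "001")), "mixed")
})

test_that("rate matrix implements the downhill-rate rule", {
  tab <- random_fe_table(1)
  tab$F_kT <- c(0, -2)  # folding is downhill by 2 kBT
  K <- build_rate_matrix(tab, k0 = 5)
  expect_equal(K["1", "0"], 5)            # downhill at k0
  expect_equal(K["0", "1"], 5 * exp(-2))  # uphill penalized
  expect_equal(colSums(unclass(K)), c("0" = 0, "1" = 0), tolerance = 1e-12)
})

test_that("random rate matrices conserve probability and obey detailed balance", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    tab <- random_fe_table(n)
    K <- build_rate_matrix(tab, k0 = 1)
    expect_lt(max(abs(colSums(unclass(K)))), 1e-12)
    p <- exp(-tab$F_kT); p <- p / sum(p)
    names(p) <- tab$label
    for (e in seq_len(nrow(tab))) {
      a <- tab$label[e]
      for (b in tab$label) {
        expect_lt(abs(K[b, a] * p[a] - K[a, b] * p[b]), 1e-12)
      }
    }
    # off-diagonal support confined to Hamming-1 pairs
    for (a in tab$label) for (b in tab$label) {
      if (a != b && K[b, a] != 0) {
        expect_equal(sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), 1L)
      }
    }
  }
})

test_that("spectral solve: analytic two-state eigenvalues and zero mode", {
  flat <- random_fe_table(1); flat$F_kT <- c(0, 0)
  d1 <- spectral_solve(build_rate_matrix(flat, k0 = 1))
  expect_equal(sort(d1$values), c(-2, 0), tolerance = 1e-12)

  tilt <- random_fe_table(1); tilt$F_kT <- c(0, -1)
  d2 <- spectral_solve(build_rate_matrix(tilt, k0 = 1))
  expect_equal(min(d2$values), -(1 + exp(-1)), tolerance = 1e-12)

  set.seed(11)
  tab <- random_fe_table(4)
  K <- build_rate_matrix(tab, k0 = 1)
  dec <- spectral_solve(K)
  expect_lt(abs(dec$values[1]), 1e-10)
  expect_true(all(dec$values <= 1e-10))
  # zero-mode eigenvector is proportional to the Boltzmann weights
  v0 <- dec$vectors[, 1]
  boltz <- exp(-tab$F_kT); boltz <- boltz / sum(boltz)
  expect_equal(v0 / sum(v0), boltz, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("propagate matches RK4 integration and the analytic 2-state decay", {
  tab <- random_fe_table(1); tab$F_kT <- c(0, -1.5)
  K <- build_rate_matrix(tab, k0 = 1)
  dec <- spectral_solve(K)
  P0 <- c("0" = 1, "1" = 0)
  times <- c(0, 0.3, 1, 3)
  P <- propagate(dec, P0, times)
  expect_equal(unname(P[1, ]), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
  # analytic relaxation: P_folded(t) = pi_f (1 - exp(-(kf + ku) t))
  kf <- 1; ku <- exp(-1.5)
  pif <- kf / (kf + ku)
  expect_equal(unname(P[, "1"]), pif * (1 - exp(-(kf + ku) * times)),
               tolerance = 1e-10)
  # long-time limit is Boltzmann
  Pinf <- propagate(dec, P0, 200)
  expect_equal(unname(Pinf[1, ]), c(1 - pif, pif), tolerance = 1e-8)
  # independent RK4 oracle on a random 4-foldon instance
  set.seed(12)
  tab4 <- random_fe_table(4)
  K4 <- build_rate_matrix(tab4, k0 = 1)
  dec4 <- spectral_solve(K4)
  P04 <- as.numeric(rownames(K4) == "0000")
  tt <- c(0.1, 0.5, 2)
  Pspec <- propagate(dec4, P04, tt)
  Pode <- rk4_propagate(K4, P04, tt)
  expect_lt(max(abs(Pspec - Pode)), 1e-8)
})

test_that("relaxation rate picks the slowest nonzero mode and flags gaps", {
  flat <- random_fe_table(1); flat$F_kT <- c(0, 0)
  k <- relaxation_rate(spectral_solve(build_rate_matrix(flat, k0 = 1)))
  expect_equal(as.numeric(k), 2, tolerance = 1e-12)

  steep <- random_fe_table(1); steep$F_kT <- c(0, -30)
  k2 <- relaxation_rate(spectral_solve(build_rate_matrix(steep, k0 = 1)))
  expect_equal(as.numeric(k2), 1, tolerance = 1e-10)

  set.seed(13)
  tab <- random_fe_table(3)
  dec <- spectral_solve(build_rate_matrix(tab, k0 = 1))
  expect_false(is.na(attr(relaxation_rate(dec), "gap_ratio")))

  # a disconnected sampled set has multiple zero modes
  disc <- data.frame(label = c("000", "011"), F_kT = c(0, 0),
                     stderr_kT = 0)
  attr(disc, "temperature") <- 1
  class(disc) <- c("free_energy_table", "data.frame")
  Kd <- build_rate_matrix(disc, k0 = 1)
  expect_error(relaxation_rate(spectral_solve(Kd)), "disconnected")
})

test_that("chevron scan: analytic V for one foldon, k0 linearity", {
  mk <- function(dF, Tt) {
    tab <- data.frame(label = c("0", "1"), F_kT = c(0, dF), stderr_kT = 0,
                      stringsAsFactors = FALSE)
    attr(tab, "temperature") <- Tt
    class(tab) <- c("free_energy_table", "data.frame")
    tab
  }
  dFs <- seq(-10, 10, by = 0.5)
  tabs <- Map(mk, dFs, seq_along(dFs))
  ch <- chevron_scan(tabs, k0 = 1)
  expect_equal(ch$stability_kT, dFs)
  expect_equal(ch$log10_rate, log10(1 + exp(-abs(dFs))), tolerance = 1e-10)
  expect_equal(ch$stability_kT[which.min(ch$log10_rate)][1], -10)
  expect_equal(min(10^ch$log10_rate[ch$stability_kT == 0]), 2)

  ch2 <- chevron_scan(tabs, k0 = 2)
  expect_equal(ch2$log10_rate - ch$log10_rate,
               rep(log10(2), length(dFs)), tolerance = 1e-12)

  # temperatures with unsampled endpoints are skipped and reported
  broken <- mk(0, 99); broken <- broken[1, , drop = FALSE]
  attr(broken, "temperature") <- 99
  class(broken) <- c("free_energy_table", "data.frame")
  ch3 <- chevron_scan(c(tabs[1:3], list(broken)), k0 = 1)
  expect_equal(attr(ch3, "skipped"), 99)
})
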