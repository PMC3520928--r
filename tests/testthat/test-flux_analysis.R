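two_state_table <- function(dF) {
  tab <- data.frame(label = c("0", "1"), F_kT = c(0, dF), stderr_kT = 0,
                    stringsAsFactors = FALSE)
  attr(tab, "temperature") <- 1
  class(tab) <- c("free_energy_table", "data.frame")
  tab
}

test_that("two-state cumulative flux matches the analytic integral", {
  tab <- two_state_table(-1.2)
  K <- build_rate_matrix(tab, k0 = 1)
  dec <- spectral_solve(K)
  pif <- exp(1.2) / (1 + exp(1.2))
  P0 <- c("0" = 1, "1" = 0)
  # tau = Inf: all initial unfolded population ends up folded
  J <- cumulative_flux(dec, K, P0, Inf)
  expect_equal(J["1", "0"], pif, tolerance = 1e-12)
  expect_equal(J["0", "1"], -pif, tolerance = 1e-12)
  # tau = 0 gives the zero matrix; finite tau interpolates monotonically
  expect_equal(max(abs(unclass(cumulative_flux(dec, K, P0, 0)))), 0,
               tolerance = 1e-14)
  taus <- c(0.2, 0.5, 1, 2, 5)
  js <- vapply(taus, function(tau) {
    cumulative_flux(dec, K, P0, tau)["1", "0"]
  }, numeric(1))
  # instantaneous net flux from all-unfolded is pi_F * lam * e^(-lam t),
  # so J(tau) = pi_F (1 - e^(-lam tau))
  lam <- 1 + exp(-1.2)
  expect_equal(js, pif * (1 - exp(-lam * taus)), tolerance = 1e-12)
  expect_true(all(diff(abs(js)) > 0))  # tau-monotone convergence
})

test_that("equilibrium start yields zero flux; antisymmetry holds everywhere", {
  set.seed(20)
  for (rep in 1:10) {
    tab <- random_fe_table(3)
    K <- build_rate_matrix(tab, k0 = 1)
    dec <- spectral_solve(K)
    Jeq <- cumulative_flux(dec, K, dec$pi, Inf)
    expect_lt(max(abs(unclass(Jeq))), 1e-10)
    P0 <- as.numeric(rownames(K) == "000")
    J <- cumulative_flux(dec, K, P0, Inf)
    expect_lt(max(abs(unclass(J) + t(unclass(J)))), 1e-12)
    # support confined to Hamming-1 edges
    for (a in rownames(J)) for (b in rownames(J)) {
      if (a != b && abs(J[b, a]) > 0) {
        expect_equal(sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), 1L)
      }
    }
  }
})

test_that("flux conservation across every cut (4-foldon, ODE-checked)", {
  set.seed(21)
  tab <- random_fe_table(4)
  K <- build_rate_matrix(tab, k0 = 1)
  dec <- spectral_solve(K)
  labels <- rownames(K)
  P0 <- as.numeric(labels == "0000")
  J <- cumulative_flux(dec, K, P0, Inf)
  # every single-label cut plus 30 random cuts
  cuts <- c(as.list(labels),
            replicate(30, sample(labels, sample(1:15, 1)), simplify = FALSE))
  for (cut in cuts) {
    expect_lt(cut_balance(J, cut), 1e-10)
  }
  expect_equal(cut_balance(J, labels), 0, tolerance = 1e-12)
  # two-state analytic cut
  tab2 <- two_state_table(-0.7)
  K2 <- build_rate_matrix(tab2, k0 = 1)
  d2 <- spectral_solve(K2)
  J2 <- cumulative_flux(d2, K2, c("0" = 1, "1" = 0), Inf)
  pif <- exp(0.7) / (1 + exp(0.7))
  expect_equal(cut_balance(J2, "1"), 0, tolerance = 1e-12)
  expect_equal(J2["1", "0"] - (pif - 0), 0, tolerance = 1e-12)
})

test_that("spectral flux equals trapezoidal integration of instantaneous flux", {
  set.seed(22)
  tab <- random_fe_table(3)
  K <- build_rate_matrix(tab, k0 = 1)
  dec <- spectral_solve(K)
  P0 <- as.numeric(rownames(K) == "000")
  tau <- 4
  J <- cumulative_flux(dec, K, P0, tau)
  tt <- seq(0, tau, length.out = 4001)
  P <- propagate(dec, P0, tt)
  Km <- unclass(K); diag(Km) <- 0
  labels <- rownames(K)
  for (a in labels) for (b in labels) {
    if (sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) == 1) {
      inst <- Km[a, b] * P[, b] - Km[b, a] * P[, a]
      trap <- sum((inst[-1] + inst[-length(inst)]) / 2 * diff(tt))
      expect_equal(J[a, b], trap, tolerance = 1e-6)
    }
  }
})

test_that("DOT export is deterministic and honors the minimum line width", {
  tab2 <- two_state_table(-1)
  K2 <- build_rate_matrix(tab2, k0 = 1)
  d2 <- spectral_solve(K2)
  J2 <- cumulative_flux(d2, K2, c("0" = 1, "1" = 0), Inf)
  dot <- export_flux_dot(J2, tab2, min_width = 0.1)
  expect_match(dot, "digraph folding")
  expect_equal(length(gregexpr("->", dot)[[1]]), 1L)
  expect_match(dot, '"0" -> "1"', fixed = TRUE)
  expect_match(dot, "\\(-1\\.00\\)")  # free energy annotated in parentheses
  expect_identical(dot, export_flux_dot(J2, tab2, min_width = 0.1))

  # all-zero flux: every edge drawn at exactly the minimum width
  tab3 <- random_fe_table(2)[c(1, 2, 4), ]
  attr(tab3, "temperature") <- 1
  class(tab3) <- c("free_energy_table", "data.frame")
  J0 <- matrix(0, 3, 3, dimnames = list(tab3$label, tab3$label))
  class(J0) <- c("flux_matrix", "matrix")
  dot0 <- export_flux_dot(J0, tab3, min_width = 0.1)
  widths <- regmatches(dot0, gregexpr("penwidth=[0-9.]+", dot0))[[1]]
  expect_true(length(widths) >= 2)
  expect_true(all(widths == "penwidth=0.1000"))

  empty <- matrix(numeric(0), 0, 0)
  class(empty) <- c("flux_matrix", "matrix")
  expect_error(export_flux_dot(empty, tab3), "empty")
})

test_that("dominant pathway equals the brute-force bottleneck oracle", {
  # two-state and linear chain trivials
  tab2 <- two_state_table(-1)
  K2 <- build_rate_matrix(tab2, k0 = 1)
  J2 <- cumulative_flux(spectral_solve(K2), K2, c("0" = 1, "1" = 0), Inf)
  expect_equal(as.character(dominant_pathway(J2, "0", "1")), c("0", "1"))

  set.seed(23)
  for (rep in 1:8) {
    tab <- random_fe_table(4)
    K <- build_rate_matrix(tab, k0 = 1)
    dec <- spectral_solve(K)
    P0 <- as.numeric(rownames(K) == "0000")
    J <- cumulative_flux(dec, K, P0, Inf)
    got <- dominant_pathway(J, "0000", "1111")
    oracle <- brute_bottleneck_path(J, "0000", "1111")
    expect_equal(attr(got, "bottleneck"), oracle$width, tolerance = 1e-12)
    expect_equal(as.character(got), oracle$path)
  }

  # no positive-flux path errors
  Jz <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  class(Jz) <- c("flux_matrix", "matrix")
  expect_error(dominant_pathway(Jz, "0", "1"), "no positive-flux path")
})

test_that("flux tables round-trip deterministically through TSV", {
  set.seed(24)
  tab <- random_fe_table(3)
  K <- build_rate_matrix(tab, k0 = 1)
  J <- cumulative_flux(spectral_solve(K), K,
                       as.numeric(rownames(K) == "000"), Inf)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_flux_table(J, f1)
  write_flux_table(J, f2)
  expect_identical(readLines(f1), readLines(f2))
  df <- read.delim(f1, colClasses = c(from_label = "character",
                                      to_label = "character"))
  expect_true(all(df$net_flux > 0))
})
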