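test_that("gamma specs are moment-matched", {
  g <- gamma_from_mean_stdpct(200, 49.61)
  expect_equal(g$sd, 99.22)
  expect_equal(g$shape, (200 / 99.22)^2, tolerance = 1e-12)
  expect_equal(g$scale, 99.22^2 / 200, tolerance = 1e-12)
  expect_equal(g$shape * g$scale, 200, tolerance = 1e-12)
  expect_equal(g$shape * g$scale^2, 99.22^2, tolerance = 1e-12)

  e <- gamma_from_mean_stdpct(1, 100)   # exponential
  expect_equal(e$shape, 1)
  expect_equal(e$scale, 1)
  expect_error(gamma_from_mean_stdpct(-1, 10), "mean")

  # seeded Monte-Carlo moment check
  set.seed(11)
  x <- rgamma(1e6, shape = g$shape, scale = g$scale)
  expect_equal(mean(x), 200, tolerance = 0.01)
  expect_equal(sd(x), 99.22, tolerance = 0.01)
})

test_that("std-percentage reporting matches the published table", {
  expect_equal(std_pct_from_layer_stats(1.27, 0.63), 49.61)
  expect_equal(std_pct_from_layer_stats(21.6, 7.12), 32.96)
  expect_equal(std_pct_from_layer_stats(1.0, 0.0), 0)
})

test_that("basis polynomials are orthonormal under their gamma measure", {
  for (s in default_gamma_specs()) {
    gq <- gauss_gamma(20, s$shape, s$scale)
    P <- tpvuq:::eval_orthonormal(gq$nodes, 4, s$shape, s$scale)
    G <- t(P) %*% (gq$weights * P)
    expect_lt(max(abs(G - diag(5))), 1e-8)
  }
})

test_that("design size follows the basis-plus-oversample rule", {
  specs <- default_gamma_specs()
  X <- pce_design(specs, order = 4, oversample = 10, seed = 5)
  expect_equal(nrow(X), 136)
  expect_equal(ncol(X), 5)
  expect_true(all(X[, "kappa"] <= 1 / 3))
  expect_true(all(X > 0))

  X1 <- pce_design(specs["c"], order = 1, oversample = 0, seed = 5)
  expect_equal(nrow(X1), 2)   # C(2, 1)
  expect_error(pce_design(specs, oversample = -1), "oversample")

  # clipping rule piles rejected draws onto the bound instead
  Xc <- pce_design(specs, order = 4, oversample = 10, seed = 5,
                   kappa_rule = "clip")
  expect_true(any(Xc[, "kappa"] == 1 / 3))
})

test_that("the PCE reproduces degree-4 polynomials exactly", {
  specs <- default_gamma_specs()
  X <- pce_design(specs, order = 4, oversample = 10, seed = 2)
  f <- function(X) 2 + 3 * X[, 1] + 0.5 * X[, 2]^2 -
    0.01 * X[, 1] * X[, 3]^3 + 1e-4 * X[, 4]^4 + X[, 5]
  m <- pce(X, f(X), specs, order = 4)
  Xt <- tpvuq:::sample_gamma_product(specs, 300, seed = 77)
  expect_lt(max(abs(predict(m, Xt) - f(Xt))) / max(abs(f(Xt))), 1e-9)

  # constant output: only the mean coefficient survives
  mc <- pce(X, rep(7, nrow(X)), specs)
  expect_equal(unname(mc$coefficients[1]), 7)
  expect_lt(max(abs(mc$coefficients[-1])), 1e-10)
})

test_that("fitted coefficients match the quadrature projection oracle", {
  specs <- default_gamma_specs()[c("c", "k2", "kappa")]
  X <- tpvuq:::sample_gamma_product(specs, 100, seed = 8)
  f <- function(X) (X[, 1] / 200)^2 * X[, 2] + 3 * X[, 3] - 0.2 * X[, 2]^2
  m <- pce(X, f(X), specs, order = 4)

  # independent projection a_alpha = E[f phi_alpha] by tensor Gauss
  # quadrature (8 nodes/dim, exact through degree 15)
  gqs <- lapply(specs, function(s) gauss_gamma(8, s$shape, s$scale))
  nodes <- as.matrix(expand.grid(lapply(gqs, `[[`, "nodes")))
  w <- Reduce(`*`, as.data.frame(expand.grid(lapply(gqs, `[[`, "weights"))))
  Phi <- tpvuq:::pce_basis_matrix(nodes, m$indices, specs, 4)
  a_ref <- drop(t(Phi) %*% (w * f(nodes)))
  expect_lt(max(abs(unname(m$coefficients) - a_ref)) /
              max(abs(a_ref)), 1e-6)
})

test_that("Sobol indices match analytic ANOVA for test functions", {
  specs <- default_gamma_specs()
  X <- pce_design(specs, order = 4, oversample = 10, seed = 4)

  # additive: first-order equals total-order, indices sum to 1
  ya <- (X[, 1] - 200) / 99.22 + 2 * (X[, 4] - 18.85)
  sa <- sobol_indices(pce(X, ya, specs))
  expect_equal(sa$table$S_first, sa$table$S_total, tolerance = 1e-9)
  expect_equal(sum(sa$table$S_first), 1, tolerance = 1e-9)

  # pure product x1 * x2: closed-form gamma ANOVA
  y12 <- X[, 1] * X[, 2]
  s12 <- sobol_indices(pce(X, y12, specs))
  mu1 <- specs$c$mean; sd1 <- specs$c$sd
  mu2 <- specs$k1$mean; sd2 <- specs$k1$sd
  V <- (mu1^2 + sd1^2) * (mu2^2 + sd2^2) - mu1^2 * mu2^2
  expect_equal(s12$table$S_first[1], mu2^2 * sd1^2 / V, tolerance = 1e-6)
  expect_equal(s12$table$S_first[2], mu1^2 * sd2^2 / V, tolerance = 1e-6)
  expect_equal(s12$table$S_total[1], (mu2^2 * sd1^2 + sd1^2 * sd2^2) / V,
               tolerance = 1e-6)
  expect_gt(s12$table$S_total[1], s12$table$S_first[1])

  # constant output: all indices zero
  s0 <- sobol_indices(pce(X, rep(3, nrow(X)), specs))
  expect_true(all(s0$table$S_first == 0))
  expect_true(all(s0$table$S_total == 0))
  expect_equal(s0$variance, 0)
})

test_that("partial variances over all subsets sum to the total variance", {
  specs <- default_gamma_specs()
  X <- pce_design(specs, order = 4, oversample = 10, seed = 6)
  y <- X[, 1] * X[, 5] + X[, 2]^2 + sqrt(X[, 3])
  m <- pce(X, y, specs)
  a <- m$coefficients
  idx <- m$indices
  nz <- rowSums(idx) > 0
  support <- apply(idx > 0, 1, paste, collapse = "")
  partial <- tapply(a[nz]^2, support[nz], sum)
  expect_equal(sum(partial), sum(a[nz]^2), tolerance = 1e-10)
  expect_equal(sobol_indices(m)$variance, sum(a[nz]^2))
})

test_that("failed runs are dropped and under-determined fits rejected", {
  specs <- default_gamma_specs()
  X <- pce_design(specs, order = 4, oversample = 10, seed = 9)
  y <- X[, 1] + X[, 2]
  y[c(5, 50, 100)] <- NA
  m <- pce(X, y, specs)
  expect_equal(m$n_used, 133)
  expect_equal(m$n_failed, 3)
  y2 <- y
  y2[1:15] <- NA   # 121 survivors < 126 basis terms
  expect_error(pce(X, y2, specs), "under-determined")
})

test_that("the emulator is deterministic and matches gamma moments", {
  specs <- default_gamma_specs()
  X <- pce_design(specs, order = 4, oversample = 10, seed = 3)
  m <- pce(X, 5 + 2 * X[, 3], specs)
  q1 <- query_emulator(m, n = 1000, seed = 13)
  q2 <- query_emulator(m, n = 1000, seed = 13)
  expect_identical(q1$summary, q2$summary)
  expect_identical(q1$values, q2$values)
  # linear model in one gamma variable: sample mean within 3 SE
  se <- 2 * specs$k2$sd / sqrt(1000)
  expect_lt(abs(mean(q1$values) - (5 + 2 * specs$k2$mean)), 3 * se)

  mc <- pce(X, rep(4.2, nrow(X)), specs)
  qc <- query_emulator(mc, n = 50, seed = 1)
  expect_equal(unname(qc$summary["min"]), 4.2, tolerance = 1e-9)
  expect_equal(unname(qc$summary["max"]), 4.2, tolerance = 1e-9)
  expect_equal(unname(qc$summary["median"]), 4.2, tolerance = 1e-9)
})
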