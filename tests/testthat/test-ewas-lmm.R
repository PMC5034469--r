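# Normalisation, mixed-model fitting oracles, LRT behaviour, Bonferroni.

test_that("z-score and inverse-normal normalisation behave as specified", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 2, 2, 2, 2),
             c = c(10, 3, 7, 1, 9))
  z <- normalise_windows(m, "zscore")
  expect_equal(unname(rowMeans(z[c("a", "c"), ])), c(0, 0))
  expect_equal(unname(apply(z[c("a", "c"), ], 1, sd)), c(1, 1))
  expect_equal(attr(z, "flagged"), "b")
  expect_true(all(z["b", ] == 0))

  # rank-based normal scores are invariant to strictly monotone transforms
  i1 <- normalise_windows(m[c("a", "c"), ], "inverse_normal")
  i2 <- normalise_windows(exp(m[c("a", "c"), ] / 2), "inverse_normal")
  expect_equal(i1[, ], i2[, ], tolerance = 1e-12)

  r <- normalise_windows(m, "none")
  expect_equal(r[, ], m)
})

test_that("Bonferroni threshold reproduces the genome-wide cut-off", {
  thr <- bonferroni_threshold(2708462)
  expect_equal(thr, 0.05 / 2708462)
  expect_equal(signif(thr, 3), 1.85e-8)
  expect_lt(thr, 1.85e-8)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 2.5e-3)
  expect_error(bonferroni_threshold(0))
})

make_family_data <- function(n_fam = 40, seed = 1, fam_sd = 0, pair_sd = 0,
                             sigma = 1) {
  set.seed(seed)
  d <- data.frame(family_id = factor(rep(sprintf("F%02d", 1:n_fam), each = 2)),
                  pair_id = factor(rep(sprintf("P%02d", 1:n_fam), each = 2)),
                  age = rep(runif(n_fam, 20, 80), each = 2),
                  x = rnorm(2 * n_fam))
  u <- rnorm(n_fam, 0, fam_sd) + rnorm(n_fam, 0, pair_sd)
  d$y <- 1 + 0.05 * d$age + 0.3 * d$x + u[as.integer(d$family_id)] +
    rnorm(2 * n_fam, 0, sigma)
  d
}

test_that("with zero variance components the LMM collapses to OLS", {
  d <- make_family_data(n_fam = 40, seed = 2, fam_sd = 0, pair_sd = 0)
  f <- fit_lmm(d$y, d, ~ age + x)
  ols <- lm(y ~ age + x, d)
  expect_lt(max(abs(f$beta - coef(ols))), 1e-6)
  expect_lt(abs(f$ll - as.numeric(logLik(ols))), 1e-6)
  expect_lt(f$varcomp["family_id"] + f$varcomp["pair_id"], 1e-6)
  expect_true(all(f$varcomp >= 0))
})

test_that("on balanced pairs the LMM equals GLS at the fitted ratio", {
  d <- make_family_data(n_fam = 60, seed = 3, fam_sd = 0.8, pair_sd = 0)
  f <- fit_lmm(d$y, d, ~ age + x)
  s2u <- unname(f$varcomp["family_id"] + f$varcomp["pair_id"])
  s2e <- unname(f$varcomp["Residual"])
  # closed-form GLS with the 2x2 exchangeable block covariance plugged in
  X <- model.matrix(~ age + x, d)
  Vb <- matrix(s2u, 2, 2) + diag(s2e, 2)
  Vinv_b <- solve(Vb)
  XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X))
  for (fam in levels(d$family_id)) {
    ix <- which(d$family_id == fam)
    XtVX <- XtVX + t(X[ix, ]) %*% Vinv_b %*% X[ix, ]
    XtVy <- XtVy + t(X[ix, ]) %*% Vinv_b %*% d$y[ix]
  }
  beta_gls <- solve(XtVX, XtVy)
  expect_lt(max(abs(f$beta - beta_gls)), 1e-5)
})

test_that("a constant response yields zero slopes", {
  d <- make_family_data(n_fam = 20, seed = 4)
  f <- suppressWarnings(fit_lmm(rep(2, nrow(d)), d, ~ age + x))
  expect_lt(max(abs(f$beta[-1])), 1e-8)
})

test_that("fewer than two families is an error", {
  d <- make_family_data(n_fam = 1, seed = 5)
  expect_error(fit_lmm(d$y, d, ~ age), "families")
})

test_that("the age LRT is invariant to affine rescaling of the response", {
  sim <- simulate_study(tiny_config(seed = 21))
  idx <- c(which(sim$truth$effect_class == "age")[1:3],
           which(sim$truth$effect_class == "null")[1:5])
  m1 <- sim$matrix[idx, , drop = FALSE]
  m2 <- 3.7 * m1 + 2
  e1 <- ewas_age(m1, sim$cohort, sim$windows[idx, ], normalise = "none")
  e2 <- ewas_age(m2, sim$cohort, sim$windows[idx, ], normalise = "none")
  ez <- ewas_age(m1, sim$cohort, sim$windows[idx, ], normalise = "zscore")
  expect_equal(e1$p, e2$p, tolerance = 1e-6)
  expect_equal(e1$beta_age * 3.7, e2$beta_age, tolerance = 1e-6)
  expect_true(all(sign(e1$beta_age) == sign(ez$beta_age)))
  expect_equal(e1$p, ez$p, tolerance = 1e-4)
  expect_true(all(e1$lrt_stat >= 0))
  expect_true(all(e1$p > 0 & e1$p <= 1))
})

test_that("EWAS result bookkeeping: constant windows flagged, denominator kept", {
  sim <- simulate_study(tiny_config(seed = 22))
  m <- sim$matrix[1:6, , drop = FALSE]
  m[3, ] <- 5  # constant window
  e <- ewas_age(m, sim$cohort, sim$windows[1:6, ])
  expect_equal(e$status[3], "constant")
  expect_true(is.na(e$p[3]))
  expect_equal(attr(e, "n_tests"), 6L)
  expect_equal(sum(e$status == "ok"), 5L)
})

test_that("interaction test flags monomorphic blocks and detects planted slopes", {
  # full-size cohort: the genotype-by-age slope is a subtle effect and the
  # detection-power claim is stated at the default study size
  sim <- simulate_study(sim_config(seed = 23, n_age_windows = 5L,
                                   n_geno_windows = 5L, n_cell_windows = 5L))
  ii <- which(sim$truth$effect_class == "interaction")
  ni <- which(sim$truth$effect_class == "null")[1:10]
  ew <- ewas_interaction(sim$matrix[c(ii, ni), ], sim$cohort,
                         sim$windows[c(ii, ni), ])
  pi_int <- ew$p[seq_along(ii)]
  expect_gt(mean(pi_int < 0.05), 0.5)

  # monomorphic genotype: fix one block's genotypes to a constant
  co2 <- sim$cohort
  co2$genotype[, sim$windows$block_id[ii[1]]] <- 1L
  ew2 <- ewas_interaction(sim$matrix[ii[1], , drop = FALSE], co2,
                          sim$windows[ii[1], , drop = FALSE])
  expect_equal(ew2$status, "monomorphic")
  expect_true(is.na(ew2$p))
})
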