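# The fitter is authored in-package; base glm, MASS::glm.nb and lme4::glmer
# act as independent oracles on small fixtures.

test_that("Poisson fixed-effects fit matches an independent IRLS oracle", {
  # 10-row hand dataset
  x <- c(-1.2, -0.8, -0.3, 0, 0.1, 0.4, 0.8, 1.1, 1.5, 2)
  y <- c(0, 1, 1, 2, 1, 3, 2, 4, 6, 9)
  d <- data.frame(x1 = x, x2 = rep(c(0, 1), 5))
  f <- fit_count_model(d, y, fixed_only_spec("poisson"))
  # independent IRLS implementation
  X <- cbind(1, d$x1, d$x2)
  b <- c(log(mean(y)), 0, 0)
  for (i in 1:50) {
    mu <- exp(drop(X %*% b))
    W <- diag(mu)
    z <- drop(X %*% b) + (y - mu) / mu
    b <- solve(t(X) %*% W %*% X, t(X) %*% W %*% z)
  }
  expect_equal(unname(f$beta), drop(b), tolerance = 1e-7)
  g <- glm(y ~ x1 + x2, data = d, family = poisson)
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-10)
  expect_equal(f$aic, AIC(g), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("NB2 fixed-effects fit matches MASS::glm.nb", {
  skip_if_not_installed("MASS")
  s <- sim_counts(400, "nb2", theta = 0.8, seed = 31)
  f <- fit_count_model(s$design, s$y, fixed_only_spec("nb2"))
  g <- MASS::glm.nb(y ~ x1 + x2, data = cbind(s$design, y = s$y))
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$theta, g$theta, tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  # observed- vs expected-information SEs agree to a few percent here
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 0.15)
})

test_that("NB2 log-likelihood converges to Poisson as theta -> infinity", {
  s <- sim_counts(300, "poisson", seed = 32)
  fp <- fit_count_model(s$design, s$y, fixed_only_spec("poisson"))
  fnb <- fit_count_model(s$design, s$y, fixed_only_spec("nb2"),
                         opts = list(theta_fix = 1e6))
  expect_equal(unname(fnb$beta), unname(fp$beta), tolerance = 1e-4)
  expect_lt(abs(fnb$loglik - fp$loglik) / length(s$y), 1e-3)
})

test_that("all random variances fixed at 0 reduce Laplace to the fixed-effects likelihood", {
  s <- sim_counts(300, "nb2", seed = 33)
  d <- s$design
  d$grp <- rep(sprintf("g%d", 1:10), each = 30)
  sp0 <- count_model_spec("papers", "nb2", fixed_terms = c("x1", "x2"),
                          random_terms = "grp")
  f_fixed <- fit_count_model(d, s$y, fixed_only_spec("nb2"))
  f_zero <- fit_count_model(d, s$y, sp0, opts = list(sigma_fix = 0))
  expect_equal(f_zero$loglik, f_fixed$loglik, tolerance = 1e-6)
  expect_equal(unname(f_zero$beta), unname(f_fixed$beta), tolerance = 1e-5)
})

test_that("mixed Poisson fit agrees with lme4::glmer Laplace", {
  set.seed(34)
  n <- 800; ng <- 15
  g <- sample(sprintf("g%02d", 1:ng), n, TRUE)
  x <- rnorm(n)
  b <- rnorm(ng, 0, 0.6); names(b) <- sprintf("g%02d", 1:ng)
  y <- rpois(n, exp(0.4 + 0.5 * x + b[g]))
  d <- data.frame(x1 = x, grp = g)
  f <- fit_count_model(d, y, count_model_spec("papers", "poisson",
                                              fixed_terms = "x1",
                                              random_terms = "grp"))
  m <- lme4::glmer(y ~ x + (1 | grp), data = d, family = poisson)
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 0.02)
  expect_equal(unname(f$sigma2_g), as.numeric(lme4::VarCorr(m)$grp),
               tolerance = 0.02)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 0.02)
  expect_equal(unname(f$se), unname(sqrt(diag(as.matrix(vcov(m))))),
               tolerance = 0.02)
})

test_that("zero-inflation collapses gracefully when the generator has pi = 0", {
  s <- sim_counts(1500, "nb2", theta = 0.7, seed = 35)
  fnb <- fit_count_model(s$design, s$y, fixed_only_spec("nb2"))
  fzi <- fit_count_model(s$design, s$y, fixed_only_spec("zinb2"))
  expect_lt(fzi$zi_prob, 0.05)
  expect_equal(unname(fzi$beta), unname(fnb$beta), tolerance = 0.05)
  # and the plain model wins on AIC (one parameter cheaper)
  expect_lt(fnb$aic, fzi$aic + 2.5)
})

test_that("zinb2 recovers a known zero-inflation probability", {
  s <- sim_counts(2000, "zinb2", theta = 0.7, pi = 0.3, seed = 36)
  f <- fit_count_model(s$design, s$y, fixed_only_spec("zinb2"))
  expect_true(f$converged)
  expect_lt(abs(f$zi_prob - 0.3), 0.05)
  expect_equal(unname(f$beta), s$beta, tolerance = 0.15)
  expect_equal(f$theta, 0.7, tolerance = 0.15)
})

test_that("overdispersion_check is calibrated and detects NB2 data under Poisson", {
  s <- sim_counts(2000, "poisson", seed = 37)
  fp <- fit_count_model(s$design, s$y, fixed_only_spec("poisson"))
  od <- overdispersion_check(fp)
  expect_gt(od$dispersion_ratio, 0.8)
  expect_lt(od$dispersion_ratio, 1.2)
  expect_identical(od$df, fp$n_obs - 3L)  # n - p, p = intercept + 2 slopes
  s2 <- sim_counts(2000, "nb2", theta = 0.5, seed = 38)
  fp2 <- fit_count_model(s2$design, s2$y, fixed_only_spec("poisson"))
  od2 <- overdispersion_check(fp2)
  expect_gt(od2$dispersion_ratio, 1.5)
  expect_lt(od2$p_overdispersion, 0.001)
})

test_that("zero_check is calibrated, flags ZINB data, handles no zeros", {
  s <- sim_counts(2000, "nb2", theta = 0.7, seed = 39)
  f <- fit_count_model(s$design, s$y, fixed_only_spec("nb2"))
  zc <- zero_check(f)
  expect_gt(zc$zero_ratio, 0.9)
  expect_lt(zc$zero_ratio, 1.1)
  s2 <- sim_counts(2000, "zinb2", theta = 0.7, pi = 0.3, seed = 40)
  f2 <- fit_count_model(s2$design, s2$y, fixed_only_spec("nb2"))
  zc2 <- zero_check(f2)
  expect_lt(zc2$zero_ratio, 1)
  # all-positive response
  y3 <- pmax(s$y, 1)
  f3 <- fit_count_model(s$design, y3, fixed_only_spec("nb2"))
  zc3 <- zero_check(f3)
  expect_identical(zc3$observed_zeros, 0L)
  expect_true(is.na(zc3$zero_ratio))
  expect_match(zc3$note, "no observed zeros")
})

test_that("vif matches the closed form and flags collinearity", {
  set.seed(41)
  n <- 400
  # exactly orthonormal columns via QR
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  ortho <- as.data.frame(Q)
  names(ortho) <- c("a", "b", "c")
  expect_equal(unname(vif(ortho)), rep(1, 3), tolerance = 1e-10)
  # two columns with correlation exactly 0.9 -> VIF = 1/(1 - 0.81)
  x <- Q[, 1]; z <- Q[, 2]
  d <- data.frame(x = x, y = 0.9 * x + sqrt(1 - 0.81) * z)
  expect_equal(unname(vif(d)), rep(1 / (1 - 0.81), 2), tolerance = 1e-8)
  # duplicated column is infinite with a warning
  dd <- data.frame(x = x, z = z, x2 = x)
  ws <- testthat::capture_warnings(v <- vif(dd))
  expect_true(any(grepl("collinear", ws)))
  expect_true(is.infinite(v[["x2"]]))
  expect_error(vif(data.frame(x = x, k = rep(1, n))), "constant")
})

test_that("compare_fits ranks by AIC, invariant to order, checks n", {
  s <- sim_counts(800, "zinb2", theta = 0.7, pi = 0.3, seed = 42)
  fnb <- fit_count_model(s$design, s$y, fixed_only_spec("nb2"))
  fzi <- fit_count_model(s$design, s$y, fixed_only_spec("zinb2"))
  r1 <- compare_fits(list(fnb, fzi))
  r2 <- compare_fits(list(fzi, fnb))
  expect_identical(r1, r2)
  expect_identical(r1$delta_aic[1], 0)
  expect_true(all(diff(r1$aic) >= 0))
  expect_identical(compare_fits(list(fnb, fnb))$delta_aic, c(0, 0))
  short <- fit_count_model(s$design[1:700, ], s$y[1:700],
                           fixed_only_spec("nb2"))
  expect_error(compare_fits(list(fnb, short)), "mismatched n_obs")
})

test_that("significance_flags applies the Wald z-test at the configured alpha", {
  fake <- list(beta = c(a = 3, b = 0, c = 2.2), se = c(a = 1, b = 1, c = 1))
  fl01 <- significance_flags(fake, alpha = 0.01)
  expect_identical(unname(fl01), c(TRUE, FALSE, FALSE))  # 2.576 threshold
  fl05 <- significance_flags(fake, alpha = 0.05)
  expect_identical(unname(fl05), c(TRUE, FALSE, TRUE))
  # monotonicity: alpha = 0.05 flags are a superset of alpha = 0.01 flags
  expect_true(all(!fl01 | fl05))
})

test_that("AIC penalty counts dispersion, inflation and variance parameters", {
  s <- sim_counts(500, "nb2", theta = 0.8, seed = 43)
  d <- s$design
  d$grp <- rep(sprintf("g%d", 1:10), each = 50)
  f_nb <- fit_count_model(d, s$y, fixed_only_spec("nb2"))
  f_zi <- fit_count_model(d, s$y, fixed_only_spec("zinb2"))
  f_mix <- suppressWarnings(
    fit_count_model(d, s$y, count_model_spec("papers", "nb2",
                                             fixed_terms = c("x1", "x2"),
                                             random_terms = "grp")))
  expect_identical(f_nb$n_params, 4L)   # 3 beta + theta
  expect_identical(f_zi$n_params, 5L)   # + pi
  expect_identical(f_mix$n_params, 5L)  # + sigma2_grp
  expect_equal(f_nb$aic, 2 * 4 - 2 * f_nb$loglik)
})

test_that("influence_screen reports, never removes, high-residual points", {
  s <- sim_counts(200, "nb2", theta = 1, seed = 44)
  scr <- influence_screen(s$design, s$y, fixed_only_spec("nb2"), k = 3)
  expect_identical(nrow(scr), 3L)
  expect_true(all(scr$max_coef_shift >= 0))
  expect_true(all(scr$row %in% seq_len(200)))
})
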