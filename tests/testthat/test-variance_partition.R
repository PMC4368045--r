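test_that("observation variances are the quadratic forms z' Sigma z", {
  Sigma <- matrix(c(2, 0.5, 0.5, 1), 2)
  tm <- re_term(rbind(c(1, 0), c(1, 1), c(1, 2)), Sigma = Sigma)
  v <- observation_variances(tm)
  # x = 0: the intercept variance; x = 1: s00 + 2 s01 + s11; x = 2 by hand
  expect_equal(v, c(2, 4, 8))

  # definitional brute force on random instances
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(1:3, 1)
    n <- sample(2:40, 1)
    Sigma <- random_psd(k)
    Z <- matrix(rnorm(n * k), n, k)
    expect_equal(observation_variances(re_term(Z, Sigma)),
                 brute_obs_var(Z, Sigma), tolerance = 1e-12)
  }
})

test_that("observation_variances demands a covariance and matching shapes", {
  tm <- re_term(cbind(1, 0:2))
  expect_error(observation_variances(tm), "no Sigma")
  expect_error(mean_random_effect_variance(tm), "no Sigma")
  tm$Sigma <- matrix(1)
  expect_error(observation_variances(tm), "mismatch")
})

test_that("mean random-effect variance is the trace formula", {
  Sigma <- matrix(c(2, 0.5, 0.5, 1), 2)
  tm <- re_term(rbind(c(1, 0), c(1, 1)), Sigma = Sigma)
  expect_equal(mean_random_effect_variance(tm), 3)          # (2 + 4) / 2

  # no-intercept term
  ns <- re_term(cbind(c(2, 4)), Sigma = matrix(1), intercept = FALSE)
  expect_equal(mean_random_effect_variance(ns), 10)         # (4 + 16) / 2
})

test_that("trace identity holds on random instances to 1e-12", {
  set.seed(32)
  for (rep in 1:100) {
    k <- sample(1:3, 1)
    n <- sample(2:200, 1)
    Sigma <- random_psd(k)
    Z <- matrix(rnorm(n * k, sd = 2), n, k)
    tm <- re_term(Z, Sigma)
    m <- mean_random_effect_variance(tm)
    expect_equal(m, mean(observation_variances(tm)), tolerance = 1e-12)
    expect_equal(m, sum(diag(Sigma %*% crossprod(Z))) / n, tolerance = 1e-12)
  }
})

test_that("random-intercepts terms reduce to the intercept variance exactly", {
  for (n in c(1, 2, 17, 500)) {
    tm <- re_term(matrix(1, n, 1), Sigma = matrix(0.73))
    expect_identical(mean_random_effect_variance(tm), 0.73)
  }
})

test_that("scaling the slope covariate scales a slope-only variance by c^2", {
  set.seed(33)
  x <- rnorm(25)
  s2 <- 0.8
  for (c_ in c(0.1, 2, -3)) {
    tm1 <- re_term(cbind(x), Sigma = matrix(s2), intercept = FALSE)
    tm2 <- re_term(cbind(c_ * x), Sigma = matrix(s2), intercept = FALSE)
    expect_equal(mean_random_effect_variance(tm2),
                 c_^2 * mean_random_effect_variance(tm1))
    expect_equal(mean_random_effect_variance(tm2),
                 mean(brute_obs_var(cbind(c_ * x), matrix(s2))))
  }
})

test_that("fixed-effects variance is the sample variance of X beta", {
  expect_equal(fixed_effects_variance(cbind(1, c(5, 5, 5)), c(2, 1)), 0)
  expect_equal(fixed_effects_variance(cbind(c(0, 1, 2)), 1), 1)
  X <- cbind(1, rnorm(10))
  b <- c(0.3, -2)
  expect_equal(fixed_effects_variance(X, 3 * b),
               9 * fixed_effects_variance(X, b))
  expect_error(fixed_effects_variance(cbind(1), 1), "at least 2")
})

test_that("beta0 is the mean linear predictor, exact for centred designs", {
  expect_equal(estimate_beta0(cbind(c(1, 2, 3)), 1), 2)
  x <- rnorm(20)
  X <- cbind(1, x - mean(x))
  expect_equal(estimate_beta0(X, c(1.7, 5)), 1.7)
  expect_equal(estimate_beta0(X, c(0, 0)), 0)
  expect_error(estimate_beta0(matrix(numeric(), 0, 1), 1), "no rows")
})

test_that("distribution-specific variances follow the family constants", {
  expect_identical(distribution_specific_variance("gaussian-identity"), 0)
  expect_equal(distribution_specific_variance("binomial-logit"), pi^2 / 3)
  expect_identical(distribution_specific_variance("binomial-probit"), 1)
  expect_identical(distribution_specific_variance("poisson-sqrt"), 0.25)
  expect_equal(distribution_specific_variance("poisson-log", 0), log(2))
  # strictly decreasing in beta0, vanishing for large counts
  b0 <- seq(-3, 8, by = 0.5)
  v <- vapply(b0, distribution_specific_variance,
              family_link = "poisson-log", numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(distribution_specific_variance("poisson-log", 20), 1e-8)
  expect_error(distribution_specific_variance("poisson-log", NA))
  expect_error(distribution_specific_variance("gamma-log"))
})

test_that("assemble_partition composes the components", {
  x <- c(0, 1)
  Sigma <- matrix(c(2, 0.5, 0.5, 1), 2)
  tm <- re_term(cbind(1, x), Sigma = Sigma, grouping = c("a", "b"))
  mc <- model_components(cbind(1, x), beta = c(0, sqrt(2)), terms = tm,
                         sigma2_e = 1)
  p <- assemble_partition(mc)
  expect_equal(p$sigma2_f, 1)
  expect_equal(unname(p$sigma2_terms), 3)
  expect_equal(p$sigma2_e, 1)
  expect_equal(p$sigma2_d, 0)
  expect_equal(total_variance(p), 5)
  expect_equal(r2_marginal(p), 0.2)
  expect_equal(r2_conditional(p), 0.8)

  # gaussian intercept-only: the classical random-intercepts partition
  ri <- model_components(cbind(1, x), beta = c(1, 2),
                         terms = re_term(matrix(1, 2, 1),
                                         Sigma = matrix(0.6)),
                         sigma2_e = 0.4)
  pri <- assemble_partition(ri)
  expect_equal(pri$sigma2_f, var(c(1, 3)))
  expect_equal(unname(pri$sigma2_terms), 0.6)

  # two independent terms contribute additively
  two <- model_components(cbind(1, x), beta = c(0, 1),
                          terms = list(re_term(matrix(1, 2, 1),
                                               Sigma = matrix(0.3),
                                               label = "site"),
                                       re_term(matrix(1, 2, 1),
                                               Sigma = matrix(0.2),
                                               label = "year")),
                          sigma2_e = 1)
  p2 <- assemble_partition(two)
  expect_equal(p2$sigma2_terms, c(site = 0.3, year = 0.2))
  expect_equal(total_variance(p2), var(c(0, 1)) + 0.5 + 1)

  # poisson-log with no terms: total is sigma2_f plus the latent-scale piece
  po <- model_components(cbind(1, x), beta = c(0, 1), sigma2_e = 0,
                         family_link = "poisson-log")
  pp <- assemble_partition(po)
  expect_equal(pp$sigma2_d,
               distribution_specific_variance("poisson-log", 0.5))
  expect_equal(total_variance(pp), 0.5 + pp$sigma2_d)

  # all-zero variance is degenerate
  z <- model_components(cbind(1, c(1, 1)), beta = c(0, 0), sigma2_e = 0)
  expect_error(assemble_partition(z), "[Dd]egenerate")
})

test_that("R2 bounds and ordering hold for random valid partitions", {
  set.seed(34)
  for (rep in 1:200) {
    p <- structure(
      list(sigma2_f = rexp(1), sigma2_terms = rexp(sample(0:3, 1)),
           sigma2_e = rexp(1), sigma2_d = sample(c(0, 1, pi^2 / 3), 1)),
      class = "variance_partition")
    m <- r2_marginal(p)
    c_ <- r2_conditional(p)
    expect_true(m >= 0 && m <= c_ && c_ <= 1)
  }
})

test_that("r2 edge cases: all-fixed, no-fixed, no-residual, no-random", {
  mk <- function(f, terms, e, d) {
    structure(list(sigma2_f = f, sigma2_terms = terms, sigma2_e = e,
                   sigma2_d = d), class = "variance_partition")
  }
  expect_equal(r2_marginal(mk(1, numeric(), 0, 0)), 1)
  expect_equal(r2_marginal(mk(0, c(g = 2), 1, 0)), 0)
  expect_equal(r2_conditional(mk(0.4, c(g = 2.2), 0, 0)), 1)
  nr <- mk(1, numeric(), 3, 0)
  expect_equal(r2_conditional(nr), r2_marginal(nr))
  expect_error(r2_marginal(mk(0, numeric(), 0, 0)), "[Dd]egenerate")
})

test_that("conditioned ICC matches the quadratic form and its bounds", {
  Sigma <- matrix(c(2, 0.5, 0.5, 1), 2)
  tm <- re_term(cbind(1, c(0, 1)), Sigma = Sigma)
  # at v = 0 with sigma2_e equal to the intercept variance: exactly 1/2
  expect_equal(icc_conditional(tm, sigma2_e = 2, covariate_values = 0), 0.5)
  # at v = 1: sigma2_a = 4, so 4 / (4 + 1)
  expect_equal(icc_conditional(tm, sigma2_e = 1, covariate_values = 1), 0.8)
  # zero covariance matrix: ICC identically 0
  z <- re_term(cbind(1, c(0, 1)), Sigma = matrix(0, 2, 2))
  expect_equal(icc_conditional(z, 1, 0, c(-2, 0, 5)), c(0, 0, 0))
  # large |v| drives the ICC toward 1
  icc <- icc_conditional(tm, sigma2_e = 1, covariate_values = c(0, 10, 1e4))
  expect_true(all(icc >= 0 & icc <= 1))
  expect_true(all(diff(icc) > 0))
  expect_gt(icc[3], 0.999)
  # degenerate: nothing varies
  expect_error(icc_conditional(z, 0, 0, 1), "[Dd]egenerate")
  # needs exactly one slope
  expect_error(icc_conditional(re_term(matrix(1, 3, 1), matrix(1)), 1, 0, 0),
               "one slope")
})

test_that("conditioned ICC agrees with Monte-Carlo group-effect variance", {
  set.seed(35)
  Sigma <- matrix(c(1, 0.25, 0.25, 0.5), 2)
  tm <- re_term(cbind(1, c(0, 1)), Sigma = Sigma)
  n <- 1e5
  a <- matrix(rnorm(2 * n), n, 2) %*% chol(Sigma)
  for (v in c(0, 0.5, 2)) {
    eff <- a[, 1] + a[, 2] * v
    s2_mc <- var(eff)
    s2_th <- as.numeric(c(1, v) %*% Sigma %*% c(1, v))
    se <- s2_th * sqrt(2 / (n - 1))
    expect_lt(abs(s2_mc - s2_th), 3 * se)
    expect_equal(icc_conditional(tm, sigma2_e = 1, covariate_values = v),
                 s2_th / (s2_th + 1), tolerance = 1e-12)
  }
})
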