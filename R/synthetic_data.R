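#' Specify a random-slopes simulation
#'
#' True parameters and design layout for the synthetic-data generator. The
#' data model is the random intercept + slope mixed model: per-group
#' deviations `(a0_j, a1_j) ~ MVN(0, Sigma)` around the global intercept
#' and slope, a covariate `x`, and Gaussian residual noise (or a Poisson
#' log-link response computed from the same linear predictor).
#'
#' @param n_groups number of groups J.
#' @param group_sizes either a single count (balanced design) or a vector
#'   of J counts (unbalanced design, e.g. from
#'   [make_unbalanced_design()]).
#' @param beta numeric length-2 vector `(beta0, beta1)`: global intercept
#'   and slope.
#' @param Sigma 2 x 2 covariance matrix of the random intercept and slope.
#' @param sigma2_eps residual variance (Gaussian only; must be 0 for
#'   poisson-log).
#' @param covariate_rule `"shared"` (x ~ Uniform(0,1) identically in every
#'   group, the balanced covariate distribution) or `"group-ranges"`
#'   (each group draws x uniformly from its own subinterval, inducing
#'   covariate imbalance between groups).
#' @param family_link `"gaussian-identity"` or `"poisson-log"`.
#' @param seed integer RNG seed; every dataset is reproducible from it.
#'
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_groups = 100, group_sizes = 10,
                            beta = c(0.5, 1),
                            Sigma = matrix(c(1, 0.25, 0.25, 0.5), 2),
                            sigma2_eps = 1,
                            covariate_rule = c("shared", "group-ranges"),
                            family_link = c("gaussian-identity",
                                            "poisson-log"),
                            seed = 1L) {
  covariate_rule <- match.arg(covariate_rule)
  family_link <- match.arg(family_link)
  if (length(group_sizes) == 1L) {
    group_sizes <- rep(as.integer(group_sizes), n_groups)
  }
  if (length(group_sizes) != n_groups) {
    stop("`group_sizes` must have length 1 or `n_groups`.", call. = FALSE)
  }
  if (any(group_sizes < 1L)) {
    stop("Every group must have at least one observation.", call. = FALSE)
  }
  if (length(beta) != 2L) {
    stop("`beta` must be (beta0, beta1).", call. = FALSE)
  }
  Sigma <- validate_covariance(as.matrix(Sigma))
  if (nrow(Sigma) != 2L) stop("`Sigma` must be 2 x 2.", call. = FALSE)
  if (sigma2_eps < 0) stop("`sigma2_eps` must be >= 0.", call. = FALSE)
  if (family_link == "poisson-log" && sigma2_eps != 0) {
    stop("poisson-log simulations have no Gaussian residual: set ",
         "`sigma2_eps = 0` (overdispersion is added via the partition's ",
         "sigma2_e).", call. = FALSE)
  }
  structure(
    list(n_groups = as.integer(n_groups), group_sizes = group_sizes,
         beta = as.numeric(beta), Sigma = Sigma,
         sigma2_eps = as.numeric(sigma2_eps),
         covariate_rule = covariate_rule, family_link = family_link,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Simulation spec (", x$family_link, "): J = ", x$n_groups,
      ", n = ", sum(x$group_sizes),
      if (length(unique(x$group_sizes)) == 1L) " (balanced)"
      else " (unbalanced)",
      ", seed = ", x$seed, "\n", sep = "")
  cat("  beta = (", paste(x$beta, collapse = ", "), "), sigma2_eps = ",
      x$sigma2_eps, ", covariates: ", x$covariate_rule, "\n", sep = "")
  invisible(x)
}

# MVN draws via the (pivoted) Cholesky factor; handles singular Sigma.
#' @keywords internal
rmvn <- function(n, Sigma) {
  k <- nrow(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(stats::rnorm(n * k), n, k) %*% rt
}

#' Simulate a dataset from a random-slopes mixed model
#'
#' Draws per-group random intercepts and slopes from `MVN(0, Sigma)`,
#' covariates per the spec's rule, and responses
#' `y = beta0 + a0_j + (beta1 + a1_j) x + eps` (Gaussian) or
#' `y ~ Poisson(exp(linear predictor))` (poisson-log). Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [simulation_spec].
#' @return A data frame with columns `group` (factor), `x`, `y`, carrying
#'   the spec as attribute `"sim_spec"`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  J <- spec$n_groups
  sizes <- spec$group_sizes
  n <- sum(sizes)
  group <- factor(rep(seq_len(J), times = sizes))
  alpha <- rmvn(J, spec$Sigma)            # J x 2: (a0_j, a1_j)
  x <- if (spec$covariate_rule == "shared") {
    stats::runif(n)
  } else {
    # group-specific subranges of width 0.3 with left ends spread over [0, 0.7]
    lo <- stats::runif(J, 0, 0.7)
    unlist(lapply(seq_len(J), function(j) {
      stats::runif(sizes[j], lo[j], lo[j] + 0.3)
    }), use.names = FALSE)
  }
  j <- as.integer(group)
  eta <- spec$beta[1] + alpha[j, 1] + (spec$beta[2] + alpha[j, 2]) * x
  y <- if (spec$family_link == "gaussian-identity") {
    eta + stats::rnorm(n, 0, sqrt(spec$sigma2_eps))
  } else {
    stats::rpois(n, exp(eta))
  }
  out <- data.frame(group = group, x = x, y = y)
  attr(out, "sim_spec") <- spec
  out
}

#' Analytic variance partition at the true parameters
#'
#' Evaluates the variance components at the generator's true parameters
#' over the realized covariate values: the fixed-effects variance is the
#' sample variance of `beta0 + beta1 * x`, the mean random-effect variance
#' is `Tr([1 x] Sigma [1 x]') / n`, and the residual and
#' distribution-specific pieces follow the family. The resulting marginal
#' and conditional R-squared are the recovery targets for fits to the
#' simulated data.
#'
#' @param spec a [simulation_spec].
#' @param realized_x numeric vector of the covariate values actually drawn
#'   (column `x` of the simulated dataset).
#' @return A `variance_partition`.
#' @export
true_partition <- function(spec, realized_x) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (length(realized_x) < 2L) {
    stop("Need at least 2 covariate values.", call. = FALSE)
  }
  if (anyNA(realized_x)) stop("`realized_x` has missing values.",
                              call. = FALSE)
  X <- cbind(1, realized_x)
  term <- re_term(X, Sigma = spec$Sigma, label = "group", intercept = TRUE)
  sigma2_f <- fixed_effects_variance(X, spec$beta)
  sigma2_a <- mean_random_effect_variance(term)
  beta0 <- estimate_beta0(X, spec$beta)
  sigma2_d <- distribution_specific_variance(spec$family_link, beta0)
  structure(
    list(sigma2_f = sigma2_f, sigma2_terms = c(group = sigma2_a),
         sigma2_e = spec$sigma2_eps, sigma2_d = sigma2_d),
    class = "variance_partition"
  )
}

#' Group sizes for an unbalanced (dominant-group) design
#'
#' One group contributes a fixed fraction of all observations, emulating a
#' site or individual that yields an unusually large share of the data;
#' the remaining observations are split as evenly as possible over the
#' other groups. Sizes always sum to `total_n`.
#'
#' @param J number of groups (>= 2).
#' @param dominant_fraction fraction of `total_n` in group 1, in (0, 1).
#' @param total_n total number of observations.
#' @return integer vector of J group sizes.
#' @examples
#' make_unbalanced_design(10, 0.8, 1000)
#' @export
make_unbalanced_design <- function(J, dominant_fraction, total_n) {
  if (J < 2L) stop("Need J >= 2 groups.", call. = FALSE)
  if (dominant_fraction <= 0 || dominant_fraction >= 1) {
    stop("`dominant_fraction` must be in (0, 1).", call. = FALSE)
  }
  big <- round(dominant_fraction * total_n)
  rest <- total_n - big
  others <- rep(rest %/% (J - 1L), J - 1L)
  extra <- rest - sum(others)
  if (extra > 0) others[seq_len(extra)] <- others[seq_len(extra)] + 1L
  sizes <- as.integer(c(big, others))
  if (any(sizes < 1L)) {
    stop("Design leaves a group with no observations; lower ",
         "`dominant_fraction` or raise `total_n`.", call. = FALSE)
  }
  sizes
}
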