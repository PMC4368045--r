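#' Observation-level random-effect variances
#'
#' The variance contributed by a random-effect term to each observation:
#' element i is `z_i' Sigma z_i`, where `z_i` is row i of the term's design
#' matrix. These are the diagonal entries of `Z Sigma Z'`, computed without
#' forming the n x n matrix. In a random intercept + slope term they equal
#' `sigma2_a0 + 2 x_i sigma_a01 + x_i^2 sigma2_a1`: the variance at the
#' intercept when x = 0, and the sum of all three covariance elements at
#' x = 1.
#'
#' Tiny negative values (within -1e-10, floating-point noise from
#' boundary-PSD `Sigma`) are clipped to zero; larger negatives are an error.
#'
#' @param term an [re_term] with `Sigma` set.
#' @return numeric vector of length n.
#' @export
observation_variances <- function(term) {
  stopifnot(inherits(term, "re_term"))
  if (is.null(term$Sigma)) {
    stop("Term '", term$label, "' has no Sigma; fit the model or supply ",
         "the covariance matrix first.", call. = FALSE)
  }
  Z <- term$Z
  if (ncol(Z) != nrow(term$Sigma)) {
    stop("Dimension mismatch: Z has ", ncol(Z), " columns but Sigma is ",
         nrow(term$Sigma), " x ", nrow(term$Sigma), ".", call. = FALSE)
  }
  v <- rowSums((Z %*% term$Sigma) * Z)
  neg <- v < 0
  if (any(v < -1e-10)) {
    stop("Negative observation variance ", format(min(v)),
         " from an invalid covariance matrix.", call. = FALSE)
  }
  v[neg] <- 0
  v
}

#' Mean random-effect variance of a term
#'
#' The variance of the zero-mean mixture of the per-observation
#' random-effect distributions: the mean of the observation-level variances,
#' i.e. `Tr(Z Sigma Z') / n`. Computed as `Tr(Sigma Z'Z) / n`, which never
#' materializes the n x n matrix. For a pure random-intercept term (Z a
#' column of ones) this is exactly the intercept variance, recovering the
#' classical random-intercepts variance component; it applies equally to
#' random-slopes terms and to terms with no intercept.
#'
#' @param term an [re_term] with `Sigma` set.
#' @return a single non-negative number.
#' @export
mean_random_effect_variance <- function(term) {
  stopifnot(inherits(term, "re_term"))
  if (is.null(term$Sigma)) {
    stop("Term '", term$label, "' has no Sigma; fit the model or supply ",
         "the covariance matrix first.", call. = FALSE)
  }
  Z <- term$Z
  n <- nrow(Z)
  if (n == 0L) stop("Term has zero observations.", call. = FALSE)
  if (ncol(Z) != nrow(term$Sigma)) {
    stop("Dimension mismatch: Z has ", ncol(Z), " columns but Sigma is ",
         nrow(term$Sigma), " x ", nrow(term$Sigma), ".", call. = FALSE)
  }
  # Tr(Sigma Z'Z)/n; dividing Z'Z first keeps the ones-column case exact
  v <- sum(term$Sigma * (crossprod(Z) / n))
  max(v, 0)
}

#' Variance of the fixed-effects linear predictor
#'
#' The sample variance (denominator n - 1) of `X beta`, the variance
#' attributable to the fixed effects.
#'
#' @param X fixed-effects design matrix (n x p, n >= 2).
#' @param beta fixed-effect estimates (length p).
#' @return a single non-negative number.
#' @export
fixed_effects_variance <- function(X, beta) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2L) {
    stop("Need at least 2 observations to compute a variance.", call. = FALSE)
  }
  if (ncol(X) != length(beta)) {
    stop("length(beta) = ", length(beta), " but `X` has ", ncol(X),
         " columns.", call. = FALSE)
  }
  stats::var(as.numeric(X %*% beta))
}

#' Estimate beta0 as the mean of the linear predictor
#'
#' The latent-scale grand intercept used by the Poisson
#' distribution-specific variance: rather than refitting the model with
#' centred (or dropped) covariates, take the mean of the linear predictor
#' `X beta`. With centred covariates and an intercept column this returns
#' the fitted intercept exactly.
#'
#' @inheritParams fixed_effects_variance
#' @return a single number.
#' @export
estimate_beta0 <- function(X, beta) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) == 0L) stop("`X` has no rows.", call. = FALSE)
  if (ncol(X) != length(beta)) {
    stop("length(beta) = ", length(beta), " but `X` has ", ncol(X),
         " columns.", call. = FALSE)
  }
  mean(as.numeric(X %*% beta))
}

#' Distribution-specific variance on the link scale
#'
#' The link-scale variance implied by the response distribution:
#' 0 for gaussian-identity, `pi^2/3` for binomial-logit, 1 for
#' binomial-probit, 0.25 for poisson-sqrt, and the lognormal-Poisson
#' approximation `log(1 + 1/exp(beta0))` for poisson-log, where `beta0` is
#' the latent-scale grand intercept (see [estimate_beta0()]).
#'
#' @param family_link family-link string (see [model_components()]).
#' @param beta0 grand intercept on the link scale; required (finite) for
#'   `"poisson-log"`, ignored for families with constant variance.
#' @return a single non-negative number.
#' @export
distribution_specific_variance <- function(family_link, beta0 = NA_real_) {
  family_link <- match.arg(family_link, c("gaussian-identity", "poisson-log",
                                          "poisson-sqrt", "binomial-logit",
                                          "binomial-probit"))
  switch(family_link,
    "gaussian-identity" = 0,
    "binomial-logit" = pi^2 / 3,
    "binomial-probit" = 1,
    "poisson-sqrt" = 0.25,
    "poisson-log" = {
      if (!is.finite(beta0)) {
        stop("`beta0` must be finite for the poisson-log family.",
             call. = FALSE)
      }
      log1p(1 / exp(beta0))
    }
  )
}

#' Partition the total variance of a mixed model
#'
#' Assembles the named variance components of the latent-scale total
#' variance: the fixed-effects variance, one mean random-effect variance
#' per term, the additive-dispersion / residual variance, and the
#' distribution-specific variance (using the mean of the linear predictor
#' as `beta0` where needed).
#'
#' @param components a [model_components] object with every term's `Sigma`
#'   set.
#' @return An object of class `variance_partition` with fields `sigma2_f`,
#'   `sigma2_terms` (named, one per term), `sigma2_e`, `sigma2_d`.
#' @export
assemble_partition <- function(components) {
  stopifnot(inherits(components, "model_components"))
  sigma2_f <- fixed_effects_variance(components$X, components$beta)
  sigma2_terms <- vapply(components$terms, mean_random_effect_variance,
                         numeric(1))
  names(sigma2_terms) <- vapply(components$terms, `[[`, character(1), "label")
  beta0 <- if (components$family_link == "poisson-log") {
    estimate_beta0(components$X, components$beta)
  } else NA_real_
  sigma2_d <- distribution_specific_variance(components$family_link, beta0)
  p <- structure(
    list(sigma2_f = sigma2_f, sigma2_terms = sigma2_terms,
         sigma2_e = components$sigma2_e, sigma2_d = sigma2_d),
    class = "variance_partition"
  )
  if (total_variance(p) <= 0) {
    stop("Degenerate model: total variance is zero, R-squared is undefined.",
         call. = FALSE)
  }
  p
}

#' Total latent-scale variance of a partition
#' @param partition a `variance_partition`.
#' @return a single number.
#' @export
total_variance <- function(partition) {
  stopifnot(inherits(partition, "variance_partition"))
  partition$sigma2_f + sum(partition$sigma2_terms) + partition$sigma2_e +
    partition$sigma2_d
}

#' @export
print.variance_partition <- function(x, ...) {
  comp <- c("fixed" = x$sigma2_f, x$sigma2_terms,
            "residual/dispersion" = x$sigma2_e, "distribution" = x$sigma2_d)
  cat("Variance partition (total = ", format(sum(comp)), "):\n", sep = "")
  print(round(comp, 6))
  invisible(x)
}

#' Marginal R-squared of a variance partition
#'
#' The proportion of the total latent-scale variance attributable to the
#' fixed effects.
#'
#' @param partition a `variance_partition` (see [assemble_partition()]).
#' @return a number in \[0, 1\].
#' @export
r2_marginal <- function(partition) {
  tot <- total_variance(partition)
  if (tot <= 0) {
    stop("Degenerate model: total variance is zero.", call. = FALSE)
  }
  partition$sigma2_f / tot
}

#' Conditional R-squared of a variance partition
#'
#' The proportion of the total latent-scale variance attributable to fixed
#' and random effects jointly.
#'
#' @inheritParams r2_marginal
#' @return a number in \[0, 1\]; never less than [r2_marginal()].
#' @export
r2_conditional <- function(partition) {
  tot <- total_variance(partition)
  if (tot <= 0) {
    stop("Degenerate model: total variance is zero.", call. = FALSE)
  }
  (partition$sigma2_f + sum(partition$sigma2_terms)) / tot
}

#' Marginal and conditional R-squared from model components
#'
#' Convenience wrapper: partitions the variance and returns both R-squared
#' statistics with the component breakdown.
#'
#' @inheritParams assemble_partition
#' @return An object of class `r2_result` with fields `marginal`,
#'   `conditional`, `partition`.
#' @examples
#' tm <- re_term(cbind(1, c(0, 1)), Sigma = matrix(c(2, .5, .5, 1), 2))
#' mc <- model_components(X = cbind(1, c(0, 1)), beta = c(0, 1),
#'                        terms = tm, sigma2_e = 1)
#' r2_glmm(mc)
#' @export
r2_glmm <- function(components) {
  partition <- assemble_partition(components)
  structure(
    list(marginal = r2_marginal(partition),
         conditional = r2_conditional(partition),
         partition = partition),
    class = "r2_result"
  )
}

#' @export
print.r2_result <- function(x, ...) {
  cat("R2 (marginal)    = ", format(round(x$marginal, 4)), "\n",
      "R2 (conditional) = ", format(round(x$conditional, 4)), "\n", sep = "")
  print(x$partition)
  invisible(x)
}

#' Intraclass correlation conditioned on a covariate value
#'
#' Repeatability at a fixed covariate value: fixing the slope column of the
#' random-effect design at `v` gives the between-group variance
#' `sigma2_a(v) = [1, v] Sigma [1, v]'` (or `v^2` times the slope variance
#' for a no-intercept term), and the conditioned ICC is
#' `sigma2_a(v) / (sigma2_a(v) + sigma2_e + sigma2_d)`. With an
#' intercept-and-slope term this traces, e.g., how phenotypic consistency
#' changes with age.
#'
#' @param term an [re_term] with `Sigma` set and exactly one slope column.
#' @param sigma2_e additive-dispersion / residual variance.
#' @param sigma2_d distribution-specific variance.
#' @param covariate_values numeric vector of values at which to condition.
#' @return numeric vector of ICCs in \[0, 1\], one per value.
#' @export
icc_conditional <- function(term, sigma2_e, sigma2_d = 0, covariate_values) {
  stopifnot(inherits(term, "re_term"))
  if (is.null(term$Sigma)) {
    stop("Term '", term$label, "' has no Sigma.", call. = FALSE)
  }
  n_slopes <- ncol(term$Z) - as.integer(term$intercept)
  if (n_slopes != 1L) {
    stop("Conditioned ICC needs a term with exactly one slope column; got ",
         n_slopes, ".", call. = FALSE)
  }
  if (any(!is.finite(covariate_values))) {
    stop("`covariate_values` must be finite.", call. = FALSE)
  }
  vapply(covariate_values, function(v) {
    row <- if (term$intercept) c(1, v) else v
    s2a <- max(as.numeric(row %*% term$Sigma %*% row), 0)
    denom <- s2a + sigma2_e + sigma2_d
    if (denom <= 0) {
      stop("Degenerate model: zero total variance at covariate value ",
           format(v), ".", call. = FALSE)
    }
    s2a / denom
  }, numeric(1))
}
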