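#' @keywords internal
theta_to_lambda <- function(theta, k) {
  if (length(theta) != k * (k + 1) / 2) {
    stop("`theta` must have k(k+1)/2 = ", k * (k + 1) / 2, " elements.",
         call. = FALSE)
  }
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- theta
  L
}

# Per-group cross-products; everything the profiled criterion needs.
# Lambda changes across optimizer iterations, the data does not, so the
# criterion works entirely in k- and p-dimensional quantities.
#' @keywords internal
prepare_lmm <- function(y, X, Z, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) {
    stop("Need at least 2 groups to fit a mixed model.", call. = FALSE)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop("Fixed-effects design is rank deficient.", call. = FALSE)
  }
  idx <- split(seq_along(y), group)
  blocks <- lapply(idx, function(i) {
    Zi <- Z[i, , drop = FALSE]
    Xi <- X[i, , drop = FALSE]
    yi <- y[i]
    list(ZtZ = crossprod(Zi), ZtX = crossprod(Zi, Xi),
         Zty = crossprod(Zi, yi))
  })
  list(blocks = blocks, XtX = crossprod(X), Xty = crossprod(X, y),
       yty = sum(y^2), n = length(y), p = p, k = ncol(Z),
       J = length(blocks), group = group)
}

#' @keywords internal
criterion_from_prepared <- function(theta, prep, method = c("REML", "ML"),
                                    details = FALSE) {
  method <- match.arg(method)
  if (any(!is.finite(theta))) {
    stop("`theta` must be finite.", call. = FALSE)
  }
  L <- theta_to_lambda(theta, prep$k)
  XtViX <- prep$XtX
  XtViy <- prep$Xty
  ytViy <- prep$yty
  logdetV0 <- 0
  for (b in prep$blocks) {
    # Woodbury: V0^-1 = I - Z L M^-1 L' Z',  M = I + L' Z'Z L
    M <- diag(prep$k) + crossprod(L, b$ZtZ %*% L)
    cM <- chol(M)
    logdetV0 <- logdetV0 + 2 * sum(log(diag(cM)))
    LtZtX <- crossprod(L, b$ZtX)          # k x p
    LtZty <- crossprod(L, b$Zty)          # k x 1
    WX <- backsolve(cM, backsolve(cM, LtZtX, transpose = TRUE))
    Wy <- backsolve(cM, backsolve(cM, LtZty, transpose = TRUE))
    XtViX <- XtViX - crossprod(LtZtX, WX)
    XtViy <- XtViy - crossprod(LtZtX, Wy)
    ytViy <- ytViy - sum(LtZty * Wy)
  }
  cX <- chol(XtViX)
  beta <- backsolve(cX, backsolve(cX, XtViy, transpose = TRUE))
  rss <- max(as.numeric(ytViy - crossprod(XtViy, beta)), 1e-300)
  n <- prep$n; p <- prep$p
  if (method == "REML") {
    sigma2 <- rss / (n - p)
    crit <- (n - p) * (log(2 * pi * sigma2) + 1) + logdetV0 +
      2 * sum(log(diag(cX)))
  } else {
    sigma2 <- rss / n
    crit <- n * (log(2 * pi * sigma2) + 1) + logdetV0
  }
  if (!details) return(crit)
  list(criterion = crit, beta = as.numeric(beta), sigma2 = sigma2,
       Lambda = L)
}

#' Profiled deviance of the Gaussian random-slopes LMM
#'
#' Minus twice the profiled (restricted) log-likelihood of the model
#' `y = X beta + Z_j b_j + e`, `b_j ~ N(0, sigma2 * Lambda Lambda')`,
#' `e ~ N(0, sigma2 * I)`, as a function of `theta`, the lower-triangular
#' elements (column-major) of the relative covariance factor `Lambda`.
#' `beta` and `sigma2` are profiled out analytically; the group structure is
#' handled blockwise via the Woodbury identity, so no n x n matrix is
#' formed. At `theta = 0` the criterion reduces to the ordinary
#' least-squares deviance.
#'
#' @param theta numeric vector of length `k(k+1)/2`.
#' @param y numeric response vector.
#' @param X fixed-effects design matrix (n x p).
#' @param Z random-effects design matrix (n x k, term-level).
#' @param group grouping factor (length n).
#' @param method `"REML"` (default) or `"ML"`.
#' @return a single number, -2 times the profiled log-likelihood.
#' @export
profiled_criterion <- function(theta, y, X, Z, group,
                               method = c("REML", "ML")) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(Z)) Z <- as.matrix(Z)
  prep <- prepare_lmm(as.numeric(y), X, Z, group)
  criterion_from_prepared(theta, prep, method = match.arg(method))
}

#' Fit a Gaussian random-slopes linear mixed model
#'
#' Self-contained REML/ML estimation of the linear mixed model with a
#' single grouping factor: a global intercept and slopes (fixed effects)
#' plus correlated per-group random deviations with covariance `Sigma`.
#' The covariance is parameterized through the lower-triangular factor of
#' `Sigma / sigma2_e`, so the estimate is positive semi-definite by
#' construction; `beta` and the residual variance are profiled out and the
#' factor is optimized by Nelder-Mead. Boundary fits (zero variances) are
#' returned as-is and remain valid inputs to the variance partition.
#'
#' @param data a data frame.
#' @param response name of the numeric response column.
#' @param fixed character vector of fixed-covariate column names; a fixed
#'   intercept is always included.
#' @param random list with elements `grouping` (column name), `intercept`
#'   (flag, default `TRUE`) and `slopes` (character vector, default the
#'   `fixed` columns); same conventions as [build_random_design()].
#' @param method `"REML"` (default) or `"ML"`.
#' @param control list: `maxit` (default 500), `reltol` (default 1e-10),
#'   `start` (optional starting `theta`).
#'
#' @return An object of class `fit_result`: `components` (a
#'   [model_components] with estimated `beta`, `Sigma`, `sigma2_e`),
#'   `loglik`, `criterion`, `method`, `converged`, `n_groups`, `iterations`,
#'   `theta`.
#' @examples
#' spec <- simulation_spec(n_groups = 30, group_sizes = 5, seed = 1)
#' d <- simulate_dataset(spec)
#' fit <- fit_lmm(d, "y", fixed = "x",
#'                random = list(grouping = "group", slopes = "x"))
#' r2_glmm(fit$components)
#' @export
fit_lmm <- function(data, response, fixed = character(),
                    random = list(grouping = "group", intercept = TRUE,
                                  slopes = NULL),
                    method = c("REML", "ML"), control = list()) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  intercept <- random$intercept %||% TRUE
  slopes <- random$slopes %||% fixed
  grouping <- random$grouping %||% "group"
  used <- unique(c(response, fixed, grouping, slopes))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0L) {
    stop("Column(s) not found in `data`: ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  if (!is.numeric(data[[response]])) {
    stop("Response column '", response, "' must be numeric.", call. = FALSE)
  }
  keep <- stats::complete.cases(data[used])
  if (any(!keep)) {
    message("Dropping ", sum(!keep), " row(s) with missing values.")
    data <- data[keep, , drop = FALSE]
  }
  y <- data[[response]]
  if (stats::var(y) == 0) {
    stop("Degenerate data: the response is constant, there is no variance ",
         "to model.", call. = FALSE)
  }
  X <- cbind("(Intercept)" = rep(1, nrow(data)))
  for (cl in fixed) X <- cbind(X, data[[cl]])
  colnames(X) <- c("(Intercept)", fixed)
  term <- build_random_design(data, grouping, intercept = intercept,
                              slope_columns = slopes)
  prep <- prepare_lmm(y, X, term$Z, term$grouping)
  k <- prep$k
  n_theta <- k * (k + 1) / 2
  start <- control$start %||% {
    th <- numeric(n_theta)
    th[cumsum(c(1, if (k > 1) (k):2))[seq_len(k)]] <- 0.5  # diagonal of Lambda
    th
  }
  maxit <- control$maxit %||% 500L
  reltol <- control$reltol %||% 1e-10
  fn <- function(th) criterion_from_prepared(th, prep, method = method)
  if (n_theta == 1L) {
    opt <- stats::optim(start, fn, method = "Brent", lower = -50, upper = 50,
                        control = list(maxit = maxit))
  } else {
    opt <- stats::optim(start, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    # polish from the simplex optimum; quasi-Newton with numeric gradient
    opt2 <- tryCatch(
      stats::optim(opt$par, fn, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(opt2) && opt2$value <= opt$value) {
      opt2$counts <- opt$counts + opt2$counts
      opt <- opt2
    }
  }
  det_fit <- criterion_from_prepared(opt$par, prep, method = method,
                                     details = TRUE)
  Sigma <- det_fit$sigma2 * tcrossprod(det_fit$Lambda)
  Sigma <- (Sigma + t(Sigma)) / 2
  term$Sigma <- Sigma
  beta <- det_fit$beta
  names(beta) <- colnames(X)
  components <- model_components(X = X, beta = beta, terms = list(term),
                                 sigma2_e = det_fit$sigma2,
                                 family_link = "gaussian-identity")
  structure(
    list(components = components, loglik = -det_fit$criterion / 2,
         criterion = det_fit$criterion, method = method,
         converged = identical(opt$convergence, 0L) ||
           identical(opt$convergence, 0),
         n_groups = prep$J,
         iterations = unname(opt$counts["function"]),
         theta = opt$par),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Linear mixed model fit (", x$method, "), ",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " evaluations\n", sep = "")
  cat("  groups: ", x$n_groups, ", log-likelihood: ",
      format(x$loglik), "\n", sep = "")
  cat("  fixed effects: ",
      paste(names(x$components$beta), round(x$components$beta, 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  residual variance: ", format(x$components$sigma2_e), "\n", sep = "")
  cat("  random-effect covariance:\n")
  print(round(x$components$terms[[1]]$Sigma, 6))
  invisible(x)
}
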