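#' Validate a random-effect covariance matrix
#'
#' Checks that `Sigma` is square, symmetric within `tol`, and positive
#' semi-definite (smallest eigenvalue no smaller than `-tol` times the
#' spectral norm). Small asymmetries are symmetrized away; anything larger
#' is an error.
#'
#' @param Sigma numeric matrix, the covariance of the random effects
#'   (k x k, ordered as the columns of the corresponding design matrix).
#' @param tol non-negative tolerance for asymmetry and for negative
#'   eigenvalues (relative to the spectral norm). Default `1e-8`.
#'
#' @return The symmetrized covariance matrix.
#' @examples
#' validate_covariance(matrix(c(1, 0.3, 0.3, 0.5), 2))
#' @export
validate_covariance <- function(Sigma, tol = 1e-8) {
  if (!is.matrix(Sigma) || !is.numeric(Sigma)) {
    stop("`Sigma` must be a numeric matrix.", call. = FALSE)
  }
  if (nrow(Sigma) != ncol(Sigma)) {
    stop("`Sigma` must be square; got ", nrow(Sigma), " x ", ncol(Sigma), ".",
         call. = FALSE)
  }
  if (anyNA(Sigma) || any(!is.finite(Sigma))) {
    stop("`Sigma` contains missing or non-finite entries.", call. = FALSE)
  }
  asym <- max(abs(Sigma - t(Sigma)))
  if (asym > tol) {
    stop("`Sigma` is asymmetric: max |Sigma - t(Sigma)| = ",
         format(asym), " exceeds tol = ", format(tol), ".", call. = FALSE)
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  spectral <- max(abs(ev), 0)
  if (min(ev) < -tol * max(spectral, 1)) {
    stop("`Sigma` is not positive semi-definite: eigenvalue ",
         format(min(ev)), " is negative.", call. = FALSE)
  }
  if (any(diag(Sigma) < 0)) {
    stop("`Sigma` has a negative diagonal (variance) entry.", call. = FALSE)
  }
  Sigma
}

#' Create a random-effect term
#'
#' A random-effect term bundles the observation-level design matrix `Z`
#' (n x k: an all-ones column if the term has a random intercept, then one
#' column per slope covariate), the k x k covariance matrix `Sigma` of the
#' effects, and the grouping factor. `Sigma` may be left `NULL` when the
#' term is destined for [fit_lmm()], which fills it in.
#'
#' @param Z numeric matrix (n observations x k effects).
#' @param Sigma covariance matrix of the effects (k x k), or `NULL`.
#' @param grouping vector of group labels, one per observation, or `NULL`
#'   when only variance computations (which do not need it) are intended.
#' @param label name of the term.
#' @param intercept does column 1 of `Z` correspond to a random intercept?
#'
#' @return An object of class `re_term`.
#' @export
re_term <- function(Z, Sigma = NULL, grouping = NULL, label = "group",
                    intercept = NULL) {
  if (!is.matrix(Z)) Z <- as.matrix(Z)
  if (!is.numeric(Z)) stop("`Z` must be numeric.", call. = FALSE)
  if (anyNA(Z)) stop("`Z` contains missing values.", call. = FALSE)
  if (ncol(Z) < 1L) stop("`Z` must have at least one column.", call. = FALSE)
  if (is.null(intercept)) {
    intercept <- all(Z[, 1L] == 1)
  }
  if (!is.null(Sigma)) {
    Sigma <- validate_covariance(Sigma)
    if (nrow(Sigma) != ncol(Z)) {
      stop("`Sigma` is ", nrow(Sigma), " x ", nrow(Sigma),
           " but `Z` has ", ncol(Z), " columns.", call. = FALSE)
    }
  }
  if (!is.null(grouping)) {
    if (length(grouping) != nrow(Z)) {
      stop("`grouping` must have one label per row of `Z`.", call. = FALSE)
    }
    grouping <- factor(grouping)
  }
  structure(
    list(label = label, Z = Z, Sigma = Sigma, grouping = grouping,
         intercept = isTRUE(intercept)),
    class = "re_term"
  )
}

#' @export
print.re_term <- function(x, ...) {
  cat("Random-effect term '", x$label, "': ", nrow(x$Z), " observations x ",
      ncol(x$Z), " effect(s)",
      if (x$intercept) " (incl. intercept)" else "", "\n", sep = "")
  if (is.null(x$Sigma)) {
    cat("  Sigma: <unset>\n")
  } else {
    cat("  Sigma:\n")
    print(x$Sigma)
  }
  invisible(x)
}

#' Build a random-effect design matrix from a data table
#'
#' Constructs the n x k design matrix `Z` of a random-effect term from
#' named columns of a data frame: an all-ones intercept column first (if
#' requested), then the slope covariates in the order given. Rows with
#' missing values in any used column (including the grouping column) are
#' dropped with a message. `Sigma` is left unset, to be estimated by
#' [fit_lmm()] or supplied by the user.
#'
#' @param data a data frame.
#' @param grouping_column name of the grouping-factor column.
#' @param intercept include a random intercept? Default `TRUE`.
#' @param slope_columns character vector of numeric covariate columns that
#'   get random slopes; may be empty when `intercept = TRUE`.
#' @param label term label; defaults to the grouping column name.
#'
#' @return An `re_term` with `Sigma = NULL`.
#' @examples
#' d <- data.frame(g = c("a", "a", "b"), x = c(0, 1, 2))
#' build_random_design(d, "g", intercept = TRUE, slope_columns = "x")
#' @export
build_random_design <- function(data, grouping_column, intercept = TRUE,
                                slope_columns = character(), label = NULL) {
  stopifnot(is.data.frame(data))
  slope_columns <- as.character(slope_columns)
  if (!intercept && length(slope_columns) == 0L) {
    stop("A term needs at least one effect: set `intercept = TRUE` or give ",
         "`slope_columns`.", call. = FALSE)
  }
  used <- c(grouping_column, slope_columns)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0L) {
    stop("Column(s) not found in `data`: ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  for (cl in slope_columns) {
    if (!is.numeric(data[[cl]])) {
      stop("Slope column '", cl, "' must be numeric.", call. = FALSE)
    }
  }
  keep <- stats::complete.cases(data[used])
  if (any(!keep)) {
    message("Dropping ", sum(!keep), " row(s) with missing values.")
    data <- data[keep, , drop = FALSE]
  }
  n <- nrow(data)
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, n)
  for (cl in slope_columns) cols[[cl]] <- data[[cl]]
  Z <- do.call(cbind, cols)
  colnames(Z) <- names(cols)
  re_term(Z, Sigma = NULL, grouping = data[[grouping_column]],
          label = label %||% grouping_column, intercept = intercept)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle fitted model components for variance partitioning
#'
#' Everything the variance-partition machinery needs: the fixed-effects
#' design and estimates, one or more random-effect terms (each with its
#' covariance matrix set), the additive-dispersion / residual variance, and
#' the response family and link.
#'
#' @param X numeric matrix, n x p fixed-effects design (include the
#'   intercept column if the model has one).
#' @param beta numeric vector of p fixed-effect estimates.
#' @param terms a single `re_term` or a list of them; distinct terms are
#'   treated as independent, so their mean variances add.
#' @param sigma2_e non-negative scalar: residual variance for
#'   gaussian-identity models, additive (observation-level) dispersion
#'   variance on the link scale otherwise.
#' @param family_link one of `"gaussian-identity"`, `"poisson-log"`,
#'   `"poisson-sqrt"`, `"binomial-logit"`, `"binomial-probit"`.
#'
#' @return An object of class `model_components`.
#' @export
model_components <- function(X, beta, terms = list(), sigma2_e = 0,
                             family_link = "gaussian-identity") {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) {
    stop("`X` must be a numeric matrix without missing values.", call. = FALSE)
  }
  beta <- stats::setNames(as.numeric(beta), names(beta))
  if (length(beta) != ncol(X)) {
    stop("length(beta) = ", length(beta), " but `X` has ", ncol(X),
         " columns.", call. = FALSE)
  }
  if (inherits(terms, "re_term")) terms <- list(terms)
  if (!all(vapply(terms, inherits, logical(1), "re_term"))) {
    stop("`terms` must be re_term objects (see re_term(), ",
         "build_random_design()).", call. = FALSE)
  }
  for (tm in terms) {
    if (nrow(tm$Z) != nrow(X)) {
      stop("Term '", tm$label, "' has ", nrow(tm$Z),
           " rows but `X` has ", nrow(X), ".", call. = FALSE)
    }
  }
  if (!is.numeric(sigma2_e) || length(sigma2_e) != 1L || sigma2_e < 0) {
    stop("`sigma2_e` must be a single non-negative number.", call. = FALSE)
  }
  family_link <- match.arg(family_link, c("gaussian-identity", "poisson-log",
                                          "poisson-sqrt", "binomial-logit",
                                          "binomial-probit"))
  structure(
    list(X = X, beta = beta, terms = terms, sigma2_e = sigma2_e,
         family_link = family_link),
    class = "model_components"
  )
}

#' @export
print.model_components <- function(x, ...) {
  cat("Model components (", x$family_link, "): n = ", nrow(x$X),
      ", p = ", length(x$beta), ", ", length(x$terms),
      " random-effect term(s), sigma2_e = ", format(x$sigma2_e), "\n",
      sep = "")
  invisible(x)
}
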