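# Random problem generators and independent oracles used across tests.

# random k x k PSD covariance via A'A (occasionally rank-deficient on purpose)
random_psd <- function(k, rank = k) {
  A <- matrix(rnorm(rank * k), rank, k)
  crossprod(A)
}

random_term <- function(n, k, intercept = k > 1, Sigma = random_psd(k)) {
  Z <- matrix(rnorm(n * k), n, k)
  if (intercept) Z[, 1] <- 1
  re_term(Z, Sigma = Sigma, intercept = intercept)
}

# Brute-force per-observation quadratic forms: the definitional path,
# independent of the vectorized implementation.
brute_obs_var <- function(Z, Sigma) {
  vapply(seq_len(nrow(Z)), function(i) {
    as.numeric(Z[i, , drop = FALSE] %*% Sigma %*% t(Z[i, , drop = FALSE]))
  }, numeric(1))
}

# Dense-covariance REML/ML criterion: builds the full n x n marginal
# covariance (up to sigma2) and evaluates the profiled -2 log-likelihood
# with generic solve()/determinant(). Oracle for profiled_criterion().
dense_criterion <- function(theta, y, X, Z, group, method = "REML") {
  k <- ncol(Z)
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- theta
  G <- L %*% t(L)
  n <- length(y)
  p <- ncol(X)
  V0 <- diag(n)
  for (g in split(seq_len(n), group)) {
    Zg <- Z[g, , drop = FALSE]
    V0[g, g] <- V0[g, g] + Zg %*% G %*% t(Zg)
  }
  Vinv <- solve(V0)
  XtViX <- t(X) %*% Vinv %*% X
  beta <- solve(XtViX, t(X) %*% Vinv %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Vinv %*% r)
  ldV0 <- as.numeric(determinant(V0, logarithm = TRUE)$modulus)
  if (method == "REML") {
    sigma2 <- rss / (n - p)
    (n - p) * (log(2 * pi * sigma2) + 1) + ldV0 +
      as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  } else {
    sigma2 <- rss / n
    n * (log(2 * pi * sigma2) + 1) + ldV0
  }
}

# small mixed-model dataset with arbitrary (non-estimated) structure
random_lmm_data <- function(n_groups = 5, size_range = c(3, 10), k = 2) {
  sizes <- sample(size_range[1]:size_range[2], n_groups, replace = TRUE)
  group <- factor(rep(seq_len(n_groups), times = sizes))
  n <- length(group)
  x <- runif(n)
  X <- cbind(1, x)
  Z <- if (k == 2) cbind(1, x) else matrix(1, n, 1)
  y <- rnorm(n, mean = 0.5 + x)
  list(y = y, X = X, Z = Z, group = group, x = x)
}
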