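# Ridge-penalized logistic regression by iteratively reweighted least squares.
#
# Training data for competing factors are typically perfectly separable, where
# unpenalized ML estimates diverge; a small ridge penalty on standardized
# slopes keeps the Newton system solvable and the iteration count bounded. The
# returned slopes are on the original predictor scale. Only the direction of
# the fitted linear score matters downstream (the intercept is re-chosen by
# the factor-fitting mode), so the iteration cap is not a practical limit.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 50L, tol = 1e-8) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0, 1)))
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  keep <- sd > 0          # constant predictors get slope 0
  Xs <- sweep(X[, keep, drop = FALSE], 2L, mu[keep])
  Xs <- sweep(Xs, 2L, sd[keep], "/")
  p <- ncol(Xs)
  Z <- cbind(1, Xs)
  beta <- numeric(p + 1L)
  pen <- diag(c(0, rep(lambda, p)), p + 1L)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    prob <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(prob, 1e-300)) +
                    (1 - y) * log(pmax(1 - prob, 1e-300)))
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) break
    dev_old <- dev
    w <- pmax(prob * (1 - prob), 1e-10)
    z <- eta + (y - prob) / w
    beta <- drop(solve(crossprod(Z, Z * w) + pen, crossprod(Z, w * z)))
  }
  slopes <- numeric(ncol(X))
  slopes[keep] <- beta[-1L] / sd[keep]
  intercept <- beta[1L] - sum(beta[-1L] * mu[keep] / sd[keep])
  list(intercept = intercept, slopes = slopes)
}
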