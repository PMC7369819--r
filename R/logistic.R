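# Internal logistic-regression machinery shared by the QTL disease scan and
# the causal inference test. The fast path is a compiled IRLS; fits that fail
# to converge or sit on the boundary of the parameter space (separation) are
# refit with Firth's penalized likelihood.

# Fit logistic y ~ X (X includes the intercept column). Returns coefficients,
# log-likelihood (penalized log-likelihood when firth = TRUE), convergence
# and separation flags.
logit_fit <- function(X, y, firth = FALSE) {
  if (firth) return(firth_logit(X, y))
  f <- .cpp_logit_irls(X, y)
  cf <- drop(f$coefficients)
  list(coefficients = cf, loglik = f$loglik,
       converged = f$converged, boundary = f$boundary, firth = FALSE)
}

# Firth-penalized logistic regression (Jeffreys-prior score correction).
# Standard algorithm: score U* = X'(y - p + h (1/2 - p)) with h the hat
# diagonals; penalized log-likelihood ll + log det(I)/2. Keeps estimates
# finite under complete separation.
firth_logit <- function(X, y, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    R <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(R)) stop("Firth fit failed: information matrix not positive definite")
    # hat diagonals of W^1/2 X (X'WX)^-1 X' W^1/2
    h <- rowSums((XW %*% chol2inv(R))* XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(chol2inv(R) %*% score)
    # cap the step to keep the iteration stable under separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta_new <- beta + step
    eta_new <- drop(X %*% beta_new)
    pll <- sum(y * eta_new - log1p(exp(pmin(eta_new, 700)))) +
      0.5 * determinant(crossprod(X * sqrt(pmax(plogis(eta_new) *
        (1 - plogis(eta_new)), 1e-12))), logarithm = TRUE)$modulus
    beta <- beta_new
    if (max(abs(step)) < tol) { converged <- TRUE; pll_old <- pll; break }
    pll_old <- pll
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  list(coefficients = beta, loglik = as.numeric(pll_old), se = se,
       converged = converged, boundary = FALSE, firth = TRUE)
}

# Likelihood-ratio test of the extra columns in X_full relative to X_reduced
# (binary outcome). Falls back to Firth penalized likelihood for BOTH models
# when either fit is non-convergent or separated, so the two log-likelihoods
# remain comparable. Returns the chi-square statistic, df, p and flags.
logit_lrt <- function(X_full, X_reduced, y) {
  f1 <- logit_fit(X_full, y)
  f0 <- logit_fit(X_reduced, y)
  firth <- FALSE
  if (!f1$converged || !f0$converged || f1$boundary || f0$boundary) {
    f1 <- firth_logit(X_full, y)
    f0 <- firth_logit(X_reduced, y)
    firth <- TRUE
  }
  df <- ncol(X_full) - ncol(X_reduced)
  stat <- max(0, 2 * (f1$loglik - f0$loglik))
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       coefficients = f1$coefficients, firth = firth)
}
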