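#' Logistic regression with optional Firth penalization
#'
#' Fits a binary logistic regression by Newton-Raphson, optionally with
#' Firth's Jeffreys-prior penalty. The penalty removes the first-order bias
#' of the maximum-likelihood estimate and yields finite estimates under
#' (quasi-)separation, which is the typical regime for rare-variant carrier
#' exposures where a cell of the 2x2 carrier/status table can be empty.
#'
#' @param X Design matrix (including the intercept column).
#' @param y Binary response vector (0/1).
#' @param firth Logical; apply Firth's penalty.
#' @param maxit Maximum Newton iterations.
#' @param tol Convergence tolerance on the (penalized) score.
#' @return List with elements `coef`, `se`, `vcov`, `loglik` (penalized when
#'   `firth = TRUE`), `converged`, `flagged` (TRUE when the fit is unreliable:
#'   non-convergence or exploding standard errors) and `iter`.
#' @export
logistic_fit <- function(X, y, firth = FALSE, maxit = 100, tol = 1e-7) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stopf("length(y) != nrow(X)")
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")

  pll <- function(beta) {
    eta <- drop(X %*% beta)
    ll <- sum(y * eta) - sum(softplus(eta))
    if (firth) {
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-12)
      I <- crossprod(X * sqrt(w))
      ll <- ll + 0.5 * determinant(I, logarithm = TRUE)$modulus
    }
    as.numeric(ll)
  }

  beta <- numeric(p)
  ybar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  if (all(X[, 1] == 1)) beta[1] <- stats::qlogis(ybar)
  ll_old <- pll(beta)
  converged <- FALSE
  iter <- 0
  I <- diag(p)

  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    Xs <- X * sqrt(w)
    I <- crossprod(Xs)
    V <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(V)) break
    resid <- y - mu
    if (firth) {
      h <- rowSums((Xs %*% V) * Xs)
      resid <- resid + h * (0.5 - mu)
    }
    U <- crossprod(X, resid)
    if (max(abs(U)) < tol) {
      converged <- TRUE
      break
    }
    delta <- drop(V %*% U)
    # step-halving to guarantee ascent of the (penalized) likelihood
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- pll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
      step <- step / 2
      if (step < 1e-6) break
    }
    if (max(abs(step * delta)) < 1e-10) {
      beta <- beta_new
      ll_old <- ll_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    ll_old <- ll_new
  }

  V <- tryCatch(solve(I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(V), 0))
  flagged <- !converged || any(!is.finite(se)) || any(se > 50)
  list(coef = beta, se = se, vcov = V, loglik = ll_old,
       converged = converged, flagged = flagged, iter = iter)
}

#' Two-sided Wald P-value for one coefficient of a logistic fit
#'
#' @param fit A [logistic_fit()] result.
#' @param j Coefficient index.
#' @return Two-sided normal-approximation P-value.
#' @export
wald_p <- function(fit, j) {
  z <- fit$coef[j] / fit$se[j]
  unname(2 * stats::pnorm(-abs(z)))
}

#' Likelihood-ratio test for one column of a logistic design
#'
#' Penalized (or plain) likelihood-ratio test comparing the full model to
#' the model without column `j`. Better calibrated than the Wald test for
#' sparse carrier exposures.
#'
#' @param X Design matrix (including intercept).
#' @param y Binary response.
#' @param j Column of `X` to test.
#' @param firth Apply Firth penalization to both fits.
#' @return List: `p`, `full` (the full-model [logistic_fit()]), `stat`.
#' @export
lrt_p <- function(X, y, j, firth = FALSE) {
  full <- logistic_fit(X, y, firth = firth)
  red <- logistic_fit(X[, -j, drop = FALSE], y, firth = firth)
  stat <- max(0, 2 * (full$loglik - red$loglik))
  list(p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       full = full, stat = stat)
}
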