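#' Fit a logistic regression by penalized maximum likelihood
#'
#' Newton / iteratively reweighted least squares with step-halving,
#' maximizing the Bernoulli log-likelihood minus `(l2 / 2) * ||theta||^2`
#' over the non-intercept coefficients (the intercept is never
#' penalized).  The default ridge `l2 = 1e-6` only guards against
#' divergence under (near-)separable data; `l2 = 0` gives the pure
#' maximum-likelihood fit.
#'
#' @param X Numeric matrix of features (no intercept column; it is added
#'   internally as the constant regressor `x_0 = 1`).
#' @param y Binary labels (0/1), both classes present.
#' @param l2 Ridge penalty on non-intercept weights, default `1e-6`.
#' @param tol Convergence tolerance on the penalized log-likelihood
#'   improvement and on the gradient norm, default `1e-8`.
#' @param max_iter Maximum Newton iterations, default 100.
#' @return A list of class `logit_fit`: `coef` (named, `(Intercept)`
#'   first), `converged`, `iterations`, `loglik` (final unpenalized
#'   log-likelihood), `loglik_trace` (penalized objective per iteration)
#'   and `gradient_norm`.
#' @export
#' @examples
#' x <- matrix(rnorm(200), ncol = 1)
#' y <- rbinom(100, 1, plogis(2 * x[, 1]))
#' fit <- fit_logistic(x, y)
#' round(coef(fit), 2)
fit_logistic <- function(X, y, l2 = 1e-6, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y) || length(y) < 2L) {
    abort("`X` and `y` must agree in length (>= 2)")
  }
  if (length(unique(y)) < 2L) {
    abort("both classes must be present in `y`")
  }
  if (is.null(colnames(X)) && ncol(X) > 0L) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  A <- cbind(`(Intercept)` = 1, X)
  p <- ncol(A)
  pen <- c(0, rep(l2, p - 1L))         # intercept unpenalized
  theta <- numeric(p)

  objective <- function(theta) {
    eta <- drop(A %*% theta)
    # numerically stable Bernoulli log-likelihood
    ll <- sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
    ll - sum(pen * theta^2) / 2
  }

  obj <- objective(theta)
  trace <- obj
  converged <- FALSE
  grad_norm <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(A %*% theta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(A, y - mu)) - pen * theta
    grad_norm <- sqrt(sum(grad^2))
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(A * w, A)
    diag(H) <- diag(H) + pen + 1e-12
    step <- solve(H, grad)
    # step-halving on the penalized objective
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      cand_obj <- objective(cand)
      if (is.finite(cand_obj) && cand_obj >= obj - 1e-14) break
      lambda <- lambda / 2
      if (lambda < 1e-10) {
        cand <- theta
        cand_obj <- obj
        break
      }
    }
    improvement <- cand_obj - obj
    theta <- cand
    obj <- cand_obj
    trace <- c(trace, obj)
    if (grad_norm < tol || improvement < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "logistic fit did not converge in %d iterations (gradient norm %.3g)",
      max_iter, grad_norm))
  }
  names(theta) <- colnames(A)
  eta <- drop(A %*% theta)
  ll <- sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  structure(list(coef = theta, converged = converged, iterations = iter,
                 loglik = ll, loglik_trace = trace,
                 gradient_norm = grad_norm, l2 = l2, n = length(y)),
            class = "logit_fit")
}

#' @export
coef.logit_fit <- function(object, ...) object$coef

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: %d obs, %d coefficients, %sconverged in %d iterations\n",
              x$n, length(x$coef), if (x$converged) "" else "NOT ",
              x$iterations))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predicted acetylation probability from logistic weights
#'
#' `sigmoid(theta . (1, x))`; the constant regressor is added internally,
#' user-facing feature vectors never contain it.
#'
#' @param weights A `logit_fit` or a numeric weight vector with the
#'   intercept first.
#' @param X Numeric matrix (or vector for a single observation) of
#'   features, columns matching the non-intercept weights.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict_prob <- function(weights, X) {
  theta <- if (inherits(weights, "logit_fit")) weights$coef else weights
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) + 1L != length(theta)) {
    abort(sprintf("feature count %d does not match weight count %d (+ intercept)",
                  ncol(X), length(theta) - 1L))
  }
  drop(stats::plogis(theta[1] + X %*% theta[-1]))
}

#' @method tidy logit_fit
#' @export
tidy.logit_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @method glance logit_fit
#' @export
glance.logit_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, iterations = x$iterations,
                 converged = x$converged, nobs = x$n)
}
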