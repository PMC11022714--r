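# Elastic-net penalized logistic regression. The solver (src/enet.cpp) runs
# cyclic coordinate descent on the IRLS quadratic approximation with warm
# starts along a descending lambda path; soft thresholding yields exact
# zeros, which is what the selection-frequency criterion counts.

#' Fit an elastic-net logistic classifier
#'
#' Minimizes
#' \deqn{(1/n)\sum_i \ell(y_i, \beta_0 + x_i'\beta) +
#'       \lambda[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2]}
#' where \eqn{\ell} is the logistic log-loss, by cyclic coordinate descent
#' on the iteratively reweighted least-squares approximation. The intercept
#' is unpenalized. Convergence is declared when the largest coefficient
#' change across an outer reweighting falls below `tol`.
#'
#' @param X numeric n x p matrix (standardized columns recommended).
#' @param y 0/1 labels, both classes present.
#' @param alpha L1/L2 mixing parameter in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda penalty strength (>= 0); may be a descending vector, in
#'   which case the fit at the *last* value is returned (warm-started).
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_outer maximum IRLS reweightings per lambda.
#' @param feature_mz optional m/z provenance attached to the coefficients.
#' @return Object of class `enet_fit`: `beta`, `intercept`, `alpha`,
#'   `lambda`, `converged`, `feature_mz`.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, lambda, tol = 1e-7,
                            max_outer = 100, feature_mz = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (any(!is.finite(X))) stop_param("non-finite values in X")
  if (!all(y %in% c(0, 1))) stop_param("y must be 0/1")
  if (length(unique(y)) < 2L)
    stop_param("both classes must be present in y")
  if (alpha < 0 || alpha > 1) stop_param("alpha must be in [0, 1]")
  if (any(lambda < 0)) stop_param("lambda must be >= 0")
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  fit <- .cd_enet_logistic(X, y, alpha, lambda, tol, max_outer)
  l <- length(lambda)
  structure(list(beta = fit$beta[, l],
                 intercept = fit$intercept[l],
                 alpha = alpha, lambda = lambda[l],
                 converged = fit$converged[l],
                 feature_mz = feature_mz),
            class = "enet_fit")
}

# Warm-started fits at every lambda of a descending path; returns the
# p x nlambda coefficient matrix and intercept vector.
enet_path <- function(X, y, alpha, lambdas, tol = 1e-7, max_outer = 100L,
                      max_sweeps = 10000L) {
  .cd_enet_logistic(as.matrix(X), as.numeric(y), alpha,
                    as.numeric(lambdas), tol, max_outer, max_sweeps)
}

#' Elastic-net regularization objective
#'
#' The penalized average logistic loss minimized by [fit_elastic_net()];
#' exposed so fits can be compared against generic convex optimizers.
#'
#' @param X,y data as in [fit_elastic_net()].
#' @param beta,intercept coefficients.
#' @param alpha,lambda penalty parameters.
#' @return The objective value (scalar).
#' @export
enet_objective <- function(X, y, beta, intercept, alpha, lambda) {
  eta <- intercept + as.matrix(X) %*% beta
  loss <- mean(log1p(exp(eta)) - y * eta)
  loss + lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf(
    "elastic-net logistic fit: alpha = %.3g, lambda = %.4g, %d/%d nonzero coefficients\n",
    x$alpha, x$lambda, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' @export
coef.enet_fit <- function(object, ...) {
  c(`(Intercept)` = object$intercept,
    stats::setNames(object$beta,
                    if (!is.null(object$feature_mz))
                      sprintf("mz%.4f", object$feature_mz)
                    else paste0("V", seq_along(object$beta))))
}

#' @export
predict.enet_fit <- function(object, newdata, type = c("response", "link"),
                             ...) {
  type <- match.arg(type)
  eta <- drop(object$intercept + as.matrix(newdata) %*% object$beta)
  if (type == "link") eta else stats::plogis(eta)
}

# Descending lambda grid: from lambda_max (the smallest penalty that zeroes
# every coefficient; alpha is floored at 0.001 so ridge gets a finite grid)
# down `decades` orders of magnitude, log-spaced.
lambda_grid <- function(X, y, alpha, nlambda = 30, decades = 4) {
  ybar <- mean(y)
  lmax <- max(abs(crossprod(as.matrix(X), y - ybar))) /
    (length(y) * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = nlambda))
}
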