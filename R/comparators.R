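# Comparator classifiers benchmarked against the elastic net: ridge
# logistic regression (alpha-0 elastic net), k-nearest neighbours, and
# Gaussian naive Bayes (via e1071). Each returns an object usable with
# score_samples() to obtain class-1 scores on new data.

#' Fit a comparator classifier
#'
#' @param X numeric n x p matrix (standardized columns expected).
#' @param y 0/1 labels, both classes present.
#' @param kind `"ridge"`, `"knn"` or `"naive_bayes"`.
#' @param hyperparams list: `lambda` for ridge; `k` for knn.
#' @return Object of class `comparator_fit`.
#' @export
fit_comparator <- function(X, y, kind = c("ridge", "knn", "naive_bayes"),
                           hyperparams = list()) {
  kind <- match.arg(kind)
  X <- as.matrix(X); y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop_param("both classes must be present")
  fit <- switch(kind,
    ridge = {
      lam <- hyperparams$lambda %||% 0.01
      fit_elastic_net(X, y, alpha = 0, lambda = lam)
    },
    knn = {
      k <- hyperparams$k %||% 5L
      if (k > nrow(X)) stop_param("k exceeds the number of training samples")
      list(X = X, y = y, k = as.integer(k))
    },
    naive_bayes = {
      keep <- which(apply(X, 2, stats::sd) > 1e-12)
      if (!length(keep)) stop_param("all features are constant")
      df <- as.data.frame(X[, keep, drop = FALSE])
      names(df) <- paste0("V", keep)
      list(nb = e1071::naiveBayes(df, factor(y, levels = c(0, 1))),
           keep = keep)
    })
  structure(list(kind = kind, fit = fit), class = "comparator_fit")
}

#' Score samples with a fitted model
#'
#' Class-1 score in \[0, 1\]: predicted probability for the penalized
#' logistic models and naive Bayes, and the fraction of class-1 neighbours
#' among the k nearest (Euclidean distance, deterministic index-order tie
#' break) for knn.
#'
#' @param model an `enet_fit` or `comparator_fit`.
#' @param X matrix of samples to score (same feature space/standardization
#'   as training).
#' @return Numeric score vector.
#' @export
score_samples <- function(model, X) {
  X <- as.matrix(X)
  if (inherits(model, "enet_fit")) return(predict(model, X))
  stopifnot(inherits(model, "comparator_fit"))
  switch(model$kind,
    ridge = predict(model$fit, X),
    knn = {
      tr <- model$fit
      d2 <- outer(rowSums(X^2), rowSums(tr$X^2), "+") -
        2 * tcrossprod(X, tr$X)
      apply(d2, 1, function(d) {
        nn <- order(d)[seq_len(tr$k)]
        mean(tr$y[nn])
      })
    },
    naive_bayes = {
      df <- as.data.frame(X[, model$fit$keep, drop = FALSE])
      names(df) <- paste0("V", model$fit$keep)
      unname(predict(model$fit$nb, df, type = "raw")[, "1"])
    })
}
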