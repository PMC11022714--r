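# Nested cross-validation: the outer folds estimate generalization, the
# inner folds choose hyperparameters, and repeated rounds give the model
# ensemble whose per-feature selection frequency drives biomarker
# selection. rounds x outer_folds models in total (20 x 5 = 100 at the
# defaults). Standardization statistics are always computed on the training
# portion of a split and applied to its held-out portion, so no test-fold
# information leaks into training.

#' Nested cross-validation configuration
#'
#' @param outer_folds number of outer folds (default 5).
#' @param inner_folds number of inner folds for hyperparameter search
#'   (default 5).
#' @param rounds number of repeated rounds (default 20; rounds x
#'   outer_folds models are fitted).
#' @param alpha_grid elastic-net mixing grid.
#' @param nlambda,lambda_decades penalty grid: `nlambda` log-spaced values
#'   from lambda_max (smallest penalty zeroing all coefficients) down
#'   `lambda_decades` orders of magnitude.
#' @param k_grid neighbour counts searched for the knn comparator.
#' @param seed base RNG seed; round r uses `seed + r - 1`.
#' @param stratified preserve class proportions within folds (default TRUE).
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 5L, inner_folds = 5L, rounds = 20L,
                      alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      nlambda = 30L, lambda_decades = 4,
                      k_grid = c(3L, 5L, 7L, 9L, 11L, 15L, 21L),
                      seed = 1L, stratified = TRUE) {
  if (outer_folds < 2L) stop_param("outer_folds must be >= 2")
  if (inner_folds < 2L) stop_param("inner_folds must be >= 2")
  if (rounds < 1L) stop_param("rounds must be >= 1")
  if (!length(alpha_grid) || !nlambda)
    stop_param("hyperparameter grids must be non-empty")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 rounds = as.integer(rounds),
                 alpha_grid = sort(alpha_grid), nlambda = as.integer(nlambda),
                 lambda_decades = lambda_decades,
                 k_grid = sort(as.integer(k_grid)),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "cv_config")
}

# Platt rescaling: a one-dimensional logistic refit of the class label on
# the penalized model's linear predictor, estimated on the training fold.
# Penalized maximum likelihood shrinks coefficients, which preserves
# ranking but compresses predicted probabilities toward the class
# prevalence; the rescaled probabilities restore an honest scale around
# the 0.5 decision threshold. Returns c(offset, slope).
platt_calibration <- function(eta, y) {
  if (length(unique(y)) < 2L || stats::sd(eta) < 1e-12) return(c(0, 1))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, eta), y,
                   family = stats::binomial(link = "logit")))
  co <- fit$coefficients
  if (anyNA(co) || any(!is.finite(co)) || co[2] <= 0) return(c(0, 1))
  unname(co)
}

# Balanced (optionally stratified) fold assignment drawn from the current
# RNG stream.
stratified_folds <- function(y, k, stratified = TRUE) {
  fold <- integer(length(y))
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k)
        stop_param("class ", cl, " has fewer samples (", length(idx),
                   ") than folds (", k, ")")
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    if (length(y) < k) stop_param("fewer samples than folds")
    fold <- sample(rep_len(seq_len(k), length(y)))
  }
  fold
}

# AUC as the mid-rank (concordant-pair) statistic; used in the inner loop
# where only the value, not the curve, is needed.
fast_auc <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- length(y) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Inner-loop hyperparameter search for the penalized logistic learners:
# pooled inner out-of-fold AUC over the (alpha, lambda) grid; ties resolve
# to the first grid point scanned (smallest alpha, largest lambda), i.e.
# toward the more grouped, more penalized model, which is what makes the
# selection frequencies stable. Probability calibration is handled
# downstream (Platt rescaling at refit time), so the search only has to
# rank well. Inner solves use a looser tolerance than final refits: the
# ranking over the grid is insensitive to the last decimals of the
# coefficients.
inner_search_enet <- function(X, y, alphas, config) {
  n <- nrow(X)
  ifold <- stratified_folds(y, config$inner_folds, config$stratified)
  st_all <- standardize_stats(X)
  Zall <- apply_standardize(X, st_all)
  base_lmax <- max(abs(crossprod(Zall, y - mean(y)))) / n
  fold_data <- lapply(seq_len(config$inner_folds), function(f) {
    tr <- which(ifold != f); te <- which(ifold == f)
    if (length(unique(y[tr])) < 2L) return(NULL)
    st <- standardize_stats(X[tr, , drop = FALSE])
    list(tr = tr, te = te,
         Ztr = apply_standardize(X[tr, , drop = FALSE], st),
         Zte = apply_standardize(X[te, , drop = FALSE], st))
  })
  if (any(vapply(fold_data, is.null, TRUE)))
    stop_param("inner cross-validation failed: a class is absent from an inner training fold")
  best <- list(auc = -Inf)
  first_grid <- NULL
  for (a in alphas) {
    lmax <- base_lmax / max(a, 1e-3)
    lgrid <- exp(seq(log(lmax), log(lmax) - config$lambda_decades * log(10),
                     length.out = config$nlambda))
    if (is.null(first_grid)) first_grid <- lgrid
    scores <- matrix(NA_real_, n, length(lgrid))
    for (fd in fold_data) {
      path <- enet_path(fd$Ztr, y[fd$tr], a, lgrid, tol = 1e-4,
                        max_outer = 12L, max_sweeps = 60L)
      # linear predictor suffices: AUC is invariant to the logistic link
      scores[fd$te, ] <- sweep(fd$Zte %*% path$beta, 2, path$intercept, "+")
    }
    for (l in seq_along(lgrid)) {
      auc <- fast_auc(scores[, l], y)
      if (auc > best$auc)
        best <- list(auc = auc, alpha = a, lambda = lgrid[l],
                     lambda_index = l, lgrid = lgrid,
                     oof_eta = scores[, l])
    }
  }
  # Chance gate: with G grid points searched, the maximum inner AUC on a
  # signal-free cohort concentrates near 0.5 + z_{1-0.05/G} * SE0, where
  # SE0^2 = (n+1)/(12 n1 n0) is the null variance of the rank-sum AUC.
  # A winner that does not clear this bound is indistinguishable from
  # chance, so the fully penalized null model is kept instead; this keeps
  # stability-selection frequencies calibrated on null cohorts and is a
  # no-op whenever genuine signal is present.
  n1 <- sum(y == 1); n0 <- n - n1
  G <- length(alphas) * config$nlambda
  gate <- 0.5 + stats::qnorm(1 - 0.05 / G) *
    sqrt((n + 1) / (12 * n1 * n0))
  if (best$auc < min(gate, 0.95)) {
    best <- list(auc = 0.5, alpha = alphas[1], lambda = first_grid[1],
                 lambda_index = 1L, lgrid = first_grid, gated = TRUE)
  }
  best
}

inner_search_knn <- function(X, y, config) {
  n <- nrow(X)
  ifold <- stratified_folds(y, config$inner_folds, config$stratified)
  ks <- config$k_grid[config$k_grid < n - ceiling(n / config$inner_folds)]
  if (!length(ks)) ks <- 1L
  best <- list(auc = -Inf)
  for (k in ks) {
    scores <- numeric(n)
    for (f in seq_len(config$inner_folds)) {
      tr <- which(ifold != f); te <- which(ifold == f)
      st <- standardize_stats(X[tr, , drop = FALSE])
      m <- fit_comparator(apply_standardize(X[tr, , drop = FALSE], st),
                          y[tr], "knn", list(k = k))
      scores[te] <- score_samples(
        m, apply_standardize(X[te, , drop = FALSE], st))
    }
    auc <- roc_auc(scores, y)$auc
    if (auc > best$auc) best <- list(auc = auc, k = k)
  }
  best
}

#' Nested cross-validated classification
#'
#' The package's central fitting function. For each round (seeded
#' `seed + round - 1`) the samples are split into stratified outer folds;
#' within each outer-training set an inner 5-fold grid search picks the
#' hyperparameters maximizing pooled inner out-of-fold AUC; the model is
#' refit on the outer-training set and scores its outer-test fold. With the
#' default configuration this yields 20 x 5 = 100 models, each sample
#' scored exactly once per round, and (for the elastic net) the fraction
#' of the 100 models in which each feature kept a nonzero coefficient —
#' the selection frequency used for biomarker discovery.
#'
#' @param x a [feature_matrix()] (TIC-normalized, unstandardized:
#'   standardization happens inside training folds), or a plain numeric
#'   matrix with `y` supplied.
#' @param y 0/1 labels when `x` is a plain matrix.
#' @param config a [cv_config()].
#' @param learner `"elastic_net"`, `"ridge"`, `"knn"` or `"naive_bayes"`.
#' @return Object of class `nested_cv` with components `models` (one per
#'   round x fold: coefficients or fitted comparator, standardization
#'   statistics, chosen hyperparameters, training indices), `oof_scores`
#'   (rounds x n, each row a complete out-of-fold scoring of the cohort),
#'   `folds` (rounds x n fold assignment), `selection_frequency` (length-p,
#'   elastic net only), `chosen_hyperparams`, `round_auc`, `mean_auc`,
#'   `pooled_scores` (per-sample mean out-of-fold score), `pooled_roc`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `fitted`,
#'   `residuals`.
#' @export
nested_cv <- function(x, y = NULL, config = cv_config(),
                      learner = c("elastic_net", "ridge", "knn",
                                  "naive_bayes")) {
  learner <- match.arg(learner)
  stopifnot(inherits(config, "cv_config"))
  if (inherits(x, "feature_matrix")) {
    if (x$standardized)
      stop_param("pass the unstandardized matrix: standardization is done inside training folds")
    X <- x$X; y <- x$y; feature_mz <- x$feature_mz
    sample_ids <- x$sample_ids
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop_param("y required when x is a plain matrix")
    feature_mz <- as.numeric(colnames(X) %||% seq_len(ncol(X)))
    sample_ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 10L) stop_param("need at least 10 samples")
  if (length(unique(y)) < 2L) stop_param("both classes must be present")

  models <- vector("list", config$rounds * config$outer_folds)
  oof <- matrix(NA_real_, config$rounds, n,
                dimnames = list(NULL, sample_ids))
  folds <- matrix(NA_integer_, config$rounds, n)
  hp <- list()
  mi <- 0L
  for (r in seq_len(config$rounds)) {
    with_seed(config$seed + r - 1L, {
      fold <- stratified_folds(y, config$outer_folds, config$stratified)
      folds[r, ] <- fold
      for (f in seq_len(config$outer_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
        st <- standardize_stats(Xtr)
        Ztr <- apply_standardize(Xtr, st)
        Zte <- apply_standardize(X[te, , drop = FALSE], st)
        mi <- mi + 1L
        model <- list(learner = learner, round = r, fold = f,
                      train_idx = tr, center = st$center, scale = st$scale,
                      zero = st$zero)
        if (learner %in% c("elastic_net", "ridge")) {
          alphas <- if (learner == "ridge") 0 else config$alpha_grid
          best <- inner_search_enet(Xtr, ytr, alphas, config)
          fit <- enet_path(Ztr, ytr, best$alpha,
                           best$lgrid[seq_len(best$lambda_index)])
          l <- best$lambda_index
          model$beta <- fit$beta[, l]
          model$intercept <- fit$intercept[l]
          model$alpha <- best$alpha; model$lambda <- best$lambda
          # calibrate on held-out (inner out-of-fold) predictors, where
          # the two classes overlap, so the slope cannot diverge
          model$calib <- if (is.null(best$oof_eta)) c(0, 1) else
            platt_calibration(best$oof_eta, ytr)
          eta_te <- drop(model$intercept + Zte %*% model$beta)
          oof[r, te] <- stats::plogis(
            model$calib[1] + model$calib[2] * eta_te)
          hp[[mi]] <- data.frame(round = r, fold = f, alpha = best$alpha,
                                 lambda = best$lambda,
                                 inner_auc = best$auc)
        } else if (learner == "knn") {
          best <- inner_search_knn(Xtr, ytr, config)
          model$k <- best$k
          fitk <- fit_comparator(Ztr, ytr, "knn", list(k = best$k))
          oof[r, te] <- score_samples(fitk, Zte)
          hp[[mi]] <- data.frame(round = r, fold = f, k = best$k,
                                 inner_auc = best$auc)
        } else {
          fitnb <- fit_comparator(Ztr, ytr, "naive_bayes")
          model$nb <- fitnb
          oof[r, te] <- score_samples(fitnb, Zte)
          hp[[mi]] <- data.frame(round = r, fold = f)
        }
        models[[mi]] <- model
      }
    })
  }
  selection_frequency <- if (learner == "elastic_net") {
    rowMeans(matrix(vapply(models, function(m) m$beta != 0, logical(p)),
                    nrow = p))
  } else NULL
  round_auc <- apply(oof, 1, function(s) roc_auc(s, y)$auc)
  pooled <- colMeans(oof)
  structure(list(models = models, oof_scores = oof, folds = folds,
                 selection_frequency = selection_frequency,
                 chosen_hyperparams = do.call(rbind, hp),
                 round_auc = round_auc, mean_auc = mean(round_auc),
                 pooled_scores = pooled,
                 pooled_roc = roc_auc(pooled, y),
                 learner = learner, config = config,
                 feature_mz = feature_mz, sample_ids = sample_ids,
                 y = y, X = X, call = match.call()),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf(
    "nested_cv (%s): %d rounds x %d outer folds = %d models on %d samples x %d features\n",
    x$learner, x$config$rounds, x$config$outer_folds, length(x$models),
    length(x$y), length(x$feature_mz)))
  cat(sprintf("  mean out-of-fold AUC: %.4f (rounds %.4f-%.4f)\n",
              x$mean_auc, min(x$round_auc), max(x$round_auc)))
  if (!is.null(x$selection_frequency))
    cat(sprintf("  features with selection frequency > 0.8: %d\n",
                sum(x$selection_frequency > 0.8)))
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, cutoff = "closest01", ...) {
  ci <- auc_ci(object$pooled_scores, object$y)
  cut <- choose_cutoff(object$pooled_roc, cutoff)
  out <- list(learner = object$learner,
              n = length(object$y), p = length(object$feature_mz),
              n_models = length(object$models),
              mean_auc = object$mean_auc,
              round_auc = object$round_auc,
              pooled_auc = object$pooled_roc$auc,
              pooled_ci95 = as.numeric(ci),
              cutoff_method = cutoff, cutoff = cut,
              selection_frequency = object$selection_frequency,
              feature_mz = object$feature_mz,
              chosen_hyperparams = object$chosen_hyperparams)
  class(out) <- "summary.nested_cv"
  out
}

#' @export
print.summary.nested_cv <- function(x, ...) {
  cat(sprintf("Nested cross-validated %s on %d samples x %d features\n",
              x$learner, x$n, x$p))
  cat(sprintf("  %d models; mean AUC %.4f; pooled AUC %.4f (95%% CI %.4f-%.4f)\n",
              x$n_models, x$mean_auc, x$pooled_auc,
              x$pooled_ci95[1], x$pooled_ci95[2]))
  cat(sprintf("  cutoff (%s): threshold %.4f, sensitivity %.3f, specificity %.3f\n",
              x$cutoff_method, x$cutoff$threshold, x$cutoff$sensitivity,
              x$cutoff$specificity))
  if (!is.null(x$selection_frequency)) {
    top <- order(-x$selection_frequency)[seq_len(min(6, x$p))]
    cat("  top selection frequencies:\n")
    for (j in top)
      cat(sprintf("    m/z %9.4f  freq %.2f\n", x$feature_mz[j],
                  x$selection_frequency[j]))
  }
  invisible(x)
}

#' @export
coef.nested_cv <- function(object, ...) {
  if (object$learner %in% c("elastic_net", "ridge")) {
    p <- length(object$feature_mz)
    B <- matrix(vapply(object$models, `[[`, numeric(p), "beta"), nrow = p)
    data.frame(feature_mz = object$feature_mz,
               mean_beta = rowMeans(B),
               selection_frequency = object$selection_frequency %||%
                 rep(NA_real_, length(object$feature_mz)))
  } else NULL
}

#' @export
predict.nested_cv <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_mz))
    stop_param("newdata has ", ncol(newdata), " features; model expects ",
               length(object$feature_mz))
  scores <- vapply(object$models, function(m) {
    st <- list(center = m$center, scale = m$scale, zero = m$zero)
    Z <- apply_standardize(newdata, st)
    switch(m$learner,
      elastic_net = ,
      ridge = {
        cal <- m$calib %||% c(0, 1)
        stats::plogis(cal[1] + cal[2] * drop(m$intercept + Z %*% m$beta))
      },
      knn = {
        sttr <- apply_standardize(object$X[m$train_idx, , drop = FALSE], st)
        fitk <- fit_comparator(sttr, object$y[m$train_idx], "knn",
                               list(k = m$k))
        score_samples(fitk, Z)
      },
      naive_bayes = score_samples(m$nb, Z))
  }, numeric(nrow(newdata)))
  rowMeans(matrix(scores, nrow = nrow(newdata)))
}

#' @export
fitted.nested_cv <- function(object, ...) object$pooled_scores

#' @export
residuals.nested_cv <- function(object, ...)
  object$y - object$pooled_scores

#' @export
plot.nested_cv <- function(x, ...) {
  plot(x$pooled_roc,
       main = sprintf("%s: pooled out-of-fold ROC (mean AUC %.3f)",
                      x$learner, x$mean_auc), ...)
  invisible(x)
}
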