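# ROC/AUC machinery: the AUC as the proportion of concordant case-control
# pairs (ties counted half), DeLong structural-component variance for
# confidence intervals and paired AUC comparison, and the three decision
# cutoff strategies.

#' ROC curve and AUC
#'
#' The AUC equals the proportion of concordant pairs among all case-control
#' pairs of observations (ties counted 1/2), computed via mid-ranks. The
#' curve is built from the sorted unique scores used as thresholds (a
#' sample is called positive when its score >= threshold), with the
#' (fpr, tpr) staircase anchored at (0,0) and (1,1).
#'
#' @param scores numeric classifier scores, higher = more case-like.
#' @param labels 0/1 labels, both classes present.
#' @return Object of class `roc_curve`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   and `ci95` (NULL until [auc_ci()] is consulted).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop_param("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_param("both classes must be present")
  if (anyNA(scores) || any(!is.finite(scores)))
    stop_param("non-finite scores")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1), 0) / n1
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0), 0) / n0
  structure(list(thresholds = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr),
                 auc = auc, ci95 = NULL,
                 scores = scores, labels = labels),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d cases / %d controls)\n",
              x$auc, sum(x$labels == 1), sum(x$labels == 0)))
  if (!is.null(x$ci95))
    cat(sprintf("  95%% CI (DeLong): %.4f-%.4f\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    plot.default(x$fpr, x$tpr, type = "s", col = col,
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
    abline(0, 1, lty = 3, col = "grey60")
  } else lines(x$fpr, x$tpr, type = "s", col = col, ...)
  invisible(x)
}

# DeLong structural components: V10[i] = mean_j psi(case_i, control_j),
# V01[j] = mean_i psi(case_i, control_j), psi = 1/0.5/0 for >/=/<.
delong_components <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  psi <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong confidence interval for an AUC
#'
#' Normal-approximation 95% interval using the DeLong structural-component
#' variance estimate, clipped to \[0, 1\].
#'
#' @param scores,labels as in [roc_auc()]; each class needs >= 2 members.
#' @param conf_level confidence level (default 0.95).
#' @return Numeric length-2 vector `(lo, hi)`; attribute `"var"` carries
#'   the variance estimate.
#' @export
auc_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- as.numeric(labels)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop_param("each class needs at least two members")
  dc <- delong_components(scores, labels)
  v <- stats::var(dc$v10) / length(dc$v10) +
    stats::var(dc$v01) / length(dc$v01)
  if (v <= 0) {
    out <- c(dc$auc, dc$auc)
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    out <- pmin(pmax(dc$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  }
  attr(out, "var") <- v
  attr(out, "auc") <- dc$auc
  out
}

#' Choose a decision cutoff on a ROC curve
#'
#' Three strategies: `youden` maximizes sensitivity + specificity - 1;
#' `closest01` minimizes the Euclidean distance to the perfect corner
#' (0, 1); `equal_ss` minimizes |sensitivity - specificity|. Ties are
#' broken by higher sensitivity, then by lower threshold.
#'
#' @param curve a `roc_curve` from [roc_auc()].
#' @param method `"youden"`, `"closest01"` or `"equal_ss"`.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
choose_cutoff <- function(curve, method = c("youden", "closest01",
                                            "equal_ss")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "roc_curve"))
  sens <- curve$tpr
  spec <- 1 - curve$fpr
  crit <- switch(method,
    youden = -(sens + spec - 1),                  # minimized
    closest01 = sqrt(curve$fpr^2 + (1 - sens)^2),
    equal_ss = abs(sens - spec))
  # lexicographic: smallest criterion, then higher sensitivity, then lower
  # threshold
  ord <- order(crit, -sens, curve$thresholds)
  i <- ord[1L]
  list(threshold = curve$thresholds[i], sensitivity = sens[i],
       specificity = spec[i])
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two classifiers scored on the same samples, using
#' the difference of DeLong structural components; two-sided normal
#' p-value.
#'
#' @param scoresA,scoresB paired score vectors on the same samples.
#' @param labels shared 0/1 labels.
#' @return List with `z`, `p.value`, `aucA`, `aucB`.
#' @export
delong_test <- function(scoresA, scoresB, labels) {
  labels <- as.numeric(labels)
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop_param("scoresA, scoresB and labels must have equal length")
  a <- delong_components(scoresA, labels)
  b <- delong_components(scoresB, labels)
  v <- stats::var(a$v10 - b$v10) / length(a$v10) +
    stats::var(a$v01 - b$v01) / length(a$v01)
  d <- a$auc - b$auc
  if (v <= 0) {
    if (d != 0)
      warning("zero DeLong variance with unequal AUCs", call. = FALSE)
    return(list(z = 0, p.value = 1, aucA = a$auc, aucB = b$auc))
  }
  z <- d / sqrt(v)
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)),
       aucA = a$auc, aucB = b$auc)
}
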