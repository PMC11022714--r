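# Three-criterion biomarker selection on nested-CV output: a feature is a
# biomarker candidate when (1) its selection frequency across the CV model
# ensemble exceeds 80%, (2) its two-sided t-test p-value is below 0.05,
# and (3) its 107Ag/109Ag isotope partner also survives both filters.
# Surviving features are grouped into doublets, each doublet mapping to one
# metabolite.

#' Selection criteria for biomarker discovery
#'
#' @param freq_min minimum selection frequency; features must exceed this
#'   strictly (default 0.80, i.e. "over 80% of the models").
#' @param p_max t-test significance threshold, strict (default 0.05).
#' @param require_pair require the 107Ag/109Ag isotope partner to survive
#'   both filters as well (default TRUE).
#' @param pair_tol doublet spacing tolerance (Da) passed to
#'   [find_isotope_pairs()] when pairs are not supplied.
#' @param adjust p-value adjustment method (`"none"`, the default and the
#'   criterion as stated, or any method of [stats::p.adjust()], e.g.
#'   `"BH"`).
#' @return Object of class `selection_criteria`.
#' @export
selection_criteria <- function(freq_min = 0.80, p_max = 0.05,
                               require_pair = TRUE, pair_tol = 0.02,
                               adjust = "none") {
  if (freq_min <= 0 || freq_min > 1) stop_param("freq_min must be in (0, 1]")
  if (p_max <= 0 || p_max >= 1) stop_param("p_max must be in (0, 1)")
  structure(list(freq_min = freq_min, p_max = p_max,
                 require_pair = isTRUE(require_pair), pair_tol = pair_tol,
                 adjust = adjust),
            class = "selection_criteria")
}

#' Per-feature two-sided Welch t-tests
#'
#' Welch (unequal-variance) two-sample t-test of case versus control for
#' every feature column, applied to the normalized (pre-standardization)
#' intensities. Features that are constant within the cohort, or for which
#' the test is degenerate (zero variance in both classes), get p = 1.
#'
#' @param matrix a [feature_matrix()] (unstandardized).
#' @param adjust optional [stats::p.adjust()] method (default `"none"`).
#' @return Numeric vector of p-values, one per feature.
#' @export
ttest_features <- function(matrix, adjust = "none") {
  stopifnot(inherits(matrix, "feature_matrix"))
  g1 <- matrix$y == 1; g0 <- matrix$y == 0
  if (sum(g1) < 2L || sum(g0) < 2L)
    stop_param("each class needs at least two samples for t-tests")
  p <- apply(matrix$X, 2, function(v) {
    out <- tryCatch(
      stats::t.test(v[g1], v[g0], var.equal = FALSE)$p.value,
      error = function(e) 1)
    if (is.na(out)) 1 else out
  })
  stats::p.adjust(p, method = adjust)
}

#' Select biomarkers by the three-criterion rule
#'
#' Applies the conjunction of the frequency, significance and isotope-pair
#' criteria to a nested-CV elastic-net result, then groups survivors into
#' 107/109 doublets. The direction of regulation (up/down in cases) is the
#' sign of mean(case) - mean(control) on the normalized intensities; the
#' two members of a doublet must agree on direction, otherwise the doublet
#' is dropped with a warning. Per-criterion pass counts are reported via
#' `message()` for audit.
#'
#' @param cv a `nested_cv` fit with `selection_frequency` (elastic-net
#'   learner).
#' @param pvals per-feature p-values from [ttest_features()].
#' @param pairs isotope doublets from [find_isotope_pairs()] (computed from
#'   `cv$feature_mz` if NULL).
#' @param criteria a [selection_criteria()].
#' @param matrix the normalized [feature_matrix()] the fit was run on,
#'   used for directions (defaults to the data stored in `cv`).
#' @param annotate_table metabolite table for annotation, or NULL to skip.
#' @return Object of class `biomarker_panel`: a data frame with one row per
#'   selected doublet (`name`, `mz107`, `mz109`, `direction`, `p107`,
#'   `p109`, `freq107`, `freq109`) and attribute `feature_idx` (column
#'   indices of all selected features).
#' @export
select_biomarkers <- function(cv, pvals, pairs = NULL,
                              criteria = selection_criteria(),
                              matrix = NULL,
                              annotate_table = metabolite_table()) {
  stopifnot(inherits(cv, "nested_cv"))
  freq <- cv$selection_frequency
  if (is.null(freq))
    stop_param("selection frequency undefined for learner '", cv$learner,
               "'; use the elastic-net learner")
  p <- length(freq)
  if (length(pvals) != p)
    stop_param("pvals length does not match the feature count")
  if (is.null(pairs))
    pairs <- find_isotope_pairs(cv$feature_mz, criteria$pair_tol)
  if (criteria$adjust != "none")
    pvals <- stats::p.adjust(pvals, method = criteria$adjust)

  pass_freq <- freq > criteria$freq_min
  pass_p <- pvals < criteria$p_max
  surv <- pass_freq & pass_p

  partner <- rep(NA_integer_, p)
  if (nrow(pairs)) {
    partner[pairs$idx107] <- pairs$idx109
    partner[pairs$idx109] <- pairs$idx107
  }
  pass_pair <- !is.na(partner) & surv[pmax(partner, 1L)] & !is.na(surv)
  pass_pair[is.na(partner)] <- FALSE
  message(sprintf(
    "selection criteria: %d/%d pass frequency > %.2f, %d pass p < %g, %d have a surviving isotope partner",
    sum(pass_freq), p, criteria$freq_min, sum(pass_p), criteria$p_max,
    sum(surv & pass_pair)))

  selected <- if (criteria$require_pair) surv & pass_pair else surv

  X <- if (!is.null(matrix)) matrix$X else cv$X
  y <- if (!is.null(matrix)) matrix$y else cv$y
  dirsign <- colMeans(X[y == 1, , drop = FALSE]) -
    colMeans(X[y == 0, , drop = FALSE])

  rows <- list(); idx <- integer(0)
  if (criteria$require_pair) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$idx107[r]; j <- pairs$idx109[r]
      if (!(selected[i] && selected[j])) next
      if (sign(dirsign[i]) != sign(dirsign[j])) {
        warning(sprintf(
          "doublet (%.4f, %.4f) dropped: members disagree on direction",
          pairs$mz107[r], pairs$mz109[r]), call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = pairs$annotation[r] %||% NA_character_,
        mz107 = pairs$mz107[r], mz109 = pairs$mz109[r],
        direction = if (dirsign[i] > 0) "up" else "down",
        p107 = pvals[i], p109 = pvals[j],
        freq107 = freq[i], freq109 = freq[j],
        stringsAsFactors = FALSE)
      idx <- c(idx, i, j)
    }
  } else {
    for (i in which(selected)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = NA_character_, mz107 = cv$feature_mz[i], mz109 = NA_real_,
        direction = if (dirsign[i] > 0) "up" else "down",
        p107 = pvals[i], p109 = NA_real_, freq107 = freq[i],
        freq109 = NA_real_, stringsAsFactors = FALSE)
      idx <- c(idx, i)
    }
  }
  panel <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), mz107 = numeric(0), mz109 = numeric(0),
               direction = character(0), p107 = numeric(0),
               p109 = numeric(0), freq107 = numeric(0), freq109 = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(annotate_table) && nrow(panel)) {
    fake <- panel[, c("mz107", "mz109")]
    fake$idx107 <- seq_len(nrow(fake)); fake$idx109 <- fake$idx107
    fake$delta_error <- 0; fake$annotation <- NA_character_
    class(fake) <- c("isotope_pairs", "data.frame")
    panel$name <- annotate_pairs(fake, table = annotate_table)$annotation
  }
  attr(panel, "feature_idx") <- sort(unique(idx))
  class(panel) <- c("biomarker_panel", "data.frame")
  panel
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel: %d doublet(s), %d feature(s)\n",
              nrow(x), length(attr(x, "feature_idx"))))
  if (nrow(x)) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Refit and evaluate a panel-only classifier
#'
#' Restricts the fingerprint to the panel's features (both members of each
#' doublet), reruns the nested cross-validated elastic net on that reduced
#' space, and compares the panel model with each single-biomarker model
#' (one doublet at a time) by the DeLong test on the pooled out-of-fold
#' scores.
#'
#' @param matrix the normalized [feature_matrix()].
#' @param panel a [select_biomarkers()] result with at least one doublet.
#' @param config a [cv_config()].
#' @return List of class `panel_model`: `roc` (pooled out-of-fold ROC of
#'   the panel model), `cv`, `single` (named list of per-biomarker ROC
#'   curves), `delong` (data frame of panel-vs-single comparisons).
#' @export
panel_model <- function(matrix, panel, config = cv_config()) {
  stopifnot(inherits(matrix, "feature_matrix"))
  idx <- attr(panel, "feature_idx")
  if (is.null(idx) || !length(idx)) stop_param("empty biomarker panel")
  sub <- feature_matrix(matrix$X[, idx, drop = FALSE],
                        matrix$feature_mz[idx], matrix$y,
                        matrix$sample_ids)
  cv <- nested_cv(sub, config = config, learner = "elastic_net")
  singles <- list(); cmp <- list()
  for (r in seq_len(nrow(panel))) {
    jd <- which(matrix$feature_mz %in% c(panel$mz107[r], panel$mz109[r]))
    smat <- feature_matrix(matrix$X[, jd, drop = FALSE],
                           matrix$feature_mz[jd], matrix$y,
                           matrix$sample_ids)
    scv <- nested_cv(smat, config = config, learner = "elastic_net")
    nm <- if (!is.na(panel$name[r])) panel$name[r]
      else sprintf("mz%.2f", panel$mz107[r])
    singles[[nm]] <- scv$pooled_roc
    dt <- delong_test(cv$pooled_scores, scv$pooled_scores, matrix$y)
    cmp[[nm]] <- data.frame(biomarker = nm, auc_single = dt$aucB,
                            auc_panel = dt$aucA, z = dt$z,
                            p.value = dt$p.value, stringsAsFactors = FALSE)
  }
  structure(list(roc = cv$pooled_roc, cv = cv, single = singles,
                 delong = do.call(rbind, cmp)),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel model: pooled out-of-fold AUC %.4f over %d biomarkers\n",
              x$roc$auc, length(x$single)))
  if (!is.null(x$delong)) print(x$delong, digits = 4, row.names = FALSE)
  invisible(x)
}
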