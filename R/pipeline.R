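# End-to-end orchestration: simulate (or ingest) a cohort, preprocess,
# train the nested-CV classifier, select biomarkers, and report.

#' Run the screening pipeline end to end
#'
#' Convenience wrapper chaining cohort generation (or a supplied feature
#' matrix), nested cross-validated elastic-net classification, per-feature
#' Welch t-tests, isotope-doublet detection, and three-criterion biomarker
#' selection.
#'
#' @param spec a [cohort_spec()] used to simulate the cohort; ignored when
#'   `matrix` is supplied.
#' @param matrix optional pre-built [feature_matrix()] (unstandardized).
#' @param config a [cv_config()].
#' @param criteria a [selection_criteria()].
#' @param from_spectra simulate at the spectrum level and run the full
#'   preprocessing chain (slower) instead of the direct feature table.
#' @param preprocess_args list of arguments forwarded to
#'   [preprocess_cohort()] when `from_spectra = TRUE`.
#' @return List of class `agfinger_run`: `matrix`, `truth` (NULL for
#'   supplied matrices), `cv`, `pvals`, `pairs`, `panel`.
#' @export
run_screening_pipeline <- function(spec = cohort_spec(), matrix = NULL,
                                   config = cv_config(),
                                   criteria = selection_criteria(),
                                   from_spectra = FALSE,
                                   preprocess_args = list()) {
  truth <- NULL
  if (is.null(matrix)) {
    if (from_spectra) {
      sim <- make_cohort_spectra(spec)
      labels <- stats::setNames(
        as.numeric(sim$manifest$label == spec$case_label),
        sim$manifest$sample_id)
      matrix <- do.call(preprocess_cohort,
                        c(list(spectra = sim$spectra, labels = labels),
                          preprocess_args))
      truth <- sim$truth
    } else {
      tab <- make_feature_table(spec)
      matrix <- normalize_tic(tab$matrix)
      truth <- tab$truth
    }
  } else if (!matrix$standardized) {
    matrix <- normalize_tic(matrix)  # idempotent on already-normalized rows
  }
  cv <- nested_cv(matrix, config = config, learner = "elastic_net")
  pvals <- ttest_features(matrix)
  pairs <- find_isotope_pairs(matrix$feature_mz, criteria$pair_tol)
  panel <- select_biomarkers(cv, pvals, pairs, criteria, matrix = matrix)
  structure(list(matrix = matrix, truth = truth, cv = cv, pvals = pvals,
                 pairs = pairs, panel = panel),
            class = "agfinger_run")
}

#' @export
print.agfinger_run <- function(x, ...) {
  cat("agfinger screening run\n")
  print(x$cv)
  print(x$panel)
  invisible(x)
}

#' Export a biomarker panel as CSV
#'
#' @param panel a [select_biomarkers()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
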