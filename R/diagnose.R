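# Two-step diagnostic decision procedure on metabolic fingerprints:
# step 1 screens PKU against control; for screen positives, step 2 calls
# the subtype (PAH vs BH4). Both steps use trained nested-CV classifiers
# and a 0.5 probability threshold. The clinical reference rules (blood Phe
# concentration and urinary biopterin percentage) are provided as
# comparator decision functions.

#' Two-step PKU screening and subtype identification
#'
#' Scores each sample with the screening model; samples with screening
#' probability > 0.5 are called PKU and then scored with the subtype model
#' (probability > 0.5 = PAH, otherwise BH4). Screen-negative samples get no
#' subtype. A probability of exactly 0.5 resolves conservatively to the
#' control (respectively BH4) side with a warning.
#'
#' @param x samples to diagnose: a [feature_matrix()] or numeric matrix
#'   (rows = samples) on the screening model's feature space. A single
#'   sample may be given as a vector.
#' @param screen_model `nested_cv` fit of control (0) vs PKU (1).
#' @param subtype_model `nested_cv` fit of BH4 (0) vs PAH (1), trained on
#'   PKU samples; its feature space may differ from the screening space,
#'   in which case `x`'s columns are matched to it by m/z within
#'   `align_tol`.
#' @param align_tol m/z tolerance for matching feature spaces (default
#'   0.01).
#' @param sample_ids identifiers for the rows of `x`.
#' @return Data frame of class `diagnosis_result` with columns
#'   `sample_id`, `screen_prob`, `screen_call` (`control`/`PKU`),
#'   `subtype_prob` (NA for screen negatives), `subtype_call`
#'   (`PAH`/`BH4`/NA).
#' @export
two_step_diagnose <- function(x, screen_model, subtype_model = NULL,
                              align_tol = 0.01, sample_ids = NULL) {
  stopifnot(inherits(screen_model, "nested_cv"))
  if (inherits(x, "feature_matrix")) {
    sample_ids <- sample_ids %||% x$sample_ids
    mz <- x$feature_mz
    x <- x$X
  } else {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    mz <- as.numeric(colnames(x) %||% screen_model$feature_mz)
  }
  sample_ids <- sample_ids %||% rownames(x) %||%
    as.character(seq_len(nrow(x)))
  Xs <- align_to_model(x, mz, screen_model$feature_mz, align_tol)
  screen_prob <- predict(screen_model, Xs)
  if (any(screen_prob == 0.5))
    warning("screening probability of exactly 0.5 resolved to 'control'",
            call. = FALSE)
  screen_call <- ifelse(screen_prob > 0.5, "PKU", "control")
  subtype_prob <- rep(NA_real_, length(screen_prob))
  subtype_call <- rep(NA_character_, length(screen_prob))
  pos <- which(screen_call == "PKU")
  if (length(pos)) {
    if (is.null(subtype_model))
      stop_param("screen-positive samples present but no subtype model given")
    stopifnot(inherits(subtype_model, "nested_cv"))
    Xu <- align_to_model(x[pos, , drop = FALSE], mz,
                         subtype_model$feature_mz, align_tol)
    sp <- predict(subtype_model, Xu)
    if (any(sp == 0.5))
      warning("subtype probability of exactly 0.5 resolved to 'BH4'",
              call. = FALSE)
    subtype_prob[pos] <- sp
    subtype_call[pos] <- ifelse(sp > 0.5, "PAH", "BH4")
  }
  structure(data.frame(sample_id = sample_ids, screen_prob = screen_prob,
                       screen_call = screen_call,
                       subtype_prob = subtype_prob,
                       subtype_call = subtype_call,
                       stringsAsFactors = FALSE),
            class = c("diagnosis_result", "data.frame"))
}

# Match the columns of x (at m/z `mz`) onto a model's feature grid.
align_to_model <- function(x, mz, model_mz, tol) {
  if (length(mz) == length(model_mz) &&
      all(abs(mz - model_mz) <= tol)) return(x)
  idx <- vapply(model_mz, function(m) {
    d <- abs(mz - m)
    j <- which.min(d)
    if (d[j] > tol) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx))
    stop_param(sum(is.na(idx)),
               " model feature(s) have no matching input column within ",
               tol, " m/z")
  x[, idx, drop = FALSE]
}

#' Clinical reference rule: blood phenylalanine screen
#'
#' The first-step clinical screening rule: PKU-positive iff the blood Phe
#' concentration exceeds 120 umol/L (strict inequality).
#'
#' @param phe_umol_per_L non-negative Phe concentration(s) in umol/L.
#' @return Logical vector: TRUE = screen positive.
#' @export
reference_screen_phe <- function(phe_umol_per_L) {
  if (any(is.na(phe_umol_per_L)) || any(phe_umol_per_L < 0))
    stop_param("Phe concentration must be >= 0")
  phe_umol_per_L > 120
}

#' Clinical reference rule: urinary biopterin percentage
#'
#' The second-step clinical rule: B% = 100 * B / (B + N); a value over 5
#' (strict) indicates PAH deficiency, otherwise BH4 deficiency.
#'
#' @param B biopterin measurement(s), >= 0.
#' @param N neopterin measurement(s), >= 0.
#' @return List with `b_percent` and `call` (`"PAH"`/`"BH4"`).
#' @export
reference_subtype_bpercent <- function(B, N) {
  if (any(B < 0) || any(N < 0)) stop_param("pterin measurements must be >= 0")
  if (any(B + N == 0))
    stop_param("B%% undefined: biopterin + neopterin is zero")
  b_percent <- 100 * B / (B + N)
  list(b_percent = b_percent, call = ifelse(b_percent > 5, "PAH", "BH4"))
}
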