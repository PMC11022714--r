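# Preprocessing chain turning replicate LDI-MS acquisitions into the
# samples x features fingerprint matrix: replicate averaging, morphological
# baseline correction, SNR-gated peak picking, greedy m/z binning across
# samples, top-k fingerprint selection, TIC normalization and column
# standardization.

#' Construct a feature matrix
#'
#' The fingerprint container: an n x p intensity matrix over aligned m/z
#' feature bins, with 0/1 class labels (0 = control, 1 = case).
#'
#' @param X numeric n x p matrix of intensities (or z-scores once
#'   standardized).
#' @param feature_mz strictly increasing vector of p bin-center m/z values.
#' @param y numeric vector of n labels in {0, 1}.
#' @param sample_ids character vector of n sample identifiers.
#' @param standardized logical; TRUE once columns are z-scored.
#' @param zero_variance optional integer indices of columns flagged as
#'   zero-variance during standardization.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, feature_mz, y, sample_ids,
                           standardized = FALSE, zero_variance = integer(0)) {
  X <- as.matrix(X)
  if (ncol(X) != length(feature_mz))
    stop_param("ncol(X) must equal length(feature_mz)")
  if (nrow(X) != length(y) || nrow(X) != length(sample_ids))
    stop_param("nrow(X) must equal length(y) and length(sample_ids)")
  if (length(feature_mz) && any(diff(feature_mz) <= 0))
    stop_param("feature_mz must be strictly increasing")
  if (!all(y %in% c(0, 1))) stop_param("y must contain only 0/1 labels")
  if (any(!is.finite(X))) stop_param("non-finite values in X")
  structure(list(X = X, feature_mz = as.numeric(feature_mz),
                 y = as.numeric(y), sample_ids = as.character(sample_ids),
                 standardized = isTRUE(standardized),
                 zero_variance = as.integer(zero_variance)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "feature_matrix: %d samples x %d features (m/z %.2f-%.2f), %s, %d cases / %d controls\n",
    nrow(x$X), ncol(x$X),
    if (length(x$feature_mz)) min(x$feature_mz) else NA,
    if (length(x$feature_mz)) max(x$feature_mz) else NA,
    if (x$standardized) "standardized" else "unstandardized",
    sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

#' Average replicate spectra
#'
#' Replicates are resampled by linear interpolation onto the union of their
#' m/z grids clipped to the overlapping range, then averaged pointwise.
#' Averaging before peak detection raises SNR and yields one fingerprint
#' per sample.
#'
#' @param spectra list of [raw_spectrum()] objects from the same sample.
#' @return A [raw_spectrum()] with `replicate_index = 0`.
#' @export
average_replicates <- function(spectra) {
  if (!length(spectra)) stop_param("no spectra to average")
  stopifnot(all(vapply(spectra, inherits, TRUE, "raw_spectrum")))
  ids <- unique(vapply(spectra, `[[`, "", "sample_id"))
  if (length(ids) > 1L)
    stop_param("replicates from different samples: ",
               paste(ids, collapse = ", "))
  if (length(spectra) == 1L) {
    s <- spectra[[1L]]
    s$replicate_index <- 0L
    return(s)
  }
  lo <- max(vapply(spectra, function(s) min(s$mz), 0))
  hi <- min(vapply(spectra, function(s) max(s$mz), 0))
  if (lo >= hi) stop_param("replicate spectra have disjoint m/z ranges")
  grid <- sort(unique(unlist(lapply(spectra, `[[`, "mz"))))
  grid <- grid[grid >= lo & grid <= hi]
  acc <- rowMeans(vapply(spectra, function(s)
    stats::approx(s$mz, s$intensity, xout = grid, rule = 2)$y,
    numeric(length(grid))))
  raw_spectrum(grid, acc, sample_id = ids, replicate_index = 0L,
               meta = list(n_replicates = as.character(length(spectra))))
}

#' Morphological-opening baseline correction
#'
#' Estimates the baseline as a morphological opening (rolling minimum then
#' rolling maximum over a +/- `half_window` m/z window) and subtracts it;
#' resulting intensities are clipped at zero. The opening removes any
#' additive component varying on scales wider than the window while leaving
#' peaks narrower than `half_window` intact.
#'
#' @param spectrum a [raw_spectrum()].
#' @param half_window window half-width in m/z units (> 0).
#' @return Baseline-corrected [raw_spectrum()].
#' @export
baseline_correct <- function(spectrum, half_window = 1.0) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (!is.numeric(half_window) || half_window <= 0)
    stop_param("half_window must be > 0")
  base <- .opening_baseline(spectrum$mz, spectrum$intensity, half_window)
  spectrum$intensity <- pmax(spectrum$intensity - base, 0)
  spectrum
}

#' Detect peaks in a baseline-corrected spectrum
#'
#' Peaks are strict local maxima (greater than both neighbours). The noise
#' scale sigma is estimated robustly as 1.4826 x the median absolute
#' deviation of the first differences of the intensity divided by sqrt(2)
#' (differencing removes slowly varying structure; the sqrt(2) undoes the
#' variance doubling). A maximum is retained iff intensity/sigma >=
#' `snr_min` and its m/z lies in `window`; retained maxima closer than
#' `merge_tol` are merged keeping the taller.
#'
#' @param spectrum baseline-corrected [raw_spectrum()].
#' @param snr_min minimum signal-to-noise ratio (default 3).
#' @param window numeric length-2 detection window (default c(100, 1000),
#'   the instrument's acquisition range).
#' @param merge_tol minimum m/z separation between reported peaks
#'   (default 0.05).
#' @return An object of class `peak_set`: list with `sample_id` and a data
#'   frame `peaks` (columns `mz`, `intensity`, `snr`) sorted by m/z.
#' @export
detect_peaks <- function(spectrum, snr_min = 3,
                         window = c(100, 1000), merge_tol = 0.05) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (length(window) != 2L || window[1] >= window[2])
    stop_param("window must be (mz_lo, mz_hi) with mz_lo < mz_hi")
  v <- spectrum$intensity
  n <- length(v)
  sigma <- if (n >= 3L) stats::mad(diff(v)) / sqrt(2) else 0
  idx <- if (n >= 3L)
    which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  else integer(0)
  if (length(idx)) {
    keep <- spectrum$mz[idx] >= window[1] & spectrum$mz[idx] <= window[2]
    if (sigma > 0) keep <- keep & (v[idx] / sigma >= snr_min)
    idx <- idx[keep]
  }
  mz <- spectrum$mz[idx]
  int <- v[idx]
  snr <- if (sigma > 0) int / sigma else rep(Inf, length(int))
  # merge near-coincident maxima: accept in order of descending height,
  # suppressing any maximum within merge_tol of an already accepted one
  if (length(mz) > 1L) {
    ord <- order(-int, mz)
    keep <- logical(length(mz))
    for (i in ord) {
      if (!any(keep & abs(mz - mz[i]) < merge_tol)) keep[i] <- TRUE
    }
    mz <- mz[keep]; int <- int[keep]; snr <- snr[keep]
  }
  structure(list(sample_id = spectrum$sample_id,
                 peaks = data.frame(mz = mz, intensity = int, snr = snr)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks\n", x$sample_id, nrow(x$peaks)))
  invisible(x)
}

#' Align peaks across samples into m/z feature bins
#'
#' Pools all peaks, sorts by m/z, and applies single-linkage greedy
#' binning: a new bin opens whenever the gap to the previous peak exceeds
#' `tol`. Bin centers are intensity-weighted mean m/z; the raw feature
#' matrix entry is the summed intensity of a sample's peaks in that bin
#' (0 if absent).
#'
#' @param peaksets list of `peak_set` objects (>= 2).
#' @param tol maximum within-bin gap between adjacent pooled peaks (m/z).
#' @return List with `feature_mz` (bin centers), `X_raw` (n x p matrix with
#'   rownames = sample ids), `sample_ids`.
#' @export
align_features <- function(peaksets, tol = 0.1) {
  if (tol <= 0) stop_param("tol must be > 0")
  if (length(peaksets) < 2L) stop_param("need at least two peak sets to align")
  stopifnot(all(vapply(peaksets, inherits, TRUE, "peak_set")))
  sample_ids <- vapply(peaksets, `[[`, "", "sample_id")
  if (anyDuplicated(sample_ids)) stop_param("duplicate sample ids in peaksets")
  pooled <- do.call(rbind, lapply(seq_along(peaksets), function(i) {
    pk <- peaksets[[i]]$peaks
    if (!nrow(pk)) return(NULL)
    data.frame(sample = i, mz = pk$mz, intensity = pk$intensity)
  }))
  n <- length(peaksets)
  if (is.null(pooled) || !nrow(pooled)) {
    return(list(feature_mz = numeric(0),
                X_raw = matrix(0, n, 0, dimnames = list(sample_ids, NULL)),
                sample_ids = sample_ids))
  }
  pooled <- pooled[order(pooled$mz), ]
  bin <- cumsum(c(1L, as.integer(diff(pooled$mz) > tol)))
  wsum <- tapply(pooled$intensity, bin, sum)
  feature_mz <- as.numeric(
    tapply(pooled$mz * pooled$intensity, bin, sum) / wsum)
  # zero-intensity peaks would zero the weight; fall back to plain mean
  zero <- !is.finite(feature_mz)
  if (any(zero))
    feature_mz[zero] <- as.numeric(tapply(pooled$mz, bin, mean))[zero]
  p <- max(bin)
  X <- matrix(0, n, p, dimnames = list(sample_ids, NULL))
  for (r in seq_len(nrow(pooled)))
    X[pooled$sample[r], bin[r]] <- X[pooled$sample[r], bin[r]] +
      pooled$intensity[r]
  o <- order(feature_mz)
  list(feature_mz = feature_mz[o], X_raw = X[, o, drop = FALSE],
       sample_ids = sample_ids)
}

#' Select the top-k fingerprint features
#'
#' Ranks bins by their median intensity across samples (descending, ties
#' broken by lower m/z) and keeps the top `k`; the kept columns are then
#' re-sorted by m/z. With the default k = 830 this reproduces the
#' "localized highest intensity" fingerprint size.
#'
#' @param feature_mz,X_raw output of [align_features()].
#' @param k number of features to keep (default 830); if `k` exceeds the
#'   number of bins, all are kept.
#' @param y 0/1 class labels, one per row of `X_raw`.
#' @param sample_ids sample identifiers (default rownames of `X_raw`).
#' @return An unstandardized [feature_matrix()].
#' @export
select_top_features <- function(feature_mz, X_raw, k = 830, y,
                                sample_ids = rownames(X_raw)) {
  if (k < 1) stop_param("k must be >= 1")
  med <- apply(X_raw, 2, stats::median)
  ord <- order(-med, feature_mz)
  keep <- ord[seq_len(min(k, length(feature_mz)))]
  keep <- keep[order(feature_mz[keep])]
  feature_matrix(X_raw[, keep, drop = FALSE], feature_mz[keep], y,
                 sample_ids %||% as.character(seq_len(nrow(X_raw))))
}

#' Total-ion-current normalization
#'
#' Divides each sample row by its row sum so rows sum to one, removing
#' per-sample scaling (spot-to-spot and shot-to-shot intensity variation).
#' All-zero rows are left unchanged with a warning.
#'
#' @param matrix unstandardized [feature_matrix()].
#' @return TIC-normalized [feature_matrix()].
#' @export
normalize_tic <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (matrix$standardized)
    stop_param("normalize_tic expects an unstandardized matrix")
  rs <- rowSums(matrix$X)
  zero <- rs == 0
  if (any(zero))
    warning(sum(zero), " all-zero sample row(s) left unnormalized",
            call. = FALSE)
  rs[zero] <- 1
  matrix$X <- matrix$X / rs
  matrix
}

#' Column standardization (z-scoring)
#'
#' Centers each feature column and scales by its population standard
#' deviation (divisor n). Zero-variance columns are set to all-zero and
#' recorded in `zero_variance`.
#'
#' @param matrix a [feature_matrix()] (typically TIC-normalized).
#' @return Standardized [feature_matrix()] with `standardized = TRUE`.
#' @export
standardize <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  st <- standardize_stats(matrix$X)
  matrix$X <- apply_standardize(matrix$X, st)
  matrix$standardized <- TRUE
  matrix$zero_variance <- which(st$zero)
  matrix
}

# center/scale statistics (population sd); shared with the in-fold
# standardization used by nested_cv so no test-fold data leaks in.
standardize_stats <- function(X) {
  center <- colMeans(X)
  scale <- sqrt(colMeans(X^2) - center^2)
  zero <- scale < 1e-12
  scale[zero] <- 1
  list(center = center, scale = scale, zero = zero)
}

apply_standardize <- function(X, st) {
  Z <- sweep(sweep(X, 2, st$center), 2, st$scale, "/")
  if (any(st$zero)) Z[, st$zero] <- 0
  Z
}

#' Preprocess a cohort of spectra into a fingerprint matrix
#'
#' Runs the full chain on a list of replicate spectra grouped by sample:
#' average replicates, baseline-correct, detect peaks, align across
#' samples, keep the top-k fingerprint, TIC-normalize and (optionally)
#' standardize.
#'
#' @param spectra list of [raw_spectrum()] objects (replicates carry the
#'   same `sample_id`).
#' @param labels named 0/1 vector (names = sample ids) or a
#'   `cohort_manifest` whose labels are mapped via `positive_label`.
#' @param positive_label manifest label treated as class 1 when `labels`
#'   is a manifest (default `"PKU"`).
#' @param half_window,snr_min,window,merge_tol,align_tol,k tuning
#'   parameters of the individual stages; see [baseline_correct()],
#'   [detect_peaks()], [align_features()], [select_top_features()].
#' @param do_standardize z-score the final matrix (default FALSE: model
#'   fitting standardizes inside CV training folds to avoid leakage).
#' @return A [feature_matrix()].
#' @export
preprocess_cohort <- function(spectra, labels, positive_label = "PKU",
                              half_window = 1.0, snr_min = 3,
                              window = c(100, 1000), merge_tol = 0.05,
                              align_tol = 0.1, k = 830,
                              do_standardize = FALSE) {
  ids <- vapply(spectra, `[[`, "", "sample_id")
  if (inherits(labels, "cohort_manifest")) {
    lab <- stats::setNames(as.numeric(labels$label == positive_label),
                           labels$sample_id)
  } else lab <- labels
  groups <- split(spectra, factor(ids, levels = unique(ids)))
  peaksets <- lapply(groups, function(g) {
    s <- average_replicates(g)
    s <- baseline_correct(s, half_window = half_window)
    detect_peaks(s, snr_min = snr_min, window = window,
                 merge_tol = merge_tol)
  })
  aligned <- align_features(peaksets, tol = align_tol)
  if (!all(aligned$sample_ids %in% names(lab)))
    stop_param("labels missing for sample(s): ",
               paste(setdiff(aligned$sample_ids, names(lab)), collapse = ", "))
  fm <- select_top_features(aligned$feature_mz, aligned$X_raw, k = k,
                            y = lab[aligned$sample_ids],
                            sample_ids = aligned$sample_ids)
  fm <- normalize_tic(fm)
  if (do_standardize) fm <- standardize(fm)
  fm
}
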