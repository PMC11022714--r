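#' Construct a raw mass spectrum
#'
#' A `raw_spectrum` holds one replicate acquisition: parallel m/z and
#' intensity vectors plus sample bookkeeping. Input arrays may arrive in any
#' order; they are sorted by m/z in lockstep. After sorting, m/z must be
#' strictly increasing (no duplicate sampling points) and all intensities
#' finite and non-negative.
#'
#' @param mz numeric vector of m/z values (Da for singly charged ions).
#' @param intensity numeric vector of intensities (arbitrary counts), same
#'   length as `mz`.
#' @param sample_id sample identifier.
#' @param replicate_index replicate number (>= 1; 0 denotes a replicate
#'   average).
#' @param meta optional named list of string metadata.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, sample_id = "", replicate_index = 1L,
                         meta = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) < 1L) stop_param("spectrum must contain at least one point")
  if (length(mz) != length(intensity))
    stop_param("mz and intensity must have equal length")
  if (anyNA(mz) || any(!is.finite(mz)))
    stop_param("non-finite m/z value in spectrum")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop_param("non-finite intensity in spectrum")
  if (any(intensity < 0))
    stop_param("negative intensity in spectrum")
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  if (any(diff(mz) <= 0))
    stop_param("m/z values must be strictly increasing (duplicate grid point?)")
  if (replicate_index < 0) stop_param("replicate_index must be >= 0")
  structure(
    list(sample_id = as.character(sample_id),
         replicate_index = as.integer(replicate_index),
         mz = mz, intensity = intensity, meta = meta),
    class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw_spectrum '%s' (replicate %d): %d points, m/z %.4f-%.4f\n",
              x$sample_id, x$replicate_index, length(x$mz),
              min(x$mz), max(x$mz)))
  invisible(x)
}

#' @export
length.raw_spectrum <- function(x) length(x$mz)

#' Read a spectrum from disk
#'
#' Reads a single spectrum from a two-column text file (m/z, intensity;
#' whitespace-, tab- or comma-delimited; optional header) or from an mzML
#' file (first spectrum unless `scan` is given; requires the mzR package).
#'
#' @param path file path.
#' @param format `"tsv"`, `"mzml"`, or `"auto"` (by file extension).
#' @param sample_id,replicate_index passed to [raw_spectrum()]; default
#'   `sample_id` is the file name without extension.
#' @param scan scan number for mzML input.
#' @return A [raw_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "tsv", "mzml"),
                          sample_id = NULL, replicate_index = 1L, scan = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_param("spectrum file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop_param("reading mzML requires the mzR package")
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, scan)
    return(raw_spectrum(pk[, 1], pk[, 2], sample_id = sample_id,
                        replicate_index = replicate_index))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_param("empty spectrum file: ", path)
  start <- 1L
  parse_line <- function(ln) {
    toks <- strsplit(trimws(ln), "[,\t ]+")[[1]]
    suppressWarnings(as.numeric(toks))
  }
  first <- parse_line(lines[1L])
  if (anyNA(first)) start <- 2L  # header row
  if (start > length(lines)) stop_param("no data rows in spectrum file: ", path)
  n <- length(lines) - start + 1L
  mz <- numeric(n); intensity <- numeric(n)
  for (i in seq_len(n)) {
    v <- parse_line(lines[start + i - 1L])
    if (length(v) < 2L || anyNA(v[1:2]))
      stop_param(sprintf("cannot parse line %d of %s", start + i - 1L, path))
    mz[i] <- v[1L]; intensity[i] <- v[2L]
  }
  raw_spectrum(mz, intensity, sample_id = sample_id,
               replicate_index = replicate_index)
}

#' Write a spectrum as two-column tab-separated text
#'
#' @param spectrum a [raw_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  writeLines(c("mz\tintensity",
               sprintf("%.12g\t%.12g", spectrum$mz, spectrum$intensity)),
             path)
  invisible(path)
}

cohort_labels <- c("control", "PKU", "PAH", "BH4")

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `sample_id`, `label` and `paths`
#' (one or more spectrum paths separated by `;`), plus optional `age_days`
#' and `sex`. Labels must be one of `control`, `PKU`, `PAH`, `BH4`;
#' sample ids must be unique and every path must resolve (relative paths
#' are resolved against the manifest's directory).
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every spectrum path exists (default TRUE).
#' @return A data frame of class `cohort_manifest` with one row per sample;
#'   column `paths` is a list column of character vectors.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop_param("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "paths")
  if (!all(need %in% names(df)))
    stop_param("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_param("duplicate sample_id in manifest: ",
               paste(unique(df$sample_id[duplicated(df$sample_id)]),
                     collapse = ", "))
  bad <- setdiff(unique(df$label), cohort_labels)
  if (length(bad))
    stop_param("unknown label(s) ", paste(bad, collapse = ", "),
               "; allowed: ", paste(cohort_labels, collapse = ", "))
  paths <- strsplit(df$paths, ";", fixed = TRUE)
  base <- dirname(normalizePath(path))
  paths <- lapply(paths, function(p) {
    p <- trimws(p)
    ifelse(grepl("^/", p), p, file.path(base, p))
  })
  if (any(lengths(paths) < 1L))
    stop_param("every sample needs at least one spectrum path")
  if (check_paths) {
    missing <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing))
      stop_param("unresolvable spectrum path(s): ",
                 paste(utils::head(missing, 3L), collapse = ", "))
  }
  out <- data.frame(sample_id = df$sample_id, label = df$label,
                    stringsAsFactors = FALSE)
  out$paths <- paths
  if ("age_days" %in% names(df)) out$age_days <- df$age_days
  if ("sex" %in% names(df)) out$sex <- df$sex
  class(out) <- c("cohort_manifest", "data.frame")
  out
}

#' Write a cohort manifest
#'
#' @param manifest a `cohort_manifest` (or data frame with `sample_id`,
#'   `label` and a `paths` list column).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- data.frame(sample_id = manifest$sample_id, label = manifest$label,
                   paths = vapply(manifest$paths, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix as CSV
#'
#' Layout: an optional comment line `# standardized: TRUE/FALSE`, then a
#' header row whose first two fields are `sample_id` and `label` followed by
#' the feature m/z bin centers, then one row per sample. Numeric values are
#' written with 12 significant digits so the round trip is lossless to about
#' 1e-9 relative.
#'
#' @param matrix a [feature_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_feature_matrix()]
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# standardized: %s", matrix$standardized), con)
  writeLines(paste(c("sample_id", "label",
                     sprintf("%.12g", matrix$feature_mz)), collapse = ","), con)
  for (i in seq_along(matrix$sample_ids)) {
    writeLines(paste(c(matrix$sample_ids[i], matrix$y[i],
                       sprintf("%.12g", matrix$X[i, ])), collapse = ","), con)
  }
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_param("feature matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  standardized <- FALSE
  if (length(lines) && grepl("^#", lines[1L])) {
    standardized <- grepl("true", lines[1L], ignore.case = TRUE)
    lines <- lines[-1L]
  }
  if (length(lines) < 2L) stop_param("feature matrix file has no data rows")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1]]
  feature_mz <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(feature_mz)) stop_param("non-numeric feature m/z in header")
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  ncol_expect <- length(header)
  if (any(lengths(rows) != ncol_expect))
    stop_param("ragged row in feature matrix file")
  sample_ids <- vapply(rows, `[`, "", 1L)
  y <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 2L)))
  X <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-(1:2)]))
    if (anyNA(v)) stop_param("non-numeric cell in feature matrix file")
    v
  }, numeric(length(feature_mz))))
  feature_matrix(X, feature_mz, y, sample_ids, standardized = standardized)
}
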