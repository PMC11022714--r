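# Silver cationization arithmetic and 107/109 isotope-doublet handling.
#
# On plasmonic silver substrates metabolites ionize as [M+Ag]+ cations, and
# silver's two stable isotopes (107Ag, 109Ag) split every adduct into a
# doublet separated by m(109Ag) - m(107Ag) ~ 2.0 Da at the natural-abundance
# intensity ratio. The doublet is used both to annotate features and as the
# third biomarker-selection criterion.

# Monoisotopic masses (Da) of the isotopes and elements involved.
.ag <- list(
  m107 = 106.9050916,
  m109 = 108.9047553,
  m_electron = 0.000548579909,
  abundance107 = 0.51839,
  abundance109 = 0.48161
)

.atomic_mass <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Silver isotope constants
#'
#' Monoisotopic masses of 107Ag and 109Ag, the electron mass, and the
#' natural isotopic abundances, all from standard isotope tables.
#'
#' @return A list with elements `m107`, `m109`, `m_electron` (Da),
#'   `abundance107`, `abundance109`.
#' @export
ag_isotopes <- function() .ag

#' Monoisotopic mass from a molecular formula
#'
#' Parses a Hill-notation formula over C, H, N, O, S, P and sums standard
#' monoisotopic atomic masses.
#'
#' @param formula character vector of formulas, e.g. `"C9H11NO2"`.
#' @return Numeric vector of monoisotopic neutral masses (Da).
#' @examples
#' formula_mass("C9H11NO2")  # phenylalanine, ~165.079
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", f))
      stop_param("cannot parse formula: ", f)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    total <- 0
    for (tk in toks) {
      el <- gsub("[0-9]", "", tk)
      ct <- gsub("[A-Za-z]", "", tk)
      ct <- if (nzchar(ct)) as.integer(ct) else 1L
      if (!el %in% names(.atomic_mass))
        stop_param("unsupported element '", el, "' in formula ", f)
      total <- total + .atomic_mass[[el]] * ct
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' m/z of a silver cation adduct
#'
#' For a neutral metabolite of monoisotopic mass M, the singly charged
#' silver adduct [M+Ag]+ appears at `M + m(Ag isotope) - m(electron)`.
#' Phenylalanine (C9H11NO2, 165.0790 Da) gives 271.98 / 273.98 for the
#' 107/109 isotopes at two-decimal precision.
#'
#' @param neutral_mass neutral monoisotopic mass(es), Da; must be >= 0.
#' @param isotope 107 or 109.
#' @return m/z value(s) of the cation adduct.
#' @export
adduct_mz <- function(neutral_mass, isotope = 107) {
  if (length(isotope) != 1L || !isotope %in% c(107, 109))
    stop_param("isotope must be 107 or 109")
  if (any(neutral_mass < 0)) stop_param("neutral_mass must be >= 0")
  m_ag <- if (isotope == 107) .ag$m107 else .ag$m109
  neutral_mass + m_ag - .ag$m_electron
}

#' Embedded metabolite mass table
#'
#' The metabolites discussed in the PKU screening / subtype workflow, with
#' monoisotopic masses computed from their molecular formulas. Roles:
#' `pku_panel` (the six screening biomarkers: Phe, Phen, AA, IA up in
#' cases; Eth, OA down) and `subtype_panel` (the three PAH-vs-BH4
#' discriminators).
#'
#' @return Data frame with columns `name`, `formula`, `neutral_mass`,
#'   `role`, `direction`.
#' @export
metabolite_table <- function() {
  df <- data.frame(
    name = c("Phe", "Phen", "AA", "IA", "Eth", "OA",
             "cholest-5-ene", "tetradecanoylcarnitine", "heptacosanoic acid"),
    formula = c("C9H11NO2", "C8H8O", "C3H5NO4", "C11H9NO2", "C2H7N",
                "C18H34O2", "C27H46", "C21H41NO4", "C27H54O2"),
    role = c(rep("pku_panel", 6), rep("subtype_panel", 3)),
    direction = c("up", "up", "up", "up", "down", "down",
                  "up", "up", "up"),
    stringsAsFactors = FALSE)
  df$neutral_mass <- formula_mass(df$formula)
  df[, c("name", "formula", "neutral_mass", "role", "direction")]
}

#' Find 107Ag/109Ag isotope doublets in a feature list
#'
#' Scans a sorted feature m/z vector for pairs whose spacing matches the
#' silver isotope mass difference (~1.9997 Da) within `pair_tol`. When a
#' feature could pair with several partners, pairs are accepted greedily by
#' ascending spacing error so each feature appears in at most one pair.
#'
#' @param feature_mz sorted ascending numeric vector of feature m/z.
#' @param pair_tol tolerance (Da) on the deviation of the observed spacing
#'   from the isotopic mass difference.
#' @return Data frame of class `isotope_pairs` with columns `idx107`,
#'   `idx109` (indices into `feature_mz`), `mz107`, `mz109`, `delta_error`,
#'   `annotation` (NA until [annotate_pairs()] is applied).
#' @export
find_isotope_pairs <- function(feature_mz, pair_tol = 0.02) {
  if (pair_tol <= 0) stop_param("pair_tol must be > 0")
  if (is.unsorted(feature_mz, strictly = FALSE))
    stop_param("feature_mz must be sorted ascending")
  delta <- .ag$m109 - .ag$m107
  p <- length(feature_mz)
  cand <- list()
  for (i in seq_len(p)) {
    lo <- feature_mz[i] + delta - pair_tol
    hi <- feature_mz[i] + delta + pair_tol
    js <- which(feature_mz >= lo & feature_mz <= hi)
    js <- js[js > i]
    for (j in js) {
      cand[[length(cand) + 1L]] <-
        c(i, j, abs((feature_mz[j] - feature_mz[i]) - delta))
    }
  }
  out <- data.frame(idx107 = integer(0), idx109 = integer(0),
                    mz107 = numeric(0), mz109 = numeric(0),
                    delta_error = numeric(0), annotation = character(0),
                    stringsAsFactors = FALSE)
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, 3]), , drop = FALSE]
    used <- logical(p)
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j <- cm[r, 2]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      out <- rbind(out, data.frame(
        idx107 = as.integer(i), idx109 = as.integer(j),
        mz107 = feature_mz[i], mz109 = feature_mz[j],
        delta_error = cm[r, 3], annotation = NA_character_,
        stringsAsFactors = FALSE))
    }
    out <- out[order(out$mz107), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("isotope_pairs", "data.frame")
  out
}

#' Annotate isotope doublets against a metabolite table
#'
#' Each pair is assigned the metabolite whose predicted 107Ag adduct m/z is
#' nearest to the pair's `mz107`, provided the distance is within
#' `match_tol`; ties break alphabetically by metabolite name.
#'
#' @param pairs an `isotope_pairs` data frame from [find_isotope_pairs()].
#' @param table metabolite table as from [metabolite_table()].
#' @param match_tol maximum |observed - predicted| m/z distance (Da).
#' @return `pairs` with the `annotation` column filled (NA where no
#'   metabolite matches).
#' @export
annotate_pairs <- function(pairs, table = metabolite_table(),
                           match_tol = 0.05) {
  if (match_tol <= 0) stop_param("match_tol must be > 0")
  if (!nrow(pairs) || !nrow(table)) return(pairs)
  pred <- adduct_mz(table$neutral_mass, 107)
  ord <- order(table$name)
  for (r in seq_len(nrow(pairs))) {
    d <- abs(pairs$mz107[r] - pred)
    at_min <- ord[abs(d[ord] - min(d)) < 1e-12]  # alphabetical at ties
    best <- at_min[1L]
    if (d[best] <= match_tol) pairs$annotation[r] <- table$name[best]
  }
  pairs
}
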