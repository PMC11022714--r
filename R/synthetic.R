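# Seeded synthetic-cohort generator with known ground truth. It emulates
# the structure of the screening study's data: positive-mode spectra over
# m/z 100-1000, five replicates per sample, exponentially decaying baseline
# plus Gaussian noise, Gaussian peaks with log-normal intensities, silver
# 107/109 adduct doublets at the natural-abundance ratio, and a small
# differential metabolite panel among hundreds of null features, at the
# discovery-cohort sizes (240 controls / 77 cases).

#' Default differential panel for the screening cohort
#'
#' The six screening biomarkers with their monoisotopic masses, regulation
#' direction in cases, and a common fold change.
#'
#' @param fold_change multiplicative case/control effect (> 1); applied as
#'   x`fold_change` for up-regulated and /`fold_change` for down-regulated
#'   metabolites.
#' @param role `"pku_panel"` (default) or `"subtype_panel"`.
#' @return Data frame with `name`, `neutral_mass`, `fold_change`,
#'   `direction`.
#' @export
default_panel <- function(fold_change = 3, role = "pku_panel") {
  tab <- metabolite_table()
  tab <- tab[tab$role == role, ]
  data.frame(name = tab$name, neutral_mass = tab$neutral_mass,
             fold_change = fold_change, direction = tab$direction,
             stringsAsFactors = FALSE)
}

#' Synthetic cohort specification
#'
#' Generative parameters defining a synthetic cohort and its ground truth.
#' Defaults reproduce the discovery-cohort design: 240 controls vs 77
#' cases, five replicate spectra per sample, m/z 100-1000, the six-member
#' differential panel (Phe, Phen, AA, IA up; Eth, OA down; fold change 3)
#' among 818 null features for 830 feature bins in total.
#'
#' @param n_control,n_case per-class sample counts.
#' @param replicates_per_sample replicate spectra per sample (default 5).
#' @param mz_range acquisition window (default c(100, 1000)).
#' @param grid_step spectral sampling step, m/z (default 0.02).
#' @param panel differential metabolites, as from [default_panel()]; each
#'   contributes a 107/109 adduct doublet.
#' @param n_null_features number of non-differential features (default
#'   818).
#' @param peak_sigma Gaussian peak width (sd) in m/z (default 0.05).
#' @param baseline_amplitude,baseline_decay baseline
#'   `amplitude * exp(-decay * (mz - mz_lo))`.
#' @param noise_sd additive white-noise sd on rendered spectra.
#' @param intensity_meanlog,intensity_sdlog log-normal biological
#'   abundance model: each feature's base abundance is
#'   `exp(N(intensity_meanlog, 1))` and each sample draws
#'   `exp(N(log base +- log fold_change, intensity_sdlog))`.
#' @param measurement_sdlog multiplicative measurement noise (log-sd)
#'   applied independently to each adduct feature.
#' @param isotope_ratio 107/109 intensity ratio (default the natural
#'   silver abundance ratio).
#' @param case_label,control_label class names used in manifests.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 240L, n_case = 77L,
                        replicates_per_sample = 5L,
                        mz_range = c(100, 1000), grid_step = 0.02,
                        panel = default_panel(), n_null_features = 818L,
                        peak_sigma = 0.05, baseline_amplitude = 20,
                        baseline_decay = 0.005, noise_sd = 1,
                        intensity_meanlog = log(200),
                        intensity_sdlog = 0.6, measurement_sdlog = 0.2,
                        isotope_ratio = 0.51839 / 0.48161,
                        case_label = "PKU", control_label = "control",
                        seed = 42L) {
  if (n_control < 0 || n_case < 0) stop_param("negative sample count")
  if (!is.null(panel) && nrow(panel) &&
      any(panel$fold_change <= 0))
    stop_param("panel fold changes must be > 0")
  if (n_null_features < 0) stop_param("n_null_features must be >= 0")
  structure(list(n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 replicates_per_sample = as.integer(replicates_per_sample),
                 mz_range = mz_range, grid_step = grid_step,
                 panel = panel, n_null_features = as.integer(n_null_features),
                 peak_sigma = peak_sigma,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay, noise_sd = noise_sd,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 measurement_sdlog = measurement_sdlog,
                 isotope_ratio = isotope_ratio,
                 case_label = case_label, control_label = control_label,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: %d controls / %d cases, %d panel metabolite(s) + %d null features, seed %d\n",
    x$n_control, x$n_case,
    if (is.null(x$panel)) 0L else nrow(x$panel), x$n_null_features, x$seed))
  invisible(x)
}

# Feature layout and per-sample "true" feature amplitudes shared by the
# feature-table and spectrum renderers. Must be called inside with_seed().
draw_cohort <- function(spec) {
  n <- spec$n_control + spec$n_case
  y <- c(rep(0, spec$n_control), rep(1, spec$n_case))
  sample_ids <- sprintf("S%04d", seq_len(max(n, 1L)))[seq_len(n)]
  panel <- spec$panel
  n_met <- if (is.null(panel)) 0L else nrow(panel)

  mz107 <- mz109 <- numeric(n_met)
  if (n_met) {
    mz107 <- adduct_mz(panel$neutral_mass, 107)
    mz109 <- adduct_mz(panel$neutral_mass, 109)
    bad <- which(mz107 < spec$mz_range[1] | mz109 > spec$mz_range[2])
    if (length(bad))
      stop_param("panel metabolite(s) outside the m/z window: ",
                 paste(panel$name[bad], collapse = ", "))
  }
  # null feature positions: uniform in the window, kept clear of the panel
  # doublets and of each other so alignment cannot merge features
  min_gap <- 0.3
  taken <- sort(c(mz107, mz109))
  null_mz <- numeric(0)
  while (length(null_mz) < spec$n_null_features) {
    cand <- runif(spec$n_null_features * 2,
                  spec$mz_range[1] + 1, spec$mz_range[2] - 1)
    for (m in cand) {
      if (length(null_mz) >= spec$n_null_features) break
      occ <- c(taken, null_mz)
      if (!length(occ) || min(abs(occ - m)) > min_gap)
        null_mz <- c(null_mz, m)
    }
  }
  feature_mz <- c(mz107, mz109, null_mz)
  met_of <- c(seq_len(n_met), seq_len(n_met),
              rep(NA_integer_, length(null_mz)))
  iso_of <- c(rep(107L, n_met), rep(109L, n_met),
              rep(NA_integer_, length(null_mz)))
  o <- order(feature_mz)
  feature_mz <- feature_mz[o]; met_of <- met_of[o]; iso_of <- iso_of[o]
  p <- length(feature_mz)

  # per-feature base abundance levels (fixed by the seed)
  base_met <- rnorm(n_met, spec$intensity_meanlog, 1)
  base_null <- rnorm(length(null_mz), spec$intensity_meanlog, 1)

  share107 <- spec$isotope_ratio / (1 + spec$isotope_ratio)
  share109 <- 1 / (1 + spec$isotope_ratio)

  amp <- matrix(0, n, p)
  if (n > 0) {
    # metabolite-level biological abundance, shared by both adduct features
    A <- matrix(0, n, max(n_met, 1L))
    for (m in seq_len(n_met)) {
      eff <- if (panel$direction[m] == "up") log(panel$fold_change[m])
        else -log(panel$fold_change[m])
      A[, m] <- exp(base_met[m] + eff * y +
                      rnorm(n, 0, spec$intensity_sdlog))
    }
    kn <- 0L
    for (j in seq_len(p)) {
      if (!is.na(met_of[j])) {
        share <- if (iso_of[j] == 107L) share107 else share109
        amp[, j] <- A[, met_of[j]] * share *
          exp(rnorm(n, 0, spec$measurement_sdlog))
      } else {
        kn <- kn + 1L
        amp[, j] <- exp(base_null[kn] + rnorm(n, 0, spec$intensity_sdlog) +
                          rnorm(n, 0, spec$measurement_sdlog))
      }
    }
  }
  partner <- rep(NA_integer_, p)
  for (m in seq_len(n_met)) {
    jj <- which(!is.na(met_of) & met_of == m)
    if (length(jj) == 2L) { partner[jj[1]] <- jj[2]; partner[jj[2]] <- jj[1] }
  }
  truth <- data.frame(
    feature_mz = feature_mz,
    is_differential = !is.na(met_of) &
      (if (n_met) panel$fold_change[ifelse(is.na(met_of), 1L, met_of)] != 1
       else FALSE),
    metabolite = if (n_met) ifelse(is.na(met_of), NA_character_,
                                   panel$name[ifelse(is.na(met_of), 1L,
                                                     met_of)])
      else NA_character_,
    isotope = iso_of, partner = partner,
    direction = if (n_met) ifelse(is.na(met_of), NA_character_,
                                  panel$direction[ifelse(is.na(met_of), 1L,
                                                         met_of)])
      else NA_character_,
    fold_change = if (n_met) ifelse(is.na(met_of), NA_real_,
                                    panel$fold_change[ifelse(is.na(met_of),
                                                             1L, met_of)])
      else NA_real_,
    stringsAsFactors = FALSE)
  truth$is_panel <- !is.na(met_of)
  list(y = y, sample_ids = sample_ids, feature_mz = feature_mz,
       amplitudes = amp, truth = truth)
}

#' Generate a synthetic feature table
#'
#' Fast path bypassing spectral rendering: directly emits the per-sample
#' log-normal feature intensities (both doublet members per panel
#' metabolite plus the null features), statistically identical to running
#' [make_cohort_spectra()] through an ideal peak detector.
#'
#' @param spec a [cohort_spec()].
#' @return List with `matrix` (unstandardized, unnormalized
#'   [feature_matrix()]) and `truth` (per-feature ground-truth data frame
#'   with `feature_mz`, `is_differential`, `metabolite`, `isotope`,
#'   `partner`, `direction`, `fold_change`, `is_panel`).
#' @export
make_feature_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- with_seed(spec$seed, draw_cohort(spec))
  fm <- feature_matrix(d$amplitudes, d$feature_mz, d$y, d$sample_ids)
  list(matrix = fm, truth = d$truth)
}

#' Generate synthetic replicate spectra for a cohort
#'
#' Renders each sample's feature amplitudes as Gaussian peaks (sd
#' `peak_sigma`) on a regular m/z grid, over an exponentially decaying
#' baseline, with fresh additive Gaussian noise per replicate; peak
#' amplitudes are fixed per sample so replicates differ only in noise.
#' Panel metabolites appear as 107/109 adduct doublets at the configured
#' isotope intensity ratio.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional directory: when given, spectra are written as
#'   two-column tsv files and a manifest CSV referencing them.
#' @return List with `spectra` (list of [raw_spectrum()]), `manifest`
#'   (`cohort_manifest` data frame; paths refer to files under `dir` when
#'   written), `truth` (as in [make_feature_table()]).
#' @export
make_cohort_spectra <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- with_seed(spec$seed, {
    d <- draw_cohort(spec)
    grid <- seq(spec$mz_range[1], spec$mz_range[2], by = spec$grid_step)
    baseline <- spec$baseline_amplitude *
      exp(-spec$baseline_decay * (grid - spec$mz_range[1]))
    n <- length(d$y)
    spectra <- vector("list", n * spec$replicates_per_sample)
    si <- 0L
    for (i in seq_len(n)) {
      clean <- baseline
      for (j in seq_along(d$feature_mz)) {
        lo <- findInterval(d$feature_mz[j] - 8 * spec$peak_sigma, grid) + 1L
        hi <- findInterval(d$feature_mz[j] + 8 * spec$peak_sigma, grid)
        if (hi < lo) next
        win <- lo:hi
        clean[win] <- clean[win] + d$amplitudes[i, j] *
          exp(-(grid[win] - d$feature_mz[j])^2 / (2 * spec$peak_sigma^2))
      }
      for (rep_k in seq_len(spec$replicates_per_sample)) {
        si <- si + 1L
        noisy <- if (spec$noise_sd > 0)
          pmax(clean + rnorm(length(grid), 0, spec$noise_sd), 0)
        else clean
        spectra[[si]] <- raw_spectrum(grid, noisy,
                                      sample_id = d$sample_ids[i],
                                      replicate_index = rep_k)
      }
    }
    list(d = d, spectra = spectra)
  })
  d <- out$d
  label <- ifelse(d$y == 1, spec$case_label, spec$control_label)
  files <- lapply(seq_along(d$sample_ids), function(i)
    sprintf("%s_rep%d.tsv", d$sample_ids[i],
            seq_len(spec$replicates_per_sample)))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    si <- 0L
    for (i in seq_along(d$sample_ids)) {
      for (k in seq_len(spec$replicates_per_sample)) {
        si <- si + 1L
        write_spectrum(out$spectra[[si]], file.path(dir, files[[i]][k]))
      }
    }
  }
  manifest <- data.frame(sample_id = d$sample_ids, label = label,
                         stringsAsFactors = FALSE)
  manifest$paths <- if (is.null(dir)) files else
    lapply(files, function(f) file.path(dir, f))
  class(manifest) <- c("cohort_manifest", "data.frame")
  if (!is.null(dir))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(spectra = out$spectra, manifest = manifest, truth = d$truth)
}

#' Simulation-based power analysis
#'
#' For each candidate per-class sample size, simulates cohorts from the
#' generative model, runs per-feature Welch t-tests with
#' Benjamini-Hochberg correction at FDR `fdr_q`, and estimates power as
#' the mean fraction of panel features declared significant.
#'
#' @param spec a [cohort_spec()] (its sample sizes are overridden by
#'   `n_grid`); must contain at least one panel feature.
#' @param n_grid vector of per-class sample sizes (each >= 2).
#' @param fdr_q false discovery rate for the BH correction (default 0.10).
#' @param n_sim simulated cohorts per size (default 100).
#' @param seed base seed for the simulation stream.
#' @return Data frame with columns `n` (per-class size) and `power`.
#' @export
power_analysis <- function(spec, n_grid, fdr_q = 0.10, n_sim = 100,
                           seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(spec$panel) || !nrow(spec$panel))
    stop_param("spec must contain at least one panel metabolite")
  if (fdr_q <= 0 || fdr_q >= 1) stop_param("fdr_q must be in (0, 1)")
  if (any(n_grid < 2)) stop_param("need at least 2 samples per class")
  res <- vapply(seq_along(n_grid), function(k) {
    nn <- n_grid[k]
    hits <- vapply(seq_len(n_sim), function(s) {
      sp <- spec
      sp$n_control <- sp$n_case <- as.integer(nn)
      sp$seed <- as.integer((seed + 7919 * k + s) %% .Machine$integer.max)
      tab <- make_feature_table(sp)
      pv <- ttest_features(tab$matrix)
      padj <- stats::p.adjust(pv, method = "BH")
      mean(padj[tab$truth$is_panel] < fdr_q)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  data.frame(n = n_grid, power = res)
}
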