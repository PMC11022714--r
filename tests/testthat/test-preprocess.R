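test_that("replicate averaging: identity, idempotence, arithmetic mean", {
  s1 <- raw_spectrum(1:5 + 100, c(1, 2, 3, 2, 1), "a", 1L)
  one <- average_replicates(list(s1))
  expect_equal(one$mz, s1$mz)
  expect_equal(one$intensity, s1$intensity)
  expect_equal(one$replicate_index, 0L)

  s2 <- s1; s2$replicate_index <- 2L
  two <- average_replicates(list(s1, s2))
  expect_equal(two$intensity, s1$intensity)

  a <- raw_spectrum(1:5 + 100, rep(2, 5), "a")
  b <- raw_spectrum(1:5 + 100, rep(4, 5), "a")
  expect_equal(average_replicates(list(a, b))$intensity, rep(3, 5))
})

test_that("replicate averaging resamples onto the union grid", {
  a <- raw_spectrum(c(100, 102, 104), c(0, 2, 4), "a")
  b <- raw_spectrum(c(101, 103), c(10, 10), "a")
  m <- average_replicates(list(a, b))
  # overlap is [101, 103]; union grid there is 101,102,103
  expect_equal(m$mz, c(101, 102, 103))
  expect_equal(m$intensity, c((1 + 10) / 2, (2 + 10) / 2, (3 + 10) / 2))
  expect_error(average_replicates(list()), "no spectra")
  expect_error(average_replicates(list(
    raw_spectrum(1:3, 1:3, "a"), raw_spectrum(7:9, 1:3, "a"))), "disjoint")
  expect_error(average_replicates(list(
    raw_spectrum(1:3, 1:3, "a"), raw_spectrum(1:3, 1:3, "b"))),
    "different samples")
})

test_that("opening baseline removes offsets and matches the brute-force oracle", {
  z <- raw_spectrum(seq(100, 110, 0.1), rep(0, 101))
  expect_equal(baseline_correct(z, 1)$intensity, rep(0, 101))

  g <- gaussian_spectrum(105, 50, sigma = 0.05,
                         mz = seq(100, 110, by = 0.02), offset = 10)
  bc <- baseline_correct(g, half_window = 1)
  apex <- which.max(g$intensity)
  expect_equal(bc$intensity[apex], g$intensity[apex] - 10, tolerance = 1e-6)

  set.seed(3)
  mz <- sort(runif(150, 100, 120))
  v <- abs(rnorm(150, 5, 3))
  ours <- agfinger:::.opening_baseline(mz, v, 0.7)
  oracle <- opening_baseline_oracle(mz, v, 0.7)
  expect_equal(as.numeric(ours), oracle, tolerance = 1e-12)

  expect_error(baseline_correct(g, 0), "half_window")
})

test_that("peak detection finds planted peaks inside the window only", {
  g <- gaussian_spectrum(271.98, 1000, mz = seq(260, 280, by = 0.02))
  ps <- detect_peaks(g, snr_min = 3)
  expect_equal(nrow(ps$peaks), 1L)
  expect_lt(abs(ps$peaks$mz - 271.98), 0.02 + 1e-12)

  low <- gaussian_spectrum(50, 1000, mz = seq(40, 60, by = 0.02))
  expect_equal(nrow(detect_peaks(low, snr_min = 3)$peaks), 0L)

  expect_error(detect_peaks(g, window = c(500, 100)), "mz_lo")
})

test_that("white noise yields under 1% spurious peaks at snr_min 5", {
  set.seed(42)
  mz <- seq(100, 1000, by = 0.1)
  s <- raw_spectrum(mz, abs(rnorm(length(mz))))
  ps <- detect_peaks(s, snr_min = 5)
  expect_lt(nrow(ps$peaks) / length(mz), 0.01)
})

test_that("noiseless synthetic spectra yield exactly the planted peaks", {
  spec <- tiny_spec(n_control = 1L, n_case = 1L, n_null = 10L)
  spec$noise_sd <- 0
  spec$baseline_amplitude <- 0
  sim <- make_cohort_spectra(spec)
  s <- baseline_correct(sim$spectra[[1]], 1)
  ps <- detect_peaks(s, snr_min = 3)
  planted <- sim$truth$feature_mz
  expect_equal(nrow(ps$peaks), length(planted))
  d <- vapply(ps$peaks$mz, function(m) min(abs(planted - m)), numeric(1))
  expect_true(all(d <= spec$grid_step))
})

test_that("alignment bins by single-linkage gaps and matches the scan oracle", {
  mk <- function(id, mz) structure(list(
    sample_id = id,
    peaks = data.frame(mz = mz, intensity = rep(1, length(mz)),
                       snr = rep(10, length(mz)))), class = "peak_set")
  al <- align_features(list(mk("a", 200.00), mk("b", 200.04)), tol = 0.1)
  expect_equal(length(al$feature_mz), 1L)
  al2 <- align_features(list(mk("a", 200.0), mk("b", 200.4)), tol = 0.1)
  expect_equal(length(al2$feature_mz), 2L)

  set.seed(5)
  mzs <- lapply(1:3, function(i) sort(runif(5, 100, 103)))
  al3 <- align_features(lapply(1:3, function(i) mk(letters[i], mzs[[i]])),
                        tol = 0.2)
  pooled <- sort(unlist(mzs))
  oracle_bins <- cumsum(c(1, as.integer(diff(pooled) > 0.2)))
  expect_equal(length(al3$feature_mz), max(oracle_bins))
  # every sample's total intensity is conserved in X_raw
  expect_equal(unname(rowSums(al3$X_raw)), rep(5, 3))
  expect_error(align_features(list(mk("a", 200)), tol = 0.1), "at least two")
  expect_error(align_features(list(mk("a", 200), mk("b", 201)), tol = 0),
               "tol")
})

test_that("top-k selection ranks by median intensity, ties to lower m/z", {
  X <- rbind(c(5, 9, 1), c(5, 9, 1))
  fmz <- c(100, 200, 300)
  fm <- select_top_features(fmz, X, k = 830, y = c(0, 1))
  expect_equal(length(fm$feature_mz), 3L)
  fm2 <- select_top_features(fmz, X, k = 2, y = c(0, 1))
  expect_equal(fm2$feature_mz, c(100, 200))

  set.seed(9)
  Xr <- matrix(rlnorm(20 * 100), 20, 100)
  fmzr <- sort(runif(100, 100, 1000))
  keep_oracle <- sort(order(-apply(Xr, 2, median), fmzr)[1:40])
  fm3 <- select_top_features(fmzr, Xr, k = 40, y = rep(0:1, 10))
  expect_equal(fm3$feature_mz, fmzr[keep_oracle])

  # invariance to the order in which bins are supplied
  perm <- sample(100)
  fm4 <- select_top_features(fmzr[perm], Xr[, perm], k = 40, y = rep(0:1, 10))
  expect_equal(fm4$feature_mz, fm3$feature_mz)
  expect_equal(fm4$X, fm3$X, ignore_attr = TRUE)
})

test_that("TIC normalization and standardization behave as defined", {
  fm <- feature_matrix(rbind(c(2, 2), c(1, 3), c(0, 0)), c(100, 200),
                       c(0, 1, 0), c("a", "b", "c"))
  expect_warning(nm <- normalize_tic(fm), "all-zero")
  expect_equal(nm$X[1, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(unname(rowSums(nm$X)[1:2]), c(1, 1))
  expect_equal(nm$X[3, ], c(0, 0), ignore_attr = TRUE)

  fm2 <- feature_matrix(cbind(c(1, 3), c(5, 5)), c(100, 200), c(0, 1),
                        c("a", "b"))
  sd2 <- standardize(fm2)
  expect_equal(sd2$X[, 1], c(-1, 1), ignore_attr = TRUE)
  expect_equal(sd2$X[, 2], c(0, 0), ignore_attr = TRUE)
  expect_equal(sd2$zero_variance, 2L)
  expect_true(sd2$standardized)

  set.seed(2)
  fm3 <- feature_matrix(matrix(rnorm(100), 20, 5), 1:5 * 100,
                        rep(0:1, 10), paste0("s", 1:20))
  st <- standardize(fm3)
  expect_true(all(abs(colMeans(st$X)) < 1e-12))
  pop_sd <- apply(st$X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_true(all(abs(pop_sd - 1) < 1e-12))
})

test_that("the preprocessing chain is permutation-equivariant in samples", {
  spec <- tiny_spec(n_control = 3L, n_case = 3L, n_null = 8L)
  spec$mz_range <- c(100, 420)
  sim <- make_cohort_spectra(spec)
  labels <- stats::setNames(as.numeric(sim$manifest$label == "PKU"),
                            sim$manifest$sample_id)
  fm <- preprocess_cohort(sim$spectra, labels, k = 30)
  # permute samples (keeping replicates grouped)
  ids <- unique(vapply(sim$spectra, `[[`, "", "sample_id"))
  perm_ids <- rev(ids)
  reordered <- sim$spectra[order(match(
    vapply(sim$spectra, `[[`, "", "sample_id"), perm_ids))]
  fm2 <- preprocess_cohort(reordered, labels, k = 30)
  expect_equal(fm2$feature_mz, fm$feature_mz)
  expect_equal(fm2$X[fm$sample_ids, ], fm$X, ignore_attr = TRUE)
})
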