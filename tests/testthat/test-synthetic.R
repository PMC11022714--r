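test_that("generation is byte-identical under a fixed seed", {
  spec <- tiny_spec(n_control = 4L, n_case = 3L, n_null = 10L)
  t1 <- make_feature_table(spec)
  t2 <- make_feature_table(spec)
  expect_identical(t1, t2)
  spec$mz_range <- c(100, 420)
  s1 <- make_cohort_spectra(spec)
  s2 <- make_cohort_spectra(spec)
  expect_identical(s1$spectra, s2$spectra)
  expect_identical(s1$truth, s2$truth)
  spec2 <- spec; spec2$seed <- spec$seed + 1L
  expect_false(identical(make_feature_table(spec2)$matrix$X, t1$matrix$X))
})

test_that("empty cohorts and out-of-window panels are handled", {
  spec <- tiny_spec(n_control = 0L, n_case = 0L, n_null = 5L)
  tab <- make_feature_table(spec)
  expect_equal(nrow(tab$matrix$X), 0L)
  expect_equal(ncol(tab$matrix$X), 9L)  # 2 doublets + 5 nulls

  bad <- tiny_spec()
  bad$mz_range <- c(100, 200)  # Phe adducts at ~272/274 fall outside
  expect_error(make_feature_table(bad), "Phe")
})

test_that("every panel metabolite contributes one 107/109 doublet", {
  spec <- tiny_spec(n_control = 2L, n_case = 2L, n_null = 20L)
  tab <- make_feature_table(spec)
  tr <- tab$truth
  expect_equal(sum(tr$is_panel), 4L)
  for (m in unique(na.omit(tr$metabolite))) {
    jj <- which(!is.na(tr$metabolite) & tr$metabolite == m)
    expect_length(jj, 2L)
    expect_setequal(tr$isotope[jj], c(107L, 109L))
    expect_equal(tr$partner[jj], rev(jj))
    d <- diff(sort(tab$matrix$feature_mz[jj]))
    expect_equal(d, ag_isotopes()$m109 - ag_isotopes()$m107,
                 tolerance = 1e-9)
  }
})

test_that("noiseless spectra carry only the planted doublet at the isotope ratio", {
  pan <- default_panel()[1, ]  # Phe only
  spec <- cohort_spec(n_control = 1L, n_case = 0L, panel = pan,
                      n_null_features = 0L, noise_sd = 0,
                      baseline_amplitude = 0, measurement_sdlog = 0,
                      replicates_per_sample = 1L, mz_range = c(100, 400),
                      seed = 3L)
  sim <- make_cohort_spectra(spec)
  s <- sim$spectra[[1]]
  mz107 <- adduct_mz(pan$neutral_mass, 107)
  mz109 <- adduct_mz(pan$neutral_mass, 109)
  near <- abs(s$mz - mz107) < 0.5 | abs(s$mz - mz109) < 0.5
  expect_true(all(s$intensity[!near] < 1e-6 * max(s$intensity)))
  i107 <- sum(s$intensity[abs(s$mz - mz107) < 0.5])
  i109 <- sum(s$intensity[abs(s$mz - mz109) < 0.5])
  expect_equal(i107 / i109, spec$isotope_ratio, tolerance = 1e-9)
})

test_that("case/control intensity ratios converge to the fold change", {
  spec <- tiny_spec(n_control = 500L, n_case = 500L, n_null = 5L,
                    seed = 99L)
  tab <- make_feature_table(spec)
  tr <- tab$truth
  X <- tab$matrix$X; y <- tab$matrix$y
  ratios <- vapply(which(tr$is_panel), function(j)
    mean(X[y == 1, j]) / mean(X[y == 0, j]), numeric(1))
  expected <- ifelse(tr$direction[tr$is_panel] == "up",
                     tr$fold_change[tr$is_panel],
                     1 / tr$fold_change[tr$is_panel])
  expect_lt(mean(abs(ratios / expected - 1)), 0.05)
})

test_that("a null cohort is exchangeable under label permutation", {
  pan <- default_panel(fold_change = 1)
  pan$fold_change <- 1
  spec <- cohort_spec(n_control = 30L, n_case = 30L, panel = pan,
                      n_null_features = 20L, seed = 8L)
  tab <- make_feature_table(spec)
  expect_false(any(tab$truth$is_differential))
  pv <- ttest_features(normalize_tic(tab$matrix))
  # no feature should be wildly significant on a null cohort of this size
  expect_gt(min(pv), 1e-4 / length(pv))
})

test_that("feature table and rendered spectra agree through peak detection", {
  spec <- tiny_spec(n_control = 3L, n_case = 3L, n_null = 10L, seed = 21L)
  spec$mz_range <- c(100, 420)
  spec$baseline_amplitude <- 0
  spec$noise_sd <- 0
  sim <- make_cohort_spectra(spec)
  tab <- make_feature_table(spec)
  # the amplitudes underlying both generators are identical by seed
  s1 <- sim$spectra[[1]]
  apex <- vapply(tab$truth$feature_mz, function(m) {
    w <- abs(s1$mz - m) < 0.2
    max(s1$intensity[w])
  }, numeric(1))
  expect_equal(apex, unname(tab$matrix$X[1, ]), tolerance = 0.1)
})

test_that("power analysis: null panels stay near zero, effects match theory", {
  pan <- data.frame(name = "Phe", neutral_mass = formula_mass("C9H11NO2"),
                    fold_change = 1, direction = "up",
                    stringsAsFactors = FALSE)
  null_spec <- cohort_spec(panel = pan, n_null_features = 10L,
                           intensity_sdlog = 0.3, measurement_sdlog = 0,
                           seed = 1L)
  pow0 <- power_analysis(null_spec, n_grid = 12, fdr_q = 0.10,
                         n_sim = 60, seed = 4L)
  expect_lt(pow0$power, 0.2)

  # one doublet, no nulls, measurement noise off: both features share one
  # p-value, so BH rejects both iff p <= q. Standardized effect ~1.2 at
  # sigma 0.1 corresponds to fold change ~1.128.
  eff_spec <- cohort_spec(panel = transform(pan, fold_change = 1.128),
                          n_null_features = 0L, intensity_sdlog = 0.1,
                          measurement_sdlog = 0, seed = 1L)
  pow <- power_analysis(eff_spec, n_grid = 8, fdr_q = 0.10, n_sim = 400,
                        seed = 5L)
  d <- 1.2
  ncp <- d * sqrt(8 * 8 / 16)
  df <- 14
  crit <- qt(1 - 0.10 / 2, df)
  theory <- 1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
  expect_lt(abs(pow$power - theory), 0.07)

  # power is nondecreasing in n (up to Monte-Carlo error)
  pow_n <- power_analysis(eff_spec, n_grid = c(4, 10, 24), fdr_q = 0.10,
                          n_sim = 60, seed = 6L)
  expect_true(all(diff(pow_n$power) > -0.1))
  expect_error(power_analysis(eff_spec, n_grid = 1), "at least 2")
  expect_error(power_analysis(eff_spec, n_grid = 10, fdr_q = 2), "fdr_q")
})
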