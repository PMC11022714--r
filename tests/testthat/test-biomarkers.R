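# hand-built nested_cv shell carrying chosen selection frequencies
stub_cv <- function(freq, feature_mz, X, y) {
  structure(list(selection_frequency = freq, feature_mz = feature_mz,
                 X = X, y = y, learner = "elastic_net"),
            class = "nested_cv")
}

delta_ag <- function() ag_isotopes()$m109 - ag_isotopes()$m107

test_that("Welch t-tests match the longhand formula on a printed fixture", {
  # fixture: case 5.1, 6.3, 5.8 vs control 4.0, 3.6, 4.4
  x1 <- c(5.1, 6.3, 5.8); x0 <- c(4.0, 3.6, 4.4)
  fm <- feature_matrix(matrix(c(x0, x1), ncol = 1), 200,
                       c(0, 0, 0, 1, 1, 1), paste0("s", 1:6))
  p <- ttest_features(fm)
  se <- sqrt(var(x1) / 3 + var(x0) / 3)
  tstat <- (mean(x1) - mean(x0)) / se
  df <- se^4 / ((var(x1) / 3)^2 / 2 + (var(x0) / 3)^2 / 2)
  expect_equal(p, 2 * pt(-abs(tstat), df), ignore_attr = TRUE)

  # label swap leaves the two-sided p unchanged
  fm_sw <- fm; fm_sw$y <- 1 - fm$y
  expect_equal(ttest_features(fm_sw), p)
})

test_that("constant features get p = 1 and tiny classes error", {
  fm <- feature_matrix(cbind(rep(2, 6), rnorm(6)), c(100, 200),
                       rep(0:1, each = 3), paste0("s", 1:6))
  p <- ttest_features(fm)
  expect_equal(p[[1]], 1)
  fm_small <- feature_matrix(matrix(rnorm(3), ncol = 1), 100, c(0, 0, 1),
                             paste0("s", 1:3))
  expect_error(ttest_features(fm_small), "at least two")
})

test_that("the frequency boundary is strict and pairing is enforced", {
  d <- delta_ag()
  fmz <- c(200, 200 + d, 300, 300 + d, 500)
  set.seed(1)
  X <- matrix(rlnorm(10 * 5), 10, 5)
  X[6:10, 1:2] <- X[6:10, 1:2] * 4   # first doublet differential
  y <- rep(0:1, each = 5)
  pairs <- find_isotope_pairs(fmz, 0.02)
  expect_equal(nrow(pairs), 2L)

  # frequency exactly at the threshold is excluded ("over 80%")
  cv <- stub_cv(c(0.80, 0.81, 1, 1, 1), fmz, X, y)
  pv <- c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4)
  pan <- suppressMessages(select_biomarkers(cv, pv, pairs,
                                            selection_criteria(),
                                            annotate_table = NULL))
  expect_equal(pan$mz107, 300)

  # a surviving feature whose partner fails the p-filter is dropped
  cv2 <- stub_cv(c(1, 1, 1, 1, 1), fmz, X, y)
  pv2 <- c(1e-4, 0.2, 1e-4, 1e-4, 1e-4)
  pan2 <- suppressMessages(select_biomarkers(cv2, pv2, pairs,
                                             selection_criteria(),
                                             annotate_table = NULL))
  expect_equal(pan2$mz107, 300)

  # without the pair requirement the unpaired feature also survives
  pan3 <- suppressMessages(select_biomarkers(
    cv2, pv2, pairs, selection_criteria(require_pair = FALSE),
    annotate_table = NULL))
  expect_equal(length(attr(pan3, "feature_idx")), 4L)
})

test_that("doublets disagreeing on direction are dropped with a warning", {
  d <- delta_ag()
  fmz <- c(200, 200 + d)
  X <- cbind(c(1, 1, 1, 5, 5, 5), c(5, 5, 5, 1, 1, 1))
  y <- rep(0:1, each = 3)
  cv <- stub_cv(c(1, 1), fmz, X, y)
  pairs <- find_isotope_pairs(fmz, 0.02)
  expect_warning(
    pan <- suppressMessages(select_biomarkers(cv, c(1e-4, 1e-4), pairs,
                                              selection_criteria(),
                                              annotate_table = NULL)),
    "disagree")
  expect_equal(nrow(pan), 0L)
})

test_that("selection is monotone in the criteria", {
  d <- delta_ag()
  set.seed(23)
  fmz <- sort(c(runif(6, 100, 900), 250, 250 + d, 400, 400 + d))
  X <- matrix(rlnorm(12 * 10), 12, 10)
  y <- rep(0:1, each = 6)
  X[y == 1, fmz %in% c(250, 250 + d)] <-
    X[y == 1, fmz %in% c(250, 250 + d)] * 3
  freq <- runif(10, 0.5, 1)
  pv <- runif(10, 0, 0.1)
  cv <- stub_cv(freq, fmz, X, y)
  pairs <- find_isotope_pairs(fmz, 0.02)
  strict <- suppressMessages(select_biomarkers(
    cv, pv, pairs, selection_criteria(freq_min = 0.9, p_max = 0.01),
    annotate_table = NULL))
  loose <- suppressMessages(select_biomarkers(
    cv, pv, pairs, selection_criteria(freq_min = 0.6, p_max = 0.09),
    annotate_table = NULL))
  expect_true(all(attr(strict, "feature_idx") %in%
                    attr(loose, "feature_idx")))
})

test_that("selection frequency is required", {
  fm <- feature_matrix(matrix(rlnorm(40), 10, 4),
                       c(100, 200, 300, 400), rep(0:1, 5), paste0("s", 1:10))
  cvk <- structure(list(selection_frequency = NULL, learner = "knn"),
                   class = "nested_cv")
  expect_error(select_biomarkers(cvk, rep(0.01, 4),
                                 find_isotope_pairs(fm$feature_mz, 0.02)),
               "elastic-net")
})

test_that("panel refit beats single biomarkers on a planted cohort", {
  spec <- tiny_spec(n_control = 40L, n_case = 20L, n_null = 16L, seed = 31L,
                    panel_names = default_panel()$name)
  tab <- make_feature_table(spec)
  fm <- normalize_tic(tab$matrix)
  cfg <- cv_config(rounds = 2, seed = 1)
  cv <- nested_cv(fm, config = cfg)
  pv <- ttest_features(fm)
  pan <- suppressMessages(select_biomarkers(cv, pv, criteria =
                                              selection_criteria(),
                                            matrix = fm))
  expect_gt(nrow(pan), 0L)
  pm <- panel_model(fm, pan, config = cfg)
  expect_s3_class(pm, "panel_model")
  best_single <- max(vapply(pm$single, `[[`, numeric(1), "auc"))
  expect_gte(pm$roc$auc + 1e-9, best_single)
  expect_error(panel_model(fm, structure(data.frame(),
                                         feature_idx = integer(0),
                                         class = c("biomarker_panel",
                                                   "data.frame"))),
               "empty")
})
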