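# Shared fixtures for the test suite. All synthetic data is generated in
# code under fixed seeds.

# A small cohort specification that keeps nested CV fast: two differential
# metabolites among a handful of nulls.
tiny_spec <- function(n_control = 30L, n_case = 15L, n_null = 30L,
                      seed = 7L, fold_change = 3,
                      panel_names = c("Phe", "Eth")) {
  pan <- default_panel(fold_change = fold_change)
  pan <- pan[pan$name %in% panel_names, ]
  cohort_spec(n_control = n_control, n_case = n_case,
              panel = pan, n_null_features = n_null, seed = seed)
}

# Sampled Gaussian peak on a regular grid.
gaussian_spectrum <- function(center, height, sigma = 0.05,
                              mz = seq(center - 10, center + 10, by = 0.02),
                              offset = 0, sample_id = "g") {
  raw_spectrum(mz, offset + height * exp(-(mz - center)^2 / (2 * sigma^2)),
               sample_id = sample_id)
}

# Brute-force rolling min/max opening baseline (oracle for the C++ path).
opening_baseline_oracle <- function(mz, v, h) {
  n <- length(mz)
  roll <- function(x, f) vapply(seq_len(n), function(i)
    f(x[abs(mz - mz[i]) <= h]), numeric(1))
  roll(roll(v, min), max)
}

# Exhaustive concordant-pair AUC (oracle).
auc_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  mean(outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b)))
}

# A minimal hand-built nested_cv-like object whose predictions are a fixed
# linear model; used to exercise decision logic without training.
stub_cv_model <- function(beta, intercept, feature_mz) {
  structure(list(
    models = list(list(learner = "elastic_net", beta = beta,
                       intercept = intercept,
                       center = rep(0, length(beta)),
                       scale = rep(1, length(beta)),
                       zero = rep(FALSE, length(beta)))),
    feature_mz = feature_mz, learner = "elastic_net"),
    class = "nested_cv")
}
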