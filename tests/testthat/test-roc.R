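test_that("AUC equals the exhaustive concordant-pair proportion", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)

  for (seed in 1:5) {
    set.seed(seed)
    s <- sample(seq(0, 1, 0.1), 12, replace = TRUE)  # forces ties
    l <- c(rep(1, 5), rep(0, 7))
    expect_equal(roc_auc(s, l)$auc, auc_oracle(s, l))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("the ROC staircase is monotone and its trapezoid area is the AUC", {
  set.seed(8)
  s <- rnorm(40); l <- rbinom(40, 1, 0.5); l[1:2] <- 0:1
  r <- roc_auc(s, l)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  xs <- c(r$fpr, 1); ys <- c(r$tpr, 1)
  trap <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(4)
  s <- rnorm(30); l <- rbinom(30, 1, 0.4); l[1:2] <- 0:1
  a0 <- roc_auc(s, l)$auc
  expect_equal(roc_auc(exp(s), l)$auc, a0)
  expect_equal(roc_auc(stats::plogis(3 * s + 2), l)$auc, a0)
})

test_that("DeLong interval matches the longhand structural components", {
  set.seed(12)
  s <- rnorm(20); l <- c(rep(1, 8), rep(0, 12))
  ci <- auc_ci(s, l)
  # longhand: psi matrix, component variances
  cs <- s[l == 1]; ct <- s[l == 0]
  psi <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  vref <- var(v10) / 8 + var(v01) / 12
  expect_equal(attr(ci, "var"), vref)
  expect_equal(as.numeric(ci),
               pmin(pmax(mean(psi) + c(-1, 1) * qnorm(0.975) * sqrt(vref),
                         0), 1))
  # independent implementation: pROC (direction pinned: higher = case)
  pr <- pROC::roc(l, s, quiet = TRUE, direction = "<", levels = c(0, 1))
  expect_equal(as.numeric(ci), as.numeric(pROC::ci.auc(pr, method = "delong"))[c(1, 3)],
               tolerance = 1e-10)
})

test_that("perfect separation clips the DeLong interval at 1", {
  ci <- auc_ci(c(3, 4, 5, 6, 1, 2, 0, -1), c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(as.numeric(ci), c(1, 1))
})

test_that("doubling the cohort shrinks the DeLong variance", {
  set.seed(13)
  s <- rnorm(24); l <- rbinom(24, 1, 0.5); l[1:4] <- c(0, 0, 1, 1)
  v1 <- attr(auc_ci(s, l), "var")
  v2 <- attr(auc_ci(c(s, s), c(l, l)), "var")
  expect_lt(v2, v1)
})

test_that("cutoff strategies match an exhaustive threshold scan", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  for (m in c("youden", "closest01", "equal_ss")) {
    cut <- choose_cutoff(r, m)
    expect_equal(cut$sensitivity, 1)
    expect_equal(cut$specificity, 1)
  }

  toy <- structure(list(thresholds = c(Inf, 0.7, 0.1),
                        fpr = c(0, 0.2, 1), tpr = c(0, 0.9, 1)),
                   class = "roc_curve")
  yj <- choose_cutoff(toy, "youden")
  expect_equal(yj$sensitivity, 0.9)
  expect_equal(yj$specificity, 0.8)

  set.seed(21)
  s <- rnorm(50); l <- rbinom(50, 1, 0.5); l[1:2] <- 0:1
  r2 <- roc_auc(s, l)
  scan <- data.frame(t = r2$thresholds, sens = r2$tpr, spec = 1 - r2$fpr)
  oracle <- list(
    youden = scan[order(-(scan$sens + scan$spec - 1), -scan$sens,
                        scan$t)[1], ],
    closest01 = scan[order(sqrt((1 - scan$spec)^2 + (1 - scan$sens)^2),
                           -scan$sens, scan$t)[1], ],
    equal_ss = scan[order(abs(scan$sens - scan$spec), -scan$sens,
                          scan$t)[1], ])
  for (m in names(oracle)) {
    cut <- choose_cutoff(r2, m)
    expect_equal(cut$threshold, oracle[[m]]$t)
    expect_equal(cut$sensitivity, oracle[[m]]$sens)
    expect_equal(cut$specificity, oracle[[m]]$spec)
  }
})

test_that("DeLong test: identity gives p = 1, swapping negates z", {
  set.seed(30)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5); l[1:2] <- 0:1
  same <- delong_test(s, s, l)
  expect_equal(same$z, 0)
  expect_equal(same$p.value, 1)

  s2 <- rnorm(30)
  ab <- delong_test(s, s2, l)
  ba <- delong_test(s2, s, l)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p.value, ba$p.value)
})

test_that("DeLong test agrees with pROC's paired implementation", {
  set.seed(31)
  l <- rbinom(40, 1, 0.4); l[1:2] <- 0:1
  sA <- rnorm(40) + l; sB <- rnorm(40) + 0.5 * l
  ours <- delong_test(sA, sB, l)
  ref <- pROC::roc.test(
    pROC::roc(l, sA, quiet = TRUE, direction = "<", levels = c(0, 1)),
    pROC::roc(l, sB, quiet = TRUE, direction = "<", levels = c(0, 1)),
    method = "delong", paired = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)),
               tolerance = 1e-10)
})
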