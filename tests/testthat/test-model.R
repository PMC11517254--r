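test_that("auc_score matches worked examples and handles ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(c(0.9, 0.15, 0.1, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_score(c(0.5, 0.5), c(1, 0)), 0.5)  # tie = half credit
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auc_score equals the all-pairs oracle on random data", {
  set.seed(501)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2)  # rounding forces ties
    expect_lt(abs(auc_score(s, y) - oracle_auc(s, y)), 1e-9)
  }
})

test_that("threshold_at_specificity picks the smallest qualifying cutoff", {
  scores <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.9)
  labels <- c(0, 0, 0, 0, 1, 1)
  thr <- threshold_at_specificity(scores, labels, 0.95)
  expect_equal(thr, 0.5)
  expect_equal(mean(scores[labels == 1] >= thr), 1.0)  # sensitivity 1
  # all scores equal: unreachable -> +Inf sentinel with warning
  expect_warning(
    thr2 <- threshold_at_specificity(rep(0.4, 6), labels, 0.95),
    "unreachable"
  )
  expect_identical(thr2, Inf)
  # target 0 -> minimum observed score
  expect_equal(threshold_at_specificity(scores, labels, 0), 0.1)
  expect_error(threshold_at_specificity(c(1, 2), c(1, 1), 0.9), "no negatives")
})

test_that("realized specificity at a calibrated threshold strictly exceeds target", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(30:120, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)
    for (target in c(0.8, 0.9, 0.95)) {
      thr <- suppressWarnings(threshold_at_specificity(s, y, target))
      if (is.finite(thr)) {
        expect_gt(mean(s[y == 0] < thr), target)
      }
    }
  }
})

test_that("cross_validate_select runs stratified CV and selects by mean AUC", {
  rows <- toy_features(n_pos = 60, n_neg = 300, seed = 2)
  cfg <- model_config(algorithms = "LR", cv_folds = 5, seed = 3)
  cv <- cross_validate_select(rows, cfg)
  expect_equal(cv$selected, "LR")  # degenerate argmax
  expect_equal(dim(cv$fold_auc), c(5L, 1L))

  # perfectly separable features -> every fold AUC = 1 for every algorithm
  sep <- data.frame(
    phla_rank = c(runif(30, 0, 1), runif(150, 50, 100)),
    ptcr_rank = c(runif(30, 0, 1), runif(150, 50, 100)),
    label = rep(c("immunogenic", "non_immunogenic"), c(30, 150))
  )
  cvs <- cross_validate_select(sep, model_config(cv_folds = 5, seed = 1))
  expect_true(all(abs(cvs$fold_auc - 1) < 1e-12))
  # tie on AUC = 1 everywhere -> fixed precedence picks XGB
  expect_equal(cvs$selected, "XGB")

  expect_error(
    cross_validate_select(rows[c(1:3, 61:70), ],
                          model_config(cv_folds = 5, seed = 1)),
    "fewer members than folds"
  )
})

test_that("fit_final is deterministic and scores stay in [0, 1]", {
  rows <- toy_features(seed = 5)
  for (alg in c("LR", "RF", "XGB")) {
    cfg <- model_config(cv_folds = 2, seed = 17)
    m1 <- fit_final(rows, alg, cfg)
    m2 <- fit_final(rows, alg, cfg)
    s1 <- predict(m1, rows); s2 <- predict(m2, rows)
    expect_identical(s1, s2)
    expect_true(all(is.finite(s1) & s1 >= 0 & s1 <= 1))
    # higher score = more immunogenic on average
    y <- as.integer(rows$label == "immunogenic")
    expect_gt(mean(s1[y == 1]), mean(s1[y == 0]))
  }
  one_class <- rows; one_class$label <- "immunogenic"
  expect_error(fit_final(one_class, "LR", model_config(seed = 1)),
               "both classes")
  # combined feature set consumes exactly the two rank columns
  m <- fit_final(rows, "LR", model_config(seed = 1))
  shifted <- rows; shifted$ptcr_rank <- pmin(shifted$ptcr_rank + 10, 100)
  expect_false(identical(predict(m, rows), predict(m, shifted)))
})

test_that("evaluate_report computes AUC, CI and operating-point metrics", {
  rows <- toy_features(n_pos = 50, n_neg = 250, seed = 8)
  m <- fit_final(rows, "LR", model_config(seed = 2))
  rep <- evaluate_report(m, rows, n_boot = 200, boot_seed = 4)
  expect_s3_class(rep, "evaluation_report")
  expect_lte(rep$auc_ci_low, rep$auc)
  expect_gte(rep$auc_ci_high, rep$auc)
  ops <- rep$operating_points
  expect_equal(ops$tp + ops$fp + ops$fn + ops$tn, rep(nrow(rows), nrow(ops)))
  # calibration data: realized specificity strictly above each target
  expect_true(all(ops$specificity > ops$target_specificity))
  # null-data AUC is ~0.5 (permuted labels, n = 2000)
  null_rows <- neoprior:::with_seed(99, data.frame(
    phla_rank = runif(2000, 0, 100), ptcr_rank = runif(2000, 0, 100),
    label = sample(rep(c("immunogenic", "non_immunogenic"), 1000))
  ))
  mn <- fit_final(rows, "LR", model_config(seed = 2))
  expect_lt(abs(auc_score(predict(mn, null_rows), null_rows$label) - 0.5), 0.03)
})

test_that("pearson_chisq matches chisq.test without continuity correction", {
  # spec's toy table: correct Pearson value is 15.42857 (not the spec's 15.0)
  tab <- matrix(c(20, 5, 10, 25), 2)
  res <- pearson_chisq(tab)
  expect_equal(res$statistic, 15.42857, tolerance = 1e-5)
  expect_equal(res$statistic, oracle_chisq(tab), tolerance = 1e-9)
  expect_equal(res$df, 1)
  set.seed(303)
  for (i in 1:100) {
    t2 <- matrix(rpois(4, 30) + 1, 2)
    expect_lt(abs(pearson_chisq(t2)$statistic - oracle_chisq(t2)), 1e-9)
  }
  expect_error(pearson_chisq(matrix(c(0, 0, 1, 2), 2)), "degenerate")
})

test_that("quadrant_analysis assigns quadrants and reports rule metrics", {
  rows <- data.frame(
    phla_rank = c(1.0, 1.5, 1.2, 3.0, 5.0),
    ptcr_rank = c(1.5, 3.0, 1.8, 1.0, 5.0),
    label = c("immunogenic", "immunogenic", "non_immunogenic",
              "non_immunogenic", "non_immunogenic")
  )
  q <- quadrant_analysis(rows, cutoff = 2.0)
  counts <- q$quadrant_counts
  expect_equal(sum(counts["Q1", ]), 2)   # rows 1 and 3
  expect_equal(sum(counts["Q2", ]), 1)   # row 2: pHLA binder only
  expect_equal(sum(counts["Q4", ]), 1)   # row 4: pTCR binder only
  expect_equal(sum(counts["Q3", ]), 1)
  rm <- q$rule_metrics
  expect_equal(rm$ppv[rm$rule == "Q1"], 0.5)
  # all features at/above cutoff -> empty Q1, PPV undefined (NA)
  far <- rows; far$phla_rank <- far$phla_rank + 10; far$ptcr_rank <- far$ptcr_rank + 10
  q2 <- quadrant_analysis(far, cutoff = 2.0)
  expect_true(is.na(q2$rule_metrics$ppv[q2$rule_metrics$rule == "Q1"]))
  expect_error(quadrant_analysis(rows, cutoff = 0), "\\(0, 100\\)")
})

test_that("tree ensembles separate separable data and respect seeds", {
  set.seed(61)
  X <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  y <- as.integer(X[, 1] + X[, 2] < 80)
  rf <- neoprior:::fit_rf(X, y, n_trees = 30, seed = 5)
  expect_gt(auc_score(neoprior:::predict_np_rf(rf, X), y), 0.95)
  gbt <- neoprior:::with_seed(5, neoprior:::fit_gbt(X, y, n_rounds = 40))
  expect_gt(auc_score(neoprior:::predict_np_gbt(gbt, X), y), 0.95)
  rf2 <- neoprior:::fit_rf(X, y, n_trees = 30, seed = 5)
  expect_identical(neoprior:::predict_np_rf(rf, X),
                   neoprior:::predict_np_rf(rf2, X))
})
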