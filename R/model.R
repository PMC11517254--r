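#' Model configuration for the combined immunogenicity classifier
#'
#' @param algorithms candidate algorithms, a subset of `"LR"` (logistic
#'   regression), `"RF"` (random forest), `"XGB"` (gradient boosting).
#' @param cv_folds number of stratified cross-validation folds (default 10).
#' @param feature_set `"combined"` (both percentile ranks), `"phla_only"`,
#'   or `"ptcr_only"`.
#' @param specificity_targets operating-point specificities (default
#'   `c(0.95, 0.99)`; the alternative pair `c(0.90, 0.95)` is equally valid
#'   and can be passed here).
#' @param seed RNG seed for fold assignment and ensemble fitting.
#' @return A list of class `model_config`.
#' @export
model_config <- function(algorithms = c("LR", "RF", "XGB"),
                         cv_folds = 10L,
                         feature_set = c("combined", "phla_only", "ptcr_only"),
                         specificity_targets = c(0.95, 0.99),
                         seed = 1L) {
  feature_set <- match.arg(feature_set)
  algorithms <- match.arg(algorithms, c("LR", "RF", "XGB"), several.ok = TRUE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  if (any(specificity_targets <= 0 | specificity_targets >= 1)) {
    stop("specificity targets must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    algorithms = algorithms, cv_folds = as.integer(cv_folds),
    feature_set = feature_set, specificity_targets = specificity_targets,
    seed = as.integer(seed)
  ), class = "model_config")
}

feature_matrix <- function(rows, feature_set) {
  switch(feature_set,
    combined = cbind(phla_rank = rows$phla_rank, ptcr_rank = rows$ptcr_rank),
    phla_only = cbind(phla_rank = rows$phla_rank),
    ptcr_only = cbind(ptcr_rank = rows$ptcr_rank)
  )
}

label_vector <- function(rows) {
  if (!all(rows$label %in% LABELS)) {
    stop("rows must carry immunogenic/non_immunogenic labels", call. = FALSE)
  }
  as.integer(rows$label == "immunogenic")
}

fit_algorithm <- function(X, y, algorithm, seed) {
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to fit", call. = FALSE)
  }
  switch(algorithm,
    LR = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X), y, family = stats::binomial())
      )
      list(kind = "LR", coef = fit$coefficients)
    },
    RF = list(kind = "RF", model = fit_rf(X, y, seed = seed)),
    XGB = list(kind = "XGB", model = with_seed(seed, fit_gbt(X, y)))
  )
}

score_algorithm <- function(fit, X) {
  switch(fit$kind,
    LR = as.vector(1 / (1 + exp(-(cbind(1, X) %*% fit$coef)))),
    RF = predict_np_rf(fit$model, X),
    XGB = predict_np_gbt(fit$model, X)
  )
}

# Stratified fold assignment (1..k per row), seeded.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop("class with fewer members than folds; cannot stratify",
             call. = FALSE)
      }
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Cross-validated algorithm selection
#'
#' Runs stratified k-fold cross-validation on the discovery feature rows
#' for every configured algorithm, scores each fold by ROC AUC, and
#' selects the algorithm with the highest mean fold AUC. Ties break by the
#' fixed precedence XGB, RF, LR.
#'
#' @param rows a labeled feature table ([build_feature_table()] output or
#'   any data.frame with `phla_rank`, `ptcr_rank`, `label`).
#' @param config a [model_config()].
#' @return List with `cv_table` (algorithm, mean_auc, sd_auc, fold AUCs)
#'   and `selected`.
#' @export
cross_validate_select <- function(rows, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  X <- feature_matrix(rows, config$feature_set)
  y <- label_vector(rows)
  if (nrow(X) < config$cv_folds) stop("fewer rows than folds", call. = FALSE)
  folds <- stratified_folds(y, config$cv_folds, config$seed)
  fold_auc <- sapply(config$algorithms, function(alg) {
    vapply(seq_len(config$cv_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[!tr])) < 2L) {
        stop("fold ", f, " lacks a class; increase data or reduce folds",
             call. = FALSE)
      }
      fit <- fit_algorithm(X[tr, , drop = FALSE], y[tr], alg,
                           seed = config$seed + f)
      auc_score(score_algorithm(fit, X[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
  })
  fold_auc <- matrix(fold_auc, nrow = config$cv_folds,
                     dimnames = list(NULL, config$algorithms))
  mean_auc <- colMeans(fold_auc)
  precedence <- c("XGB", "RF", "LR")
  cand <- names(mean_auc)[mean_auc >= max(mean_auc) - 1e-12]
  selected <- precedence[precedence %in% cand][1]
  list(
    cv_table = data.frame(
      algorithm = names(mean_auc),
      mean_auc = as.numeric(mean_auc),
      sd_auc = apply(fold_auc, 2, stats::sd),
      row.names = NULL
    ),
    fold_auc = fold_auc,
    selected = selected
  )
}

#' Fit the final classifier and calibrate operating points
#'
#' Fits the chosen algorithm on the full discovery set, then fixes one
#' score cutoff per configured specificity target on the discovery scores
#' (classification rule: predicted immunogenic iff score >= cutoff).
#'
#' @param rows labeled discovery feature rows.
#' @param algorithm `"LR"`, `"RF"` or `"XGB"`; typically
#'   `cross_validate_select()$selected`.
#' @param config a [model_config()].
#' @param cv_mean_auc optional mean CV AUC to store alongside the model.
#' @return An object of class `trained_classifier`.
#' @export
fit_final <- function(rows, algorithm, config = model_config(),
                      cv_mean_auc = NA_real_) {
  stopifnot(inherits(config, "model_config"))
  X <- feature_matrix(rows, config$feature_set)
  y <- label_vector(rows)
  fit <- fit_algorithm(X, y, algorithm, seed = config$seed)
  scores <- score_algorithm(fit, X)
  thresholds <- vapply(config$specificity_targets, function(t) {
    threshold_at_specificity(scores, y, t)
  }, numeric(1))
  names(thresholds) <- sprintf("spec_%g", config$specificity_targets)
  structure(list(
    algorithm = algorithm, feature_set = config$feature_set,
    fit = fit, thresholds = thresholds,
    specificity_targets = config$specificity_targets,
    cv_mean_auc = cv_mean_auc, seed = config$seed
  ), class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf(
    "<trained_classifier> %s on %s features; thresholds: %s\n",
    x$algorithm, x$feature_set,
    paste(sprintf("%s=%.4g", names(x$thresholds), x$thresholds),
          collapse = ", ")
  ))
  invisible(x)
}

#' Score feature rows with a trained classifier
#'
#' @param object a `trained_classifier`.
#' @param rows feature rows (same schema as training).
#' @param ... unused.
#' @return Numeric scores in `[0, 1]`; higher = more immunogenic.
#' @export
predict.trained_classifier <- function(object, rows, ...) {
  score_algorithm(object$fit, feature_matrix(rows, object$feature_set))
}

#' Score cutoff achieving a target specificity
#'
#' Returns the smallest observed score value such that the rule
#' "predicted immunogenic iff score >= cutoff" attains specificity
#' strictly exceeding `target` on the given data. `target = 0` returns the
#' minimum observed score. When no cutoff reaches the target (e.g. all
#' scores tie), returns `Inf` with a warning: the operating point then has
#' sensitivity 0.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 vector (1 = immunogenic) or label strings.
#' @param target specificity target in `[0, 1)`.
#' @return A score cutoff.
#' @export
threshold_at_specificity <- function(scores, labels, target) {
  y <- coerce_binary(labels)
  neg <- scores[y == 0]
  if (length(neg) == 0L) stop("no negatives to calibrate on", call. = FALSE)
  if (target <= 0) return(min(scores))
  cand <- sort(unique(scores))
  # specificity at cutoff c = fraction of negatives strictly below c
  spec <- vapply(cand, function(c) mean(neg < c), numeric(1))
  ok <- spec > target
  if (!any(ok)) {
    warning("specificity target ", target,
            " unreachable; returning +Inf sentinel (sensitivity 0)")
    return(Inf)
  }
  cand[which(ok)[1]]
}

coerce_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "immunogenic")
  } else {
    as.integer(labels)
  }
}

#' ROC AUC by the rank statistic
#'
#' Mann-Whitney formulation with average ranks, so tied scores earn 0.5
#' concordance credit.
#'
#' @param scores numeric scores, higher = more immunogenic.
#' @param labels 0/1 or label strings.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- coerce_binary(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both classes", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a trained classifier
#'
#' Computes ROC AUC with a stratified-bootstrap confidence interval and,
#' at every stored fixed-specificity threshold, the realized sensitivity,
#' specificity, PPV, NPV and confusion counts.
#'
#' @param model a `trained_classifier`.
#' @param rows labeled feature rows to evaluate on.
#' @param n_boot bootstrap resamples for the AUC CI (default 2000).
#' @param conf confidence level (default 0.95).
#' @param boot_seed seed for the bootstrap.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_report <- function(model, rows, n_boot = 2000L, conf = 0.95,
                            boot_seed = 1L) {
  stopifnot(inherits(model, "trained_classifier"))
  scores <- stats::predict(model, rows)
  y <- label_vector(rows)
  auc <- auc_score(scores, y)
  pos_i <- which(y == 1); neg_i <- which(y == 0)
  boot <- with_seed(boot_seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- c(sample(pos_i, replace = TRUE), sample(neg_i, replace = TRUE))
      auc_score(scores[i], y[i])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  ops <- lapply(seq_along(model$thresholds), function(i) {
    thr <- model$thresholds[i]
    pred <- scores >= thr
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
    data.frame(
      operating_point = names(model$thresholds)[i],
      target_specificity = model$specificity_targets[i],
      cutoff = unname(thr),
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
      tp = tp, fp = fp, fn = fn, tn = tn
    )
  })
  structure(list(
    auc = auc, auc_ci_low = min(ci[1], auc), auc_ci_high = max(ci[2], auc),
    conf = conf, n = length(y),
    operating_points = do.call(rbind, ops)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d AUC %.3f (%g%% CI %.3f-%.3f)\n",
              x$n, x$auc, 100 * x$conf, x$auc_ci_low, x$auc_ci_high))
  print(x$operating_points, row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square test of a contingency table
#'
#' Plain Pearson statistic without continuity correction,
#' \eqn{\sum (O-E)^2/E}, with the asymptotic chi-square p-value.
#'
#' @param tab contingency table (matrix of counts).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) stop("degenerate margin in contingency table",
                               call. = FALSE)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fixed-cutoff quadrant analysis of the two binding ranks
#'
#' Splits labeled feature rows into four groups at a fixed percentile
#' cutoff (default 2, the conventional binder threshold): Q1 = both ranks
#' below cutoff, Q2 = pHLA rank only, Q4 = pHLA-TCR rank only, Q3 =
#' neither (the Q2/Q4 naming of the single-binder groups is a package
#' convention, stated in the output). Reports per-quadrant label counts,
#' PPV/sensitivity/specificity for the three binder rules (pHLA binder,
#' pHLA-TCR binder, Q1), and a 2x2 Pearson chi-square of binder status
#' against label for each feature.
#'
#' @param rows labeled feature rows.
#' @param cutoff percentile cutoff in (0, 100); default 2.
#' @return List of class `quadrant_report`: `cutoff`, `quadrant_counts`,
#'   `rule_metrics`, `chisq_phla`, `chisq_ptcr`. Metrics on an empty
#'   group are `NA` (undefined), never silent zeros.
#' @export
quadrant_analysis <- function(rows, cutoff = 2.0) {
  if (cutoff <= 0 || cutoff >= 100) stop("cutoff must be in (0, 100)",
                                         call. = FALSE)
  y <- label_vector(rows)
  phla_b <- rows$phla_rank < cutoff
  ptcr_b <- rows$ptcr_rank < cutoff
  quadrant <- ifelse(phla_b & ptcr_b, "Q1",
              ifelse(phla_b, "Q2", ifelse(ptcr_b, "Q4", "Q3")))
  qc <- table(factor(quadrant, levels = c("Q1", "Q2", "Q3", "Q4")),
              factor(ifelse(y == 1, "immunogenic", "non_immunogenic"),
                     levels = LABELS))
  rule_metrics <- do.call(rbind, lapply(
    list(phla_binder = phla_b, ptcr_binder = ptcr_b, Q1 = phla_b & ptcr_b),
    function(pred) {
      tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
      fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
      data.frame(
        ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
        n_called = tp + fp
      )
    }
  ))
  rule_metrics <- cbind(rule = rownames(rule_metrics), rule_metrics)
  rownames(rule_metrics) <- NULL
  chisq_for <- function(binder) {
    tab <- table(factor(binder, levels = c(TRUE, FALSE)),
                 factor(y, levels = c(1, 0)))
    # a degenerate margin (e.g. no binders at all) makes the test undefined
    tryCatch(pearson_chisq(tab),
             error = function(e) list(statistic = NA_real_, df = 1L,
                                      p_value = NA_real_))
  }
  structure(list(
    cutoff = cutoff,
    quadrant_counts = qc,
    rule_metrics = rule_metrics,
    chisq_phla = chisq_for(phla_b),
    chisq_ptcr = chisq_for(ptcr_b)
  ), class = "quadrant_report")
}

#' @export
print.quadrant_report <- function(x, ...) {
  cat(sprintf("<quadrant_report> cutoff %g%% (Q1 both<cutoff, Q2 pHLA only, Q4 pHLA-TCR only, Q3 neither)\n",
              x$cutoff))
  print(x$quadrant_counts)
  print(x$rule_metrics, row.names = FALSE)
  if (!is.na(x$chisq_phla$statistic)) {
    cat(sprintf("chi-square (pHLA binder x label): %.4f, p=%.3g\n",
                x$chisq_phla$statistic, x$chisq_phla$p_value))
  }
  if (!is.na(x$chisq_ptcr$statistic)) {
    cat(sprintf("chi-square (pHLA-TCR binder x label): %.4f, p=%.3g\n",
                x$chisq_ptcr$statistic, x$chisq_ptcr$p_value))
  }
  invisible(x)
}
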