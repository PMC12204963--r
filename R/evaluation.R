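# Diagnostic accuracy statistics: one-vs-rest confusion counts, sensitivity /
# specificity / accuracy / PPV / NPV, balanced-accuracy AUC, binomial CIs,
# and chi-square subgroup comparisons.

#' One-vs-rest confusion counts per class
#'
#' @param predicted,truth Equal-length label vectors over `classes`.
#' @param classes Class set (defaults to the four contrast phases).
#' @return A `class_counts` tibble with per-class `tp`, `fn`, `fp`, `tn`;
#'   the full confusion matrix is attached as attribute `"confusion"`.
#' @export
confusion_from_predictions <- function(predicted, truth, classes = PHASES4) {
  assert_that(length(predicted) == length(truth) && length(truth) > 0,
              "predicted and truth must be equal-length, non-empty")
  bad <- setdiff(unique(c(predicted, truth)), classes)
  assert_that(length(bad) == 0,
              paste0("unknown labels: ", paste(bad, collapse = ", ")))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  total <- length(truth)
  counts <- tibble(
    class = classes,
    tp = map_dbl(classes, function(cl) cm[cl, cl]),
    fn = map_dbl(classes, function(cl) sum(cm[cl, ]) - cm[cl, cl]),
    fp = map_dbl(classes, function(cl) sum(cm[, cl]) - cm[cl, cl]),
    tn = map_dbl(classes, function(cl) {
      total - sum(cm[cl, ]) - sum(cm[, cl]) + cm[cl, cl]
    })
  )
  structure(counts, class = c("class_counts", class(counts)), confusion = cm)
}

#' Diagnostic metrics from confusion counts
#'
#' Computes per-class sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/total`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)` (all in
#' percent) with two-sided 95% binomial CIs, and the AUC of the hard
#' (argmax) classifier as balanced accuracy `(sensitivity + specificity)/2`.
#' Zero-denominator metrics are reported as `NA` (undefined), never as 0.
#'
#' @param counts A `class_counts` tibble (or any data frame with columns
#'   `class`, `tp`, `fn`, `fp`, `tn`).
#' @param ci_method CI method for the rate CIs, see [proportion_ci()].
#' @param digits If not `NULL`, round half-up: percents to `digits[1]`
#'   decimals and AUC to `digits[2]` (report formatting: `c(1, 3)`).
#' @return A `metrics_report` tibble, one row per class; overall accuracy
#'   (total agreement percent) as attribute `"overall_accuracy"` and in
#'   [glance()].
#' @export
metrics_from_counts <- function(counts, ci_method = "wilson", digits = NULL) {
  assert_that(all(c("class", "tp", "fn", "fp", "tn") %in% names(counts)),
              "counts needs columns class, tp, fn, fp, tn")
  assert_that(all(counts$tp >= 0 & counts$fn >= 0 & counts$fp >= 0 & counts$tn >= 0),
              "counts must be non-negative")
  rate <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  ci <- function(num, den) {
    map2(num, den, function(s, n) {
      if (n > 0) proportion_ci(s, n, ci_method) else c(NA_real_, NA_real_)
    })
  }
  total <- counts$tp + counts$fn + counts$fp + counts$tn
  out <- tibble(
    class = counts$class,
    sensitivity = rate(counts$tp, counts$tp + counts$fn),
    specificity = rate(counts$tn, counts$tn + counts$fp),
    accuracy = rate(counts$tp + counts$tn, total),
    ppv = rate(counts$tp, counts$tp + counts$fp),
    npv = rate(counts$tn, counts$tn + counts$fn)
  )
  out$auc <- (out$sensitivity + out$specificity) / 200
  cis <- list(
    sensitivity = ci(counts$tp, counts$tp + counts$fn),
    specificity = ci(counts$tn, counts$tn + counts$fp),
    accuracy = ci(counts$tp + counts$tn, total),
    ppv = ci(counts$tp, counts$tp + counts$fp),
    npv = ci(counts$tn, counts$tn + counts$fn)
  )
  for (m in names(cis)) {
    out[[paste0(m, "_low")]] <- map_dbl(cis[[m]], 1)
    out[[paste0(m, "_high")]] <- map_dbl(cis[[m]], 2)
  }
  if (!is.null(digits)) {
    pct_cols <- setdiff(names(out), c("class", "auc"))
    out <- mutate(out,
                  across(all_of(pct_cols), function(x) round_half_up(x, digits[1])),
                  auc = round_half_up(.data$auc, digits[2]))
  }
  overall <- 100 * sum(counts$tp) / total[1]
  if (!is.null(digits)) overall <- round_half_up(overall, digits[1])
  structure(out, class = c("metrics_report", class(out)),
            overall_accuracy = overall, ci_method = ci_method)
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble(overall_accuracy = attr(x, "overall_accuracy"),
         ci_method = attr(x, "ci_method"))
}

#' Two-sided 95% binomial proportion interval
#'
#' Wilson score interval (closed form) by default; Clopper-Pearson (exact,
#' via the beta quantile) optionally.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @param conf Confidence level.
#' @return `c(low, high)` in percent.
#' @export
proportion_ci <- function(successes, n, method = c("wilson", "clopper-pearson"),
                          conf = 0.95) {
  method <- match.arg(method)
  assert_that(is_count(successes) && is_count(n) && n > 0 && successes <= n,
              "need 0 <= successes <= n with n > 0")
  p <- successes / n
  if (method == "wilson") {
    z <- qnorm(1 - (1 - conf) / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    out <- c(centre - half, centre + half)
  } else {
    lo <- if (successes == 0) 0 else qbeta((1 - conf) / 2, successes, n - successes + 1)
    hi <- if (successes == n) 1 else qbeta(1 - (1 - conf) / 2, successes + 1, n - successes)
    out <- c(lo, hi)
  }
  100 * pmin(pmax(out, 0), 1)
}

#' Chi-square subgroup comparison with Bonferroni adjustment
#'
#' Pearson chi-square test of association on a contingency table, with the
#' p-value Bonferroni-adjusted for `n_comparisons` inter-group comparisons
#' (`p_adj = min(1, p * n_comparisons)`).
#'
#' @param tab Contingency table (matrix, >= 2x2, non-negative counts).
#' @param n_comparisons Number of comparisons in the family.
#' @param correct Continuity correction (off by default, matching the plain
#'   Pearson statistic).
#' @return Tibble with `statistic`, `df`, `p_value`, `p_adjusted`.
#' @export
chi_square_subgroups <- function(tab, n_comparisons = 1L, correct = FALSE) {
  tab <- as.matrix(tab)
  assert_that(all(tab >= 0), "table entries must be non-negative")
  assert_that(nrow(tab) >= 2 && ncol(tab) >= 2, "table must be at least 2x2")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  assert_that(all(expected > 0),
              "zero expected cell count: merge or drop degenerate subgroups")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value),
         p_adjusted = min(1, unname(ct$p.value) * n_comparisons))
}

#' Score-based ROC AUC (cross-check)
#'
#' Rank-based AUC of continuous scores against a binary truth, via pROC when
#' available. This is the probability-score counterpart of the hard-label
#' balanced-accuracy AUC reported by [metrics_from_counts()].
#'
#' @param truth_positive Logical vector (is the true class the positive
#'   class).
#' @param scores Predicted probability of the positive class.
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(truth_positive, scores) {
  assert_that(length(truth_positive) == length(scores), "length mismatch")
  if (requireNamespace("pROC", quietly = TRUE)) {
    as.numeric(pROC::auc(pROC::roc(truth_positive, scores, quiet = TRUE,
                                   direction = "<")))
  } else {
    # Mann-Whitney fallback
    r <- rank(scores)
    n1 <- sum(truth_positive)
    n0 <- sum(!truth_positive)
    assert_that(n1 > 0 && n0 > 0, "need both classes present")
    (sum(r[truth_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
}

#' Compare one-step and two-step strategies on the same exams
#'
#' @param pred_one_step,pred_two_step Prediction tibbles (rows = phases) for
#'   the same examinations, with `true_phase` and a label column.
#' @param label_col Which label column to score (`"label_raw"` for
#'   phase-wise metrics, `"label_calibrated"` for exam-level).
#' @param ci_method,digits Passed to [metrics_from_counts()].
#' @return List with `one_step` and `two_step` `metrics_report`s and a
#'   tibble `overall` of phase-wise overall accuracies per strategy. No AUC
#'   difference test is computed.
#' @export
compare_strategies <- function(pred_one_step, pred_two_step,
                               label_col = "label_raw", ci_method = "wilson",
                               digits = NULL) {
  key <- function(p) paste(p$exam_id, p$phase_index)
  assert_that(setequal(key(pred_one_step), key(pred_two_step)),
              "strategy predictions must cover the same exams and phases")
  score <- function(pred) {
    counts <- confusion_from_predictions(pred[[label_col]], pred$true_phase)
    metrics_from_counts(counts, ci_method, digits)
  }
  m1 <- score(pred_one_step)
  m2 <- score(pred_two_step)
  list(one_step = m1, two_step = m2,
       overall = tibble(strategy = c("one_step", "two_step"),
                        overall_accuracy = c(attr(m1, "overall_accuracy"),
                                             attr(m2, "overall_accuracy")),
                        n_phases = c(nrow(pred_one_step), nrow(pred_two_step))))
}

#' Published benchmark confusion counts
#'
#' Per-class one-vs-rest counts (TP/FN/FP/TN) of the multicentre benchmark
#' evaluation of this classification approach: internal test set (288
#' phases) under both strategies, and external test set (645 phases) under
#' the two-step strategy. Used as a regression fixture for the metric
#' formulas.
#'
#' @return Tibble with columns `cohort`, `strategy`, `class`, `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
benchmark_counts <- function() {
  path <- system.file("extdata", "benchmark_counts.csv", package = "ctphase")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
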