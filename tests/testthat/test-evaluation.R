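test_that("one-vs-rest confusion counts conserve totals", {
  truths <- rep(PHASES4, each = 2)
  perfect <- confusion_from_predictions(truths, truths)
  expect_equal(perfect$tp, rep(2, 4))
  expect_equal(perfect$fp, rep(0, 4))
  expect_equal(perfect$fn, rep(0, 4))
  expect_equal(perfect$tn, rep(6, 4))
  all_pvp <- confusion_from_predictions(rep("PVP", 8), truths)
  row <- all_pvp[all_pvp$class == "PVP", ]
  expect_equal(row$fp, 8 - row$tp)
  # per-class totals all equal the number of phases scored
  expect_equal(unique(all_pvp$tp + all_pvp$fn + all_pvp$fp + all_pvp$tn), 8)
  # row/column sums of the attached confusion matrix match phase counts
  cm <- attr(all_pvp, "confusion")
  expect_equal(as.numeric(rowSums(cm)), rep(2, 4))
  expect_equal(sum(cm), 8)
  expect_error(confusion_from_predictions(c("EAP", "XX"), c("EAP", "DP")),
               "unknown")
})

test_that("metrics reproduce the published benchmark table cells", {
  bc <- benchmark_counts()
  internal1 <- metrics_from_counts(bc[bc$cohort == "internal" &
                                        bc$strategy == "one_step", ],
                                   digits = c(1, 3))
  lap <- internal1[internal1$class == "LAP", ]
  expect_equal(lap$sensitivity, 42.9)
  expect_equal(lap$specificity, 96.8)
  expect_equal(lap$accuracy, 95.5)
  expect_equal(lap$ppv, 25.0)
  expect_equal(lap$npv, 98.6)
  expect_equal(lap$auc, 0.698)
  external <- metrics_from_counts(bc[bc$cohort == "external", ],
                                  digits = c(1, 3))
  eap <- external[external$class == "EAP", ]
  expect_equal(eap$sensitivity, 95.1)
  expect_equal(eap$specificity, 99.8)
  expect_equal(eap$accuracy, 99.4)
  expect_equal(eap$ppv, 98.3)
  expect_equal(eap$npv, 99.5)
  expect_equal(eap$auc, 0.975)
  expect_equal(attr(external, "overall_accuracy"), 99.1)
})

test_that("undefined metrics are NA, never zero", {
  counts <- tibble::tibble(class = "EAP", tp = 0, fn = 0, fp = 3, tn = 5)
  m <- metrics_from_counts(counts)
  expect_true(is.na(m$sensitivity))
  expect_false(is.na(m$specificity))
})

test_that("Wilson intervals match the quadratic closed form; Clopper-Pearson hits the boundaries", {
  # independent oracle: solve (p - c)^2 = z^2 c (1 - c) / n for the interval
  wilson_oracle <- function(s, n, conf = 0.95) {
    z <- qnorm(1 - (1 - conf) / 2)
    p <- s / n
    a <- 1 + z^2 / n
    b <- -(2 * p + z^2 / n)
    cc <- p^2
    100 * sort(Re(polyroot(c(cc, b, a))))
  }
  for (case in list(c(58, 61), c(3, 7), c(214, 215), c(1, 10))) {
    expect_equal(proportion_ci(case[1], case[2], "wilson"),
                 wilson_oracle(case[1], case[2]), tolerance = 1e-8)
  }
  cp_full <- proportion_ci(20, 20, "clopper-pearson")
  expect_equal(cp_full[2], 100)
  expect_equal(proportion_ci(0, 15, "clopper-pearson")[1], 0)
  # low <= point estimate <= high
  ci <- proportion_ci(7, 30)
  expect_lte(ci[1], 100 * 7 / 30)
  expect_gte(ci[2], 100 * 7 / 30)
  expect_error(proportion_ci(5, 0), "n > 0")
})

test_that("chi-square subgroup tests match the textbook formula with Bonferroni clamp", {
  flat <- matrix(c(10, 10, 10, 10), 2, 2)
  res <- chi_square_subgroups(flat, n_comparisons = 4)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$p_adjusted, 1)
  tab <- matrix(c(30, 10, 15, 25), 2, 2)
  # textbook Pearson statistic computed from expected counts
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  res2 <- chi_square_subgroups(tab, n_comparisons = 6)
  expect_equal(res2$statistic, stat)
  expect_lte(res2$p_adjusted, 1)
  expect_equal(res2$p_adjusted, min(1, res2$p_value * 6))
  degenerate <- matrix(c(0, 0, 5, 5), 2, 2)
  expect_error(chi_square_subgroups(degenerate), "expected")
})

test_that("hard-label AUC equals balanced accuracy and tracks the score AUC cross-check", {
  counts <- tibble::tibble(class = "EAP", tp = 80, fn = 9, fp = 4, tn = 195)
  m <- metrics_from_counts(counts)
  expect_equal(m$auc, (m$sensitivity / 100 + m$specificity / 100) / 2)
  # a perfectly separating score gives AUC 1 by the rank-based cross-check
  truth <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(score_auc(truth, c(6:10, 1:5) / 10), 1)
  expect_equal(score_auc(truth, rep(0.5, 10)), 0.5)
})

test_that("strategy comparison scores both strategies on identical exams", {
  truths <- rep(PHASES4, each = 3)
  pred1 <- tibble::tibble(exam_id = "e", phase_index = seq_along(truths),
                          true_phase = truths, label_raw = truths)
  pred1$label_raw[1] <- "DP"   # one EAP miss for the one-step arm
  pred2 <- tibble::tibble(exam_id = "e", phase_index = seq_along(truths),
                          true_phase = truths, label_raw = truths)
  cmp <- compare_strategies(pred1, pred2, digits = c(1, 3))
  expect_equal(cmp$overall$overall_accuracy,
               round_half_up(100 * c(11 / 12, 12 / 12), 1))
  # identical predictions give identical reports
  cmp2 <- compare_strategies(pred2, pred2)
  expect_identical(as.data.frame(cmp2$one_step), as.data.frame(cmp2$two_step))
  expect_error(compare_strategies(pred1[-1, ], pred2, digits = NULL),
               "same exams")
})
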