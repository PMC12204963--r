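test_that("compose_four_dim applies the product rule and conserves probability", {
  expect_equal(compose_four_dim(c(0.8, 0.1, 0.1), c(0.75, 0.25)),
               c(EAP = 0.6, LAP = 0.2, PVP = 0.1, DP = 0.1))
  expect_equal(compose_four_dim(c(0, 0.4, 0.6)),
               c(EAP = 0, LAP = 0, PVP = 0.4, DP = 0.6))
  # degenerate split puts the whole AP mass on EAP
  expect_equal(compose_four_dim(c(0.5, 0.3, 0.2), c(1, 0))[["EAP"]], 0.5)
  # unsplit AP mass conventions
  expect_equal(sum(compose_four_dim(c(0.3, 0.3, 0.4))), 1)
  expect_equal(compose_four_dim(c(0.5, 0.25, 0.25), NULL, "renormalize"),
               c(EAP = 0, LAP = 0, PVP = 0.5, DP = 0.5))
  set.seed(3)
  for (rep in 1:20) {
    s1 <- softmax_vec(rnorm(3))
    s2 <- softmax_vec(rnorm(2))
    expect_equal(sum(compose_four_dim(s1, s2)), 1, tolerance = 1e-12)
  }
  expect_error(compose_four_dim(c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(compose_four_dim(c(0.5, 0.3, 0.2), c(0.7, 0.2)), "summing to 1")
})

test_that("the second step runs iff step 1 flags an arterial phase, once per AP phase", {
  ex <- small_exam(c("LAP", "PVP", "DP"), seed = 2)
  calls <- new.env()
  calls$n <- 0L
  counting2 <- function(exam) {
    calls$n <- calls$n + 1L
    matrix(c(0.2, 0.8), length(exam$phases), 2, byrow = TRUE)
  }
  no_ap <- function(exam) {
    matrix(rep(c(0.05, 0.55, 0.40), length(exam$phases)),
           ncol = 3, byrow = TRUE)
  }
  pr <- predict_two_step(ex, no_ap, counting2, calibrate = FALSE)
  expect_equal(calls$n, 0L)
  expect_equal(attr(pr, "step2_invocations"), 0L)

  one_ap <- function(exam) {
    rows <- rbind(c(0.9, 0.05, 0.05),
                  c(0.1, 0.8, 0.1),
                  c(0.05, 0.15, 0.8))
    rows[seq_len(length(exam$phases)), , drop = FALSE]
  }
  pr2 <- predict_two_step(ex, one_ap, counting2, calibrate = FALSE)
  expect_equal(calls$n, 1L)
  expect_equal(attr(pr2, "step2_invocations"), 1L)
  expect_equal(pr2$label_raw, c("LAP", "PVP", "DP"))
  # assembled 4-vectors sum to 1
  totals <- pr2$p_EAP + pr2$p_LAP + pr2$p_PVP + pr2$p_DP
  expect_equal(totals, rep(1, 3), tolerance = 1e-9)
  # cascade composition: AP mass split by the step-2 vector
  expect_equal(pr2$p_EAP[1], 0.9 * 0.2)
  expect_equal(pr2$p_LAP[1], 0.9 * 0.8)
})

test_that("one-step prediction takes the 4-class argmax with canonical tie-break", {
  ex <- small_exam(c("EAP", "PVP"), seed = 3)
  m4 <- function(exam) {
    rbind(c(0.7, 0.1, 0.1, 0.1),
          c(0.25, 0.25, 0.25, 0.25))[seq_len(length(exam$phases)), ,
                                     drop = FALSE]
  }
  pr <- predict_one_step(ex, m4, calibrate = FALSE)
  expect_equal(pr$label_raw[1], "EAP")
  # uniform vector ties break to the first canonical class
  expect_equal(pr$label_raw[2], "EAP")
  expect_equal(pr$strategy, rep("one_step", 2))
})

test_that("calibrate_order maximizes the joint over distinct step-1 assignments", {
  ex <- small_exam(c("LAP", "PVP", "DP"), seed = 4)
  m3 <- function(exam) rbind(c(0.3, 0.6, 0.1),
                             c(0.1, 0.7, 0.2),
                             c(0.0, 0.3, 0.7))
  m2 <- function(exam) matrix(c(1, 0), 1, 2)
  raw <- predict_two_step(ex, m3, m2, calibrate = FALSE)
  expect_equal(as_step1(raw$label_raw), c("PVP", "PVP", "DP"))
  cal <- calibrate_order(raw, order_known = FALSE)
  expect_equal(as_step1(cal$label_calibrated), c("AP", "PVP", "DP"))
  expect_equal(cal$relative_order, 1:3)
  # the chosen assignment attains the brute-force maximum joint probability
  p1 <- cbind(AP = raw$p_EAP + raw$p_LAP, PVP = raw$p_PVP, DP = raw$p_DP)
  joints <- vapply(arrangements(PHASES_STEP1, 3), function(a) {
    prod(p1[cbind(1:3, match(a, PHASES_STEP1))])
  }, 0)
  expect_equal(max(joints), 0.3 * 0.7 * 0.7, tolerance = 1e-9)
  chosen <- prod(p1[cbind(1:3, match(as_step1(cal$label_calibrated),
                                     PHASES_STEP1))])
  expect_equal(chosen, max(joints))
})

test_that("calibration is a no-op when argmax labels are already distinct", {
  ex <- small_exam(c("EAP", "PVP", "DP"), seed = 5)
  m4 <- function(exam) rbind(c(0.6, 0.1, 0.2, 0.1),
                             c(0.05, 0.05, 0.7, 0.2),
                             c(0.05, 0.05, 0.2, 0.7))
  pr <- predict_one_step(ex, m4, calibrate = TRUE)
  expect_equal(pr$label_calibrated, pr$label_raw)
})

test_that("calibration searches ordered pairs on 2-phase exams and respects known order", {
  ex <- small_exam(c("PVP", "DP"), seed = 6)
  # both phases argmax-PVP; calibration must relabel one
  m3 <- function(exam) rbind(c(0.1, 0.6, 0.3),
                             c(0.1, 0.5, 0.4))
  m2 <- function(exam) matrix(c(1, 0), 1, 2)
  cal <- predict_two_step(ex, m3, m2, calibrate = TRUE)
  expect_equal(as_step1(cal$label_calibrated), c("PVP", "DP"))
  # with order known, an assignment violating acquisition order is excluded:
  # joint would prefer (DP earlier, PVP later) but timing forbids DP before PVP
  m3b <- function(exam) rbind(c(0.1, 0.3, 0.6),
                              c(0.1, 0.6, 0.3))
  calb <- predict_two_step(ex, m3b, m2, calibrate = TRUE)
  expect_equal(as_step1(calb$label_calibrated), c("PVP", "DP"))
})

test_that("calibrated exam labels are distinct at step-1 granularity (random probes)", {
  set.seed(11)
  ex <- small_exam(c("EAP", "PVP", "DP"), seed = 7)
  for (rep in 1:25) {
    rows <- t(vapply(1:3, function(i) softmax_vec(rnorm(4, sd = 2)),
                     numeric(4)))
    m4 <- function(exam) rows
    raw <- predict_one_step(ex, m4, calibrate = FALSE)
    cal <- calibrate_order(raw, order_known = FALSE)
    expect_false(anyDuplicated(as_step1(cal$label_calibrated)) > 0)
    # never worse than any other feasible distinct assignment
    p1 <- cbind(AP = rows[, 1] + rows[, 2], PVP = rows[, 3], DP = rows[, 4])
    joints <- vapply(arrangements(PHASES_STEP1, 3), function(a) {
      prod(p1[cbind(1:3, match(a, PHASES_STEP1))])
    }, 0)
    chosen <- prod(p1[cbind(1:3, match(as_step1(cal$label_calibrated),
                                       PHASES_STEP1))])
    expect_gte(chosen + 1e-12, max(joints))
  }
})
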