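test_that("phantom exams are built as requested and deterministic under seed", {
  spec <- phantom_spec()
  ex <- make_phantom_exam(spec, phase_labels = c("LAP", "PVP", "DP"),
                          rng_seed = 7)
  expect_length(ex$phases, 3)
  expect_equal(true_phases(ex), c("LAP", "PVP", "DP"))
  single <- make_phantom_exam(spec, phase_labels = "PVP", rng_seed = 1)
  expect_length(single$phases, 1)
  a <- make_phantom_exam(spec, phase_labels = c("EAP", "PVP"), rng_seed = 42)
  b <- make_phantom_exam(spec, phase_labels = c("EAP", "PVP"), rng_seed = 42)
  expect_identical(a$phases[[1]]$values, b$phases[[1]]$values)
  expect_identical(a$phases[[2]]$values, b$phases[[2]]$values)
  expect_error(make_phantom_exam(spec, phase_labels = c("EAP", "LAP")),
               "arterial")
  expect_error(make_phantom_exam(spec, phase_labels = character(0)),
               "between 1 and 3")
})

test_that("structure masks are mutually exclusive, non-empty and shared across phases", {
  spec <- phantom_spec()
  masks <- phantom_masks(spec, rng_seed = 3)
  overlap <- masks$artery + masks$portal_vein + masks$hepatic_vein +
    masks$parenchyma + masks$background
  expect_true(all(overlap == 1))
  expect_true(all(vapply(masks, sum, 0) > 0))
  # same seed -> same geometry, so all phases of one exam are co-registered
  expect_identical(masks, phantom_masks(spec, rng_seed = 3))
})

test_that("measure_enhancement recovers constructed deltas", {
  spec <- phantom_spec()
  masks <- phantom_masks(spec, rng_seed = 5)
  bl <- phantom_baseline(spec, rng_seed = 5, noise_sd = 0)
  same <- measure_enhancement(bl, bl, masks)
  expect_equal(same$delta, rep(0, 4))
  bumped <- bl
  bumped$values[masks$portal_vein] <- bumped$values[masks$portal_vein] + 100
  d <- measure_enhancement(bumped, bl, masks)
  expect_equal(d$delta[d$structure == "portal_vein"], 100)
  expect_equal(d$delta[d$structure != "portal_vein"], rep(0, 3))
  small <- phase_volume(array(0, c(8, 8, 8)))
  expect_error(measure_enhancement(small, bl, masks), "shape")
})

test_that("rule_label follows the annotation decision ladder", {
  expect_equal(rule_label(c(artery = 250, portal_vein = 5, hepatic_vein = 0,
                            parenchyma = 5)), "EAP")
  expect_equal(rule_label(c(artery = 200, portal_vein = 45, hepatic_vein = 5,
                            parenchyma = 20)), "LAP")
  pvp <- c(artery = 80, portal_vein = 100, hepatic_vein = 90, parenchyma = 50)
  dp <- c(artery = 80, portal_vein = 66, hepatic_vein = 81, parenchyma = 35)
  expect_equal(rule_label(pvp), "PVP")
  expect_equal(rule_label(dp, pvp_reference = pvp), "DP")
  expect_equal(rule_label(dp), "DP")  # absolute cut-offs agree here
  # same-exam reference demotes a weaker PVP-like volume to DP
  near_pvp <- c(artery = 80, portal_vein = 85, hepatic_vein = 70,
                parenchyma = 45)
  expect_equal(rule_label(near_pvp), "PVP")
  expect_equal(rule_label(near_pvp, pvp_reference = pvp), "DP")
  expect_error(rule_label(c(artery = 100, portal_vein = 10)), "missing")
})

test_that("round trip: generated phases are recovered by the rule labeller", {
  spec <- phantom_spec()
  sets <- list("EAP", "LAP", c("EAP", "PVP"), c("LAP", "PVP", "DP"),
               c("EAP", "PVP", "DP"), c("PVP", "DP"))
  for (seed in 1:6) {
    labels <- sets[[seed]]
    ex <- make_phantom_exam(spec, phase_labels = labels, rng_seed = seed * 17)
    lab <- rule_label_exam(ex, phantom_baseline(spec, seed * 17),
                           phantom_masks(spec, seed * 17))
    expect_equal(lab$rule_label, PHASES4[PHASES4 %in% labels])
  }
})

test_that("measured PVP deltas exceed DP deltas on every generated exam", {
  spec <- phantom_spec()
  for (seed in c(2, 9, 23)) {
    ex <- make_phantom_exam(spec, phase_labels = c("PVP", "DP"),
                            rng_seed = seed)
    lab <- rule_label_exam(ex, phantom_baseline(spec, seed),
                           phantom_masks(spec, seed))
    pvp <- lab[lab$rule_label == "PVP", ]
    dp <- lab[lab$rule_label == "DP", ]
    for (s in c("portal_vein", "hepatic_vein", "parenchyma")) {
      expect_gt(pvp[[s]], dp[[s]])
    }
  }
})

test_that("edge cases sit near the labelling decision boundaries", {
  spec <- phantom_spec()
  e1 <- make_edge_case("eap_portal_flash", spec, 3)
  m1 <- measure_enhancement(e1$phases[[1]], phantom_baseline(spec, 3),
                            phantom_masks(spec, 3))
  pv <- m1$delta[m1$structure == "portal_vein"]
  expect_gte(pv, 8)
  expect_lte(pv, 17)
  expect_equal(true_phases(e1)[1], "EAP")

  e2 <- make_edge_case("pvp_dp_flat", spec, 5)
  m2 <- rule_label_exam(e2, phantom_baseline(spec, 5), phantom_masks(spec, 5))
  expect_equal(abs(diff(m2$portal_vein)), 34, tolerance = 0.15)
  expect_lt(abs(diff(m2$hepatic_vein)), 15)

  e3 <- make_edge_case("lap_low_portal", spec, 9)
  m3 <- measure_enhancement(e3$phases[[1]], phantom_baseline(spec, 9),
                            phantom_masks(spec, 9))
  pv3 <- m3$delta[m3$structure == "portal_vein"]
  expect_gt(pv3, 25)
  expect_lt(pv3, 35)
  expect_equal(true_phases(e3)[1], "LAP")

  expect_error(make_edge_case("nope", spec, 1), "unknown")
})

test_that("profile invariants reject inconsistent enhancement orderings", {
  d <- enhancement_profile()$deltas
  d["DP", "portal_vein"] <- d["PVP", "portal_vein"] + 10
  expect_error(enhancement_profile(deltas = d), "PVP deltas")
})

test_that("simulate_cohort mixes compositions and edge cases deterministically", {
  spec <- phantom_spec()
  co <- simulate_cohort(6, spec, seed = 4, edge_case_fraction = 0.5,
                        phase_sets = list(c("arterial", "PVP", "DP"),
                                          c("arterial", "PVP")))
  expect_length(co, 6)
  co2 <- simulate_cohort(6, spec, seed = 4, edge_case_fraction = 0.5,
                         phase_sets = list(c("arterial", "PVP", "DP"),
                                           c("arterial", "PVP")))
  expect_identical(lapply(co, function(e) e$phases[[1]]$values),
                   lapply(co2, function(e) e$phases[[1]]$values))
})
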