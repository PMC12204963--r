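#' Phantom geometry specification
#'
#' Defines the grid and simplified abdominal geometry of the synthetic
#' phantom: an ellipsoidal liver containing three tubular vessels (hepatic
#' artery/aorta, portal vein, hepatic vein) surrounded by soft-tissue
#' background. Realism is not the goal; separability of the four contrast
#' phases under the annotation criteria is.
#'
#' @param grid Integer length-3 grid shape; every axis must be >= 16.
#' @param spacing Voxel spacing in mm.
#' @param liver_axes Ellipsoid semi-axes as fractions of the grid dimensions.
#' @param vessel_radius Named vessel radii in voxels
#'   (`artery`, `portal_vein`, `hepatic_vein`).
#' @param seed Integer seed used for geometry jitter when no explicit seed is
#'   given to a generator call.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32L, 32L, 32L), spacing = c(4, 4, 4),
                         liver_axes = c(0.40, 0.34, 0.30),
                         vessel_radius = c(artery = 1.6, portal_vein = 1.8,
                                           hepatic_vein = 1.6),
                         seed = 1L) {
  grid <- as.integer(grid)
  assert_that(length(grid) == 3 && all(grid >= 16),
              "grid shape must have 3 axes, each >= 16")
  assert_that(all(liver_axes > 0 & liver_axes < 0.5),
              "liver semi-axes must be fractions in (0, 0.5) of the grid")
  assert_that(all(vessel_radius > 0), "vessel radii must be positive")
  structure(
    list(grid = grid, spacing = as.numeric(spacing),
         liver_axes = liver_axes, vessel_radius = vessel_radius,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Per-phase, per-structure enhancement profile
#'
#' HU deltas over the unenhanced baseline for each contrast phase and
#' anatomical structure, with per-exam jitter SDs, voxel noise SD, and the
#' nominal post-injection timing window of each phase (seconds). The defaults
#' encode the qualitative annotation criteria: the arterial phases show strong
#' artery enhancement with the hepatic vein unenhanced (portal vein
#' unenhanced in EAP, moderately enhanced in LAP); PVP shows strong portal
#' vein, hepatic vein and parenchyma enhancement; in DP all three are less
#' enhanced than in PVP.
#'
#' @param deltas 5x4 numeric matrix (rows `unenhanced`, `EAP`, `LAP`, `PVP`,
#'   `DP`; columns `artery`, `portal_vein`, `hepatic_vein`, `parenchyma`) of
#'   mean HU deltas.
#' @param jitter_sd Matrix of the same shape (or a scalar) of per-exam SDs of
#'   the deltas, in HU.
#' @param noise_sd Additive per-voxel Gaussian noise SD in HU.
#' @param timing Named list of nominal post-injection windows in seconds.
#'
#' @return An object of class `enhancement_profile`.
#' @export
enhancement_profile <- function(deltas = NULL, jitter_sd = NULL, noise_sd = 5,
                                timing = list(unenhanced = c(0, 0),
                                              EAP = c(25, 35), LAP = c(35, 40),
                                              PVP = c(60, 75), DP = c(140, 155))) {
  phases <- c("unenhanced", PHASES4)
  if (is.null(deltas)) {
    deltas <- rbind(
      unenhanced = c(0,   0,   0,  0),
      EAP        = c(250, 5,   0,  5),
      LAP        = c(200, 45,  5,  20),
      PVP        = c(80,  100, 90, 50),
      DP         = c(50,  55,  50, 30)
    )
    colnames(deltas) <- STRUCTURES
  }
  assert_that(all(phases %in% rownames(deltas)) &&
                all(STRUCTURES %in% colnames(deltas)),
              "`deltas` needs rows unenhanced/EAP/LAP/PVP/DP and the four structure columns")
  deltas <- deltas[phases, STRUCTURES]
  if (is.null(jitter_sd)) {
    jitter_sd <- deltas * 0
    jitter_sd["EAP", ] <- c(10, 1.5, 1.5, 1.5)
    jitter_sd["LAP", ] <- c(10, 4, 1.5, 3)
    jitter_sd["PVP", ] <- c(8, 5, 5, 3)
    jitter_sd["DP", ]  <- c(8, 5, 5, 3)
  } else if (length(jitter_sd) == 1) {
    jitter_sd <- matrix(jitter_sd, nrow(deltas), ncol(deltas),
                        dimnames = dimnames(deltas))
  }
  jitter_sd <- jitter_sd[phases, STRUCTURES]
  # annotation-criteria ordering must hold for the mean profile
  assert_that(all(deltas["PVP", c("portal_vein", "hepatic_vein", "parenchyma")] >
                    deltas["DP", c("portal_vein", "hepatic_vein", "parenchyma")]),
              "PVP deltas must strictly exceed DP deltas for portal vein, hepatic vein and parenchyma")
  assert_that(deltas["EAP", "portal_vein"] < deltas["LAP", "portal_vein"],
              "EAP portal-vein delta must be below the LAP portal-vein delta")
  art <- deltas[, "artery"]
  assert_that(max(art) == max(art[c("EAP", "LAP")]),
              "artery enhancement must peak in the arterial phases")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(
    list(deltas = deltas, jitter_sd = jitter_sd, noise_sd = noise_sd,
         timing = timing),
    class = "enhancement_profile"
  )
}

#' Structure masks of a phantom
#'
#' Builds the mutually exclusive boolean masks (artery, portal vein, hepatic
#' vein, parenchyma, background) for a phantom geometry. A small seeded jitter
#' displaces vessel positions between exams.
#'
#' @param spec A [phantom_spec()].
#' @param rng_seed Integer seed for the geometry jitter.
#' @return Named list of logical 3D arrays, class `structure_masks`.
#' @export
phantom_masks <- function(spec = phantom_spec(), rng_seed = spec$seed) {
  g <- spec$grid
  ctr <- (g + 1) / 2
  ax <- spec$liver_axes * g
  jit <- with_seed(derive_seed(rng_seed, "geometry"),
                   runif(4, -0.8, 0.8))
  ix <- array(rep(seq_len(g[1]), times = g[2] * g[3]), dim = g)
  iy <- array(rep(rep(seq_len(g[2]), each = g[1]), times = g[3]), dim = g)
  iz <- array(rep(seq_len(g[3]), each = g[1] * g[2]), dim = g)

  liver <- ((ix - ctr[1]) / ax[1])^2 + ((iy - ctr[2]) / ax[2])^2 +
    ((iz - ctr[3]) / ax[3])^2 <= 1

  r <- spec$vessel_radius
  # aorta-like artery: runs the full z extent, crossing the liver contiguously
  ax_x <- ctr[1] - 0.45 * ax[1] + jit[1]
  ax_y <- ctr[2] + jit[2]
  artery <- (ix - ax_x)^2 + (iy - ax_y)^2 <= r[["artery"]]^2
  # portal vein: x-aligned tube through the liver, slightly below centre
  pv_y <- ctr[2] + 0.30 * ax[2] + jit[3]
  pv_z <- ctr[3]
  portal <- ((iy - pv_y)^2 + (iz - pv_z)^2 <= r[["portal_vein"]]^2) & liver
  # hepatic vein: y-aligned tube in the upper posterior liver
  hv_x <- ctr[1] + 0.25 * ax[1] + jit[4]
  hv_z <- ctr[3] - 0.30 * ax[3]
  hepatic <- ((ix - hv_x)^2 + (iz - hv_z)^2 <= r[["hepatic_vein"]]^2) & liver

  portal <- portal & !artery
  hepatic <- hepatic & !artery & !portal
  parenchyma <- liver & !artery & !portal & !hepatic
  masks <- list(artery = artery, portal_vein = portal,
                hepatic_vein = hepatic, parenchyma = parenchyma,
                background = !(artery | portal | hepatic | parenchyma))
  assert_that(all(map_dbl(masks, sum) > 0),
              "degenerate geometry: an anatomical mask is empty")
  structure(masks, class = "structure_masks")
}

# unenhanced attenuation by tissue class (HU): soft-tissue background,
# liver parenchyma, blood pool
BASELINE_HU <- c(background = 30, parenchyma = 55, blood = 45)

phantom_clean_baseline <- function(masks, grid) {
  vals <- array(BASELINE_HU[["background"]], dim = grid)
  vals[masks$parenchyma] <- BASELINE_HU[["parenchyma"]]
  vals[masks$artery | masks$portal_vein | masks$hepatic_vein] <-
    BASELINE_HU[["blood"]]
  vals
}

#' Unenhanced baseline volume of a phantom
#'
#' @param spec A [phantom_spec()].
#' @param rng_seed Integer seed (drives geometry jitter and voxel noise).
#' @param noise_sd Voxel noise SD in HU.
#' @param exam_id Examination identifier.
#' @return A [phase_volume()] with `true_phase = "unenhanced"`.
#' @export
phantom_baseline <- function(spec = phantom_spec(), rng_seed = spec$seed,
                             noise_sd = 5, exam_id = "phantom") {
  masks <- phantom_masks(spec, rng_seed)
  vals <- phantom_clean_baseline(masks, spec$grid)
  if (noise_sd > 0) {
    vals <- vals + with_seed(derive_seed(rng_seed, "noise_unenhanced"),
                             array(rnorm(length(vals), 0, noise_sd),
                                   dim = spec$grid))
  }
  phase_volume(vals, spec$spacing, exam_id, true_phase = "unenhanced")
}

#' Generate a synthetic multi-phase examination
#'
#' Builds one co-registered examination: every requested phase shares the same
#' geometry (and hence structure masks) and equals the unenhanced baseline
#' plus per-structure enhancement deltas (jittered per exam) plus additive
#' Gaussian voxel noise. Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param profile An [enhancement_profile()].
#' @param phase_labels Character set of phases to acquire, subset of
#'   EAP/LAP/PVP/DP; at most one of EAP/LAP (one arterial acquisition per
#'   exam); 1 to 3 phases.
#' @param rng_seed Integer seed.
#' @param exam_id Examination identifier.
#' @return An [examination()] with true labels attached and acquisition
#'   indices in canonical temporal order.
#' @export
make_phantom_exam <- function(spec = phantom_spec(),
                              profile = enhancement_profile(),
                              phase_labels = c("LAP", "PVP", "DP"),
                              rng_seed = 1L, exam_id = NULL) {
  phase_labels <- unique(as.character(phase_labels))
  assert_that(length(phase_labels) >= 1 && length(phase_labels) <= 3,
              "request between 1 and 3 phases")
  assert_that(all(phase_labels %in% PHASES4),
              "phase labels must be among EAP, LAP, PVP, DP")
  assert_that(!all(c("EAP", "LAP") %in% phase_labels),
              "an exam has a single arterial acquisition: EAP and LAP are mutually exclusive")
  exam_id <- exam_id %||% sprintf("phantom-%d", as.integer(rng_seed) %% 100000L)
  masks <- phantom_masks(spec, rng_seed)
  base <- phantom_clean_baseline(masks, spec$grid)
  phase_labels <- PHASES4[PHASES4 %in% phase_labels]  # canonical temporal order
  vols <- imap(setNames(phase_labels, phase_labels), function(ph, nm) {
    d <- with_seed(derive_seed(rng_seed, paste0("delta_", ph)),
                   rnorm(4, profile$deltas[ph, ], profile$jitter_sd[ph, ]))
    names(d) <- STRUCTURES
    vals <- base
    for (s in STRUCTURES) vals[masks[[s]]] <- vals[masks[[s]]] + d[[s]]
    if (profile$noise_sd > 0) {
      vals <- vals + with_seed(derive_seed(rng_seed, paste0("noise_", ph)),
                               array(rnorm(length(vals), 0, profile$noise_sd),
                                     dim = spec$grid))
    }
    phase_volume(vals, spec$spacing, exam_id, true_phase = ph,
                 acquisition_index = match(ph, PHASES4))
  })
  examination(unname(vols), exam_id = exam_id, order_known = TRUE)
}

#' Measure per-structure enhancement
#'
#' Mean HU difference between an enhanced volume and the unenhanced baseline
#' within each structure mask.
#'
#' @param volume,baseline [phase_volume()] objects on the same grid.
#' @param masks A `structure_masks` list (anatomical structures only are
#'   measured; background is ignored).
#' @return A tibble with columns `structure` and `delta` (HU).
#' @export
measure_enhancement <- function(volume, baseline, masks) {
  assert_that(identical(dim(volume$values), dim(baseline$values)),
              "volume and baseline must share the same grid shape")
  use <- intersect(STRUCTURES, names(masks))
  assert_that(length(use) > 0, "no anatomical structure masks supplied")
  assert_that(all(map_dbl(masks[use], sum) > 0), "empty structure mask")
  diffs <- volume$values - baseline$values
  tibble(
    structure = use,
    delta = map_dbl(use, function(s) mean(diffs[masks[[s]]]))
  )
}

#' Rule-based phase labelling thresholds
#'
#' Quantitative stand-ins for the qualitative annotation criteria
#' ("strong"/"moderate" enhancement); all values are HU deltas over baseline
#' and overridable.
#'
#' @param artery_strong Strong artery enhancement cut-off.
#' @param portal_moderate,portal_strong Moderate/strong portal-vein cut-offs
#'   (moderate means within `[portal_moderate, portal_strong)`).
#' @param hv_unenhanced Hepatic vein considered unenhanced below this.
#' @param hv_strong Strong hepatic-vein cut-off.
#' @param parenchyma_strong Strong parenchymal cut-off.
#' @return A list of class `phase_thresholds`.
#' @export
phase_thresholds <- function(artery_strong = 150, portal_moderate = 25,
                             portal_strong = 80, hv_unenhanced = 20,
                             hv_strong = 60, parenchyma_strong = 40) {
  structure(
    list(artery_strong = artery_strong, portal_moderate = portal_moderate,
         portal_strong = portal_strong, hv_unenhanced = hv_unenhanced,
         hv_strong = hv_strong, parenchyma_strong = parenchyma_strong),
    class = "phase_thresholds"
  )
}

#' Label a phase from measured enhancement deltas
#'
#' Applies the annotation decision ladder: strong artery with unenhanced
#' portal and hepatic veins is EAP; strong artery with moderate portal vein
#' and unenhanced hepatic vein is LAP; strong portal vein, hepatic vein and
#' parenchyma is PVP; anything else (enhanced but below the PVP reference) is
#' DP. When the same exam's PVP deltas are supplied, a volume whose portal
#' vein, hepatic vein and parenchyma all sit below that reference is labelled
#' DP even if it clears the absolute PVP cut-offs.
#'
#' @param deltas Named numeric vector, or a tibble with columns
#'   `structure`/`delta`, containing the four structures.
#' @param thresholds A [phase_thresholds()].
#' @param pvp_reference Optional same-exam PVP deltas (same format) used as
#'   the DP comparison reference.
#' @return One of `"EAP"`, `"LAP"`, `"PVP"`, `"DP"`.
#' @export
rule_label <- function(deltas, thresholds = phase_thresholds(),
                       pvp_reference = NULL) {
  d <- as_delta_vector(deltas)
  th <- thresholds
  if (d[["artery"]] >= th$artery_strong &&
      d[["hepatic_vein"]] < th$hv_unenhanced) {
    if (d[["portal_vein"]] < th$portal_moderate) return("EAP")
    if (d[["portal_vein"]] < th$portal_strong) return("LAP")
  }
  if (d[["portal_vein"]] >= th$portal_strong &&
      d[["hepatic_vein"]] >= th$hv_strong &&
      d[["parenchyma"]] >= th$parenchyma_strong) {
    if (!is.null(pvp_reference)) {
      r <- as_delta_vector(pvp_reference)
      keys <- c("portal_vein", "hepatic_vein", "parenchyma")
      if (all(d[keys] < r[keys])) return("DP")
    }
    return("PVP")
  }
  "DP"
}

as_delta_vector <- function(deltas) {
  if (is_tibble(deltas) || is.data.frame(deltas)) {
    deltas <- setNames(deltas$delta, deltas$structure)
  }
  missing <- setdiff(STRUCTURES, names(deltas))
  assert_that(length(missing) == 0,
              paste0("missing structure deltas: ", paste(missing, collapse = ", ")))
  deltas[STRUCTURES]
}

#' Rule-label every phase of an examination
#'
#' Measures per-structure enhancement for each phase against the unenhanced
#' baseline and applies [rule_label()]. If more than one phase clears the
#' absolute PVP criteria, the one with the strongest portal-vein enhancement
#' is kept as PVP and the others are relabelled DP (same-exam reference
#' comparison).
#'
#' @param exam An [examination()].
#' @param baseline Unenhanced [phase_volume()] on the same geometry.
#' @param masks The exam's `structure_masks`.
#' @param thresholds A [phase_thresholds()].
#' @return Tibble with one row per phase: `phase_index`, measured deltas, and
#'   `rule_label`.
#' @export
rule_label_exam <- function(exam, baseline, masks,
                            thresholds = phase_thresholds()) {
  meas <- map(exam$phases, measure_enhancement, baseline = baseline,
              masks = masks)
  labels <- map_chr(meas, rule_label, thresholds = thresholds)
  pvp_idx <- which(labels == "PVP")
  if (length(pvp_idx) > 1) {
    portal <- map_dbl(meas[pvp_idx], function(m) as_delta_vector(m)[["portal_vein"]])
    ref <- meas[[pvp_idx[which.max(portal)]]]
    labels[pvp_idx] <- map_chr(meas[pvp_idx], rule_label,
                               thresholds = thresholds, pvp_reference = ref)
    labels[pvp_idx[which.max(portal)]] <- "PVP"
  }
  wide <- bind_rows(imap(meas, function(m, i) {
    tidyr::pivot_wider(mutate(m, phase_index = i), names_from = "structure",
                       values_from = "delta")
  }))
  mutate(wide, rule_label = labels)
}

#' Generate a decision-boundary edge-case examination
#'
#' Reproduces the enhancement patterns of hard, near-boundary cases:
#' `eap_portal_flash` is an EAP whose portal vein shows a slight (~10-15 HU)
#' enhancement flash; `lap_low_portal` is a LAP with portal enhancement just
#' above the moderate threshold; `pvp_dp_flat` is a PVP/DP pair whose
#' portal-vein difference is only ~34 HU and hepatic-vein difference ~9 HU.
#' True labels are still assigned by the generating profile.
#'
#' @param case_kind One of `"eap_portal_flash"`, `"lap_low_portal"`,
#'   `"pvp_dp_flat"`.
#' @param spec A [phantom_spec()].
#' @param rng_seed Integer seed.
#' @return An [examination()].
#' @export
make_edge_case <- function(case_kind, spec = phantom_spec(), rng_seed = 1L) {
  assert_that(length(case_kind) == 1 &&
                case_kind %in% c("eap_portal_flash", "lap_low_portal", "pvp_dp_flat"),
              "unknown edge case kind")
  prof <- enhancement_profile()
  prof$jitter_sd[] <- 1
  if (case_kind == "eap_portal_flash") {
    prof$deltas["EAP", "portal_vein"] <- 12
    labels <- c("EAP", "PVP", "DP")
  } else if (case_kind == "lap_low_portal") {
    prof$deltas["LAP", "portal_vein"] <- 28
    prof$jitter_sd["LAP", "portal_vein"] <- 0.5
    labels <- c("LAP", "PVP", "DP")
  } else {
    prof$deltas["PVP", ] <- c(80, 100, 90, 50)
    prof$deltas["DP", ]  <- c(60, 66, 81, 35)
    labels <- c("PVP", "DP")
  }
  make_phantom_exam(spec, prof, labels, rng_seed,
                    exam_id = sprintf("%s-%d", case_kind, as.integer(rng_seed)))
}

#' Simulate a cohort of phantom examinations
#'
#' Convenience generator for training/evaluation cohorts: draws a phase-set
#' composition per exam (always containing an arterial phase plus PVP and/or
#' DP by default), with an optional fraction of decision-boundary edge cases.
#'
#' @param n_exams Number of examinations.
#' @param spec A [phantom_spec()].
#' @param profile An [enhancement_profile()].
#' @param seed Integer seed.
#' @param edge_case_fraction Fraction of exams drawn from [make_edge_case()].
#' @param phase_sets List of candidate phase-label sets to sample from.
#' @param p_arterial_eap Probability that the arterial acquisition is EAP
#'   (vs LAP) where a set says "arterial".
#' @return List of [examination()] objects.
#' @export
simulate_cohort <- function(n_exams, spec = phantom_spec(),
                            profile = enhancement_profile(), seed = 1L,
                            edge_case_fraction = 0,
                            phase_sets = list(c("arterial", "PVP", "DP")),
                            p_arterial_eap = 0.5) {
  assert_that(is_count(n_exams) && n_exams >= 1, "n_exams must be a positive count")
  draws <- with_seed(derive_seed(seed, "cohort"), {
    list(set = sample(length(phase_sets), n_exams, replace = TRUE),
         eap = runif(n_exams) < p_arterial_eap,
         edge = runif(n_exams) < edge_case_fraction,
         kind = sample(c("eap_portal_flash", "lap_low_portal", "pvp_dp_flat"),
                       n_exams, replace = TRUE))
  })
  map(seq_len(n_exams), function(i) {
    sd_i <- derive_seed(seed, paste0("exam_", i))
    if (draws$edge[i]) return(make_edge_case(draws$kind[i], spec, sd_i))
    labels <- phase_sets[[draws$set[i]]]
    labels[labels == "arterial"] <- if (draws$eap[i]) "EAP" else "LAP"
    make_phantom_exam(spec, profile, labels, sd_i,
                      exam_id = sprintf("sim-%05d", i))
  })
}
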