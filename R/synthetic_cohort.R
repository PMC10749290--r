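#' Specification of a synthetic FLT PET/CT phantom cohort
#'
#' Defines the statistical and geometric conditions of a simulated cohort:
#' inter-patient reference-tissue uptake distributions, within-VOI voxel
#' noise, per-stage lesion load and lesion-to-reference contrast. Defaults
#' mirror the study conditions of the clinical cohort the methodology was
#' developed on: liver uptake 5.1 +/- 1.4 SUV and bone-marrow uptake
#' 7.8 +/- 2.7 SUV across patients and stages, 23 patients over three
#' treatment stages, and per-stage lesion minimum-to-liver ratios of
#' 0.49 / 0.33 / 0.24 (baseline / iPET / fPET).
#'
#' @param n_patients number of patients.
#' @param stages subset of `c("baseline", "iPET", "fPET")`, in order.
#' @param liver_mean,liver_sd inter-patient liver SUV distribution
#'   (Gaussian truncated below at 0.5 SUV).
#' @param marrow_mean,marrow_sd inter-patient bone-marrow SUV distribution.
#' @param within_voi_cv coefficient of variation of voxel noise inside the
#'   reference tissues: a scalar, or a named vector with elements `liver`
#'   and `marrow` (non-reference soft tissue uses the liver value). Defaults
#'   to `c(liver = 0.13, marrow = 0.25)`, the within-VOI relative SDs implied
#'   by the published minimum-vs-final threshold ratios.
#' @param lesion_count_per_stage mean lesions per patient at each stage
#'   (scalar or named by stage; may be fractional - the cohort total is
#'   `round(n_patients * count)`, allocated as evenly as possible).
#' @param lesion_min_fraction target ratio of a lesion's minimum SUV to the
#'   patient's reference-tissue uptake, per stage (scalar or named by stage).
#' @param lesion_reference_tissue tissue the planted lesion minima are
#'   expressed against: `"liver"` (default) or `"marrow"`.
#' @param lesion_axis_range_mm range the three ellipsoid axis diameters are
#'   drawn from, uniformly, in mm.
#' @param lesion_peak_ratio lesion centre (plateau) uptake as a multiple of
#'   its minimum.
#' @param stage_drift per-stage fractional change of the true reference
#'   uptake (default 0: stable reference tissues; set nonzero to exercise
#'   the stability analysis).
#' @param background_suv soft-tissue background SUV.
#' @param bladder_suv SUV of the planted physiological (non-tumour) hot
#'   region.
#' @param voxel_spacing mm triplet.
#' @param grid_shape voxel-count triplet; must be large enough to hold the
#'   48 mm liver sphere VOI and the vertebral column (validated).
#' @param seed integer; fully determines every generated voxel.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 23,
                        stages = flt_stages(),
                        liver_mean = 5.1, liver_sd = 1.4,
                        marrow_mean = 7.8, marrow_sd = 2.7,
                        within_voi_cv = c(liver = 0.13, marrow = 0.25),
                        lesion_count_per_stage = c(baseline = 4, iPET = 2, fPET = 1),
                        lesion_min_fraction = c(baseline = 0.49, iPET = 0.33, fPET = 0.24),
                        lesion_reference_tissue = c("liver", "marrow"),
                        lesion_axis_range_mm = c(8, 25),
                        lesion_peak_ratio = 2.5,
                        stage_drift = c(baseline = 0, iPET = 0, fPET = 0),
                        background_suv = 0.6,
                        bladder_suv = 12,
                        voxel_spacing = c(3, 3, 3),
                        grid_shape = c(64L, 64L, 80L),
                        seed = 1L) {
  lesion_reference_tissue <- match.arg(lesion_reference_tissue)
  assert_that(n_patients >= 1, "n_patients must be >= 1")
  assert_that(all(stages %in% flt_stages()) && length(stages) >= 1 &&
              !anyDuplicated(stages), "stages must be a subset of baseline/iPET/fPET")
  stages <- flt_stages()[flt_stages() %in% stages]
  assert_that(liver_sd >= 0 && marrow_sd >= 0, "inter-patient SDs must be >= 0")
  assert_that(liver_mean > 0 && marrow_mean > 0, "uptake means must be positive")
  cv <- normalize_cv(within_voi_cv)
  assert_that(all(cv >= 0), "within_voi_cv must be >= 0")
  per_stage <- function(x, what, positive = FALSE) {
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, 3), flt_stages())
    assert_that(all(stages %in% names(x)), "%s must name every requested stage", what)
    x <- x[flt_stages()[flt_stages() %in% names(x)]]
    if (positive) assert_that(all(x[stages] > 0), "%s must be > 0", what)
    x
  }
  lesion_count_per_stage <- per_stage(lesion_count_per_stage, "lesion_count_per_stage")
  assert_that(all(lesion_count_per_stage >= 0), "lesion counts must be >= 0")
  lesion_min_fraction <- per_stage(lesion_min_fraction, "lesion_min_fraction", positive = TRUE)
  stage_drift <- per_stage(stage_drift, "stage_drift")
  assert_that(length(lesion_axis_range_mm) == 2 &&
              lesion_axis_range_mm[1] > 0 &&
              lesion_axis_range_mm[1] <= lesion_axis_range_mm[2],
              "lesion_axis_range_mm must be a positive increasing pair")
  assert_that(lesion_peak_ratio >= 1, "lesion_peak_ratio must be >= 1")
  assert_that(background_suv > 0 && bladder_suv > 0, "background and bladder SUV must be positive")
  spec <- structure(list(
    n_patients = as.integer(n_patients), stages = stages,
    liver_mean = liver_mean, liver_sd = liver_sd,
    marrow_mean = marrow_mean, marrow_sd = marrow_sd,
    within_voi_cv = cv,
    lesion_count_per_stage = lesion_count_per_stage,
    lesion_min_fraction = lesion_min_fraction,
    lesion_reference_tissue = lesion_reference_tissue,
    lesion_axis_range_mm = lesion_axis_range_mm,
    lesion_peak_ratio = lesion_peak_ratio,
    stage_drift = stage_drift,
    background_suv = background_suv, bladder_suv = bladder_suv,
    voxel_spacing = as.numeric(voxel_spacing),
    grid_shape = as.integer(grid_shape),
    seed = as.integer(seed)), class = "cohort_spec")
  phantom_geometry(spec)  # validates that the grid holds every structure
  spec
}

normalize_cv <- function(cv) {
  if (length(cv) == 1 && is.null(names(cv)))
    return(c(liver = unname(cv), marrow = unname(cv), other = unname(cv)))
  assert_that(all(c("liver", "marrow") %in% names(cv)),
              "within_voi_cv must be a scalar or name liver and marrow")
  c(liver = unname(cv[["liver"]]), marrow = unname(cv[["marrow"]]),
    other = unname(if ("other" %in% names(cv)) cv[["other"]] else cv[["liver"]]))
}

#' Phantom anatomy for a cohort specification
#'
#' Places the phantom structures on the grid, scaled to the grid's physical
#' extent: a liver ellipsoid in the upper "abdomen" octant (large enough to
#' hold the 48 mm sphere VOI), an axis-aligned vertebral column (T10, T11,
#' T12 high; L3 low) of bone-range HU, and a bladder-like physiological hot
#' sphere. Errors name the structure that does not fit.
#'
#' @param spec a [cohort_spec()] (or a bare list with `grid_shape` and
#'   `voxel_spacing`).
#' @return list with the grid geometry, structure centres/sizes in mm, and
#'   vertebra search boxes (voxel index ranges) for HU delineation.
#' @export
phantom_geometry <- function(spec) {
  geom <- grid_geometry(spec$grid_shape, spec$voxel_spacing)
  ex <- grid_extent_mm(geom)
  border_mm <- 2 * spec$voxel_spacing  # air shell: 2 voxels per axis

  fit <- function(center, half, what) {
    lo <- center - half; hi <- center + half
    ok <- all(lo > border_mm + spec$voxel_spacing) &
      all(hi < ex - border_mm - spec$voxel_spacing)
    if (!ok)
      stopf("grid %s voxels at %s mm spacing is too small to hold the %s",
            paste(spec$grid_shape, collapse = "x"),
            paste(signif(spec$voxel_spacing, 3), collapse = "x"), what)
  }

  liver_center <- c(0.32, 0.40, 0.70) * ex
  liver_semi <- c(42, 36, 36)
  fit(liver_center, liver_semi, "liver ellipsoid (must hold the 48 mm sphere VOI)")

  vert_half <- c(15, 15, 12)
  vx <- 0.68 * ex[1]; vy <- 0.68 * ex[2]
  vz <- c(T10 = 0.875, T11 = 0.750, T12 = 0.625, L3 = 0.250) * ex[3]
  if (0.125 * ex[3] < 2 * vert_half[3] + 3)
    stopf("grid %s voxels at %s mm spacing is too small to hold the vertebral column",
          paste(spec$grid_shape, collapse = "x"),
          paste(signif(spec$voxel_spacing, 3), collapse = "x"))
  vert_centers <- lapply(vz, function(z) c(vx, vy, z))
  for (v in names(vert_centers)) fit(vert_centers[[v]], vert_half, paste("vertebra", v))

  bladder_center <- c(0.32, 0.40, 0.125) * ex
  bladder_r <- 15
  fit(bladder_center, rep(bladder_r, 3), "bladder sphere")

  search_margin <- c(9, 9, 4)
  boxes <- lapply(vert_centers, function(ctr) {
    bb <- bbox_indices(geom, ctr, vert_half + search_margin)
    list(lo = bb$lo, hi = bb$hi)
  })

  list(geom = geom, border_mm = border_mm,
       liver_center_mm = liver_center, liver_semiaxes_mm = liver_semi,
       vertebra_centers_mm = vert_centers, vertebra_halfsize_mm = vert_half,
       vertebra_boxes = boxes,
       bladder_center_mm = bladder_center, bladder_radius_mm = bladder_r)
}

# Phase-1 draws: everything shared between the volume and summary generators
# (true uptakes, lesion counts/sizes/target minima), in a fixed order that
# does not depend on which scans are later rasterized.
patient_params <- function(spec) {
  s <- derive_seeds(spec$seed, 3)
  ids <- sprintf("P%02d", seq_len(spec$n_patients))

  rtruncnorm <- function(n, mean, sd, lower = 0.5) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }

  with_seed(s[1], {
    liver_true <- rtruncnorm(spec$n_patients, spec$liver_mean, spec$liver_sd)
    marrow_true <- rtruncnorm(spec$n_patients, spec$marrow_mean, spec$marrow_sd)

    lesions <- list()
    for (stage in spec$stages) {
      total <- round(spec$n_patients * spec$lesion_count_per_stage[[stage]])
      if (total == 0) next
      base <- total %/% spec$n_patients
      counts <- rep(base, spec$n_patients)
      extra <- total - base * spec$n_patients
      if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
      for (p in seq_len(spec$n_patients)) {
        if (counts[p] == 0) next
        dia <- matrix(stats::runif(3 * counts[p], spec$lesion_axis_range_mm[1],
                                   spec$lesion_axis_range_mm[2]),
                      ncol = 3)
        ref_true <- if (spec$lesion_reference_tissue == "liver") liver_true[p] else marrow_true[p]
        ref_true <- ref_true * (1 + spec$stage_drift[[stage]])
        lesions[[length(lesions) + 1]] <- data.frame(
          patient_id = ids[p], stage = stage, lesion_id = seq_len(counts[p]),
          semi_x = dia[, 1] / 2, semi_y = dia[, 2] / 2, semi_z = dia[, 3] / 2,
          target_min_suv = spec$lesion_min_fraction[[stage]] * ref_true,
          stringsAsFactors = FALSE)
      }
    }
    lesions <- if (length(lesions)) do.call(rbind, lesions) else
      data.frame(patient_id = character(), stage = character(), lesion_id = integer(),
                 semi_x = numeric(), semi_y = numeric(), semi_z = numeric(),
                 target_min_suv = numeric(), stringsAsFactors = FALSE)
  })

  scan_seeds <- with_seed(s[2], {
    m <- matrix(sample.int(2147483645L, spec$n_patients * length(spec$stages)),
                nrow = spec$n_patients,
                dimnames = list(ids, spec$stages))
    m
  })

  list(patient_ids = ids, liver_true = stats::setNames(liver_true, ids),
       marrow_true = stats::setNames(marrow_true, ids),
       lesions = lesions, scan_seeds = scan_seeds, summary_seed = s[3])
}

true_uptake <- function(params, spec, patient_id, stage, tissue) {
  base <- if (tissue == "liver") params$liver_true[[patient_id]]
          else params$marrow_true[[patient_id]]
  base * (1 + spec$stage_drift[[stage]])
}

# lesion radial profile: plateau (value 1) out to 30% of the normalized
# radius, then linear fall to 0 at the boundary
lesion_profile <- function(r) {
  g <- (1 - r) / 0.7
  g[r <= 0.3] <- 1
  pmax(g, 0)
}

#' Generate one synthetic patient-stage scan
#'
#' Rasterizes the phantom for one (patient, stage): CT with soft tissue
#' (40 HU), liver (60 HU), air border (-1000 HU) and vertebral bodies
#' (300 HU); PET with per-patient liver and marrow plateaus, soft-tissue
#' background, a physiological bladder hot spot, multiplicative Gaussian
#' voxel noise at the configured CV, and ellipsoidal lesions with a centre
#' plateau falling linearly to a controlled minimum at the rim. Lesion
#' voxels are deterministic (noise-free) so each lesion's realized minimum
#' SUV equals its target exactly; noise elsewhere. The same seed always
#' reproduces the same scan, regardless of generation order.
#'
#' @param spec a [cohort_spec()].
#' @param patient_id patient identifier (e.g. "P01") or index.
#' @param stage stage name.
#' @param params optional precomputed [patient_params] (internal reuse).
#' @return list with `pair` (a [volume_pair()]) and `truth` (ground-truth
#'   masks and true uptakes).
#' @export
generate_scan <- function(spec, patient_id, stage, params = NULL) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  assert_stage(stage)
  assert_that(stage %in% spec$stages, "stage %s not in spec$stages", stage)
  if (is.null(params)) params <- patient_params(spec)
  if (is.numeric(patient_id)) patient_id <- params$patient_ids[patient_id]
  assert_that(patient_id %in% params$patient_ids, "unknown patient '%s'", patient_id)

  ph <- phantom_geometry(spec)
  geom <- ph$geom
  d <- geom$shape
  cv <- spec$within_voi_cv

  liver_mask <- ellipsoid_mask(geom, ph$liver_center_mm, ph$liver_semiaxes_mm)
  vert_masks <- lapply(ph$vertebra_centers_mm, function(ctr)
    box_mask(geom, ctr, ph$vertebra_halfsize_mm))
  vert_union <- Reduce(`|`, vert_masks)
  bladder_mask <- ellipsoid_mask(geom, ph$bladder_center_mm, rep(ph$bladder_radius_mm, 3))

  border <- array(FALSE, d)
  border[c(1:2, d[1] - 1:0), , ] <- TRUE
  border[, c(1:2, d[2] - 1:0), ] <- TRUE
  border[, , c(1:2, d[3] - 1:0)] <- TRUE

  ct <- array(40, d)
  ct[liver_mask] <- 60
  ct[vert_union] <- 300
  ct[border] <- -1000

  suv_h <- true_uptake(params, spec, patient_id, stage, "liver")
  suv_m <- true_uptake(params, spec, patient_id, stage, "marrow")

  pet <- array(spec$background_suv, d)
  pet[liver_mask] <- suv_h
  pet[vert_union] <- suv_m
  pet[bladder_mask] <- spec$bladder_suv
  pet[border] <- 0.05

  les <- params$lesions
  les <- les[les$patient_id == patient_id & les$stage == stage, , drop = FALSE]

  scan_seed <- params$scan_seeds[patient_id, stage]
  lesion_masks <- list()
  lesion_values <- list()
  lesion_min <- numeric(0)

  with_seed(scan_seed, {
    # --- lesion placement (rejection sampling against an occupancy mask) ---
    margin <- 3  # mm kept free around every structure; pairs end >= 2 voxels apart
    forbidden <- ellipsoid_mask(geom, ph$liver_center_mm, ph$liver_semiaxes_mm + 2 * margin) |
      bladder_mask | border
    for (ctr in ph$vertebra_centers_mm)
      forbidden <- forbidden | box_mask(geom, ctr, ph$vertebra_halfsize_mm + 2 * margin)
    forbidden <- forbidden |
      ellipsoid_mask(geom, ph$bladder_center_mm, rep(ph$bladder_radius_mm + 2 * margin, 3))

    ex <- grid_extent_mm(geom)
    if (nrow(les) > 0) {
      for (k in seq_len(nrow(les))) {
        semi <- c(les$semi_x[k], les$semi_y[k], les$semi_z[k])
        placed <- FALSE
        for (try in 1:400) {
          lo <- ph$border_mm + spec$voxel_spacing + semi + margin
          hi <- ex - ph$border_mm - spec$voxel_spacing - semi - margin
          if (any(hi <= lo)) break
          ctr <- stats::runif(3, lo, hi)
          guard <- ellipsoid_mask(geom, ctr, semi + margin)
          if (!any(guard & forbidden)) {
            core <- ellipsoid_mask(geom, ctr, semi)
            if (!any(core)) next
            eb <- ellipsoid_r2_box(geom, ctr, semi)
            r <- sqrt(pmin(eb$r2, 1))
            target <- les$target_min_suv[k]
            peak <- spec$lesion_peak_ratio * target
            vals <- target + (peak - target) * lesion_profile(r)
            inside <- eb$r2 <= 1
            # pin the rim-most voxel to the target so the realized minimum
            # is exact, not merely close after rasterization
            iv <- vals[inside]
            iv[which.max(r[inside])] <- target
            vals[inside] <- iv
            sub_idx <- list(eb$bb$lo[1]:eb$bb$hi[1], eb$bb$lo[2]:eb$bb$hi[2],
                            eb$bb$lo[3]:eb$bb$hi[3])
            lesion_masks[[k]] <- core
            lesion_values[[k]] <- list(idx = sub_idx, inside = inside, vals = vals)
            lesion_min[k] <- target
            forbidden <- forbidden | guard
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stopf("could not place lesion %d for %s/%s: grid too small for the requested lesion structures",
                k, patient_id, stage)
      }
    }

    # --- voxel noise (multiplicative, tissue-specific CV) ---
    cv_field <- array(cv[["other"]], d)
    cv_field[liver_mask] <- cv[["liver"]]
    cv_field[vert_union] <- cv[["marrow"]]
    if (any(cv > 0)) {
      z <- stats::rnorm(prod(d))
      pet <- pet * (1 + cv_field * z)
      pet[pet < 0.01] <- 0.01
    }
  })

  # lesions are written after noise so their minima stay controlled
  if (length(lesion_masks)) {
    for (k in seq_along(lesion_masks)) {
      lv <- lesion_values[[k]]
      sub <- pet[lv$idx[[1]], lv$idx[[2]], lv$idx[[3]], drop = FALSE]
      dim(sub) <- dim(lv$inside)
      sub[lv$inside] <- lv$vals[lv$inside]
      pet[lv$idx[[1]], lv$idx[[2]], lv$idx[[3]]] <- sub
    }
  }

  pair <- volume_pair(ct, pet, geom, patient_id, stage)
  truth <- list(
    liver_mask = liver_mask,
    vertebra_masks = vert_masks,
    lesion_masks = lesion_masks,
    lesion_min_suv = lesion_min,
    physiological_mask = liver_mask | vert_union | bladder_mask,
    liver_true_suv = suv_h,
    marrow_true_suv = suv_m)
  list(pair = pair, truth = truth)
}

#' Generate a full synthetic cohort of PET/CT volume pairs
#'
#' Calls [generate_scan()] for every (patient, stage); the result is a named
#' list keyed `"<patient>.<stage>"`. For large cohorts prefer streaming with
#' [generate_scan()] to bound memory.
#'
#' @param spec a [cohort_spec()].
#' @return named list of `list(pair =, truth =)` entries.
#' @export
generate_cohort <- function(spec) {
  params <- patient_params(spec)
  out <- list()
  for (pid in params$patient_ids)
    for (stage in spec$stages)
      out[[paste(pid, stage, sep = ".")]] <- generate_scan(spec, pid, stage, params)
  out
}

#' Generate a summary-only synthetic cohort (no volumes)
#'
#' Draws per-patient true uptakes and lesion records from the same phase-1
#' random stream as [generate_cohort()] - identical seed implies identical
#' per-patient true means - without rasterizing any volume. Reference
#' measures report the true mean and a within-VOI SD of `cv * mean`; lesion
#' minima get multiplicative jitter at the soft-tissue CV (exactly the
#' target fraction when the CV is 0).
#'
#' @param spec a [cohort_spec()].
#' @return list with `measures` (patient_id, stage, tissue, mean_suv,
#'   sd_suv) and `lesions` (patient_id, stage, lesion_id, min_suv)
#'   data.frames.
#' @export
generate_summary_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  params <- patient_params(spec)
  cv <- spec$within_voi_cv
  grid_df <- expand.grid(patient_id = params$patient_ids, stage = spec$stages,
                         tissue = c("liver", "marrow"),
                         stringsAsFactors = FALSE)
  grid_df <- grid_df[order(match(grid_df$tissue, c("liver", "marrow")),
                           match(grid_df$stage, flt_stages()),
                           match(grid_df$patient_id, params$patient_ids)), ]
  tr <- mapply(function(p, s, t) true_uptake(params, spec, p, s, t),
               grid_df$patient_id, grid_df$stage, grid_df$tissue)
  measures <- data.frame(patient_id = grid_df$patient_id, stage = grid_df$stage,
                         tissue = grid_df$tissue,
                         mean_suv = as.numeric(tr),
                         sd_suv = as.numeric(tr) * cv[match(grid_df$tissue, names(cv))],
                         stringsAsFactors = FALSE)
  rownames(measures) <- NULL

  lesions <- params$lesions
  if (nrow(lesions)) {
    jitter <- with_seed(params$summary_seed,
                        stats::rnorm(nrow(lesions), 0, 1)) * cv[["other"]]
    lesions$min_suv <- lesions$target_min_suv * (1 + jitter)
    lesions$min_suv <- pmax(lesions$min_suv, 0.01)
  } else {
    lesions$min_suv <- numeric(0)
  }
  lesions <- lesions[, c("patient_id", "stage", "lesion_id", "min_suv")]
  rownames(lesions) <- NULL
  list(measures = measures, lesions = lesions)
}
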