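#' Spherical VOI mask
#'
#' A voxel belongs to the sphere iff its centre lies within `diameter_mm / 2`
#' of `center_mm`. The standard presets used for the liver reference are 29,
#' 41 and 48 mm diameters placed in hepatic segment VIII; 29 mm is the
#' default downstream because it is closest to the PERCIST sphere.
#'
#' @param geom a [grid_geometry()].
#' @param center_mm sphere centre in world mm.
#' @param diameter_mm sphere diameter in mm (> 0).
#' @return logical array; errors if the sphere captures no voxel centre.
#' @export
sphere_mask <- function(geom, center_mm, diameter_mm) {
  assert_that(is.numeric(diameter_mm) && diameter_mm > 0, "diameter must be positive")
  r <- diameter_mm / 2
  m <- ellipsoid_mask(geom, center_mm, rep(r, 3))
  if (!any(m))
    stopf("sphere of diameter %.3g mm at (%g, %g, %g) mm captures no voxel centre",
          diameter_mm, center_mm[1], center_mm[2], center_mm[3])
  m
}

#' Liver sphere VOI diameter presets (mm)
#' @export
liver_sphere_diameters <- function() c(sphere29 = 29, sphere41 = 41, sphere48 = 48)

#' Delineate a vertebral body on CT by Hounsfield units
#'
#' Thresholds the CT inside a search box to the given HU interval, keeps the
#' largest 26-connected component and fills interior holes (so trabecular
#' interior below the HU floor still belongs to the vertebra). The result is
#' on the CT grid; resample to the PET grid with [resample_mask_to_pet()]
#' before taking SUV statistics.
#'
#' @param ct 3D HU array.
#' @param geom CT [grid_geometry()].
#' @param search_box list with integer triplets `lo` and `hi` (1-based,
#'   inclusive voxel index ranges).
#' @param hu_range HU interval, default `c(150, 1500)` (trabecular to
#'   cortical bone; configurable since published HU criteria vary).
#' @return logical array on the CT grid.
#' @export
delineate_vertebra <- function(ct, geom, search_box, hu_range = c(150, 1500)) {
  lo <- as.integer(search_box$lo); hi <- as.integer(search_box$hi)
  assert_that(length(lo) == 3 && length(hi) == 3 && all(lo >= 1) &&
              all(hi <= geom$shape) && all(lo <= hi),
              "search box outside grid or inverted")
  assert_that(length(hu_range) == 2 && hu_range[1] < hu_range[2],
              "HU range must be a non-empty interval")
  sub <- ct[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1L
  inrange <- sub >= hu_range[1] & sub <= hu_range[2]
  if (!any(inrange))
    stopf("no voxels in HU range [%g, %g] within search box [%s]-[%s]",
          hu_range[1], hu_range[2], paste(lo, collapse = ","), paste(hi, collapse = ","))
  body <- fill_holes(largest_component(inrange, connectivity = 26))
  out <- array(FALSE, geom$shape)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- body
  out
}

#' SUV statistics over a VOI
#'
#' The within-VOI standard deviation uses the population divisor N by
#' default: the VOI is the complete set of voxels measured, and downstream
#' threshold criteria use the SD as a spread scale, not as an estimator of a
#' sampling distribution. Use `sd_type = "sample"` for the N-1 divisor.
#'
#' @param pet SUV array.
#' @param mask logical array of the same shape; must select at least one voxel.
#' @param spacing voxel spacing in mm (for the reported volume).
#' @param sd_type `"population"` (divisor N, default) or `"sample"` (N-1).
#' @return list of class `voi_stats`: `mean_suv`, `sd_suv`, `min_suv`,
#'   `max_suv`, `voxel_count`, `volume_ml`.
#' @export
voi_stats <- function(pet, mask, spacing, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  assert_that(identical(dim(pet), dim(mask)), "pet and mask must share a shape")
  v <- pet[as.logical(mask)]
  assert_that(length(v) >= 1, "empty VOI mask")
  assert_that(all(is.finite(v)), "non-finite voxels inside VOI")
  n <- length(v)
  mu <- mean(v)
  ss <- sum((v - mu)^2)
  sdv <- if (sd_type == "population") sqrt(ss / n)
         else if (n > 1) sqrt(ss / (n - 1)) else 0
  structure(list(mean_suv = mu, sd_suv = sdv, min_suv = min(v), max_suv = max(v),
                 voxel_count = n, volume_ml = n * voxel_volume_ml(spacing)),
            class = "voi_stats")
}

#' @export
print.voi_stats <- function(x, ...) {
  cat(sprintf("VOI: %d voxels (%.2f ml), SUV %.3f +/- %.3f [%.3f, %.3f]\n",
              x$voxel_count, x$volume_ml, x$mean_suv, x$sd_suv, x$min_suv, x$max_suv))
  invisible(x)
}

#' One reference-tissue measurement row
#' @keywords internal
reference_measure_row <- function(patient_id, stage, tissue, stats) {
  data.frame(patient_id = as.character(patient_id), stage = stage, tissue = tissue,
             mean_suv = stats$mean_suv, sd_suv = stats$sd_suv,
             voxel_count = stats$voxel_count, stringsAsFactors = FALSE)
}

#' Measure a reference tissue on one scan
#'
#' Liver: mean SUV (and within-VOI SD) in a sphere placed in segment VIII —
#' default the 29 mm diameter preset. Bone marrow: mean SUV in HU-delineated
#' vertebrae — default T12; `T10T11T12` pools the union of the three masks.
#' Sphere centres and vertebra search boxes must be supplied via `placement`
#' (automatic anatomical localization is out of scope).
#'
#' @param pair a [volume_pair()].
#' @param tissue `"liver"` or `"marrow"`.
#' @param voi_choice liver: `sphere29` (default), `sphere41`, `sphere48`;
#'   marrow: `T12` (default), `L3`, `T10T11T12`.
#' @param placement list. For liver: `liver_center_mm`. For marrow:
#'   `vertebra_boxes`, a named list (T10, T11, T12, L3) of search boxes, each
#'   `list(lo =, hi =)` in CT voxel indices; optionally `hu_range`.
#' @param sd_type passed to [voi_stats()].
#' @return one-row data.frame: patient_id, stage, tissue, mean_suv, sd_suv,
#'   voxel_count.
#' @export
reference_measure <- function(pair, tissue = c("liver", "marrow"),
                              voi_choice = NULL, placement,
                              sd_type = "population") {
  tissue <- match.arg(tissue)
  if (tissue == "liver") {
    voi_choice <- voi_choice %||% "sphere29"
    dia <- liver_sphere_diameters()
    assert_that(voi_choice %in% names(dia),
                "unknown liver VOI choice '%s'", as.character(voi_choice)[1])
    assert_that(!is.null(placement$liver_center_mm), "placement$liver_center_mm required")
    m <- sphere_mask(pair$geom, placement$liver_center_mm, dia[[voi_choice]])
  } else {
    voi_choice <- voi_choice %||% "T12"
    assert_that(voi_choice %in% c("T12", "L3", "T10T11T12"),
                "unknown marrow VOI choice '%s'", as.character(voi_choice)[1])
    vb <- placement$vertebra_boxes
    assert_that(!is.null(vb), "placement$vertebra_boxes required")
    hu <- placement$hu_range %||% c(150, 1500)
    verts <- if (voi_choice == "T10T11T12") c("T10", "T11", "T12") else voi_choice
    m <- array(FALSE, pair$geom$shape)
    for (v in verts) {
      assert_that(!is.null(vb[[v]]), "missing search box for vertebra %s", v)
      m <- m | delineate_vertebra(pair$ct, pair$geom, vb[[v]], hu)
    }
    # CT and PET share the grid inside a volume_pair, so this is an identity
    # resample kept for contract clarity
    m <- resample_mask_to_pet(m, pair$geom, pair$geom)
  }
  st <- voi_stats(pair$pet, m, pair$geom$spacing, sd_type = sd_type)
  reference_measure_row(pair$patient_id, pair$stage, tissue, st)
}
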