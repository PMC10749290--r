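#' Threshold-based lesion segmentation of a PET volume
#'
#' Every voxel whose SUV is strictly greater than the absolute threshold and
#' not inside the physiological-exclusion mask is foreground; foreground is
#' labelled into 3D connected components (26-connectivity by default) in a
#' deterministic order (descending size, ties by seed voxel). Exclusion is
#' mask-driven: reference tissues and known physiological hot regions
#' (e.g. bladder) are supplied by the caller, mirroring the manual care
#' taken in clinical delineation.
#'
#' @param pet SUV array.
#' @param threshold_suv absolute SUV threshold (> 0).
#' @param spacing voxel spacing, mm.
#' @param exclusion_mask optional logical array of voxels never counted.
#' @param connectivity 26 (default) or 6.
#' @param min_component_voxels drop components smaller than this many voxels
#'   (default 1: single-voxel detections count).
#' @return object of class `segmentation_result`: `threshold_suv`,
#'   `label_grid`, `n_components`, `component_voxels`, `component_volumes_ml`,
#'   `total_mtv_ml`, `spacing`; detection fields are filled by
#'   [count_detections()].
#' @export
segment_lesions <- function(pet, threshold_suv, spacing,
                            exclusion_mask = NULL, connectivity = 26,
                            min_component_voxels = 1) {
  assert_that(is.numeric(threshold_suv) && threshold_suv > 0,
              "threshold must be positive")
  assert_that(all(is.finite(pet)), "PET volume contains non-finite voxels")
  fg <- pet > threshold_suv  # strict: boundary-equal voxels are background
  if (!is.null(exclusion_mask)) {
    assert_that(identical(dim(exclusion_mask), dim(pet)),
                "exclusion mask shape mismatch")
    fg <- fg & !exclusion_mask
  }
  lab <- label_components(fg, connectivity)
  k <- max(lab)
  if (k > 0 && min_component_voxels > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = k)
    keep <- which(sizes >= min_component_voxels)
    relab <- integer(k)
    relab[keep] <- seq_along(keep)
    lab <- array(ifelse(lab > 0, relab[pmax(lab, 1)], 0L), dim(lab))
    k <- length(keep)
  }
  sizes <- if (k > 0) tabulate(lab[lab > 0], nbins = k) else integer(0)
  vols <- sizes * voxel_volume_ml(spacing)
  structure(list(threshold_suv = threshold_suv, label_grid = lab,
                 n_components = k, component_voxels = sizes,
                 component_volumes_ml = vols, total_mtv_ml = sum(vols),
                 spacing = spacing,
                 detected = NULL, detection_rate = NA_real_),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation at SUV > %.3f: %d component(s), MTV %.2f ml\n",
              x$threshold_suv, x$n_components, x$total_mtv_ml))
  if (!is.null(x$detected))
    cat(sprintf("  detected %d/%d reported lesion(s) (%.0f%%)\n",
                sum(x$detected), length(x$detected), 100 * x$detection_rate))
  invisible(x)
}

#' Count detected reported lesions
#'
#' A reported lesion counts as detected iff at least one voxel of its mask
#' is segmentation foreground. Several reported lesions may map onto one
#' merged component; overlaps are recorded per lesion.
#'
#' @param result a [segment_lesions()] result.
#' @param reported_masks list of logical lesion masks on the PET grid.
#' @return `result` with `detected` (logical per lesion), `detection_rate`,
#'   and `lesion_overlap_voxels` filled in.
#' @export
count_detections <- function(result, reported_masks) {
  assert_that(inherits(result, "segmentation_result"), "need a segmentation_result")
  overlap <- vapply(reported_masks, function(m) {
    assert_that(identical(dim(m), dim(result$label_grid)),
                "reported lesion mask not on the PET grid")
    sum(result$label_grid[m] > 0)
  }, 1L)
  result$lesion_overlap_voxels <- overlap
  result$detected <- overlap >= 1L
  result$detection_rate <- if (length(overlap) > 0) mean(result$detected) else NA_real_
  result
}

#' Metabolic tumour volume of a segmentation
#'
#' Sum over labelled components of voxel count times physical voxel volume,
#' in ml. Excluded (physiological) voxels are never labelled and therefore
#' never counted.
#'
#' @param result a [segment_lesions()] result.
#' @return MTV in ml.
#' @export
mtv <- function(result) {
  assert_that(inherits(result, "segmentation_result"), "need a segmentation_result")
  result$total_mtv_ml
}

#' Compare the three threshold criteria on one set of scans
#'
#' Segments each scan under criteria 1-3 for each eligible reference tissue
#' and tabulates reported versus detected lesion counts, a detection-table
#' analogue. `scans` is a list of entries with `pet`, `spacing`,
#' `exclusion_mask`, `reported_masks`, `stage`, `patient_id`, and per-tissue
#' reference measures `ref` (named list with `mean_suv`, `sd_suv`,
#' `in_range` per tissue).
#'
#' @param scans list as described above.
#' @param threshold_table output of [build_threshold_table()].
#' @param connectivity passed to [segment_lesions()].
#' @return data.frame: stage, tissue, criterion, n_reported, n_detected,
#'   pct_detected, total_mtv_ml.
#' @export
evaluate_criteria <- function(scans, threshold_table, connectivity = 26) {
  rows <- list()
  for (i in seq_len(nrow(threshold_table))) {
    stage <- threshold_table$stage[i]
    tissue <- threshold_table$tissue[i]
    rt <- threshold_table$rt[i]
    for (crit in 1:3) {
      n_sd <- crit - 1
      n_rep <- 0L; n_det <- 0L; mtv_ml <- 0
      for (scan in scans) {
        if (scan$stage != stage) next
        ref <- scan$ref[[tissue]]
        if (is.null(ref) || !isTRUE(ref$in_range)) next
        thr <- absolute_threshold(rt, ref$mean_suv, ref$sd_suv, n_sd)
        seg <- segment_lesions(scan$pet, thr, scan$spacing,
                               exclusion_mask = scan$exclusion_mask,
                               connectivity = connectivity)
        seg <- count_detections(seg, scan$reported_masks)
        n_rep <- n_rep + length(scan$reported_masks)
        n_det <- n_det + sum(seg$detected)
        mtv_ml <- mtv_ml + seg$total_mtv_ml
      }
      rows[[length(rows) + 1]] <- data.frame(
        stage = stage, tissue = tissue, criterion = crit,
        n_reported = n_rep, n_detected = n_det,
        pct_detected = if (n_rep > 0) round_half_up(100 * n_det / n_rep) else NA_real_,
        total_mtv_ml = mtv_ml, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
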