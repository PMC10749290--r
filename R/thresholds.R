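#' Stage-wise minimum relative threshold
#'
#' The minimum relative threshold of a stage and reference tissue is the
#' unweighted mean, over all eligible reported lesions of that stage, of the
#' ratio between the lesion's minimum SUV and the reference-tissue uptake of
#' the lesion's patient:
#' `RT = (1/N_stage) * sum_i SUVmin_i / SUVref_patient(i)`.
#' Lesions of patients whose reference uptake lies outside the tissue's
#' normal range are dropped before averaging (the dropped count is attached
#' as the `n_dropped` attribute).
#'
#' @param lesions data.frame with patient_id, stage, min_suv (one stage).
#' @param measures data.frame with patient_id, stage, tissue, mean_suv and,
#'   if eligibility filtering is wanted, a logical `in_range` column (see
#'   [flag_measures()]); without it all patients are eligible.
#' @param tissue `"liver"` or `"marrow"`.
#' @param stage stage to estimate; defaults to the single stage present in
#'   `lesions`.
#' @return the relative threshold (dimensionless fraction), with attributes
#'   `n_lesions` (N_stage, lesions averaged) and `n_dropped`.
#' @export
minimum_relative_threshold <- function(lesions, measures, tissue = c("liver", "marrow"),
                                       stage = NULL) {
  tissue <- match.arg(tissue)
  if (is.null(stage)) {
    stage <- unique(lesions$stage)
    assert_that(length(stage) == 1, "lesions span several stages; pass `stage`")
  }
  assert_stage(stage)
  les <- lesions[lesions$stage == stage, , drop = FALSE]
  ref <- measures[measures$stage == stage & measures$tissue == tissue, , drop = FALSE]
  if (!"in_range" %in% names(ref)) ref$in_range <- TRUE
  ref <- ref[ref$in_range, , drop = FALSE]
  idx <- match(les$patient_id, ref$patient_id)
  dropped <- sum(is.na(idx))
  keep <- !is.na(idx)
  if (dropped > 0)
    message(sprintf("%s/%s: dropped %d lesion(s) of patients with out-of-range %s uptake",
                    stage, tissue, dropped, tissue))
  if (!any(keep))
    stopf("zero eligible lesions for stage %s, tissue %s", stage, tissue)
  ratios <- les$min_suv[keep] / ref$mean_suv[idx[keep]]
  structure(mean(ratios), n_lesions = sum(keep), n_dropped = dropped)
}

#' Per-patient absolute SUV threshold under a criterion
#'
#' Criterion 1 multiplies the stage's relative threshold by the patient's
#' reference uptake; criteria 2 and 3 add one and two within-VOI standard
#' deviations to the reference uptake before multiplying:
#' `threshold = RT * (SUV_ref + n * SD_ref)`, n = 0, 1, 2.
#'
#' @param rt relative threshold (fraction, > 0).
#' @param mean_suv,sd_suv the patient's reference-tissue mean SUV and
#'   within-VOI SD.
#' @param n added standard deviations: 0 (criterion 1), 1 (criterion 2) or
#'   2 (criterion 3).
#' @return absolute SUV threshold (vectorized over patients).
#' @export
absolute_threshold <- function(rt, mean_suv, sd_suv, n) {
  assert_that(all(rt > 0), "relative threshold must be positive")
  assert_that(all(n %in% 0:2), "n must be 0, 1 or 2")
  assert_that(all(sd_suv >= 0), "sd_suv must be >= 0")
  rt * (mean_suv + n * sd_suv)
}

#' Reformulated relative threshold (criterion folded into one multiplier)
#'
#' For criteria 2 and 3 the per-patient threshold `RT * (SUV + n*SD)` is
#' re-expressed as a plain multiple of the reference uptake,
#' `RTtilde_j * SUV_j`, and the cohort value is the average over eligible
#' patients of the stage:
#' `RTtilde = (RT / N_pat) * sum_j (SUV_j + n*SD_j) / SUV_j`.
#' With n = 0 this reduces to RT exactly.
#'
#' @param rt minimum relative threshold of the stage/tissue.
#' @param measures data.frame of the eligible patients' reference measures
#'   at the stage: columns mean_suv (> 0) and sd_suv.
#' @param n added standard deviations (0, 1 or 2).
#' @return the reformulated relative threshold, with attribute `n_patients`.
#' @export
reformulated_threshold <- function(rt, measures, n) {
  assert_that(all(rt > 0), "relative threshold must be positive")
  assert_that(all(n %in% 0:2), "n must be 0, 1 or 2")
  assert_that(nrow(measures) >= 1, "no eligible patients at this stage")
  assert_that(all(measures$mean_suv > 0), "reference uptakes must be positive")
  assert_that(all(measures$sd_suv >= 0), "sd_suv must be >= 0")
  structure(rt * mean((measures$mean_suv + n * measures$sd_suv) / measures$mean_suv),
            n_patients = nrow(measures))
}

#' Build the full per-stage threshold table
#'
#' For every stage and reference tissue with eligible lesions: the minimum
#' relative threshold (RT), the reformulated thresholds for n = 0, 1, 2, and
#' the final threshold at the configured criterion. Criterion selection is a
#' configuration input (in the source study it came from qualitative expert
#' review): the shipped default is criterion 3 at baseline, 1 at iPET and
#' 2 at fPET. Display percentages round half-up to whole per cent; the
#' fraction columns keep full precision.
#'
#' @param measures reference measures (with `in_range` flags from
#'   [flag_measures()]; measures without flags are all eligible).
#' @param lesions lesion records (patient_id, stage, lesion_id, min_suv).
#' @param selected_criterion named integer vector, criterion (1, 2, 3) per
#'   stage.
#' @param tissues tissues to tabulate.
#' @return data.frame with one row per (stage, tissue): rt, rt_tilde_n0,
#'   rt_tilde_n1, rt_tilde_n2, final_rt, selected_criterion, n_lesions,
#'   n_dropped_lesions, n_patients, and display columns `rt_pct` /
#'   `final_pct`.
#' @export
build_threshold_table <- function(measures, lesions,
                                  selected_criterion = c(baseline = 3, iPET = 1, fPET = 2),
                                  tissues = c("liver", "marrow")) {
  assert_that(all(selected_criterion %in% 1:3),
              "selected criteria must be 1, 2 or 3")
  if (!"in_range" %in% names(measures)) measures$in_range <- TRUE
  stages <- flt_stages()[flt_stages() %in% unique(lesions$stage)]
  assert_that(length(stages) >= 1, "no stage with lesions")
  rows <- list()
  for (stage in stages) {
    stage_rows <- 0L
    for (tissue in tissues) {
      assert_that(stage %in% names(selected_criterion),
                  "no selected criterion configured for stage %s", stage)
      elig <- measures[measures$stage == stage & measures$tissue == tissue &
                         measures$in_range, , drop = FALSE]
      if (nrow(elig) == 0) next
      rt <- minimum_relative_threshold(lesions, measures, tissue, stage)
      tld <- vapply(0:2, function(n) as.numeric(reformulated_threshold(rt, elig, n)), 1)
      crit <- selected_criterion[[stage]]
      final <- tld[crit]  # criterion k uses n = k - 1
      rows[[length(rows) + 1]] <- data.frame(
        stage = stage, tissue = tissue,
        rt = as.numeric(rt),
        rt_tilde_n0 = tld[1], rt_tilde_n1 = tld[2], rt_tilde_n2 = tld[3],
        final_rt = final, selected_criterion = crit,
        n_lesions = attr(rt, "n_lesions"),
        n_dropped_lesions = attr(rt, "n_dropped"),
        n_patients = nrow(elig),
        rt_pct = round_half_up(100 * as.numeric(rt)),
        final_pct = round_half_up(100 * final),
        stringsAsFactors = FALSE)
      stage_rows <- stage_rows + 1L
    }
    if (stage_rows == 0L)
      stopf("zero eligible lesions at stage %s: no patient within any tissue's normal range", stage)
  }
  assert_that(length(rows) >= 1, "no eligible (stage, tissue) combination")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
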