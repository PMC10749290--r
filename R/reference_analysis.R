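#' Per cent relative change of uptake versus baseline
#'
#' `RC = 100 * (SUV_stage - SUV_baseline) / SUV_baseline`. Defined only for
#' patients with a baseline measurement; callers exclude such patients from
#' change plots, not from the cohort.
#'
#' @param suv_stage uptake at the later stage (SUV).
#' @param suv_baseline uptake at baseline (SUV, > 0); `NA` signals a missing
#'   baseline scan and raises a dedicated error.
#' @return relative change in per cent.
#' @export
relative_change <- function(suv_stage, suv_baseline) {
  if (any(is.na(suv_baseline)))
    stopf("missing baseline uptake: relative change is undefined for this patient")
  assert_that(all(suv_baseline > 0), "baseline uptake must be positive")
  100 * (suv_stage - suv_baseline) / suv_baseline
}

#' One-way ANOVA of per-stage reference uptake
#'
#' Classic fixed-effects one-way ANOVA of per-patient mean SUVs grouped by
#' stage, used to check that a reference tissue is stable along treatment.
#' The fully degenerate input (every group constant) is guarded: equal
#' constant groups return p = 1 by convention, unequal constant groups p = 0.
#'
#' @param measures data.frame with columns `stage` and `mean_suv` (one row
#'   per patient-stage measurement of one tissue).
#' @return list: `f`, `p`, `table` (per-stage n, mean, sd - a stability-table
#'   analogue), `df_between`, `df_within`.
#' @export
stage_anova <- function(measures) {
  assert_that(all(c("stage", "mean_suv") %in% names(measures)),
              "measures must have stage and mean_suv columns")
  g <- split(measures$mean_suv, factor(measures$stage, levels = flt_stages()), drop = TRUE)
  assert_that(length(g) >= 2, "ANOVA needs at least 2 stages with data")
  sizes <- vapply(g, length, 1L)
  assert_that(all(sizes >= 2), "every stage needs at least 2 measurements")
  tab <- data.frame(stage = names(g), n = as.integer(sizes),
                    mean_suv = vapply(g, mean, 1),
                    sd_suv = vapply(g, stats::sd, 1),
                    stringsAsFactors = FALSE)
  within_var <- vapply(g, stats::var, 1)
  if (all(within_var == 0)) {
    equal <- length(unique(vapply(g, function(x) x[1], 1))) == 1
    f <- if (equal) 0 else Inf
    p <- if (equal) 1 else 0
  } else {
    fit <- stats::oneway.test(mean_suv ~ stage, data = measures, var.equal = TRUE)
    f <- unname(fit$statistic)
    p <- unname(fit$p.value)
  }
  list(f = f, p = p, table = tab,
       df_between = length(g) - 1L, df_within = sum(sizes) - length(g))
}

#' Cohort normal uptake range of a reference tissue
#'
#' Pools every patient-stage measurement of one tissue and defines the
#' normal range as `pooled mean +/- 1 pooled SD` (sample SD, divisor N-1:
#' the cohort is a sample of the inter-patient spread, unlike the
#' within-VOI SD).
#'
#' @param mean_suv numeric vector of all measurements of the tissue, across
#'   all patients and stages (>= 2 values).
#' @param tissue label stored in the result.
#' @return object of class `normal_range`: tissue, pooled_mean, pooled_sd,
#'   low, high, n_measurements.
#' @export
normal_range <- function(mean_suv, tissue = "liver") {
  mean_suv <- as.numeric(mean_suv)
  assert_that(length(mean_suv) >= 2, "normal range needs at least 2 measurements")
  assert_that(all(is.finite(mean_suv)), "non-finite uptake measurements")
  m <- mean(mean_suv)
  s <- stats::sd(mean_suv)
  structure(list(tissue = tissue, pooled_mean = m, pooled_sd = s,
                 low = m - s, high = m + s,
                 n_measurements = length(mean_suv)),
            class = "normal_range")
}

#' @export
print.normal_range <- function(x, ...) {
  cat(sprintf("%s normal uptake range: %.1f +/- %.1f SUV -> [%.2f, %.2f] (n = %d)\n",
              x$tissue, x$pooled_mean, x$pooled_sd, x$low, x$high, x$n_measurements))
  invisible(x)
}

in_range <- function(x, rng) x >= rng$low & x <= rng$high  # inclusive bounds

#' Select the reference tissue for one patient-stage scan
#'
#' The liver is used whenever its uptake lies within the liver normal range
#' (quantifying liver uptake is simpler); otherwise the bone marrow is used
#' if within its own range; a scan with both tissues out of range is
#' excluded from threshold estimation and segmentation evaluation. Both
#' within-range flags are returned so that dual-eligible scans can also be
#' evaluated under the marrow-based thresholds.
#'
#' @param liver_mean,marrow_mean per-scan mean SUV of each tissue.
#' @param liver_range,marrow_range [normal_range()] objects.
#' @return list: `selected` (`"liver"`, `"marrow"` or `"excluded"`),
#'   `liver_in_range`, `marrow_in_range`.
#' @export
select_reference <- function(liver_mean, marrow_mean, liver_range, marrow_range) {
  assert_that(is.numeric(liver_mean) && is.numeric(marrow_mean) &&
              is.finite(liver_mean) && is.finite(marrow_mean),
              "both tissue measures are required")
  assert_that(inherits(liver_range, "normal_range") &&
              inherits(marrow_range, "normal_range"),
              "normal_range objects required")
  lin <- in_range(liver_mean, liver_range)
  min_ <- in_range(marrow_mean, marrow_range)
  selected <- if (lin) "liver" else if (min_) "marrow" else "excluded"
  list(selected = selected, liver_in_range = lin, marrow_in_range = min_)
}

#' Flag every measurement against its tissue's normal range
#'
#' @param measures data.frame with patient_id, stage, tissue, mean_suv.
#' @param ranges named list of [normal_range()] objects (`liver`, `marrow`).
#' @return `measures` with a logical `in_range` column.
#' @export
flag_measures <- function(measures, ranges) {
  assert_that(all(measures$tissue %in% names(ranges)),
              "a normal range is required for every tissue present")
  measures$in_range <- vapply(seq_len(nrow(measures)), function(i)
    in_range(measures$mean_suv[i], ranges[[measures$tissue[i]]]), logical(1))
  measures
}
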