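#' Default run configuration
#'
#' Synthetic-mode configuration for the full analysis. The shipped default
#' simulates a 16-patient cohort over the three treatment stages with the
#' study-condition uptake distributions, measures the references with the
#' 29 mm liver sphere and the T12 vertebra, and selects criterion 3 at
#' baseline, 1 at iPET and 2 at fPET.
#'
#' @param out_dir output directory for tables and reports.
#' @param seed master seed; every random draw in the run derives from it.
#' @param n_patients cohort size of the default synthetic spec.
#' @param ... overrides passed to [cohort_spec()].
#' @return a `run_config` list.
#' @export
default_run_config <- function(out_dir = tempfile("fltseg_run_"), seed = 1,
                               n_patients = 16, ...) {
  structure(list(
    mode = "synthetic",
    spec = cohort_spec(n_patients = n_patients, seed = seed, ...),
    manifest = NULL, cohort_dir = NULL, placement = NULL,
    voi = list(liver_choice = "sphere29", marrow_choice = "T12"),
    hu_range = c(150, 1500),
    selected_criterion = c(baseline = 3, iPET = 1, fPET = 2),
    connectivity = 26,
    sd_type = "population",
    normal_range_override = NULL,
    write_volumes = FALSE,
    out_dir = out_dir,
    seed = as.integer(seed)), class = "run_config")
}

#' Validate a run configuration without running it
#'
#' Collects every violation (unknown stages, bad criterion numbers, missing
#' files, bad connectivity, ...) instead of stopping at the first.
#'
#' @param config a run configuration list (see [default_run_config()]).
#' @return list with `valid` (logical) and `violations` (character vector).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  mode <- config$mode %||% ""
  if (!mode %in% c("synthetic", "cohort"))
    add(sprintf("mode: must be 'synthetic' or 'cohort', got '%s'", mode))
  if (mode == "synthetic" && !inherits(config$spec, "cohort_spec"))
    add("spec: synthetic mode requires a cohort_spec")
  if (mode == "cohort") {
    if (is.null(config$manifest) || !file.exists(config$manifest)) {
      add(sprintf("manifest: file not found: %s", config$manifest %||% "<missing>"))
    } else {
      man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
      need <- c("patient_id", "stage", "ct_path", "pet_path")
      miss <- setdiff(need, names(man))
      if (length(miss)) add(sprintf("manifest: missing column(s) %s", paste(miss, collapse = ", ")))
      if ("stage" %in% names(man) && !all(man$stage %in% flt_stages()))
        add(sprintf("manifest: unknown stage name(s): %s",
                    paste(setdiff(unique(man$stage), flt_stages()), collapse = ", ")))
      for (col in intersect(c("ct_path", "pet_path"), names(man))) {
        paths <- file.path(dirname(config$manifest), man[[col]])
        bad <- paths[!file.exists(paths)]
        for (b in bad) add(sprintf("manifest: referenced volume not found: %s", b))
      }
    }
    if (is.null(config$placement$liver_center_mm))
      add("placement: liver_center_mm required in cohort mode")
    if (is.null(config$placement$vertebra_boxes))
      add("placement: vertebra_boxes required in cohort mode")
  }
  sc <- config$selected_criterion
  if (is.null(sc) || is.null(names(sc)) || !all(names(sc) %in% flt_stages()))
    add("selected_criterion: must be named by stage (baseline/iPET/fPET)")
  if (!is.null(sc) && !all(sc %in% 1:3))
    add(sprintf("selected_criterion: criteria must be 1, 2 or 3 (got %s)",
                paste(sc[!sc %in% 1:3], collapse = ", ")))
  if (!(config$connectivity %||% 26) %in% c(6, 26))
    add("connectivity: must be 6 or 26")
  hr <- config$hu_range %||% c(150, 1500)
  if (length(hr) != 2 || hr[1] >= hr[2]) add("hu_range: must be an increasing pair")
  if (!is.null(config$voi)) {
    if (!(config$voi$liver_choice %||% "sphere29") %in% names(liver_sphere_diameters()))
      add(sprintf("voi.liver_choice: unknown choice '%s'", config$voi$liver_choice))
    if (!(config$voi$marrow_choice %||% "T12") %in% c("T12", "L3", "T10T11T12"))
      add(sprintf("voi.marrow_choice: unknown choice '%s'", config$voi$marrow_choice))
  }
  if (!is.character(config$out_dir %||% "") || !nzchar(config$out_dir %||% ""))
    add("out_dir: required")
  list(valid = length(v) == 0, violations = v)
}

# scan source abstraction: keys() gives the scan table, fetch(i) one scan
scan_source <- function(config) {
  if (config$mode == "synthetic") {
    spec <- config$spec
    params <- patient_params(spec)
    ph <- phantom_geometry(spec)
    keys <- expand.grid(patient_id = params$patient_ids, stage = spec$stages,
                        stringsAsFactors = FALSE)
    keys <- keys[order(match(keys$patient_id, params$patient_ids),
                       match(keys$stage, flt_stages())), ]
    rownames(keys) <- NULL
    placement <- list(liver_center_mm = ph$liver_center_mm,
                      vertebra_boxes = ph$vertebra_boxes,
                      hu_range = config$hu_range)
    fetch <- function(i) {
      sc <- generate_scan(spec, keys$patient_id[i], keys$stage[i], params)
      list(pair = sc$pair,
           reported_masks = sc$truth$lesion_masks,
           exclusion_mask = sc$truth$physiological_mask,
           placement = placement)
    }
  } else {
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    root <- dirname(config$manifest)
    keys <- man[, c("patient_id", "stage")]
    placement <- c(config$placement, list(hu_range = config$hu_range))
    fetch <- function(i) {
      meta <- NULL
      if (all(c("weight_kg", "activity_MBq") %in% names(man)) &&
          !is.na(man$weight_kg[i]) && !is.na(man$activity_MBq[i]))
        meta <- scan_meta(man$weight_kg[i], man$activity_MBq[i])
      pair <- load_pair(file.path(root, man$ct_path[i]), file.path(root, man$pet_path[i]),
                        man$patient_id[i], man$stage[i], meta = meta)
      read_masks <- function(cell) {
        if (is.null(cell) || is.na(cell) || !nzchar(cell)) return(list())
        lapply(strsplit(cell, ";", fixed = TRUE)[[1]], function(p) {
          m <- read_volume(file.path(root, p))
          resample_mask_to_pet(m$data > 0.5, m$geom, pair$geom)
        })
      }
      reported <- if ("lesion_mask_paths" %in% names(man)) read_masks(man$lesion_mask_paths[i]) else list()
      excl <- NULL
      if ("exclusion_mask_path" %in% names(man) && nzchar(man$exclusion_mask_path[i] %||% "")) {
        m <- read_volume(file.path(root, man$exclusion_mask_path[i]))
        excl <- resample_mask_to_pet(m$data > 0.5, m$geom, pair$geom)
      }
      list(pair = pair, reported_masks = reported, exclusion_mask = excl,
           placement = placement)
    }
  }
  list(keys = keys, fetch = fetch)
}

measure_scan <- function(scan, config) {
  lm <- reference_measure(scan$pair, "liver", config$voi$liver_choice,
                          placement = scan$placement, sd_type = config$sd_type)
  mm <- reference_measure(scan$pair, "marrow", config$voi$marrow_choice,
                          placement = scan$placement, sd_type = config$sd_type)
  lesions <- NULL
  if (length(scan$reported_masks) > 0) {
    mins <- vapply(scan$reported_masks, function(m) min(scan$pair$pet[m]), 1)
    lesions <- data.frame(patient_id = scan$pair$patient_id, stage = scan$pair$stage,
                          lesion_id = seq_along(mins), min_suv = mins,
                          stringsAsFactors = FALSE)
  }
  list(measures = rbind(lm, mm), lesions = lesions)
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full threshold-and-segmentation analysis
#'
#' Orchestrates the complete analysis: scan acquisition (synthetic phantom
#' generation or NIfTI cohort loading), reference-tissue VOI quantification,
#' stage-stability ANOVA and relative changes, cohort normal ranges,
#' eligibility flags, per-stage minimum and reformulated relative
#' thresholds, and threshold-based segmentation with detection counting and
#' MTV. All tables are written as CSV (plus JSON for ranges and the run
#' summary) under `config$out_dir`; rerunning with the same configuration
#' and seed reproduces the threshold and detection tables byte for byte.
#'
#' @param config a run configuration, e.g. [default_run_config()].
#' @return list with every computed table (`reference_measures`,
#'   `stability`, `relative_changes`, `normal_ranges`, `threshold_table`,
#'   `detection_table`, `mtv_table`, `summary`) plus `out_dir`.
#' @export
run_full_analysis <- function(config) {
  val <- validate_config(config)
  if (!val$valid)
    stopf("invalid configuration:\n  - %s", paste(val$violations, collapse = "\n  - "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  cat(sprintf("fltseg %s run, seed %d, mode %s\n",
              as.character(utils::packageVersion("fltseg")), config$seed, config$mode),
      file = log_path)

  src <- scan_source(config)
  n_scans <- nrow(src$keys)
  logf("stage voi-stats: %d scans", n_scans)

  # ---- pass 1: VOI quantification and lesion records -----------------------
  measures <- list(); lesions <- list()
  for (i in seq_len(n_scans)) {
    scan <- tryCatch(src$fetch(i), error = function(e)
      stopf("stage acquisition failed for %s/%s: %s",
            src$keys$patient_id[i], src$keys$stage[i], conditionMessage(e)))
    ms <- tryCatch(measure_scan(scan, config), error = function(e)
      stopf("stage voi-stats failed for %s/%s: %s",
            src$keys$patient_id[i], src$keys$stage[i], conditionMessage(e)))
    measures[[i]] <- ms$measures
    if (!is.null(ms$lesions)) lesions[[length(lesions) + 1]] <- ms$lesions
  }
  measures <- do.call(rbind, measures)
  lesions <- if (length(lesions)) do.call(rbind, lesions) else
    data.frame(patient_id = character(), stage = character(),
               lesion_id = integer(), min_suv = numeric(), stringsAsFactors = FALSE)
  rownames(measures) <- rownames(lesions) <- NULL

  # ---- stability and normal ranges ----------------------------------------
  stability <- list(); rc_rows <- list()
  for (tissue in c("liver", "marrow")) {
    mt <- measures[measures$tissue == tissue, , drop = FALSE]
    if (length(unique(mt$stage)) >= 2) {
      an <- stage_anova(mt)
      tab <- an$table
      tab$anova_p <- an$p
    } else {
      tab <- data.frame(stage = unique(mt$stage), n = nrow(mt),
                        mean_suv = mean(mt$mean_suv), sd_suv = stats::sd(mt$mean_suv),
                        anova_p = NA_real_, stringsAsFactors = FALSE)
    }
    tab$tissue <- tissue
    stability[[tissue]] <- tab
    base <- mt[mt$stage == "baseline", ]
    for (stage in setdiff(unique(mt$stage), "baseline")) {
      cur <- mt[mt$stage == stage, ]
      common <- intersect(cur$patient_id, base$patient_id)
      if (!length(common)) next
      rc_rows[[length(rc_rows) + 1]] <- data.frame(
        patient_id = common, stage = stage, tissue = tissue,
        relative_change_pct = relative_change(
          cur$mean_suv[match(common, cur$patient_id)],
          base$mean_suv[match(common, base$patient_id)]),
        stringsAsFactors = FALSE)
    }
  }
  stability <- do.call(rbind, stability)
  rownames(stability) <- NULL
  relative_changes <- if (length(rc_rows)) do.call(rbind, rc_rows) else
    data.frame(patient_id = character(), stage = character(), tissue = character(),
               relative_change_pct = numeric(), stringsAsFactors = FALSE)

  ranges <- config$normal_range_override %||% list(
    liver = normal_range(measures$mean_suv[measures$tissue == "liver"], "liver"),
    marrow = normal_range(measures$mean_suv[measures$tissue == "marrow"], "marrow"))
  measures <- flag_measures(measures, ranges)
  excluded <- measures[!measures$in_range, c("patient_id", "stage", "tissue")]
  if (nrow(excluded) > 0)
    logf("excluded from eligibility (out of normal range): %s",
         paste(sprintf("%s/%s/%s", excluded$patient_id, excluded$stage, excluded$tissue),
               collapse = ", "))

  # ---- thresholds ----------------------------------------------------------
  threshold_table <- tryCatch(
    build_threshold_table(measures, lesions, config$selected_criterion),
    error = function(e) stopf("stage thresholds failed: %s", conditionMessage(e)))

  # ---- pass 2: segmentation, detection, MTV --------------------------------
  det_parts <- list(); mtv_rows <- list()
  for (i in seq_len(n_scans)) {
    scan <- src$fetch(i)
    pid <- scan$pair$patient_id; stage <- scan$pair$stage
    mrow <- measures[measures$patient_id == pid & measures$stage == stage, ]
    ref <- list(
      liver = list(mean_suv = mrow$mean_suv[mrow$tissue == "liver"],
                   sd_suv = mrow$sd_suv[mrow$tissue == "liver"],
                   in_range = mrow$in_range[mrow$tissue == "liver"]),
      marrow = list(mean_suv = mrow$mean_suv[mrow$tissue == "marrow"],
                    sd_suv = mrow$sd_suv[mrow$tissue == "marrow"],
                    in_range = mrow$in_range[mrow$tissue == "marrow"]))
    entry <- list(pet = scan$pair$pet, spacing = scan$pair$geom$spacing,
                  exclusion_mask = scan$exclusion_mask,
                  reported_masks = scan$reported_masks,
                  stage = stage, patient_id = pid, ref = ref)
    det_parts[[i]] <- evaluate_criteria(list(entry), threshold_table,
                                        connectivity = config$connectivity)

    # selected-criterion segmentation for the per-scan MTV report, using the
    # tissue chosen by the reference-selection rule
    sel <- select_reference(ref$liver$mean_suv, ref$marrow$mean_suv,
                            ranges$liver, ranges$marrow)
    if (sel$selected != "excluded") {
      tt <- threshold_table[threshold_table$stage == stage &
                              threshold_table$tissue == sel$selected, , drop = FALSE]
      if (nrow(tt) == 1) {
        r <- ref[[sel$selected]]
        thr <- absolute_threshold(tt$rt, r$mean_suv, r$sd_suv, tt$selected_criterion - 1)
        seg <- segment_lesions(scan$pair$pet, thr, scan$pair$geom$spacing,
                               exclusion_mask = scan$exclusion_mask,
                               connectivity = config$connectivity)
        seg <- count_detections(seg, scan$reported_masks)
        mtv_rows[[length(mtv_rows) + 1]] <- data.frame(
          patient_id = pid, stage = stage, reference_tissue = sel$selected,
          criterion = tt$selected_criterion, threshold_suv = thr,
          n_components = seg$n_components,
          n_reported = length(scan$reported_masks),
          n_detected = if (length(scan$reported_masks)) sum(seg$detected) else 0L,
          mtv_ml = seg$total_mtv_ml, stringsAsFactors = FALSE)
        if (isTRUE(config$write_volumes))
          write_volume(seg$label_grid, scan$pair$geom,
                       file.path(config$out_dir, sprintf("%s_%s_labels.nii.gz", pid, stage)))
      }
    } else {
      logf("scan %s/%s excluded from segmentation (both tissues out of range)", pid, stage)
    }
  }
  det <- do.call(rbind, det_parts)
  detection_table <- stats::aggregate(
    cbind(n_reported, n_detected, total_mtv_ml) ~ stage + tissue + criterion,
    data = det, FUN = sum)
  detection_table <- detection_table[order(match(detection_table$stage, flt_stages()),
                                           detection_table$tissue,
                                           detection_table$criterion), ]
  detection_table$pct_detected <- ifelse(detection_table$n_reported > 0,
    round_half_up(100 * detection_table$n_detected / detection_table$n_reported), NA_real_)
  rownames(detection_table) <- NULL
  mtv_table <- if (length(mtv_rows)) do.call(rbind, mtv_rows) else
    data.frame(patient_id = character(), stage = character(),
               reference_tissue = character(), criterion = integer(),
               threshold_suv = numeric(), n_components = integer(),
               n_reported = integer(), n_detected = integer(), mtv_ml = numeric(),
               stringsAsFactors = FALSE)
  rownames(mtv_table) <- NULL

  # ---- outputs -------------------------------------------------------------
  write_table(src$keys, config$out_dir, "manifest.csv")
  write_table(measures, config$out_dir, "reference_measures.csv")
  write_table(lesions, config$out_dir, "lesion_records.csv")
  write_table(stability, config$out_dir, "stability_table.csv")
  write_table(relative_changes, config$out_dir, "relative_changes.csv")
  write_table(threshold_table, config$out_dir, "threshold_table.csv")
  write_table(detection_table, config$out_dir, "detection_table.csv")
  write_table(mtv_table, config$out_dir, "mtv_table.csv")
  ranges_plain <- lapply(ranges, function(r) r[c("tissue", "pooled_mean", "pooled_sd",
                                                 "low", "high", "n_measurements")])
  jsonlite::write_json(ranges_plain, file.path(config$out_dir, "normal_ranges.json"),
                       auto_unbox = TRUE, digits = NA)
  summary <- list(
    seed = config$seed, n_scans = n_scans,
    n_patients = length(unique(src$keys$patient_id)),
    n_lesions = nrow(lesions),
    normal_ranges = ranges_plain,
    anova_p = stats::setNames(
      as.list(stability$anova_p[!duplicated(stability$tissue)]),
      stability$tissue[!duplicated(stability$tissue)]),
    total_mtv_ml = sum(mtv_table$mtv_ml),
    overall_detection_rate = if (sum(mtv_table$n_reported) > 0)
      sum(mtv_table$n_detected) / sum(mtv_table$n_reported) else NA_real_)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("run complete: %d scans, %d lesions, total MTV %.2f ml",
       n_scans, nrow(lesions), sum(mtv_table$mtv_ml))

  invisible(list(reference_measures = measures, lesion_records = lesions,
                 stability = stability,
                 relative_changes = relative_changes, normal_ranges = ranges,
                 threshold_table = threshold_table, detection_table = detection_table,
                 mtv_table = mtv_table, summary = summary, out_dir = config$out_dir))
}
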