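test_that("cohort spec validates its inputs", {
  expect_s3_class(cohort_spec(n_patients = 2), "cohort_spec")
  expect_error(cohort_spec(liver_sd = -1), "SD")
  expect_error(cohort_spec(lesion_min_fraction = 0), "lesion_min_fraction")
  expect_error(cohort_spec(grid_shape = c(20, 20, 20)), "too small")
  expect_error(cohort_spec(grid_shape = c(64, 64, 30)), "too small")
})

test_that("identical spec and seed reproduce a scan exactly", {
  spec <- small_spec(n_patients = 2, seed = 31)
  a <- generate_scan(spec, 1, "baseline")
  b <- generate_scan(spec, 1, "baseline")
  expect_identical(a$pair$pet, b$pair$pet)
  expect_identical(a$pair$ct, b$pair$ct)
  expect_identical(a$truth$lesion_masks, b$truth$lesion_masks)
  # generation order does not matter: a scan fetched standalone equals the
  # same scan inside the full cohort
  coh <- generate_cohort(spec)
  expect_identical(coh[["P01.baseline"]]$pair$pet, a$pair$pet)
})

test_that("noiseless phantom has exact reference plateaus and controlled lesion minima", {
  spec <- small_spec(n_patients = 1, within_voi_cv = 0, seed = 5)
  sc <- generate_scan(spec, 1, "baseline")
  liver_vals <- sc$pair$pet[sc$truth$liver_mask]
  expect_equal(stats::sd(liver_vals), 0)
  expect_equal(unique(liver_vals), sc$truth$liver_true_suv)
  # realized lesion minimum equals the planted fraction of the reference
  frac <- spec$lesion_min_fraction[["baseline"]]
  for (k in seq_along(sc$truth$lesion_masks)) {
    realized <- min(sc$pair$pet[sc$truth$lesion_masks[[k]]])
    expect_equal(realized, frac * sc$truth$liver_true_suv, tolerance = 1e-12)
  }
})

test_that("lesion-free cohorts yield empty ground truth and zero segmented components", {
  spec <- small_spec(n_patients = 1, lesion_count_per_stage = 0,
                     within_voi_cv = 0, seed = 9)
  sc <- generate_scan(spec, 1, "iPET")
  expect_length(sc$truth$lesion_masks, 0)
  seg <- segment_lesions(sc$pair$pet, spec$background_suv * 1.5, sc$pair$geom$spacing,
                         exclusion_mask = sc$truth$physiological_mask)
  expect_equal(seg$n_components, 0)
})

test_that("ground-truth masks are pairwise disjoint and every lesion is non-empty", {
  spec <- small_spec(n_patients = 3, seed = 17)
  for (pid in 1:3) {
    sc <- generate_scan(spec, pid, "baseline")
    masks <- c(sc$truth$lesion_masks,
               list(sc$truth$liver_mask), sc$truth$vertebra_masks)
    for (m in sc$truth$lesion_masks) expect_gte(sum(m), 1)
    total <- Reduce(`+`, lapply(masks, function(m) as.integer(m)))
    expect_lte(max(total), 1)
  }
})

test_that("inter-patient liver draws follow the configured distribution", {
  spec <- cohort_spec(n_patients = 50, liver_mean = 5.1, liver_sd = 1.4, seed = 123)
  p <- fltseg:::patient_params(spec)
  se <- 1.4 / sqrt(50)
  expect_lt(abs(mean(p$liver_true) - 5.1), 3 * se)
  expect_gt(min(p$liver_true), 0.5)  # truncation floor
})

test_that("summary cohort shares per-patient true means with the volume cohort", {
  spec <- small_spec(n_patients = 2, seed = 77)
  s <- generate_summary_cohort(spec)
  for (pid in c("P01", "P02")) {
    sc <- generate_scan(spec, pid, "baseline")
    m <- s$measures
    expect_equal(m$mean_suv[m$patient_id == pid & m$stage == "baseline" & m$tissue == "liver"],
                 sc$truth$liver_true_suv)
    expect_equal(m$mean_suv[m$patient_id == pid & m$stage == "baseline" & m$tissue == "marrow"],
                 sc$truth$marrow_true_suv)
  }
})

test_that("summary cohort degenerate and large-sample behaviour", {
  # zero inter-patient spread: identical uptakes
  spec0 <- small_spec(n_patients = 5, liver_sd = 0, seed = 3)
  s0 <- generate_summary_cohort(spec0)
  lv <- s0$measures$mean_suv[s0$measures$tissue == "liver"]
  expect_equal(length(unique(lv)), 1)

  # noiseless lesion minima are exactly the planted fraction of the reference
  spec1 <- small_spec(n_patients = 4, within_voi_cv = 0, lesion_min_fraction = 0.5,
                      stages = "baseline", seed = 3)
  s1 <- generate_summary_cohort(spec1)
  m <- s1$measures[s1$measures$tissue == "liver" & s1$measures$stage == "baseline", ]
  ratio <- s1$lesions$min_suv / m$mean_suv[match(s1$lesions$patient_id, m$patient_id)]
  expect_equal(ratio, rep(0.5, nrow(s1$lesions)))

  # law of large numbers: empirical SD of marrow uptake near the spec SD
  spec2 <- cohort_spec(n_patients = 1000, marrow_mean = 7.8, marrow_sd = 2.7, seed = 11)
  s2 <- generate_summary_cohort(spec2)
  mar <- s2$measures$mean_suv[s2$measures$tissue == "marrow" &
                                s2$measures$stage == "baseline"]
  expect_lt(abs(stats::sd(mar) - 2.7) / 2.7, 0.10)
})

test_that("stage drift shifts the true uptake by the configured fraction", {
  spec <- small_spec(n_patients = 1, within_voi_cv = 0,
                     stage_drift = c(baseline = 0, iPET = 0.2, fPET = -0.1), seed = 8)
  b <- generate_scan(spec, 1, "baseline")
  i <- generate_scan(spec, 1, "iPET")
  f <- generate_scan(spec, 1, "fPET")
  expect_equal(i$truth$liver_true_suv, 1.2 * b$truth$liver_true_suv)
  expect_equal(f$truth$marrow_true_suv, 0.9 * b$truth$marrow_true_suv)
})
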