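test_that("segmentation thresholds strictly and labels deterministically", {
  pet <- array(1, c(8, 8, 8))
  # threshold above global max: nothing
  seg0 <- segment_lesions(pet, 2, c(2, 2, 2))
  expect_equal(seg0$n_components, 0)
  expect_equal(mtv(seg0), 0)

  # one supra-threshold blob: exactly its voxels, one component
  pet[2:3, 2:3, 2:3] <- 5
  seg1 <- segment_lesions(pet, 2, c(2, 2, 2))
  expect_equal(seg1$n_components, 1)
  expect_equal(seg1$component_voxels, 8L)
  expect_equal(sort(which(seg1$label_grid == 1)),
               which(pet > 2))
  # boundary-equal voxels are background (strict inequality)
  pet2 <- array(2, c(4, 4, 4))
  expect_equal(segment_lesions(pet2, 2, c(1, 1, 1))$n_components, 0)

  # deterministic ordering: largest component first, ties by seed voxel
  pet3 <- array(0.1, c(10, 10, 3))
  pet3[8:9, 8:9, 1:2] <- 3          # 8 voxels
  pet3[2, 2, 1] <- 3                # 1 voxel
  seg3 <- segment_lesions(pet3, 1, c(1, 1, 1))
  expect_equal(seg3$component_voxels, c(8L, 1L))
  expect_equal(seg3$label_grid[2, 2, 1], 2L)

  expect_error(segment_lesions(array(NA_real_, c(2, 2, 2)), 1, c(1, 1, 1)),
               "non-finite")
})

test_that("component counts agree with a flood-fill oracle", {
  for (case in 1:40) {
    set.seed(case)
    d <- sample(6:12, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < runif(1, 0.15, 0.5), d)
    conn <- if (case %% 2 == 0) 26 else 6
    lab <- label_components(mask, conn)
    expect_equal(max(lab), oracle_component_count(mask, conn))
    # labels partition the foreground
    expect_true(all((lab > 0) == mask))
  }
})

test_that("exclusion mask removes physiological uptake from labels and MTV", {
  pet <- array(0.5, c(10, 10, 10))
  pet[2:4, 2:4, 2:4] <- 8        # "bladder"
  pet[7:8, 7:8, 7:8] <- 4        # lesion
  excl <- array(FALSE, c(10, 10, 10)); excl[2:4, 2:4, 2:4] <- TRUE
  seg <- segment_lesions(pet, 1, c(2, 2, 2), exclusion_mask = excl)
  expect_equal(seg$n_components, 1)
  expect_equal(mtv(seg), 8 * 8 / 1000)   # 8 voxels at 8 mm^3
})

test_that("detection requires at least one foreground voxel per reported lesion", {
  pet <- array(0.5, c(10, 10, 6))
  pet[2:3, 2:3, 2:3] <- 5
  pet[7:8, 7:8, 2:3] <- 1.2
  masks <- list(a = array(FALSE, dim(pet)), b = array(FALSE, dim(pet)))
  masks$a[2:3, 2:3, 2:3] <- TRUE      # fully above threshold
  masks$b[7:8, 7:8, 2:3] <- TRUE      # fully below threshold 2
  seg <- count_detections(segment_lesions(pet, 2, c(1, 1, 1)), masks)
  expect_equal(unname(seg$detected), c(TRUE, FALSE))
  expect_equal(seg$detection_rate, 0.5)
  # all lesions supra-threshold -> rate 1
  seg2 <- count_detections(segment_lesions(pet, 1, c(1, 1, 1)), masks)
  expect_equal(seg2$detection_rate, 1.0)
})

test_that("foreground is nonincreasing in threshold and MTV matches an ellipsoid", {
  set.seed(50)
  pet <- array(runif(14^3, 0, 4), c(14, 14, 14))
  counts <- sapply(seq(0.5, 3.5, by = 0.5), function(th)
    sum(segment_lesions(pet, th, c(1, 1, 1))$label_grid > 0))
  expect_true(all(diff(counts) <= 0))

  # planted ellipsoid on a 1 mm grid: MTV within 5% of (4/3) pi abc
  geom <- grid_geometry(c(40, 36, 30), c(1, 1, 1))
  ctr <- c(19.5, 17.5, 14.5)
  semi <- c(10, 8, 6)
  pet2 <- array(0.4, geom$shape)
  pet2[ellipsoid_mask(geom, ctr, semi)] <- 2
  seg <- segment_lesions(pet2, 1, geom$spacing)
  analytic_ml <- 4 / 3 * pi * prod(semi) / 1000
  expect_lt(abs(mtv(seg) - analytic_ml) / analytic_ml, 0.05)
})

test_that("detected counts never increase from criterion 1 to 3", {
  spec <- small_spec(n_patients = 3, stages = "baseline",
                     lesion_count_per_stage = 3, seed = 13)
  s <- generate_summary_cohort(spec)
  ranges <- list(liver = normal_range(s$measures$mean_suv[s$measures$tissue == "liver"], "liver"),
                 marrow = normal_range(s$measures$mean_suv[s$measures$tissue == "marrow"], "marrow"))
  meas <- flag_measures(s$measures, ranges)
  tab <- suppressMessages(build_threshold_table(meas, s$lesions,
                                                selected_criterion = c(baseline = 1)))
  params <- fltseg:::patient_params(spec)
  scans <- lapply(params$patient_ids, function(pid) {
    sc <- generate_scan(spec, pid, "baseline", params)
    mrow <- meas[meas$patient_id == pid, ]
    list(pet = sc$pair$pet, spacing = sc$pair$geom$spacing,
         exclusion_mask = sc$truth$physiological_mask,
         reported_masks = sc$truth$lesion_masks,
         stage = "baseline", patient_id = pid,
         ref = list(
           liver = list(mean_suv = mrow$mean_suv[mrow$tissue == "liver"],
                        sd_suv = 0.13 * mrow$mean_suv[mrow$tissue == "liver"],
                        in_range = mrow$in_range[mrow$tissue == "liver"]),
           marrow = list(mean_suv = mrow$mean_suv[mrow$tissue == "marrow"],
                         sd_suv = 0.25 * mrow$mean_suv[mrow$tissue == "marrow"],
                         in_range = mrow$in_range[mrow$tissue == "marrow"])))
  })
  det <- evaluate_criteria(scans, tab)
  for (tis in unique(det$tissue)) {
    dd <- det[det$tissue == tis, ]
    dd <- dd[order(dd$criterion), ]
    expect_true(all(diff(dd$n_detected) <= 0))
    expect_true(all(diff(dd$total_mtv_ml) <= 0))
  }
})
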