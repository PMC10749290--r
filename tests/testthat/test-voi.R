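test_that("sphere mask membership is by voxel centre", {
  geom <- grid_geometry(c(11, 11, 11), c(2, 2, 2))
  ctr <- c(10, 10, 10)                          # exactly a voxel centre
  expect_equal(sum(sphere_mask(geom, ctr, 0.5)), 1)   # sub-voxel sphere: 1 voxel
  expect_error(sphere_mask(geom, c(500, 500, 500), 10), "captures no voxel")
  expect_equal(unname(liver_sphere_diameters()), c(29, 41, 48))
})

test_that("sphere voxel counts match brute force and converge to (pi/6)d^3", {
  # brute-force oracle on a coarse case
  geom <- grid_geometry(c(13, 13, 13), c(2.5, 2.5, 2.5))
  ctr <- c(15, 15, 15)
  m <- sphere_mask(geom, ctr, 21)
  expect_equal(sum(m), oracle_sphere_count(geom$shape, geom$spacing, ctr, 21))

  # volume error shrinks with spacing (2, 1, 0.5 mm) for the 29 mm preset
  analytic <- pi / 6 * 29^3
  err <- sapply(c(2, 1, 0.5), function(sp) {
    n <- ceiling(31 / sp)
    g <- grid_geometry(rep(n, 3), rep(sp, 3))
    ctr <- (g$shape - 1) / 2 * sp
    abs(sum(sphere_mask(g, ctr, 29)) * sp^3 - analytic) / analytic
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[2], 0.02)    # within 2% at 1 mm isotropic
})

test_that("vertebra delineation thresholds, keeps the largest component, fills holes", {
  geom <- grid_geometry(c(20, 20, 20), c(2, 2, 2))
  ct <- array(40, geom$shape)
  box <- list(lo = c(3, 3, 3), hi = c(16, 16, 16))
  # uniform bone box -> mask equals the whole search box content in range
  ct[5:12, 5:12, 5:12] <- 300
  m <- delineate_vertebra(ct, geom, box, c(150, 1500))
  expect_equal(sum(m), 8^3)
  # hollow body: interior below range is filled
  ct2 <- array(40, geom$shape)
  ct2[5:12, 5:12, 5:12] <- 300
  ct2[7:10, 7:10, 7:10] <- 80
  m2 <- delineate_vertebra(ct2, geom, box, c(150, 1500))
  expect_equal(sum(m2), 8^3)
  # a second, smaller bone fragment is discarded
  ct2[14:15, 14:15, 14:15] <- 400
  expect_equal(sum(delineate_vertebra(ct2, geom, box, c(150, 1500))), 8^3)
  # air box -> delineation error naming the range
  expect_error(delineate_vertebra(array(-1000, geom$shape), geom, box, c(150, 1500)),
               "no voxels in HU range")
})

test_that("phantom vertebrae are recovered from CT with high Dice", {
  spec <- small_spec(n_patients = 1, seed = 21)
  ph <- phantom_geometry(spec)
  sc <- generate_scan(spec, 1, "baseline")
  for (v in c("T12", "L3")) {
    m <- delineate_vertebra(sc$pair$ct, sc$pair$geom, ph$vertebra_boxes[[v]])
    tr <- sc$truth$vertebra_masks[[v]]
    dice <- 2 * sum(m & tr) / (sum(m) + sum(tr))
    expect_gte(dice, 0.95)
  }
})

test_that("voi_stats matches hand values, a scalar-loop oracle, and is order-invariant", {
  pet <- array(5, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4)); mask[2:3, 2:3, 2:3] <- TRUE
  st <- voi_stats(pet, mask, c(1, 1, 1))
  expect_equal(st$mean_suv, 5); expect_equal(st$sd_suv, 0); expect_equal(st$min_suv, 5)
  expect_equal(st$volume_ml, 8 / 1000)

  pet2 <- array(0, c(2, 2, 1)); pet2[1, 1, 1] <- 4; pet2[2, 1, 1] <- 6
  m2 <- array(FALSE, c(2, 2, 1)); m2[1:2, 1, 1] <- TRUE
  st2 <- voi_stats(pet2, m2, c(1, 1, 1))
  expect_equal(st2$mean_suv, 5)
  expect_equal(st2$sd_suv, 1)            # population SD over {4, 6}
  expect_equal(voi_stats(pet2, m2, c(1, 1, 1), sd_type = "sample")$sd_suv, sqrt(2))

  set.seed(33)
  pet3 <- array(runif(6 * 6 * 6, 0, 10), c(6, 6, 6))
  m3 <- array(runif(6 * 6 * 6) < 0.4, c(6, 6, 6))
  st3 <- voi_stats(pet3, m3, c(2, 2, 2))
  or <- oracle_voi_stats(pet3, m3)
  expect_equal(st3$mean_suv, or$mean_suv)
  expect_equal(st3$sd_suv, or$sd_suv)
  expect_equal(st3$min_suv, or$min_suv)
  expect_equal(st3$voxel_count, or$voxel_count)

  # permuting the volume (and mask identically) leaves the stats unchanged
  perm <- aperm(pet3, c(3, 1, 2)); permm <- aperm(m3, c(3, 1, 2))
  stp <- voi_stats(perm, permm, c(2, 2, 2))
  expect_equal(stp$mean_suv, st3$mean_suv)
  expect_equal(stp$sd_suv, st3$sd_suv)

  expect_error(voi_stats(pet3, array(FALSE, c(6, 6, 6)), c(2, 2, 2)), "empty")
})

test_that("reference_measure recovers true uptake on noiseless phantoms", {
  spec <- small_spec(n_patients = 1, within_voi_cv = 0, seed = 41)
  ph <- phantom_geometry(spec)
  sc <- generate_scan(spec, 1, "baseline")
  placement <- list(liver_center_mm = ph$liver_center_mm,
                    vertebra_boxes = ph$vertebra_boxes)
  for (choice in c("sphere29", "sphere41", "sphere48")) {
    lm <- reference_measure(sc$pair, "liver", choice, placement)
    expect_equal(lm$mean_suv, sc$truth$liver_true_suv, tolerance = 1e-10)
    expect_equal(lm$sd_suv, 0)
  }
  mm <- reference_measure(sc$pair, "marrow", "T12", placement)
  expect_equal(mm$mean_suv, sc$truth$marrow_true_suv, tolerance = 1e-10)

  # T10T11T12 pools the union of the three vertebrae
  mm3 <- reference_measure(sc$pair, "marrow", "T10T11T12", placement)
  n_union <- sum(sc$truth$vertebra_masks$T10 | sc$truth$vertebra_masks$T11 |
                   sc$truth$vertebra_masks$T12)
  expect_equal(mm3$voxel_count, n_union)
})
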