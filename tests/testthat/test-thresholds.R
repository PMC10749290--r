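test_that("minimum relative threshold is the mean of lesion/reference ratios", {
  meas <- data.frame(patient_id = c("P1", "P2"), stage = "baseline", tissue = "liver",
                     mean_suv = c(5, 4), sd_suv = 0)
  les <- data.frame(patient_id = c("P1", "P1", "P2"), stage = "baseline",
                    lesion_id = 1:3, min_suv = c(5, 2.5, 4))
  # identity ratios -> 1.0; one half-reference lesion pulls the mean down
  expect_equal(as.numeric(minimum_relative_threshold(
    les[c(1, 3), ], meas, "liver")), 1.0)
  expect_equal(as.numeric(minimum_relative_threshold(
    les[2, ], meas, "liver")), 0.5)
  rt <- minimum_relative_threshold(les, meas, "liver")
  expect_equal(as.numeric(rt), mean(c(1, 0.5, 1)))
  expect_equal(attr(rt, "n_lesions"), 3L)

  # lesions of out-of-range patients are dropped before averaging
  measf <- meas; measf$in_range <- c(TRUE, FALSE)
  expect_message(rtf <- minimum_relative_threshold(les, measf, "liver"), "dropped 1")
  expect_equal(as.numeric(rtf), mean(c(1, 0.5)))
  expect_equal(attr(rtf, "n_dropped"), 1L)

  measf$in_range <- FALSE
  expect_error(suppressMessages(minimum_relative_threshold(les, measf, "liver")),
               "zero eligible lesions for stage baseline, tissue liver")
})

test_that("mean-of-ratios equals a double-loop oracle on random cohorts", {
  for (case in 1:30) {
    set.seed(case)
    n_pat <- sample(3:10, 1)
    meas <- random_measures(n_pat, seed = case)
    n_les <- sample(5:50, 1)
    les <- data.frame(patient_id = sample(meas$patient_id, n_les, replace = TRUE),
                      stage = "baseline", lesion_id = seq_len(n_les),
                      min_suv = runif(n_les, 0.5, 4))
    rt <- minimum_relative_threshold(les, meas, "liver")
    expect_equal(as.numeric(rt), oracle_mean_ratio(les, meas, "liver", "baseline"))
  }
})

test_that("relative threshold is invariant to per-patient rescaling", {
  set.seed(99)
  meas <- random_measures(6)
  les <- data.frame(patient_id = rep(meas$patient_id, each = 3), stage = "baseline",
                    lesion_id = 1:18, min_suv = runif(18, 1, 4))
  rt0 <- as.numeric(minimum_relative_threshold(les, meas, "liver"))
  a <- runif(6, 0.2, 5)                    # per-patient scale factors
  meas2 <- meas; meas2$mean_suv <- meas2$mean_suv * a
  les2 <- les
  les2$min_suv <- les2$min_suv * a[match(les2$patient_id, meas$patient_id)]
  expect_equal(as.numeric(minimum_relative_threshold(les2, meas2, "liver")), rt0)
})

test_that("absolute thresholds follow RT * (SUV + n SD)", {
  expect_equal(absolute_threshold(0.33, 5.0, 0.7, 0), 1.65)
  expect_equal(absolute_threshold(0.49, 5.0, 0.5, 2), 0.49 * 6.0)
  # degenerate SD: all three criteria coincide
  expect_equal(absolute_threshold(0.4, 5, 0, 0),
               absolute_threshold(0.4, 5, 0, 2))
  expect_error(absolute_threshold(-0.1, 5, 0.5, 1), "positive")
  expect_error(absolute_threshold(0.4, 5, 0.5, 3), "n must be")
})

test_that("reformulated threshold reduces to RT at n = 0 and averages per patient", {
  meas1 <- data.frame(mean_suv = 5.0, sd_suv = 0.5)
  expect_equal(as.numeric(reformulated_threshold(0.49, meas1, 2)), 0.49 * 1.2)
  set.seed(21)
  meas <- random_measures(20)
  rt <- 0.37
  expect_identical(as.numeric(reformulated_threshold(rt, meas, 0)), rt)
  # per-patient algebraic oracle: solve RT(SUV + SD) = RTtilde_j * SUV, average
  tld1 <- as.numeric(reformulated_threshold(rt, meas, 1))
  per_patient <- sapply(seq_len(nrow(meas)), function(j)
    rt * (meas$mean_suv[j] + meas$sd_suv[j]) / meas$mean_suv[j])
  expect_equal(tld1, mean(per_patient))
})

test_that("cohort-mean consistency: RTtilde reproduces the criterion threshold on average", {
  set.seed(14)
  meas <- random_measures(25)
  rt <- 0.42
  for (n in 0:2) {
    tld <- as.numeric(reformulated_threshold(rt, meas, n))
    gap <- absolute_threshold(rt, meas$mean_suv, meas$sd_suv, n) - tld * meas$mean_suv
    expect_lt(abs(mean(gap / meas$mean_suv)), 1e-12)
  }
})

test_that("threshold table covers stages and tissues with the configured criteria", {
  set.seed(8)
  meas <- rbind(random_measures(8, "baseline"), random_measures(8, "iPET", seed = 9))
  meas <- rbind(meas,
                transform(meas, tissue = "marrow", mean_suv = mean_suv * 1.5))
  les <- data.frame(patient_id = rep(sprintf("P%02d", 1:8), 2),
                    stage = rep(c("baseline", "iPET"), each = 8),
                    lesion_id = 1:16, min_suv = runif(16, 1, 3))
  tab <- build_threshold_table(meas, les,
                               selected_criterion = c(baseline = 3, iPET = 1, fPET = 2))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$rt_tilde_n0, tab$rt)                       # n = 0 identity
  ipet <- tab[tab$stage == "iPET", ]
  expect_equal(ipet$final_rt, ipet$rt)                        # criterion 1 selected
  base <- tab[tab$stage == "baseline", ]
  expect_equal(base$final_rt, base$rt_tilde_n2)               # criterion 3 selected
  # monotone in n, strictly when some SD > 0
  expect_true(all(tab$rt_tilde_n0 < tab$rt_tilde_n1))
  expect_true(all(tab$rt_tilde_n1 < tab$rt_tilde_n2))
  # display respects round-half-up at whole percent
  expect_equal(tab$rt_pct, round_half_up(100 * tab$rt))

  # all patients out of range at one stage: error names the stage
  meas$in_range <- !(meas$stage == "iPET")
  expect_error(suppressMessages(build_threshold_table(meas, les)),
               "zero eligible lesions at stage iPET")
})

test_that("planted fraction is recovered from a noiseless summary cohort", {
  spec <- small_spec(n_patients = 10, stages = "baseline", within_voi_cv = 0,
                     lesion_min_fraction = 0.5, lesion_count_per_stage = 3, seed = 6)
  s <- generate_summary_cohort(spec)
  rt <- minimum_relative_threshold(s$lesions, s$measures, "liver")
  expect_equal(as.numeric(rt), 0.5, tolerance = 1e-12)
})
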