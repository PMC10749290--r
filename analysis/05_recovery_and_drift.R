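#!/usr/bin/env Rscript
# Step 5 - parameter recovery and sensitivity of the stability analysis.
#
# Two checks on the pipeline's statistical behaviour:
#   (a) planted-parameter recovery: summary cohorts with a known
#       lesion-minimum fraction are fed through the threshold estimator at
#       several noise levels; the estimated RT should sit on the planted
#       fraction with spread growing with the within-VOI CV;
#   (b) drift sensitivity: when a true per-stage drift is switched on in the
#       generator, the stage ANOVA that certifies reference stability must
#       start rejecting - stability is an empirical finding, not an
#       assumption baked into the analysis.

library(fltseg)

out <- "results/05_recovery"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# (a) recovery of the planted fraction across noise levels
rec <- do.call(rbind, lapply(c(0, 0.05, 0.13), function(cv) {
  do.call(rbind, lapply(1:5, function(rep) {
    spec <- cohort_spec(n_patients = 30, stages = "baseline",
                        lesion_count_per_stage = 100 / 30,
                        lesion_min_fraction = 0.5, within_voi_cv = cv,
                        seed = 1000 + 17 * rep + round(1e4 * cv))
    s <- generate_summary_cohort(spec)
    rt <- minimum_relative_threshold(s$lesions, s$measures, "liver")
    data.frame(within_voi_cv = cv, replicate = rep, rt_hat = as.numeric(rt),
               n_lesions = attr(rt, "n_lesions"))
  }))
}))
write.csv(rec, file.path(out, "fraction_recovery.csv"), row.names = FALSE)
cat("planted fraction 0.50 - estimated RT by noise level:\n")
print(aggregate(rt_hat ~ within_voi_cv, data = rec,
                FUN = function(x) c(mean = mean(x), max_abs_err = max(abs(x - 0.5)))))

# (b) the stage ANOVA flags a genuinely drifting reference
drift_p <- sapply(c(0, 0.05, 0.10, 0.20), function(dr) {
  spec <- cohort_spec(n_patients = 23, within_voi_cv = 0.02,
                      liver_sd = 0.5,
                      stage_drift = c(baseline = 0, iPET = dr, fPET = -dr),
                      seed = 7)
  s <- generate_summary_cohort(spec)
  stage_anova(s$measures[s$measures$tissue == "liver", ])$p
})
drift_tab <- data.frame(drift_fraction = c(0, 0.05, 0.10, 0.20), anova_p = drift_p)
write.csv(drift_tab, file.path(out, "drift_sensitivity.csv"), row.names = FALSE)
cat("\nANOVA p-value of liver stability vs injected per-stage drift:\n")
print(drift_tab)
cat("\nstable cohorts keep large p; drifting references are flagged.\n")
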