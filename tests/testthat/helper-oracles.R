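# Independent brute-force oracles used to cross-check the package's
# vectorized implementations on small instances.

# queue-based flood fill; returns number of connected components
oracle_component_count <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  offs <- as.matrix(offs)
  seen <- array(FALSE, d)
  count <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (seen[v[1], v[2], v[3]]) next
    count <- count + 1L
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  count
}

# scalar-loop VOI statistics (population SD)
oracle_voi_stats <- function(pet, mask) {
  vals <- c()
  d <- dim(pet)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) vals <- c(vals, pet[i, j, k])
  n <- length(vals)
  mu <- sum(vals) / n
  list(mean_suv = mu, sd_suv = sqrt(sum((vals - mu)^2) / n),
       min_suv = min(vals), max_suv = max(vals), voxel_count = n)
}

# explicit double loop over lesions for the stage mean-of-ratios
oracle_mean_ratio <- function(lesions, measures, tissue, stage) {
  total <- 0; n <- 0
  for (i in seq_len(nrow(lesions))) {
    if (lesions$stage[i] != stage) next
    for (j in seq_len(nrow(measures))) {
      if (measures$patient_id[j] == lesions$patient_id[i] &&
          measures$stage[j] == stage && measures$tissue[j] == tissue) {
        total <- total + lesions$min_suv[i] / measures$mean_suv[j]
        n <- n + 1
      }
    }
  }
  total / n
}

# brute-force voxel-centre count inside a sphere
oracle_sphere_count <- function(shape, spacing, center, diameter) {
  cnt <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) for (k in seq_len(shape[3])) {
    p <- (c(i, j, k) - 1) * spacing
    if (sum((p - center)^2) <= (diameter / 2)^2) cnt <- cnt + 1L
  }
  cnt
}

# small random reference-measure table
random_measures <- function(n_pat, stage = "baseline", tissue = "liver", seed = 1) {
  set.seed(seed)
  data.frame(patient_id = sprintf("P%02d", seq_len(n_pat)), stage = stage,
             tissue = tissue, mean_suv = runif(n_pat, 3, 8),
             sd_suv = runif(n_pat, 0, 1.5), stringsAsFactors = FALSE)
}

# compact phantom spec used by pipeline-level tests (coarser grid)
small_spec <- function(...) {
  cohort_spec(voxel_spacing = c(4, 4, 4), grid_shape = c(44L, 44L, 60L), ...)
}
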