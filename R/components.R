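neighbor_offsets <- function(connectivity = 26) {
  assert_that(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  lapply(seq_len(nrow(offs)), function(i) as.integer(offs[i, ]))
}

# Label propagation restricted to the foreground bounding box: every
# foreground voxel starts with its own linear index and repeatedly takes the
# minimum over its (6- or 26-) neighbourhood until a fixed point; voxels
# sharing a final value form one connected component.
label_min_propagate <- function(mask, connectivity) {
  d <- dim(mask)
  pd <- d + 2L
  i1 <- 2:(pd[1] - 1); i2 <- 2:(pd[2] - 1); i3 <- 2:(pd[3] - 1)
  lab <- array(Inf, pd)
  start <- array(Inf, d)
  start[mask] <- which(mask)
  lab[i1, i2, i3] <- start
  offs <- neighbor_offsets(connectivity)
  bg <- !mask
  repeat {
    cur <- lab[i1, i2, i3]
    new <- cur
    for (o in offs) {
      sh <- lab[i1 + o[1], i2 + o[2], i3 + o[3]]
      new <- pmin(new, sh)
    }
    new[bg] <- Inf
    if (all(new == cur)) break
    lab[i1, i2, i3] <- array(new, d)
  }
  cur
}

#' Label 3D connected components
#'
#' Labels the foreground of a binary 3D mask with 26-connectivity by default
#' (6-connectivity available). Label order is deterministic: components are
#' numbered by descending voxel count, ties broken by the smallest linear
#' index of a member voxel (the "seed" voxel, lexicographic in x, then y,
#' then z for column-major arrays).
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer array of the same shape; 0 is background, components are
#'   labelled 1..k.
#' @export
label_components <- function(mask, connectivity = 26) {
  assert_that(is.array(mask) && length(dim(mask)) == 3, "mask must be a 3D array")
  mask <- mask & !is.na(mask)
  d <- dim(mask)
  out <- array(0L, d)
  if (!any(mask)) return(out)

  # work on the tight foreground bounding box only
  w <- which(mask, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1L

  raw <- label_min_propagate(sub, connectivity)
  fg <- is.finite(raw)
  vals <- raw[fg]
  f <- factor(vals)
  sizes <- tabulate(f)
  seeds <- as.numeric(levels(f))          # seed = min linear index, equals the label value
  ord <- order(-sizes, seeds)
  relabel <- integer(length(seeds))
  relabel[ord] <- seq_along(ord)
  lab_sub <- array(0L, dim(sub))
  lab_sub[fg] <- relabel[as.integer(f)]
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lab_sub
  out
}

# Fill interior holes of a 3D mask: background components (6-connected) not
# touching the array border are converted to foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- label_components(bg, connectivity = 6)
  if (max(lab) == 0) return(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- unique(lab[border & bg])
  hole <- bg & !(lab %in% outside)
  mask | array(hole, d)
}

# Largest connected component of a mask (ties resolved by label order,
# i.e. smallest seed voxel).
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0) return(array(FALSE, dim(mask)))
  array(lab == 1L, dim(mask))
}
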