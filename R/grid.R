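#' Axis-aligned grid geometry
#'
#' Volumes are plain 3D arrays with an axis-aligned world mapping:
#' the world coordinate of 0-based voxel index `i` along an axis is
#' `origin + i * spacing`. Oblique orientations are rejected at load time.
#'
#' @param shape integer triplet, voxels per axis.
#' @param spacing mm triplet, strictly positive.
#' @param origin mm triplet, world coordinate of the first voxel centre.
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  assert_that(length(shape) == 3 && all(shape >= 1), "grid shape must be 3 positive integers")
  assert_that(length(spacing) == 3 && all(spacing > 0), "voxel spacing must be 3 positive numbers")
  assert_that(length(origin) == 3 && all(is.finite(origin)), "origin must be 3 finite numbers")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Voxel-centre world coordinates along one axis
#' @keywords internal
axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$shape[axis]) - 1) * geom$spacing[axis]
}

#' Physical voxel volume in ml
#' @keywords internal
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

#' World extent of the grid (mm, from first to last voxel centre edge-to-edge)
#' @keywords internal
grid_extent_mm <- function(geom) geom$shape * geom$spacing

# index range [lo, hi] (1-based, clipped) of voxels whose centres may fall
# within `radius_mm` of `center_mm` along each axis
bbox_indices <- function(geom, center_mm, radius_mm) {
  lo <- hi <- integer(3)
  for (a in 1:3) {
    lo[a] <- max(1L, 1L + as.integer(ceiling((center_mm[a] - radius_mm[a] - geom$origin[a]) / geom$spacing[a])))
    hi[a] <- min(geom$shape[a], 1L + as.integer(floor((center_mm[a] + radius_mm[a] - geom$origin[a]) / geom$spacing[a])))
  }
  if (any(hi < lo)) return(NULL)
  list(lo = lo, hi = hi)
}

# squared normalized ellipsoid radius over a bounding box; returns list with
# the box and an array r2 where r2 <= 1 is inside the ellipsoid
ellipsoid_r2_box <- function(geom, center_mm, semiaxes_mm) {
  bb <- bbox_indices(geom, center_mm, semiaxes_mm)
  if (is.null(bb)) return(NULL)
  cs <- lapply(1:3, function(a) {
    x <- geom$origin[a] + (seq(bb$lo[a], bb$hi[a]) - 1) * geom$spacing[a]
    ((x - center_mm[a]) / semiaxes_mm[a])^2
  })
  n <- bb$hi - bb$lo + 1L
  r2 <- array(rep(cs[[1]], times = n[2] * n[3]), n) +
    array(rep(rep(cs[[2]], each = n[1]), times = n[3]), n) +
    array(rep(cs[[3]], each = n[1] * n[2]), n)
  list(bb = bb, r2 = r2)
}

#' Rasterize an ellipsoid as a binary mask
#'
#' A voxel belongs to the ellipsoid iff its centre lies inside it
#' (membership by voxel centre, so masks are bit-stable for a given grid).
#'
#' @param geom a [grid_geometry()].
#' @param center_mm ellipsoid centre, mm.
#' @param semiaxes_mm semi-axis lengths, mm (axis-aligned).
#' @return logical array of the grid shape.
#' @export
ellipsoid_mask <- function(geom, center_mm, semiaxes_mm) {
  m <- array(FALSE, geom$shape)
  eb <- ellipsoid_r2_box(geom, center_mm, semiaxes_mm)
  if (is.null(eb)) return(m)
  sub <- eb$r2 <= 1
  m[eb$bb$lo[1]:eb$bb$hi[1], eb$bb$lo[2]:eb$bb$hi[2], eb$bb$lo[3]:eb$bb$hi[3]] <- sub
  m
}

#' Rasterize an axis-aligned box as a binary mask
#'
#' @param geom a [grid_geometry()].
#' @param center_mm box centre, mm.
#' @param halfsize_mm half edge lengths, mm.
#' @return logical array of the grid shape.
#' @export
box_mask <- function(geom, center_mm, halfsize_mm) {
  m <- array(FALSE, geom$shape)
  bb <- bbox_indices(geom, center_mm, halfsize_mm)
  if (is.null(bb)) return(m)
  m[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- TRUE
  m
}
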