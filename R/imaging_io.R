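#' Scan acquisition metadata
#'
#' Holds what is needed to convert an activity-concentration PET volume to
#' body-weight SUV. Injected activity per kilogram outside the protocol band
#' of 1.8-2.6 MBq/kg triggers a warning (not an error), since clinical
#' deviations occur.
#'
#' @param body_weight_kg patient weight in kg (> 0).
#' @param injected_activity_mbq decay-corrected injected activity in MBq (> 0).
#' @param injection_to_scan_min minutes from injection to acquisition
#'   (protocol: 60-70 min; informational only).
#' @return object of class `scan_meta`.
#' @export
scan_meta <- function(body_weight_kg, injected_activity_mbq,
                      injection_to_scan_min = NA_real_) {
  assert_that(is.numeric(body_weight_kg) && body_weight_kg > 0,
              "body weight must be positive")
  assert_that(is.numeric(injected_activity_mbq) && injected_activity_mbq > 0,
              "injected activity must be positive")
  per_kg <- injected_activity_mbq / body_weight_kg
  if (per_kg < 1.8 || per_kg > 2.6)
    warning(sprintf("injected activity %.2f MBq/kg outside the 1.8-2.6 MBq/kg protocol band",
                    per_kg), call. = FALSE)
  structure(list(body_weight_kg = as.numeric(body_weight_kg),
                 injected_activity_mbq = as.numeric(injected_activity_mbq),
                 injection_to_scan_min = as.numeric(injection_to_scan_min)),
            class = "scan_meta")
}

#' Convert activity concentration to body-weight SUV
#'
#' `SUV = concentration [kBq/ml] * weight [kg] / activity [MBq]`. The input
#' is assumed already decay-corrected by the scanner at reconstruction; no
#' decay correction is applied or removed here.
#'
#' @param concentration 3D array (or vector) of activity concentration in kBq/ml.
#' @param meta a [scan_meta()].
#' @return SUV array of the same shape.
#' @export
to_suv <- function(concentration, meta) {
  assert_that(inherits(meta, "scan_meta"), "meta must be a scan_meta object")
  assert_that(all(is.finite(concentration)), "concentration contains non-finite voxels")
  assert_that(all(concentration >= 0), "concentration must be non-negative")
  concentration * (meta$body_weight_kg / meta$injected_activity_mbq)
}

#' Co-registered CT/PET volume pair
#'
#' @param ct 3D array of Hounsfield units.
#' @param pet 3D array of SUV.
#' @param geom shared [grid_geometry()] (CT is resampled to the PET grid on
#'   load if the native grids differ).
#' @param patient_id scalar identifier.
#' @param stage one of `baseline`, `iPET`, `fPET`.
#' @return object of class `volume_pair`.
#' @export
volume_pair <- function(ct, pet, geom, patient_id, stage) {
  assert_stage(stage)
  assert_that(inherits(geom, "grid_geometry"), "geom must be a grid_geometry")
  assert_that(is.array(ct) && is.array(pet), "ct and pet must be arrays")
  assert_that(identical(dim(ct), dim(pet)), "ct and pet must share a shape")
  assert_that(all(dim(pet) == geom$shape), "volume shape does not match geometry")
  assert_that(all(is.finite(ct)) && all(is.finite(pet)),
              "volumes contain non-finite voxels")
  structure(list(ct = ct, pet = pet, geom = geom,
                 patient_id = as.character(patient_id), stage = stage),
            class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  cat(sprintf("volume_pair: patient %s, stage %s\n", x$patient_id, x$stage))
  print(x$geom)
  cat(sprintf("  PET SUV range [%.2f, %.2f]; CT HU range [%.0f, %.0f]\n",
              min(x$pet), max(x$pet), min(x$ct), max(x$ct)))
  invisible(x)
}

nifti_from <- function(arr, geom) {
  im <- RNifti::asNifti(arr)
  m <- diag(c(geom$spacing, 1))
  m[1:3, 4] <- geom$origin
  RNifti::qform(im) <- structure(m, code = 2L)
  RNifti::pixdim(im) <- geom$spacing
  im
}

geometry_from_nifti <- function(im, path = "<volume>") {
  x <- RNifti::xform(im)
  rot <- x[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stopf("oblique orientation in %s is not supported (axis-aligned volumes only)", path)
  if (any(diag(rot) <= 0))
    stopf("axis flips / non-positive scales in %s are not supported", path)
  d <- dim(im)
  assert_that(length(d) == 3, "%s is not a 3D volume", path)
  grid_geometry(d, diag(rot), x[1:3, 4])
}

#' Write a volume (with grid geometry) to NIfTI-1
#'
#' @param arr 3D array.
#' @param geom a [grid_geometry()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, geom, path) {
  RNifti::writeNifti(nifti_from(arr, geom), path)
  invisible(path)
}

#' Read a volume and its grid geometry from NIfTI-1
#'
#' @param path NIfTI file path.
#' @return list with `data` (3D array) and `geom` ([grid_geometry()]).
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  im <- RNifti::readNifti(path)
  geom <- geometry_from_nifti(im, path)
  arr <- array(as.vector(im), geom$shape)  # strip NIfTI attributes
  list(data = arr, geom = geom)
}

# Trilinear resampling of an axis-aligned volume onto a destination grid.
# Samples outside the source grid are clamped to the nearest edge voxel.
trilinear_resample <- function(vol, src_geom, dst_geom) {
  n <- dst_geom$shape
  ax <- vector("list", 3)
  for (a in 1:3) {
    # fractional (1-based) source index of each destination voxel centre
    t <- (axis_coords(dst_geom, a) - src_geom$origin[a]) / src_geom$spacing[a] + 1
    t <- pmin(pmax(t, 1), src_geom$shape[a])
    i0 <- pmin(floor(t), src_geom$shape[a] - 1)
    if (src_geom$shape[a] == 1) i0 <- rep(1, length(t))
    w <- t - i0
    ax[[a]] <- list(i0 = as.integer(i0), w = w)
  }
  rep3 <- function(v, axis) {
    if (axis == 1) rep(v, times = n[2] * n[3])
    else if (axis == 2) rep(rep(v, each = n[1]), times = n[3])
    else rep(v, each = n[1] * n[2])
  }
  sx <- src_geom$shape
  out <- numeric(prod(n))
  i0x <- rep3(ax[[1]]$i0, 1); wx <- rep3(ax[[1]]$w, 1)
  i0y <- rep3(ax[[2]]$i0, 2); wy <- rep3(ax[[2]]$w, 2)
  i0z <- rep3(ax[[3]]$i0, 3); wz <- rep3(ax[[3]]$w, 3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(i0x + dx, sx[1]); iy <- pmin(i0y + dy, sx[2]); iz <- pmin(i0z + dz, sx[3])
    wgt <- (if (dx == 1) wx else 1 - wx) *
           (if (dy == 1) wy else 1 - wy) *
           (if (dz == 1) wz else 1 - wz)
    lin <- ix + (iy - 1) * sx[1] + (iz - 1) * sx[1] * sx[2]
    out <- out + wgt * vol[lin]
  }
  array(out, n)
}

#' Load a co-registered CT/PET pair from NIfTI files
#'
#' SUV statistics are always computed on the native PET grid, so if the two
#' grids differ the CT is resampled onto the PET grid with trilinear
#' interpolation (never PET onto CT).
#'
#' @param ct_path,pet_path NIfTI files. The PET volume must already be in SUV
#'   units unless `meta` is supplied, in which case it is taken as activity
#'   concentration in kBq/ml and converted via [to_suv()].
#' @param patient_id,stage scan identity.
#' @param meta optional [scan_meta()] for SUV conversion.
#' @return a [volume_pair()] on the PET grid.
#' @export
load_pair <- function(ct_path, pet_path, patient_id, stage, meta = NULL) {
  ct <- read_volume(ct_path)
  pet <- read_volume(pet_path)
  if (!is.null(meta)) pet$data <- to_suv(pet$data, meta)
  if (!same_geometry(ct$geom, pet$geom)) {
    ct$data <- trilinear_resample(ct$data, ct$geom, pet$geom)
    ct$geom <- pet$geom
  }
  volume_pair(ct$data, pet$data, pet$geom, patient_id, stage)
}

#' Resample a binary mask onto the PET grid
#'
#' Nearest-neighbour resampling: each PET voxel centre is mapped to the
#' nearest source voxel; centres falling outside the source grid are
#' background. Masks delineated on a (typically finer) CT grid are carried
#' to the PET grid this way before any SUV statistic is taken.
#'
#' @param mask logical 3D array on the source grid.
#' @param src_geom source [grid_geometry()].
#' @param pet_geom destination (PET) [grid_geometry()].
#' @return logical array on the PET grid.
#' @export
resample_mask_to_pet <- function(mask, src_geom, pet_geom) {
  assert_that(is.array(mask) && length(dim(mask)) == 3, "mask must be a 3D array")
  assert_that(all(dim(mask) == src_geom$shape), "mask shape does not match source geometry")
  if (same_geometry(src_geom, pet_geom)) return(array(as.logical(mask), pet_geom$shape))
  n <- pet_geom$shape
  ax <- vector("list", 3)
  for (a in 1:3) {
    t <- round((axis_coords(pet_geom, a) - src_geom$origin[a]) / src_geom$spacing[a] + 1)
    ax[[a]] <- as.integer(t)  # may be out of range; handled below
  }
  ix <- rep(ax[[1]], times = n[2] * n[3])
  iy <- rep(rep(ax[[2]], each = n[1]), times = n[3])
  iz <- rep(ax[[3]], each = n[1] * n[2])
  inside <- ix >= 1 & ix <= src_geom$shape[1] &
            iy >= 1 & iy <= src_geom$shape[2] &
            iz >= 1 & iz <= src_geom$shape[3]
  out <- logical(prod(n))
  lin <- ix[inside] + (iy[inside] - 1) * src_geom$shape[1] +
         (iz[inside] - 1) * src_geom$shape[1] * src_geom$shape[2]
  out[inside] <- as.logical(mask[lin])
  array(out, n)
}

#' Write a volume pair (CT + PET) to a directory
#'
#' @param pair a [volume_pair()].
#' @param dir output directory (created if needed).
#' @return named character vector of the two paths, invisibly.
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- sprintf("%s_%s", pair$patient_id, pair$stage)
  ct_path <- file.path(dir, paste0(base, "_ct.nii.gz"))
  pet_path <- file.path(dir, paste0(base, "_pet.nii.gz"))
  write_volume(pair$ct, pair$geom, ct_path)
  write_volume(pair$pet, pair$geom, pet_path)
  invisible(c(ct = ct_path, pet = pet_path))
}
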