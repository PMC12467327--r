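#' CT volume container
#'
#' An ordered stack of axial CT slices with voxel spacing. Intensities are
#' Hounsfield units (HU); slice order is acquisition order. Internally the
#' intensity grid is a 3-D array indexed `[slice, row, col]` (1-based, the R
#' convention), so `x$slices[s, , ]` is the s-th axial slice as an H x W
#' matrix.
#'
#' @param slices 3-D numeric array, dim `(n_slices, height, width)`.
#' @param voxel_depth Through-plane spacing (slice thickness) in mm; > 0.
#' @param in_plane_spacing Numeric length-2, (row, col) pixel spacing in mm.
#' @param case_id Character identifier for the case.
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, c(4, 8, 8)), voxel_depth = 2.5)
#' dim(v$slices)
#' @export
ct_volume <- function(slices, voxel_depth = 1, in_plane_spacing = c(1, 1),
                      case_id = "case") {
  slices <- as.array(slices)
  if (length(dim(slices)) != 3L)
    stop("non-3D payload: expected (slice, row, col) array, got ",
         length(dim(slices)), " dimensions", call. = FALSE)
  if (!is.numeric(voxel_depth) || length(voxel_depth) != 1L || voxel_depth <= 0)
    stop("voxel_depth must be a single positive number", call. = FALSE)
  if (length(in_plane_spacing) != 2L || any(in_plane_spacing <= 0))
    stop("in_plane_spacing must be two positive numbers", call. = FALSE)
  structure(
    list(slices = slices, voxel_depth = as.numeric(voxel_depth),
         in_plane_spacing = as.numeric(in_plane_spacing),
         case_id = as.character(case_id)),
    class = "ct_volume")
}

#' Binary mask volume aligned with a CT volume
#'
#' Foreground (value 1) marks the aorta; everything else is 0.
#'
#' @param masks 3-D array with values in \{0, 1\}, dim `(n_slices, height, width)`.
#' @param case_id Character identifier.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(masks, case_id = "case") {
  masks <- as.array(masks)
  if (length(dim(masks)) != 3L)
    stop("non-3D payload: mask must be a (slice, row, col) array", call. = FALSE)
  u <- unique(as.vector(masks))
  if (!all(u %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  storage.mode(masks) <- "integer"
  structure(list(masks = masks, case_id = as.character(case_id)),
            class = "mask_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("CT volume '%s': %d slices of %d x %d, voxel depth %.4g mm, in-plane %.4g x %.4g mm\n",
              x$case_id, d[1], d[2], d[3], x$voxel_depth,
              x$in_plane_spacing[1], x$in_plane_spacing[2]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$slices), max(x$slices)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("Mask volume '%s': %d slices of %d x %d, %d foreground voxels\n",
              x$case_id, d[1], d[2], d[3], sum(x$masks)))
  invisible(x)
}

n_slices <- function(volume) dim(volume$slices)[1]

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$slices), dim(mask$masks)))
    stop("volume and mask shapes differ", call. = FALSE)
  invisible(TRUE)
}

#' Classify a case into a contrast-enhancement level
#'
#' Cases are split by how strongly the aortic blood pool is contrast-enhanced:
#' a mean foreground intensity above 250 HU is well contrasted ("1"), a mean
#' in the closed interval [100, 250] HU is poorly/non-contrasted ("2"), and
#' anything below 100 HU is "excluded". The boundary value 250 HU belongs to
#' Level 2 (Level 1 is strictly above 250).
#'
#' @param volume A [ct_volume()].
#' @param mask The paired [mask_volume()]; must contain at least one
#'   foreground voxel.
#' @param statistic Summary applied to the foreground HU values; the default
#'   is the mean.
#' @return `"1"`, `"2"`, or `"excluded"`.
#' @examples
#' v <- ct_volume(array(300, c(2, 4, 4)))
#' m <- mask_volume(array(1L, c(2, 4, 4)))
#' classify_level(v, m)  # "1"
#' @export
classify_level <- function(volume, mask, statistic = mean) {
  check_aligned(volume, mask)
  fg <- volume$slices[mask$masks == 1L]
  if (length(fg) == 0L)
    stop("empty mask: no foreground voxels to classify", call. = FALSE)
  s <- statistic(fg)
  if (s > 250) "1" else if (s >= 100) "2" else "excluded"
}
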