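#' Hounsfield intensity window
#'
#' Intensities are mapped affinely so `hu_min` becomes 0 and `hu_max` becomes
#' 1, with values outside the window clipped. Normalizing to a non-negative
#' range matters here because the downstream enhancement is multiplicative:
#' scaling a negative HU value by a factor > 1 would darken it instead of
#' brightening it. The default window (-100, 600) HU spans soft tissue
#' through strongly contrast-enhanced blood.
#'
#' @param hu_min,hu_max Window bounds in HU; `hu_min < hu_max`.
#' @return An object of class `hu_window`.
#' @export
hu_window <- function(hu_min = -100, hu_max = 600) {
  if (!is.finite(hu_min) || !is.finite(hu_max) || hu_min >= hu_max)
    stop("degenerate window: need hu_min < hu_max", call. = FALSE)
  structure(list(hu_min = hu_min, hu_max = hu_max), class = "hu_window")
}

#' Normalize a CT volume into a unit intensity window
#'
#' @param volume A [ct_volume()] in HU.
#' @param window A [hu_window()].
#' @return A [ct_volume()] with unitless intensities in [0, 1].
#' @examples
#' v <- ct_volume(array(250, c(1, 2, 2)))
#' normalize_hu(v, hu_window(-100, 600))$slices[1, 1, 1]  # 0.5
#' @export
normalize_hu <- function(volume, window = hu_window()) {
  stopifnot(inherits(window, "hu_window"))
  x <- (volume$slices - window$hu_min) / (window$hu_max - window$hu_min)
  volume$slices <- clamp(x, 0, 1)
  volume
}

#' Subsample a volume along the through-plane axis
#'
#' Keeps every `stride`-th slice starting at the first, emulating scans
#' acquired at larger voxel depth: a stride of 2 on a 0.625 mm volume yields
#' an effective depth of 1.25 mm, strides 4 and 8 yield 2.5 and 5.0 mm.
#'
#' @param volume A [ct_volume()] or [mask_volume()].
#' @param stride Integer >= 1 (and at most the slice count).
#' @return The subsampled object; for a `ct_volume` the voxel depth is
#'   multiplied by `stride`. Output slice count is `ceiling(S / stride)`.
#' @export
subsample_depth <- function(volume, stride) {
  if (stride < 1 || stride != round(stride))
    stop("stride must be a positive integer", call. = FALSE)
  stride <- as.integer(stride)
  if (inherits(volume, "mask_volume")) {
    S <- dim(volume$masks)[1]
    if (stride > S) stop("stride exceeds slice count", call. = FALSE)
    volume$masks <- volume$masks[seq(1L, S, by = stride), , , drop = FALSE]
    return(volume)
  }
  S <- n_slices(volume)
  if (stride > S) stop("stride exceeds slice count", call. = FALSE)
  volume$slices <- volume$slices[seq(1L, S, by = stride), , , drop = FALSE]
  volume$voxel_depth <- volume$voxel_depth * stride
  volume
}

#' Assemble overlapping 2.5D slice blocks
#'
#' Groups `n` consecutive slices into a block; consecutive blocks overlap in
#' `n - 1` slices (stride 1), so a volume of S slices yields `S - n + 1`
#' blocks and every slice from index `n` to `S` (1-based) is exactly one
#' block's target. The last slice of each block is the supervision and
#' evaluation target; earlier slices provide through-plane context.
#'
#' @param volume A [ct_volume()] (typically already normalized).
#' @param masks The aligned [mask_volume()], or `NULL` for inference-only
#'   blocks.
#' @param n Slices per block; >= 2. Default 4.
#' @return A list of `slice_block` objects with fields `slices`
#'   (n x H x W array), `masks` (or `NULL`), `start_index` (1-based index of
#'   the first slice in the source volume), `n`, and `case_id`.
#' @export
make_blocks <- function(volume, masks = NULL, n = 4L) {
  if (n < 2) stop("block size n must be >= 2", call. = FALSE)
  n <- as.integer(n)
  S <- n_slices(volume)
  if (S < n)
    stop(sprintf("case '%s' has %d slices, fewer than block size %d",
                 volume$case_id, S, n), call. = FALSE)
  if (!is.null(masks)) check_aligned(volume, masks)
  lapply(seq_len(S - n + 1L), function(s) {
    structure(list(
      slices = volume$slices[s:(s + n - 1L), , , drop = FALSE],
      masks = if (is.null(masks)) NULL else
        masks$masks[s:(s + n - 1L), , , drop = FALSE],
      start_index = s, n = n, case_id = volume$case_id),
      class = "slice_block")
  })
}

block_target_index <- function(block) block$start_index + block$n - 1L

#' Serialize / restore a block manifest
#'
#' Records `(case_id, start_index, n)` per block as JSON so a shuffled epoch
#' can be reproduced exactly.
#'
#' @param blocks List of `slice_block`s.
#' @param path JSON path.
#' @return `write_block_manifest` returns `path`; `read_block_manifest`
#'   returns a data frame.
#' @export
write_block_manifest <- function(blocks, path) {
  df <- data.frame(
    case_id = vapply(blocks, `[[`, "", "case_id"),
    start_index = vapply(blocks, `[[`, 0L, "start_index"),
    n = vapply(blocks, `[[`, 0L, "n"))
  jsonlite::write_json(df, path, dataframe = "rows")
  invisible(path)
}

#' @rdname write_block_manifest
#' @export
read_block_manifest <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
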