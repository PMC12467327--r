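#' Automatic spatial contrast configuration
#'
#' The enhancement map is built on a grid of `kernel_size` x `kernel_size`
#' kernels: a kernel whose mean previous-slice foreground probability
#' strictly exceeds `epsilon` is filled with the enhancement `factor`,
#' every other kernel with 1.0. Multiplying the next slice by this map
#' brightens regions the previous prediction placed the aorta in — a hard
#' (all-or-nothing) spatial attention gate.
#'
#' `factor` is 1.1 for well-contrasted (Level 1) data and 1.4 for
#' poorly-contrasted (Level 2) data in the reference setting; the kernel is
#' 16 x 16. `epsilon` defaults to 0.5, i.e. a kernel is enhanced when the
#' evidence for aorta covers more than half of it on average.
#'
#' @param kernel_size Kernel edge length, pixels; >= 1.
#' @param epsilon Mean-probability threshold in [0, 1]; since the comparison
#'   is strict, `epsilon = 1` disables enhancement entirely.
#' @param factor Multiplicative enhancement factor; >= 1.
#' @param binarize_first Threshold the probability map at 0.5 before the
#'   kernel means are taken (the kernel statistic is then a foreground
#'   fraction). Default `FALSE`: means are computed on the soft
#'   probabilities directly.
#' @return An object of class `asc_config`.
#' @export
asc_config <- function(kernel_size = 16L, epsilon = 0.5, factor = 1.1,
                       binarize_first = FALSE) {
  if (kernel_size < 1 || kernel_size != round(kernel_size))
    stop("kernel_size must be a positive integer", call. = FALSE)
  if (epsilon < 0 || epsilon > 1)
    stop("epsilon must be in [0, 1]", call. = FALSE)
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  structure(list(kernel_size = as.integer(kernel_size), epsilon = epsilon,
                 factor = factor, binarize_first = isTRUE(binarize_first)),
            class = "asc_config")
}

#' @export
print.asc_config <- function(x, ...) {
  cat(sprintf("ASC config: kernel %d x %d, epsilon %.3g, factor %.3g%s\n",
              x$kernel_size, x$kernel_size, x$epsilon, x$factor,
              if (x$binarize_first) ", binarized input" else ""))
  invisible(x)
}

#' Build a hard-attention enhancement map from a probability map
#'
#' The prediction is partitioned into `kernel_size` x `kernel_size` kernels
#' (zero-padded on the bottom/right when the shape is not a multiple of the
#' kernel; the map is cropped back, so boundary kernels are biased toward
#' non-enhancement). Each kernel whose mean value strictly exceeds
#' `cfg$epsilon` becomes `cfg$factor`; all others become 1.0. The result is
#' piecewise constant on the kernel grid and takes only the two values
#' \{1.0, factor\}.
#'
#' @param prediction Numeric matrix of per-pixel foreground probabilities in
#'   [0, 1] (the previous slice's prediction).
#' @param cfg An [asc_config()].
#' @return A numeric matrix of per-pixel multipliers, same shape as
#'   `prediction`.
#' @examples
#' p <- matrix(0, 32, 32); p[1:16, 1:16] <- 1
#' em <- build_enhancement_map(p, asc_config(16, 0.5, 1.4))
#' unique(as.vector(em))  # 1.4 and 1.0
#' @export
build_enhancement_map <- function(prediction, cfg) {
  stopifnot(inherits(cfg, "asc_config"))
  if (!is.matrix(prediction)) prediction <- as.matrix(prediction)
  if (any(!is.finite(prediction)))
    stop("non-finite prediction values", call. = FALSE)
  ks <- cfg$kernel_size
  if (cfg$binarize_first) prediction <- (prediction >= 0.5) + 0
  H <- nrow(prediction); W <- ncol(prediction)
  Hp <- ks * ceiling(H / ks); Wp <- ks * ceiling(W / ks)
  if (Hp != H || Wp != W) {
    padded <- matrix(0, Hp, Wp)
    padded[seq_len(H), seq_len(W)] <- prediction
  } else padded <- prediction
  # kernel means: fold (Hp, Wp) into (ks, Hp/ks, ks, Wp/ks), average axes 1, 3
  kb <- array(padded, c(ks, Hp %/% ks, ks, Wp %/% ks))
  kmeans_grid <- apply(kb, c(2, 4), mean)
  kvals <- ifelse(kmeans_grid > cfg$epsilon, cfg$factor, 1.0)
  full <- kvals[rep(seq_len(nrow(kvals)), each = ks),
                rep(seq_len(ncol(kvals)), each = ks), drop = FALSE]
  full[seq_len(H), seq_len(W), drop = FALSE]
}

#' Apply an enhancement map to a slice
#'
#' Pixel-wise multiplication `x * e_m`; pixels under map value 1.0 are
#' returned bit-identical, and no clipping is applied (enhanced normalized
#' intensities may exceed 1 — deliberately, since clipping would remove the
#' added contrast).
#'
#' @param slice_image Numeric matrix of (normalized) intensities.
#' @param e_m Enhancement map matrix of the same shape.
#' @return The enhanced slice.
#' @export
apply_enhancement <- function(slice_image, e_m) {
  if (!identical(dim(slice_image), dim(e_m)))
    stop("shape mismatch between slice and enhancement map", call. = FALSE)
  slice_image * e_m
}

#' One recurrent enhancement step
#'
#' Builds the enhancement map from the previous slice's prediction and
#' applies it to the next slice: the composition
#' `apply_enhancement(next_slice, build_enhancement_map(prev_prediction, cfg))`.
#'
#' @param prev_prediction Probability matrix predicted for the previous slice.
#' @param next_slice Intensity matrix of the slice to enhance.
#' @param cfg An [asc_config()].
#' @return The enhanced slice.
#' @export
enhance_step <- function(prev_prediction, next_slice, cfg) {
  apply_enhancement(next_slice, build_enhancement_map(prev_prediction, cfg))
}
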