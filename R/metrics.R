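#' Confusion counts between binary prediction and ground truth
#'
#' Exact indicator sums over all pixels/voxels: TP counts positions where
#' both prediction and ground truth are 1, FP where only the prediction is,
#' FN where only the ground truth is, TN where neither is.
#'
#' @param P Binary prediction (matrix or array, values 0/1).
#' @param G Binary ground truth, same shape.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(P, G) {
  if (!identical(dim(P), dim(G)))
    stop("shape mismatch between prediction and ground truth", call. = FALSE)
  p <- as.vector(P); g <- as.vector(G)
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("non-binary input", call. = FALSE)
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  c(TP = tp, FP = fp, FN = fn, TN = length(p) - tp - fp - fn)
}

dsc_from_counts <- function(TP, FP, FN) {
  den <- 2 * TP + FP + FN
  if (den == 0) 1.0 else 2 * TP / den
}

iou_from_counts <- function(TP, FP, FN) {
  den <- TP + FP + FN
  if (den == 0) 1.0 else TP / den
}

#' Dice similarity coefficient and intersection-over-union
#'
#' `DSC = 2 TP / (2 TP + FP + FN)` and `IoU = TP / (TP + FP + FN)`; the two
#' are linked by `DSC = 2 IoU / (1 + IoU)` and `DSC >= IoU` always. When
#' prediction and ground truth are both empty the formulas are 0/0; by
#' convention both metrics are then 1.0 (perfect agreement on absence),
#' while empty-vs-non-empty is 0.0.
#'
#' @param P,G Binary masks of identical shape.
#' @return A number in [0, 1].
#' @examples
#' P <- matrix(c(1, 1, 1, 0), 2); G <- matrix(c(1, 1, 0, 1), 2)
#' dsc(P, G)  # 2*2 / (2*2 + 1 + 1) = 2/3
#' iou(P, G)  # 2 / 4 = 0.5
#' @export
dsc <- function(P, G) {
  cc <- confusion_counts(P, G)
  dsc_from_counts(cc["TP"], cc["FP"], cc["FN"])[[1]]
}

#' @rdname dsc
#' @export
iou <- function(P, G) {
  cc <- confusion_counts(P, G)
  iou_from_counts(cc["TP"], cc["FP"], cc["FN"])[[1]]
}

#' Bundle confusion counts with overlap metrics
#'
#' @param TP,FP,FN,TN Non-negative integer counts.
#' @return An object of class `metrics_result` with fields `TP`, `FP`, `FN`,
#'   `TN`, `N`, `DSC`, `IoU`.
#' @export
metrics_result <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, N = TP + FP + FN + TN,
                 DSC = dsc_from_counts(TP, FP, FN),
                 IoU = iou_from_counts(TP, FP, FN)),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("DSC %.4f | IoU %.4f  (TP %d, FP %d, FN %d, TN %d; N = %d)\n",
              x$DSC, x$IoU, x$TP, x$FP, x$FN, x$TN, x$N))
  invisible(x)
}

#' Per-pixel difference map
#'
#' Categorizes every pixel as TN, TP, FN or FP for qualitative error
#' inspection. The standard rendering is black for true negatives, white for
#' true positives, blue for false negatives and red for false positives.
#'
#' @param P,G Binary masks (matrices) of identical shape.
#' @return An integer matrix of class `difference_map` with values 0 (TN),
#'   1 (TP), 2 (FN), 3 (FP) and a `legend` attribute.
#' @export
difference_map <- function(P, G) {
  if (!identical(dim(P), dim(G)))
    stop("shape mismatch", call. = FALSE)
  if (!all(P %in% c(0, 1)) || !all(G %in% c(0, 1)))
    stop("non-binary input", call. = FALSE)
  m <- matrix(0L, nrow(P), ncol(P))
  m[P == 1 & G == 1] <- 1L
  m[P == 0 & G == 1] <- 2L
  m[P == 1 & G == 0] <- 3L
  structure(m, legend = c(`0` = "TN", `1` = "TP", `2` = "FN", `3` = "FP"),
            class = c("difference_map", "matrix", "array"))
}

#' Render a difference map as RGB
#'
#' @param dm A [difference_map()].
#' @param path Optional PNG output path.
#' @return An H x W x 3 array in [0, 1] (invisibly when writing a file).
#' @export
render_difference_map <- function(dm, path = NULL) {
  colors <- rbind(TN = c(0, 0, 0), TP = c(1, 1, 1),
                  FN = c(0, 0, 1), FP = c(1, 0, 0))
  rgb <- array(0, c(nrow(dm), ncol(dm), 3))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(colors[as.vector(dm) + 1L, ch], nrow(dm), ncol(dm))
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

#' Sensitivity of the Dice coefficient to false positives
#'
#' The derivative of `DSC = 2 TP / (2 TP + FP + FN)` with respect to the
#' false-positive count: `-2 TP / (2 TP + FP + FN)^2`. It is never positive
#' — adding a false positive cannot raise the Dice score — and its magnitude
#' is smaller than the corresponding IoU sensitivity, which is why IoU
#' penalizes false-positive area more stringently than Dice.
#'
#' @param TP,FP,FN Non-negative counts; `2*TP + FP + FN` must be positive.
#' @return The (non-positive) per-pixel rate.
#' @examples
#' dsc_fp_sensitivity(1, 0, 0)  # -0.5
#' @export
dsc_fp_sensitivity <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  den <- 2 * TP + FP + FN
  if (den == 0) stop("all-zero counts: sensitivity undefined", call. = FALSE)
  -2 * TP / den^2
}
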