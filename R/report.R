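#' Relative cost of the enhancement step
#'
#' Under the standard cost model (fixed kernel size and depth), a
#' convolutional encoder-decoder spends on the order of `N * B^2` operations
#' per slice, where N is the pixel count and B the channel width after the
#' first convolution. The enhancement map costs only element-wise work,
#' O(N), so its cost relative to the segmenter is about `1 / B^2` — for
#' B = 64, one 4096th — and the combined per-slice complexity stays
#' O(N B^2).
#'
#' @param B Channel width after the first convolution; >= 1.
#' @return `1 / B^2`.
#' @examples
#' asc_cost_fraction(64)  # 1/4096
#' @export
asc_cost_fraction <- function(B) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  1 / B^2
}

#' FLOPs per target slice for a block of m slices
#'
#' Processing a block means m sequential sub-model passes to produce one
#' target-slice prediction, so the per-target-slice figure is m times the
#' single-slice FLOPs: the headline reporting convention. The enhancement
#' map's own O(N) arithmetic is excluded from this figure and reported
#' separately (see [asc_step_flops()]).
#'
#' @param per_slice_flops FLOPs of one sub-model pass on one slice.
#' @param m Slices per block.
#' @return `m * per_slice_flops`.
#' @examples
#' flops_per_target_slice(73.50e9, 4)   # 294 GFLOPs
#' flops_per_target_slice(524.53e9, 4)  # 2098.12 GFLOPs
#' @export
flops_per_target_slice <- function(per_slice_flops, m) {
  stopifnot(per_slice_flops > 0, m >= 1)
  m * per_slice_flops
}

#' Element-wise FLOPs of one enhancement step
#'
#' Building the map touches every pixel once for the kernel means, once for
#' the threshold broadcast, and the application multiplies every pixel: about
#' 3 operations per pixel, i.e. O(N) independent of channel width.
#'
#' @param H,W Slice dimensions in pixels.
#' @return Approximate FLOP count.
#' @export
asc_step_flops <- function(H, W) 3 * H * W

#' Analytic FLOPs of the reference segmenter
#'
#' Counts convolution multiply-accumulates (2 FLOPs each) plus bias adds
#' over all layers for one forward pass at the given resolution; pooling,
#' upsampling and the softmax are excluded, following the usual convention
#' of reporting convolutional cost.
#'
#' @param cfg A [ref_unet_config()].
#' @param H,W Input resolution; divisible by `2^depth`.
#' @return FLOP count (double).
#' @export
unet_flops <- function(cfg, H = 512L, W = 512L) {
  stopifnot(inherits(cfg, "ref_unet_config"))
  ch <- unet_channels(cfg)
  conv_cost <- function(h, w, cin, cout, k = 3)
    h * w * cout * (2 * k * k * cin + 1)
  total <- 0
  h <- H; w <- W
  cin <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    co <- ch$enc[i]
    total <- total + conv_cost(h, w, cin, co) + conv_cost(h, w, co, co)
    cin <- co
    h <- h %/% 2L; w <- w %/% 2L
  }
  total <- total + conv_cost(h, w, cin, ch$bottleneck) +
    conv_cost(h, w, ch$bottleneck, ch$bottleneck)
  cup <- ch$bottleneck
  for (i in rev(seq_len(cfg$depth))) {
    h <- h * 2L; w <- w * 2L
    co <- ch$enc[i]
    total <- total + conv_cost(h, w, cup + co, co) + conv_cost(h, w, co, co)
    cup <- co
  }
  total + conv_cost(H, W, ch$enc[1], cfg$n_classes, k = 1)
}

#' Improvement deltas between a baseline and an augmented result table
#'
#' Rows are matched by their label columns (every column except the metric
#' columns); per-row deltas `dsc_aug - dsc_base` and `iou_aug - iou_base`
#' are computed and the maxima over all rows reported. Maxima are invariant
#' to row order. When both tables carry an `n_params` column, paired rows
#' must agree (the enhancement adds no parameters).
#'
#' @param baseline,augmented Data frames with columns `dsc` and `iou`
#'   (percent), plus shared label columns (e.g. `model`, `level`).
#' @return An object of class `improvement_table`: list with `table` (the
#'   per-row deltas), `max_delta_dsc`, `max_delta_iou`.
#' @export
improvement_table <- function(baseline, augmented) {
  metric_cols <- c("dsc", "iou")
  if (!all(metric_cols %in% names(baseline)) ||
      !all(metric_cols %in% names(augmented)))
    stop("tables need 'dsc' and 'iou' columns", call. = FALSE)
  keys <- setdiff(intersect(names(baseline), names(augmented)),
                  c(metric_cols, "n_params", "flops", "with_asc"))
  if (length(keys) == 0) {
    if (nrow(baseline) != nrow(augmented))
      stop("label mismatch: tables have different row counts", call. = FALSE)
    merged <- cbind(baseline[metric_cols],
                    stats::setNames(augmented[metric_cols],
                                    c("dsc_aug", "iou_aug")))
  } else {
    merged <- merge(baseline, augmented, by = keys,
                    suffixes = c("", "_aug"))
    if (nrow(merged) != nrow(baseline) || nrow(merged) != nrow(augmented))
      stop("label mismatch between baseline and augmented tables",
           call. = FALSE)
    if (all(c("n_params", "n_params_aug") %in% names(merged)) &&
        !isTRUE(all.equal(merged$n_params, merged$n_params_aug)))
      stop("paired rows must share parameter counts", call. = FALSE)
  }
  merged$delta_dsc <- merged$dsc_aug - merged$dsc
  merged$delta_iou <- merged$iou_aug - merged$iou
  structure(list(table = merged,
                 max_delta_dsc = max(merged$delta_dsc),
                 max_delta_iou = max(merged$delta_iou)),
            class = "improvement_table")
}

#' @export
print.improvement_table <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("max delta DSC = %.2f, max delta IoU = %.2f\n",
              x$max_delta_dsc, x$max_delta_iou))
  invisible(x)
}

#' Ablation harness over block size, kernel size and voxel-depth stride
#'
#' Trains and evaluates one model per grid cell under shared seeds, so every
#' cell starts from identical initial weights. Stride cells re-derive the
#' voxel depth via [subsample_depth()] (e.g. a 0.625 mm volume becomes
#' 1.25 / 2.5 / 5.0 mm at strides 2 / 4 / 8). Cells whose kernel exceeds the
#' image or whose subsampled/blocked geometry is infeasible raise an error.
#'
#' @param train_volumes,train_masks Lists of training [ct_volume()] /
#'   [mask_volume()] pairs.
#' @param test_volume,test_mask Held-out case for evaluation.
#' @param block_sizes,kernel_sizes,strides Grid axes.
#' @param factor Enhancement factor.
#' @param epsilon Kernel threshold.
#' @param control [train_control()] (shared across cells).
#' @param seg_cfg [ref_unet_config()] for the per-cell segmenter.
#' @param window [hu_window()].
#' @param include_baseline Also train/evaluate the unenhanced baseline per
#'   cell (paired rows share parameter counts).
#' @param seed Seed driving segmenter initialization for every cell.
#' @return A data frame (class `result_table`): one row per cell (and per
#'   baseline row if requested) with columns `block_size, kernel_size,
#'   stride, voxel_depth_mm, with_asc, dsc, iou, n_params, flops_per_target,
#'   init_checksum`. DSC/IoU are percentages rounded to 2 decimals.
#' @export
ablation_harness <- function(train_volumes, train_masks, test_volume,
                             test_mask, block_sizes = c(2L, 3L, 4L),
                             kernel_sizes = 16L, strides = 1L,
                             factor = 1.4, epsilon = 0.5,
                             control = train_control(),
                             seg_cfg = ref_unet_config(channel_width = 8L,
                                                       depth = 2L),
                             window = hu_window(),
                             include_baseline = FALSE, seed = 1L) {
  if (inherits(train_volumes, "ct_volume")) train_volumes <- list(train_volumes)
  if (inherits(train_masks, "mask_volume")) train_masks <- list(train_masks)
  H <- dim(test_volume$slices)[2]; W <- dim(test_volume$slices)[3]
  rows <- list()
  for (ksz in kernel_sizes) {
    if (ksz > min(H, W))
      stop(sprintf("infeasible cell: kernel %d exceeds image %d x %d",
                   ksz, H, W), call. = FALSE)
    for (m in block_sizes) for (st in strides) {
      sub_tr_v <- lapply(train_volumes, subsample_depth, stride = st)
      sub_tr_m <- lapply(train_masks, subsample_depth, stride = st)
      sub_te_v <- subsample_depth(test_volume, st)
      sub_te_m <- subsample_depth(test_mask, st)
      cfg <- asc_config(kernel_size = ksz, epsilon = epsilon, factor = factor)
      arms <- if (include_baseline) list(cfg, NULL) else list(cfg)
      for (arm in arms) {
        net0 <- reference_unet(seg_cfg, seed = seed)
        checksum <- sum(abs(unlist(net0$params)))
        fit <- asc_fit(sub_tr_v, sub_tr_m, block_size = m, window = window,
                       asc = arm, segmenter = net0, control = control)
        ev <- evaluate_predictions(predict(fit, sub_te_v), sub_te_m)
        rows[[length(rows) + 1L]] <- data.frame(
          block_size = m, kernel_size = ksz, stride = st,
          voxel_depth_mm = sub_te_v$voxel_depth,
          with_asc = !is.null(arm),
          dsc = round(100 * ev$metrics$DSC, 2),
          iou = round(100 * ev$metrics$IoU, 2),
          n_params = param_count(fit$segmenter),
          flops_per_target = flops_per_target_slice(unet_flops(seg_cfg, H, W),
                                                    m),
          init_checksum = checksum)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("result_table", "data.frame")
  out
}
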