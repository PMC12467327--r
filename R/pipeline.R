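#' Wrap a segmenter with the automatic spatial contrast pipeline
#'
#' The wrapper pairs a 2D segmenter with an [asc_config()]; it adds no
#' trainable parameters ([param_count()] is unchanged), since the
#' enhancement map is a parameter-free hard gate.
#'
#' @param segmenter A contract-satisfying segmenter.
#' @param cfg An [asc_config()].
#' @return An object of class `asc_wrapped`.
#' @export
wrap_with_asc <- function(segmenter, cfg = asc_config()) {
  stopifnot(inherits(segmenter, "asc_segmenter"), inherits(cfg, "asc_config"))
  structure(list(segmenter = segmenter, cfg = cfg), class = "asc_wrapped")
}

check_probability_map <- function(p, dims) {
  if (!is.matrix(p) || !identical(dim(p), dims))
    stop("segmenter contract violation: output shape differs from input",
         call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("segmenter contract violation: output is not a probability map",
         call. = FALSE)
  invisible(TRUE)
}

#' Slice-recurrent inference on one block
#'
#' The first slice of the block is segmented from its raw (unenhanced)
#' intensities; each subsequent slice is first multiplied by the enhancement
#' map built from the immediately preceding slice's prediction, then
#' segmented by the same shared sub-model. For a block of n slices exactly
#' n - 1 enhancement steps are executed; their count is attached to the
#' result as attribute `"enhancement_steps"`.
#'
#' @param block A `slice_block` from [make_blocks()] (normalized
#'   intensities).
#' @param segmenter A contract-satisfying segmenter, or an `asc_wrapped`
#'   object (in which case `cfg` is taken from the wrapper).
#' @param cfg An [asc_config()], or `NULL` to disable enhancement (the
#'   baseline: the target slice is segmented directly and zero enhancement
#'   steps run).
#' @return Probability matrix for the block's last (target) slice.
#' @export
infer_block <- function(block, segmenter, cfg = NULL) {
  stopifnot(inherits(block, "slice_block"))
  if (inherits(segmenter, "asc_wrapped")) {
    cfg <- segmenter$cfg
    segmenter <- segmenter$segmenter
  }
  n <- block$n
  dims <- dim(block$slices)[2:3]
  if (is.null(cfg)) {
    p <- seg_forward(segmenter, matrix(block$slices[n, , ], dims[1], dims[2]))
    check_probability_map(p, dims)
    attr(p, "enhancement_steps") <- 0L
    return(p)
  }
  stopifnot(inherits(cfg, "asc_config"))
  p <- seg_forward(segmenter, matrix(block$slices[1, , ], dims[1], dims[2]))
  check_probability_map(p, dims)
  steps <- 0L
  for (k in seq_len(n - 1L) + 1L) {
    x_enh <- enhance_step(p, matrix(block$slices[k, , ], dims[1], dims[2]), cfg)
    steps <- steps + 1L
    p <- seg_forward(segmenter, x_enh)
    check_probability_map(p, dims)
  }
  attr(p, "enhancement_steps") <- steps
  p
}

#' Slice-recurrent inference over a whole volume
#'
#' Two modes. `"block"` (the evaluation protocol): every stride-1 block of
#' `n` slices is processed with [infer_block()], yielding one prediction per
#' block target, i.e. for slices `n ... S`. `"carry"` (sequential case
#' prediction): slice 1 is segmented unenhanced and each later slice is
#' enhanced by the immediately preceding prediction in a single pass,
#' yielding S predictions and S - 1 enhancement steps. The two modes
#' coincide when `S == n`.
#'
#' @param volume A [ct_volume()]; normalized internally with `window` unless
#'   `window = NULL` (already-normalized input).
#' @param segmenter Segmenter or `asc_wrapped`.
#' @param cfg [asc_config()] or `NULL` for the unenhanced baseline.
#' @param mode `"block"` or `"carry"`.
#' @param n Block size for block mode.
#' @param window A [hu_window()] or `NULL`.
#' @return An `inference_result`: list with `predictions` (probability
#'   matrices), `slice_index` (1-based target indices), `case_id`, `mode`,
#'   and `enhancement_steps`.
#' @export
infer_volume <- function(volume, segmenter, cfg = NULL,
                         mode = c("block", "carry"), n = 4L,
                         window = hu_window()) {
  mode <- match.arg(mode)
  if (inherits(segmenter, "asc_wrapped")) {
    cfg <- segmenter$cfg
    segmenter <- segmenter$segmenter
  }
  if (!is.null(window)) volume <- normalize_hu(volume, window)
  S <- n_slices(volume)
  dims <- dim(volume$slices)[2:3]
  if (mode == "block") {
    if (S < n) stop(sprintf("case '%s' has %d slices, fewer than block size %d",
                            volume$case_id, S, n), call. = FALSE)
    blocks <- make_blocks(volume, NULL, n)
    preds <- vector("list", length(blocks))
    steps <- 0L
    for (i in seq_along(blocks)) {
      p <- infer_block(blocks[[i]], segmenter, cfg)
      steps <- steps + attr(p, "enhancement_steps")
      attr(p, "enhancement_steps") <- NULL
      preds[[i]] <- p
    }
    idx <- vapply(blocks, block_target_index, 0L)
  } else {
    if (S < 2L) stop("carry mode needs at least 2 slices", call. = FALSE)
    preds <- vector("list", S)
    steps <- 0L
    p <- seg_forward(segmenter, matrix(volume$slices[1, , ], dims[1], dims[2]))
    check_probability_map(p, dims)
    preds[[1]] <- p
    for (s in 2:S) {
      x <- matrix(volume$slices[s, , ], dims[1], dims[2])
      if (!is.null(cfg)) {
        x <- enhance_step(p, x, cfg)
        steps <- steps + 1L
      }
      p <- seg_forward(segmenter, x)
      check_probability_map(p, dims)
      preds[[s]] <- p
    }
    idx <- seq_len(S)
  }
  structure(list(predictions = preds, slice_index = idx,
                 case_id = volume$case_id, mode = mode,
                 enhancement_steps = steps),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("Inference result '%s' (%s mode): %d slice predictions, %d enhancement steps\n",
              x$case_id, x$mode, length(x$predictions), x$enhancement_steps))
  invisible(x)
}

#' Evaluate volume predictions against ground truth
#'
#' Predictions are binarized at `threshold` and TP/FP/FN/TN pooled over all
#' evaluated slices (micro average) for the headline DSC/IoU; unweighted
#' per-slice means (macro) are reported alongside.
#'
#' @param result An `inference_result`.
#' @param masks The [mask_volume()] for the same case.
#' @param threshold Binarization threshold (0.5 = argmax of two classes).
#' @return A list with `metrics` ([metrics_result()], micro), `per_slice`
#'   data frame, and `macro_dsc` / `macro_iou`.
#' @export
evaluate_predictions <- function(result, masks, threshold = 0.5) {
  stopifnot(inherits(result, "inference_result"),
            inherits(masks, "mask_volume"))
  S <- dim(masks$masks)[1]
  if (any(result$slice_index < 1L | result$slice_index > S))
    stop("provenance mismatch: predicted slice index outside mask volume",
         call. = FALSE)
  tot <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  per <- vector("list", length(result$predictions))
  for (i in seq_along(result$predictions)) {
    s <- result$slice_index[i]
    P <- (result$predictions[[i]] >= threshold) + 0L
    G <- matrix(masks$masks[s, , ], nrow(P), ncol(P))
    cc <- confusion_counts(P, G)
    tot <- tot + cc
    per[[i]] <- data.frame(slice = s, TP = cc["TP"], FP = cc["FP"],
                           FN = cc["FN"], TN = cc["TN"],
                           dsc = dsc_from_counts(cc["TP"], cc["FP"], cc["FN"]),
                           iou = iou_from_counts(cc["TP"], cc["FP"], cc["FN"]),
                           row.names = NULL)
  }
  per <- do.call(rbind, per)
  list(metrics = metrics_result(tot["TP"][[1]], tot["FP"][[1]],
                                tot["FN"][[1]], tot["TN"][[1]]),
       per_slice = per,
       macro_dsc = mean(per$dsc), macro_iou = mean(per$iou))
}

#' Training control settings
#'
#' Defaults follow the reference training protocol: batch size 4, learning
#' rate 1e-6, 200 epochs, Adam. Desk-scale demonstrations typically override
#' `epochs` and `learning_rate`.
#'
#' @param batch_size Blocks per optimizer step.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param optimizer Only `"adam"` is implemented.
#' @param loss Only `"cross_entropy"` (mean per-pixel, two classes).
#' @param seed Seed for initialization-independent shuffling; fixed seed
#'   reproduces the loss trace bitwise.
#' @param supervise_intermediate Also add (equally weighted) loss terms for
#'   the non-target slices 2 ... n-1 of each block.
#' @return An object of class `train_control`.
#' @export
train_control <- function(batch_size = 4L, learning_rate = 1e-6,
                          epochs = 200L, optimizer = "adam",
                          loss = "cross_entropy", seed = 1L,
                          supervise_intermediate = FALSE) {
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "cross_entropy")
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, loss = loss, seed = as.integer(seed),
                 supervise_intermediate = isTRUE(supervise_intermediate)),
            class = "train_control")
}

# gradient contribution of one block: forward the slices sequentially
# (previous predictions are constants for map construction — no gradient
# flows through the hard thresholding), backprop the target slice's loss
# (plus intermediate terms if requested) through that slice's own pass.
block_loss_grads <- function(net, block, asc_cfg, control) {
  n <- block$n
  dims <- dim(block$slices)[2:3]
  sup <- if (control$supervise_intermediate) 2:n else n
  total <- NULL; loss <- 0; wsum <- 0
  p_prev <- NULL
  for (k in seq_len(n)) {
    x <- matrix(block$slices[k, , ], dims[1], dims[2])
    if (!is.null(asc_cfg) && k > 1L) x <- enhance_step(p_prev, x, asc_cfg)
    if (is.null(asc_cfg) && k < n) next  # baseline: only the target matters
    if (k %in% sup) {
      y <- matrix(block$masks[k, , ], dims[1], dims[2])
      lg <- slice_loss_grads(net, x, y, want_grads = TRUE)
      loss <- loss + lg$loss; wsum <- wsum + 1
      total <- if (is.null(total)) lg$grads else
        Map(`+`, total, lg$grads)
      p_prev <- lg$prob
    } else {
      p_prev <- unet_forward(net, x, want_cache = FALSE)$prob
    }
  }
  list(loss = loss / wsum, grads = lapply(total, function(g) g / wsum))
}

#' Train a segmenter through the slice-recurrent pipeline
#'
#' Blocks are shuffled as units each epoch (internal slice order never
#' changes); each block is forwarded as in [infer_block()] and the loss
#' between the target slice's prediction and its ground truth is
#' backpropagated through the shared sub-model. Previous-slice predictions
#' are constants with respect to gradients (the enhancement gate is
#' non-differentiable). The parameter count is identical before and after
#' training, and a fixed `control$seed` reproduces the per-epoch loss trace
#' bitwise.
#'
#' @param blocks Non-empty list of `slice_block`s with masks.
#' @param segmenter A trainable [reference_unet()].
#' @param asc_cfg [asc_config()] to train with enhancement, or `NULL` for
#'   the unenhanced baseline.
#' @param control A [train_control()].
#' @param verbose Print per-epoch loss.
#' @return List with `segmenter` (trained) and `trace` (mean loss per
#'   epoch).
#' @export
train_segmenter <- function(blocks, segmenter, asc_cfg = NULL,
                            control = train_control(), verbose = FALSE) {
  if (length(blocks) == 0) stop("empty block stream", call. = FALSE)
  stopifnot(inherits(control, "train_control"))
  if (!inherits(segmenter, "ref_unet") || isTRUE(segmenter$frozen))
    stop("training requires a trainable reference_unet", call. = FALSE)
  if (segmenter$cfg$n_classes != 2L)
    stop("training supports 2 output classes", call. = FALSE)
  if (any(vapply(blocks, function(b) is.null(b$masks), TRUE)))
    stop("blocks must carry masks for training", call. = FALSE)
  n_before <- param_count(segmenter)
  st <- adam_state(segmenter$params)
  trace <- numeric(control$epochs)
  with_seed(control$seed, {
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(length(blocks))
      ep_loss <- 0; nb <- 0L
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + control$batch_size - 1L, length(ord))]
        acc <- NULL; bl <- 0
        for (j in batch) {
          r <- block_loss_grads(segmenter, blocks[[j]], asc_cfg, control)
          if (!is.finite(r$loss)) stop("non-finite loss", call. = FALSE)
          bl <- bl + r$loss
          acc <- if (is.null(acc)) r$grads else Map(`+`, acc, r$grads)
        }
        acc <- lapply(acc, function(g) g / length(batch))
        upd <- adam_step(segmenter$params, acc, st, control$learning_rate)
        segmenter$params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + bl
        nb <- nb + length(batch)
        i <- i + control$batch_size
      }
      trace[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d: loss %.6f", ep, trace[ep]))
    }
  })
  stopifnot(param_count(segmenter) == n_before)
  list(segmenter = segmenter, trace = trace)
}

#' Fit a slice-recurrent segmentation model
#'
#' The main fitting front-end: normalizes the input volume(s), assembles
#' overlapping slice blocks, trains the sub-model through the recurrent
#' enhancement pipeline, and returns a fitted model object with the usual
#' methods (`print`, `summary`, `predict`, `plot`).
#'
#' @param volumes A [ct_volume()] or list of them (HU intensities).
#' @param masks The matching [mask_volume()] or list.
#' @param block_size Slices per block (n >= 2; default 4).
#' @param window A [hu_window()].
#' @param asc An [asc_config()], or `NULL` to fit the unenhanced baseline.
#' @param segmenter A trainable [reference_unet()]; default is a CPU-scale
#'   network (B = 8, depth = 2).
#' @param control A [train_control()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `asc_model`.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(level = 2, seed = 3))
#' fit <- asc_fit(ph$volume, ph$mask, asc = asc_config(16, 0.5, 1.4),
#'                control = train_control(epochs = 2, learning_rate = 1e-3))
#' pred <- predict(fit, ph$volume)
#' evaluate_predictions(pred, ph$mask)$metrics
#' }
#' @export
asc_fit <- function(volumes, masks, block_size = 4L, window = hu_window(),
                    asc = asc_config(), segmenter = NULL,
                    control = train_control(), verbose = FALSE) {
  if (inherits(volumes, "ct_volume")) volumes <- list(volumes)
  if (inherits(masks, "mask_volume")) masks <- list(masks)
  stopifnot(length(volumes) == length(masks))
  if (is.null(segmenter))
    segmenter <- reference_unet(ref_unet_config(channel_width = 8L, depth = 2L),
                                seed = control$seed)
  blocks <- list()
  for (i in seq_along(volumes)) {
    if (n_slices(volumes[[i]]) < block_size) {
      warning(sprintf("skipping case '%s': %d slices < block size %d",
                      volumes[[i]]$case_id, n_slices(volumes[[i]]), block_size))
      next
    }
    nv <- normalize_hu(volumes[[i]], window)
    blocks <- c(blocks, make_blocks(nv, masks[[i]], block_size))
  }
  fit <- train_segmenter(blocks, segmenter, asc, control, verbose)
  structure(list(segmenter = fit$segmenter, asc = asc, window = window,
                 block_size = as.integer(block_size), trace = fit$trace,
                 control = control, n_blocks = length(blocks),
                 call = match.call()),
            class = "asc_model")
}

#' @export
print.asc_model <- function(x, ...) {
  cat("Slice-recurrent CT segmentation model\n")
  cat(sprintf("  sub-model: %s, %s trainable parameters\n",
              x$segmenter$name, format(param_count(x$segmenter),
                                       big.mark = ",")))
  if (is.null(x$asc)) cat("  enhancement: none (baseline)\n")
  else cat(sprintf("  enhancement: kernel %d, epsilon %.3g, factor %.3g\n",
                   x$asc$kernel_size, x$asc$epsilon, x$asc$factor))
  cat(sprintf("  trained on %d blocks of %d slices for %d epochs; final loss %.6f\n",
              x$n_blocks, x$block_size, length(x$trace),
              x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
summary.asc_model <- function(object, ...) {
  print(object)
  cat(sprintf("  loss trace: first %.6f -> last %.6f (%d epochs)\n",
              object$trace[1], object$trace[length(object$trace)],
              length(object$trace)))
  cat(sprintf("  window: [%g, %g] HU; batch %d, lr %g\n",
              object$window$hu_min, object$window$hu_max,
              object$control$batch_size, object$control$learning_rate))
  invisible(object)
}

#' @export
plot.asc_model <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", xlab = "epoch",
       ylab = "mean loss", main = "Training loss", ...)
  invisible(x)
}

#' @rdname asc_fit
#' @param object A fitted `asc_model`.
#' @param newdata A [ct_volume()] in HU.
#' @param mode `"block"` or `"carry"` (see [infer_volume()]).
#' @param ... Unused.
#' @export
predict.asc_model <- function(object, newdata, mode = c("block", "carry"),
                              ...) {
  stopifnot(inherits(newdata, "ct_volume"))
  infer_volume(newdata, object$segmenter, object$asc, match.arg(mode),
               n = object$block_size, window = object$window)
}
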