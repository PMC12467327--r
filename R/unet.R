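# Compact trainable convolutional encoder-decoder (UNet-style) in base R.
#
# Feature maps live as (h*w, C) matrices in column-major pixel order
# (row fastest), so 3x3 convolutions become one im2col gather plus a BLAS
# matrix product, and the backward pass is the transposed product plus a
# scatter-add through the same index map. This keeps the whole pipeline
# exercisable (and trainable) on a single CPU with no external framework.

.geom_cache <- new.env(parent = emptyenv())

# precomputed index maps for one (h, w) resolution
geom_for <- function(h, w) {
  key <- paste0(h, "x", w)
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  hw <- h * w
  p <- seq_len(hw)
  r <- ((p - 1L) %% h) + 1L
  cc <- ((p - 1L) %/% h) + 1L
  conv_idx <- matrix(0L, hw, 9L)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    conv_idx[, k] <- (cc + dc - 1L) * (h + 2L) + (r + dr)
  }
  interior <- cc * (h + 2L) + (r + 1L)
  g <- list(h = h, w = w, hw = hw, hp_wp = (h + 2L) * (w + 2L),
            conv_idx = conv_idx, conv_idx_vec = as.vector(conv_idx),
            interior = interior)
  if (h %% 2L == 0L && w %% 2L == 0L) {
    hh <- h %/% 2L; wh <- w %/% 2L
    q <- seq_len(hh * wh)
    rq <- ((q - 1L) %% hh) + 1L
    cq <- ((q - 1L) %/% hh) + 1L
    r0 <- 2L * rq - 1L; c0 <- 2L * cq - 1L
    g$pool_idx <- cbind((c0 - 1L) * h + r0, (c0 - 1L) * h + r0 + 1L,
                        c0 * h + r0, c0 * h + r0 + 1L)
  }
  po <- seq_len(4L * hw)
  ro <- ((po - 1L) %% (2L * h)) + 1L
  co <- ((po - 1L) %/% (2L * h)) + 1L
  g$up_idx <- (ceiling(co / 2) - 1L) * h + ceiling(ro / 2)
  .geom_cache[[key]] <- g
  g
}

conv_fwd <- function(F, Wm, b, g) {
  Cin <- ncol(F)
  P <- matrix(0, g$hp_wp, Cin)
  P[g$interior, ] <- F
  Xcol <- matrix(P[g$conv_idx_vec, , drop = FALSE], g$hw, 9L * Cin)
  Y <- Xcol %*% Wm
  Y <- Y + rep(b, each = g$hw)
  list(Y = Y, Xcol = Xcol, Cin = Cin)
}

conv_bwd <- function(dY, cache, Wm, g) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(Wm)
  Cin <- cache$Cin
  A <- array(dXcol, c(g$hw, 9L, Cin))
  dP <- matrix(0, g$hp_wp, Cin)
  for (k in 1:9) {
    ix <- g$conv_idx[, k]
    dP[ix, ] <- dP[ix, ] + matrix(A[, k, ], g$hw, Cin)
  }
  list(dF = dP[g$interior, , drop = FALSE], dW = dW, db = db)
}

dconv_fwd <- function(F, params, prefix, g) {
  c1 <- conv_fwd(F, params[[paste0(prefix, ".W1")]],
                 params[[paste0(prefix, ".b1")]], g)
  m1 <- c1$Y > 0
  F1 <- c1$Y * m1
  c2 <- conv_fwd(F1, params[[paste0(prefix, ".W2")]],
                 params[[paste0(prefix, ".b2")]], g)
  m2 <- c2$Y > 0
  list(out = c2$Y * m2, cache = list(c1 = c1, m1 = m1, c2 = c2, m2 = m2))
}

dconv_bwd <- function(dOut, cache, params, prefix, g, grads) {
  d2 <- conv_bwd(dOut * cache$m2, cache$c2, params[[paste0(prefix, ".W2")]], g)
  grads[[paste0(prefix, ".W2")]] <- d2$dW
  grads[[paste0(prefix, ".b2")]] <- d2$db
  d1 <- conv_bwd(d2$dF * cache$m1, cache$c1, params[[paste0(prefix, ".W1")]], g)
  grads[[paste0(prefix, ".W1")]] <- d1$dW
  grads[[paste0(prefix, ".b1")]] <- d1$db
  list(dF = d1$dF, grads = grads)
}

pool_fwd <- function(F, g) {
  A1 <- F[g$pool_idx[, 1], , drop = FALSE]
  A2 <- F[g$pool_idx[, 2], , drop = FALSE]
  A3 <- F[g$pool_idx[, 3], , drop = FALSE]
  A4 <- F[g$pool_idx[, 4], , drop = FALSE]
  M <- pmax(A1, A2, A3, A4)
  m1 <- A1 == M
  m2 <- (A2 == M) & !m1
  m3 <- (A3 == M) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(out = M, cache = list(m = list(m1, m2, m3, m4)))
}

pool_bwd <- function(dM, cache, g, Cin) {
  dF <- matrix(0, g$hw, Cin)
  for (k in 1:4) {
    ix <- g$pool_idx[, k]
    dF[ix, ] <- dF[ix, ] + dM * cache$m[[k]]
  }
  dF
}

up_fwd <- function(F, g_coarse) F[g_coarse$up_idx, , drop = FALSE]

up_bwd <- function(dFup, g_coarse) {
  out <- rowsum(dFup, g_coarse$up_idx)
  dimnames(out) <- NULL
  out
}

#' Configuration for the reference encoder-decoder segmenter
#'
#' A canonical UNet-style design: `depth` encoder levels of two 3x3
#' convolutions + ReLU followed by 2x max pooling, a double-convolution
#' bottleneck, `depth` decoder levels of 2x nearest-neighbour upsampling,
#' skip concatenation and two 3x3 convolutions, and a final 1x1 convolution
#' to `n_classes` with a softmax output. Channel width doubles per level
#' starting from `channel_width`.
#'
#' @param channel_width Feature channels after the first convolution
#'   (`B`). Default 64; 8 is a convenient CPU test scale.
#' @param depth Encoder levels; input height/width must be divisible by
#'   `2^depth`.
#' @param n_classes Output classes (2: background / aorta).
#' @param in_channels Input channels (1 for a single CT slice).
#' @return An object of class `ref_unet_config`.
#' @export
ref_unet_config <- function(channel_width = 64L, depth = 4L, n_classes = 2L,
                            in_channels = 1L) {
  if (channel_width < 1 || depth < 1 || n_classes < 2 || in_channels < 1)
    stop("invalid segmenter configuration", call. = FALSE)
  structure(list(channel_width = as.integer(channel_width),
                 depth = as.integer(depth), n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "ref_unet_config")
}

unet_channels <- function(cfg) {
  enc <- cfg$channel_width * 2L^(seq_len(cfg$depth) - 1L)
  list(enc = enc, bottleneck = cfg$channel_width * 2L^cfg$depth)
}

#' Build the reference segmenter
#'
#' Returns a segmenter satisfying the pluggable contract (see
#' [seg_forward()]): it maps a 2-D non-negative intensity grid — including
#' post-enhancement values above 1 — to a per-pixel foreground probability
#' map of the same shape, deterministically, and reports its exact trainable
#' parameter count via [param_count()]. Weights use He initialization under
#' the given seed.
#'
#' @param cfg A [ref_unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ref_unet` (also `asc_segmenter`).
#' @export
reference_unet <- function(cfg = ref_unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "ref_unet_config"))
  ch <- unet_channels(cfg)
  params <- list()
  he <- function(fan_in, fan_out)
    matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
  with_seed(seed, {
    cin <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      co <- ch$enc[i]
      params[[sprintf("enc%d.W1", i)]] <- he(9L * cin, co)
      params[[sprintf("enc%d.b1", i)]] <- numeric(co)
      params[[sprintf("enc%d.W2", i)]] <- he(9L * co, co)
      params[[sprintf("enc%d.b2", i)]] <- numeric(co)
      cin <- co
    }
    params[["bot.W1"]] <- he(9L * cin, ch$bottleneck)
    params[["bot.b1"]] <- numeric(ch$bottleneck)
    params[["bot.W2"]] <- he(9L * ch$bottleneck, ch$bottleneck)
    params[["bot.b2"]] <- numeric(ch$bottleneck)
    cup <- ch$bottleneck
    for (i in rev(seq_len(cfg$depth))) {
      co <- ch$enc[i]
      params[[sprintf("dec%d.W1", i)]] <- he(9L * (cup + co), co)
      params[[sprintf("dec%d.b1", i)]] <- numeric(co)
      params[[sprintf("dec%d.W2", i)]] <- he(9L * co, co)
      params[[sprintf("dec%d.b2", i)]] <- numeric(co)
      cup <- co
    }
    params[["final.W"]] <- he(ch$enc[1], cfg$n_classes)
    params[["final.b"]] <- numeric(cfg$n_classes)
  })
  structure(list(cfg = cfg, params = params, name = "reference_unet",
                 channel_width = cfg$channel_width, frozen = FALSE),
            class = c("ref_unet", "asc_segmenter"))
}

#' @export
print.ref_unet <- function(x, ...) {
  cat(sprintf("Reference encoder-decoder segmenter: B = %d, depth = %d, %d classes, %s trainable parameters\n",
              x$cfg$channel_width, x$cfg$depth, x$cfg$n_classes,
              format(param_count(x), big.mark = ",")))
  invisible(x)
}

unet_forward <- function(net, x, want_cache = FALSE) {
  stopifnot(is.matrix(x))
  H <- nrow(x); W <- ncol(x)
  d <- net$cfg$depth
  if (H %% 2L^d != 0L || W %% 2L^d != 0L)
    stop(sprintf("input %d x %d not divisible by 2^depth = %d", H, W, 2L^d),
         call. = FALSE)
  p <- net$params
  F <- matrix(as.vector(x), ncol = 1L)
  geoms <- vector("list", d + 1L)
  skips <- vector("list", d)
  enc_caches <- vector("list", d)
  pool_caches <- vector("list", d)
  h <- H; w <- W
  for (i in seq_len(d)) {
    g <- geom_for(h, w); geoms[[i]] <- g
    dc <- dconv_fwd(F, p, sprintf("enc%d", i), g)
    skips[[i]] <- dc$out
    if (want_cache) enc_caches[[i]] <- dc$cache
    pl <- pool_fwd(dc$out, g)
    F <- pl$out
    if (want_cache) pool_caches[[i]] <- pl$cache
    h <- h %/% 2L; w <- w %/% 2L
  }
  gb <- geom_for(h, w); geoms[[d + 1L]] <- gb
  bc <- dconv_fwd(F, p, "bot", gb)
  F <- bc$out
  dec_caches <- vector("list", d)
  up_widths <- integer(d)
  for (i in rev(seq_len(d))) {
    g_coarse <- geoms[[i + 1L]]
    g_fine <- geoms[[i]]
    up_widths[i] <- ncol(F)
    Fup <- up_fwd(F, g_coarse)
    F <- cbind(Fup, skips[[i]])
    dc <- dconv_fwd(F, p, sprintf("dec%d", i), g_fine)
    F <- dc$out
    if (want_cache) dec_caches[[i]] <- dc$cache
  }
  logits <- F %*% p[["final.W"]]
  logits <- logits + rep(p[["final.b"]], each = nrow(logits))
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  out <- list(prob = matrix(probs[, net$cfg$n_classes], H, W), probs = probs)
  if (want_cache)
    out$cache <- list(geoms = geoms, enc = enc_caches, pool = pool_caches,
                      bot = bc$cache, dec = dec_caches, F_last = F,
                      up_widths = up_widths, H = H, W = W)
  out
}

unet_backward <- function(net, cache, dlogits) {
  p <- net$params
  d <- net$cfg$depth
  grads <- list()
  grads[["final.W"]] <- crossprod(cache$F_last, dlogits)
  grads[["final.b"]] <- colSums(dlogits)
  dF <- dlogits %*% t(p[["final.W"]])
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    g_fine <- cache$geoms[[i]]
    g_coarse <- cache$geoms[[i + 1L]]
    bb <- dconv_bwd(dF, cache$dec[[i]], p, sprintf("dec%d", i), g_fine, grads)
    grads <- bb$grads
    cup <- cache$up_widths[i]
    dFup <- bb$dF[, seq_len(cup), drop = FALSE]
    dskips[[i]] <- bb$dF[, -seq_len(cup), drop = FALSE]
    dF <- up_bwd(dFup, g_coarse)
  }
  gb <- cache$geoms[[d + 1L]]
  bb <- dconv_bwd(dF, cache$bot, p, "bot", gb, grads)
  grads <- bb$grads
  dF <- bb$dF
  for (i in rev(seq_len(d))) {
    g <- cache$geoms[[i]]
    cin <- ncol(dskips[[i]])
    dSkip <- pool_bwd(dF, cache$pool[[i]], g, cin) + dskips[[i]]
    bb <- dconv_bwd(dSkip, cache$enc[[i]], p, sprintf("enc%d", i), g, grads)
    grads <- bb$grads
    dF <- bb$dF
  }
  grads
}

# cross-entropy loss on one slice plus gradients w.r.t. all weights
slice_loss_grads <- function(net, x, y, want_grads = TRUE) {
  fw <- unet_forward(net, x, want_cache = want_grads)
  hw <- length(x)
  labels <- as.vector(y) + 1L  # 1 = background, 2 = foreground
  pick <- cbind(seq_len(hw), labels)
  eps <- 1e-12
  loss <- -mean(log(fw$probs[pick] + eps))
  out <- list(loss = loss, prob = fw$prob)
  if (want_grads) {
    dlogits <- fw$probs
    dlogits[pick] <- dlogits[pick] - 1
    out$grads <- unet_backward(net, fw$cache, dlogits / hw)
  }
  out
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

#' Segmenter contract: forward pass
#'
#' Any object usable as a sub-model must map a 2-D non-negative intensity
#' matrix (values may exceed 1 after enhancement) to a probability matrix of
#' identical shape with values in [0, 1], deterministically in evaluation
#' mode. [reference_unet()] satisfies this; arbitrary functions can be
#' adapted with [make_segmenter()].
#'
#' @param segmenter A segmenter object.
#' @param x Numeric matrix.
#' @param ... Passed to methods.
#' @return Probability matrix, same shape as `x`.
#' @export
seg_forward <- function(segmenter, x, ...) UseMethod("seg_forward")

#' @export
seg_forward.ref_unet <- function(segmenter, x, ...)
  unet_forward(segmenter, x, want_cache = FALSE)$prob

#' @export
seg_forward.fn_segmenter <- function(segmenter, x, ...) segmenter$forward(x, ...)

#' Segmenter contract: trainable parameter count
#'
#' The exact number of trainable scalars. Wrapping a segmenter with the ASC
#' pipeline ([wrap_with_asc()]) never changes this: the enhancement map has
#' no parameters.
#'
#' @param segmenter A segmenter (or ASC-wrapped segmenter).
#' @return Integer count.
#' @export
param_count <- function(segmenter) UseMethod("param_count")

#' @export
param_count.ref_unet <- function(segmenter) {
  if (isTRUE(segmenter$frozen)) return(0L)
  sum(vapply(segmenter$params, length, 0L))
}

#' @export
param_count.fn_segmenter <- function(segmenter) segmenter$n_params

#' @export
param_count.asc_wrapped <- function(segmenter) param_count(segmenter$segmenter)

#' Adapt a plain function to the segmenter contract
#'
#' @param forward Function mapping an intensity matrix to a probability
#'   matrix of the same shape.
#' @param n_params Trainable parameter count to report (0 for stubs).
#' @param name Display name.
#' @param channel_width Optional channel width `B` for complexity reporting.
#' @return A `fn_segmenter`.
#' @export
make_segmenter <- function(forward, n_params = 0L, name = "custom",
                           channel_width = NA_integer_) {
  stopifnot(is.function(forward))
  structure(list(forward = forward, n_params = as.integer(n_params),
                 name = name, channel_width = channel_width),
            class = c("fn_segmenter", "asc_segmenter"))
}

#' Freeze a reference segmenter
#'
#' A frozen segmenter still performs inference but reports zero trainable
#' parameters and is rejected by the training loop.
#'
#' @param segmenter A `ref_unet`.
#' @return The frozen segmenter.
#' @export
freeze_segmenter <- function(segmenter) {
  stopifnot(inherits(segmenter, "ref_unet"))
  segmenter$frozen <- TRUE
  segmenter
}

# --- registry -----------------------------------------------------------

.seg_registry <- new.env(parent = emptyenv())

#' Segmenter registry
#'
#' Segmenters are discoverable by name so run configurations can select one
#' with a string (e.g. `segmenter: reference_unet`).
#'
#' @param name Registry key.
#' @param constructor Function returning a contract-satisfying segmenter.
#' @param ... Passed to the constructor by `get_segmenter`.
#' @return `register_segmenter` returns the name invisibly; `get_segmenter`
#'   the constructed segmenter; `list_segmenters` the registered names.
#' @export
register_segmenter <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .seg_registry)
  invisible(name)
}

#' @rdname register_segmenter
#' @export
get_segmenter <- function(name, ...) {
  if (!exists(name, envir = .seg_registry))
    stop("unknown segmenter: ", name, call. = FALSE)
  get(name, envir = .seg_registry)(...)
}

#' @rdname register_segmenter
#' @export
list_segmenters <- function() ls(.seg_registry)
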