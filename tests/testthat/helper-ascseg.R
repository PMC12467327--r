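# shared fixtures and independent oracles for the test suite

# small noiseless phantom, fast to generate
tiny_phantom <- function(seed = 1, level = 2, n_slices = 8, size = 64,
                         noise_sd = 0, ...) {
  generate_phantom(phantom_spec(level = level, n_slices = n_slices,
                                height = size, width = size,
                                noise_sd = noise_sd, seed = seed, ...))
}

# segmenter stub returning a constant map
stub_segmenter <- function(value) {
  make_segmenter(function(x) matrix(value, nrow(x), ncol(x)),
                 n_params = 0L, name = sprintf("stub_%g", value))
}

# segmenter stub that records every input it receives
recording_stub <- function(value = 0) {
  calls <- new.env()
  calls$inputs <- list()
  seg <- make_segmenter(function(x) {
    calls$inputs[[length(calls$inputs) + 1L]] <- x
    matrix(value, nrow(x), ncol(x))
  }, n_params = 0L, name = "recorder")
  list(seg = seg, calls = calls)
}

# brute-force enhancement-map oracle: explicit double loop over kernels
# and pixels, independent of the vectorized implementation
oracle_enhancement_map <- function(prediction, ks, eps, ef) {
  H <- nrow(prediction); W <- ncol(prediction)
  Hp <- ks * ceiling(H / ks); Wp <- ks * ceiling(W / ks)
  padded <- matrix(0, Hp, Wp)
  padded[1:H, 1:W] <- prediction
  out <- matrix(1.0, Hp, Wp)
  for (bi in seq_len(Hp / ks)) {
    for (bj in seq_len(Wp / ks)) {
      rs <- ((bi - 1) * ks + 1):(bi * ks)
      cs <- ((bj - 1) * ks + 1):(bj * ks)
      total <- 0
      for (r in rs) for (c in cs) total <- total + padded[r, c]
      if (total / ks^2 > eps) {
        for (r in rs) for (c in cs) out[r, c] <- ef
      }
    }
  }
  out[1:H, 1:W, drop = FALSE]
}

# per-pixel confusion oracle: explicit loop
oracle_confusion <- function(P, G) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(P)) {
    if (P[i] == 1 && G[i] == 1) tp <- tp + 1L
    else if (P[i] == 1) fp <- fp + 1L
    else if (G[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# 4-connected component count via flood fill (independent of any package)
component_count <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!m[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1 && r <= H && c >= 1 && c <= W && m[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# foreground centroid of a binary slice
mask_centroid <- function(slice) {
  idx <- which(slice == 1, arr.ind = TRUE)
  colMeans(idx)
}

# published backbone comparison (Level 1 and Level 2 test sets), used as
# worked-example input for the improvement arithmetic
reported_backbone_table <- function() {
  base <- data.frame(
    model = rep(c("UNet", "AttentionUNet", "TransUNet", "SwinUNet"), 2),
    level = rep(c(1, 2), each = 4),
    dsc = c(82.22, 79.45, 84.56, 70.06, 61.58, 65.96, 49.64, 38.53),
    iou = c(79.65, 78.84, 74.92, 75.02, 55.85, 60.48, 30.15, 39.15))
  asc <- data.frame(
    model = base$model, level = base$level,
    dsc = c(84.76, 83.90, 87.15, 80.68, 67.48, 70.82, 74.48, 61.66),
    iou = c(80.92, 80.41, 73.13, 75.91, 68.23, 67.17, 58.28, 53.66))
  list(baseline = base, augmented = asc)
}
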