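test_that("the enhancement cost fraction is 1 / B^2", {
  expect_identical(asc_cost_fraction(64), 1 / 4096)
  expect_identical(asc_cost_fraction(1), 1)
  expect_identical(asc_cost_fraction(8), 1 / 64)
  expect_error(asc_cost_fraction(0), "B must be")
})

test_that("per-target-slice FLOPs scale exactly linearly in block size", {
  expect_equal(flops_per_target_slice(73.50e9, 4), 294.00e9)
  expect_equal(flops_per_target_slice(524.53e9, 4), 2098.12e9)
  expect_identical(flops_per_target_slice(123, 1), 123)
  set.seed(21)
  f <- runif(1, 1e9, 1e12)
  for (m in 2:6)
    expect_equal(flops_per_target_slice(f, m) -
                 flops_per_target_slice(f, m - 1), f)
})

test_that("analytic segmenter FLOPs match a hand count on a tiny net", {
  # depth 1, B = 1, 4x4 input:
  # enc1 convs (1->1, 1->1) at 4x4, bottleneck (1->2, 2->2) at 2x2,
  # dec1 (3->1, 1->1) at 4x4, head 1x1 (1->2) at 4x4
  cfg <- ref_unet_config(channel_width = 1L, depth = 1L)
  hand <- 16 * 1 * (2 * 9 * 1 + 1) + 16 * 1 * (2 * 9 * 1 + 1) +
    4 * 2 * (2 * 9 * 1 + 1) + 4 * 2 * (2 * 9 * 2 + 1) +
    16 * 1 * (2 * 9 * 3 + 1) + 16 * 1 * (2 * 9 * 1 + 1) +
    16 * 2 * (2 * 1 * 1 + 1)
  expect_equal(unet_flops(cfg, 4L, 4L), hand)
  expect_gt(unet_flops(ref_unet_config(16L, 2L), 64L, 64L),
            unet_flops(ref_unet_config(8L, 2L), 64L, 64L))
  expect_gt(asc_step_flops(64, 64), 0)
})

test_that("improvement deltas over the published backbone table", {
  tabs <- reported_backbone_table()
  imp <- improvement_table(tabs$baseline, tabs$augmented)
  expect_equal(imp$max_delta_dsc, 24.84)
  expect_equal(imp$max_delta_iou, 28.13)
  # the largest gains come from the poorly-contrasted TransUNet pair
  best <- imp$table[which.max(imp$table$delta_dsc), ]
  expect_identical(best$model, "TransUNet")
  expect_identical(best$level, 2)
  # identical tables give all-zero deltas
  zero <- improvement_table(tabs$baseline, tabs$baseline)
  expect_true(all(zero$table$delta_dsc == 0))
  expect_identical(zero$max_delta_dsc, 0)
})

test_that("held-out per-case deltas reproduce the published arithmetic", {
  base <- data.frame(case = c("R9", "R17"), dsc = c(60.77, 61.58),
                     iou = c(55.03, 55.85))
  aug <- data.frame(case = c("R9", "R17"), dsc = c(77.41, 67.48),
                    iou = c(77.54, 68.23))
  imp <- improvement_table(base, aug)
  r9 <- imp$table[imp$table$case == "R9", ]
  expect_equal(r9$delta_dsc, 16.64)
  expect_equal(r9$delta_iou, 22.51)
})

test_that("improvement maxima are invariant to row order", {
  tabs <- reported_backbone_table()
  set.seed(22)
  for (rep in 1:3) {
    perm <- sample(nrow(tabs$baseline))
    imp <- improvement_table(tabs$baseline[perm, ], tabs$augmented)
    expect_equal(imp$max_delta_dsc, 24.84)
    expect_equal(imp$max_delta_iou, 28.13)
  }
})

test_that("improvement tables validate labels and parameter pairing", {
  base <- data.frame(model = c("a", "b"), dsc = c(1, 2), iou = c(1, 2))
  aug <- data.frame(model = c("a", "c"), dsc = c(1, 2), iou = c(1, 2))
  expect_error(improvement_table(base, aug), "label mismatch")
  base$n_params <- c(10, 20)
  aug2 <- data.frame(model = c("a", "b"), dsc = c(2, 3), iou = c(2, 3),
                     n_params = c(10, 21))
  expect_error(improvement_table(base, aug2), "parameter counts")
  expect_error(improvement_table(base[, -2], aug), "columns")
})

test_that("the ablation harness trains each cell from shared initial weights", {
  trains <- lapply(1:2, function(i) tiny_phantom(seed = 50 + i, n_slices = 5,
                                                 size = 32))
  test_ph <- tiny_phantom(seed = 59, n_slices = 5, size = 32)
  tab <- ablation_harness(
    lapply(trains, `[[`, "volume"), lapply(trains, `[[`, "mask"),
    test_ph$volume, test_ph$mask,
    block_sizes = c(2L, 3L), kernel_sizes = 8L, strides = 1L,
    control = train_control(epochs = 1, learning_rate = 1e-3),
    seg_cfg = ref_unet_config(2L, 2L), include_baseline = TRUE, seed = 4)
  expect_s3_class(tab, "result_table")
  expect_equal(nrow(tab), 4L)  # 2 block sizes x (asc + baseline)
  expect_true(all(tab$dsc >= 0 & tab$dsc <= 100))
  expect_true(all(tab$iou <= tab$dsc + 1e-9))
  # every cell starts from the same seeded weights
  expect_length(unique(tab$init_checksum), 1L)
  # paired baseline/ASC rows share parameter counts
  for (m in unique(tab$block_size)) {
    sub <- tab[tab$block_size == m, ]
    expect_length(unique(sub$n_params), 1L)
  }
  # FLOPs column is linear in the block size
  expect_equal(tab$flops_per_target[tab$block_size == 3 & tab$with_asc] /
               tab$flops_per_target[tab$block_size == 2 & tab$with_asc],
               3 / 2)
})

test_that("stride cells re-derive the voxel depth", {
  tr <- tiny_phantom(seed = 61, n_slices = 10, size = 32, voxel_depth = 0.625)
  te <- tiny_phantom(seed = 62, n_slices = 10, size = 32, voxel_depth = 0.625)
  tab <- ablation_harness(tr$volume, tr$mask, te$volume, te$mask,
                          block_sizes = 2L, kernel_sizes = 8L,
                          strides = c(1L, 2L),
                          control = train_control(epochs = 1,
                                                  learning_rate = 1e-3),
                          seg_cfg = ref_unet_config(2L, 2L), seed = 4)
  expect_equal(sort(tab$voxel_depth_mm), c(0.625, 1.25))
})

test_that("infeasible ablation cells raise errors", {
  tr <- tiny_phantom(seed = 63, n_slices = 5, size = 32)
  expect_error(
    ablation_harness(tr$volume, tr$mask, tr$volume, tr$mask,
                     kernel_sizes = 64L,
                     control = train_control(epochs = 1)),
    "kernel 64 exceeds image")
})
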