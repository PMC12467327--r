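test_that("enhancement map matches the brute-force kernel oracle exactly", {
  set.seed(101)
  n_cases <- 0L
  for (ks in c(4, 8, 16, 32)) {
    for (eps in c(0, 0.25, 0.5)) {
      for (ef in c(1.0, 1.1, 1.4)) {
        for (rep in 1:3) {
          # mix of divisible and non-divisible shapes to exercise padding
          H <- ks * sample(1:3, 1) + sample(c(0, 3), 1)
          W <- ks * sample(1:3, 1) + sample(c(0, 5), 1)
          pred <- matrix(runif(H * W), H, W)
          got <- build_enhancement_map(pred, asc_config(ks, eps, ef))
          expect_identical(got, oracle_enhancement_map(pred, ks, eps, ef))
          n_cases <- n_cases + 1L
        }
      }
    }
  }
  expect_gte(n_cases, 100L)
})

test_that("degenerate predictions produce the obvious maps", {
  cfg <- asc_config(16, 0.5, 1.4)
  z <- build_enhancement_map(matrix(0, 32, 32), cfg)
  expect_true(all(z == 1.0))
  o <- build_enhancement_map(matrix(1, 32, 32), cfg)
  expect_true(all(o == 1.4))
})

test_that("one filled kernel enhances exactly that kernel", {
  pred <- matrix(0, 32, 32)
  pred[1:16, 17:32] <- 1
  em <- build_enhancement_map(pred, asc_config(16, 0.5, 1.4))
  expect_true(all(em[1:16, 17:32] == 1.4))
  expect_true(all(em[17:32, ] == 1.0))
  expect_true(all(em[1:16, 1:16] == 1.0))
})

test_that("a kernel mean exactly at the threshold is not enhanced", {
  # kernel mean exactly 0.5: half the pixels at 1
  pred <- matrix(0, 16, 16)
  pred[1:8, ] <- 1
  em <- build_enhancement_map(pred, asc_config(16, 0.5, 1.4))
  expect_true(all(em == 1.0))
  # one pixel more pushes it strictly over
  pred[9, 1] <- 1
  em2 <- build_enhancement_map(pred, asc_config(16, 0.5, 1.4))
  expect_true(all(em2 == 1.4))
})

test_that("maps are two-valued and piecewise-constant on the kernel grid", {
  set.seed(5)
  for (rep in 1:10) {
    ks <- sample(c(4, 8), 1)
    pred <- matrix(runif(32 * 32), 32, 32)
    ef <- 1.4
    em <- build_enhancement_map(pred, asc_config(ks, 0.3, ef))
    expect_true(all(em %in% c(1.0, ef)))
    expect_equal(sum(em == ef) %% ks^2, 0)
  }
})

test_that("non-finite predictions are rejected", {
  bad <- matrix(0.5, 8, 8); bad[3, 3] <- NaN
  expect_error(build_enhancement_map(bad, asc_config(4)), "non-finite")
})

test_that("enhancement application is exact pixel-wise multiplication", {
  x <- matrix(0.5, 4, 4)
  em1 <- matrix(1, 4, 4)
  expect_identical(apply_enhancement(x, em1), x)   # identity map, bit-exact
  em <- matrix(1.4, 4, 4)
  expect_equal(apply_enhancement(x, em)[1, 1], 0.7)
  # random case equals an explicit element-wise loop oracle
  set.seed(8)
  xr <- matrix(runif(64), 8, 8)
  er <- matrix(sample(c(1, 1.1), 64, TRUE), 8, 8)
  want <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) want[i, j] <- xr[i, j] * er[i, j]
  expect_equal(apply_enhancement(xr, er), want)
  expect_error(apply_enhancement(xr, matrix(1, 4, 4)), "shape mismatch")
  # no clipping: normalized values may exceed 1
  expect_equal(apply_enhancement(matrix(0.9, 2, 2), matrix(1.4, 2, 2))[1, 1],
               1.26)
})

test_that("enhance_step composes map construction and application", {
  set.seed(12)
  x <- matrix(runif(32 * 32), 32, 32)
  cfg <- asc_config(8, 0.25, 1.4)
  # all-zero prediction leaves the slice unchanged
  expect_identical(enhance_step(matrix(0, 32, 32), x, cfg), x)
  # all-one prediction scales every pixel by the factor
  expect_equal(enhance_step(matrix(1, 32, 32), x, asc_config(8, 0.25, 1.1)),
               x * 1.1)
  # composition equals the two independent oracles chained
  pred <- matrix(runif(32 * 32), 32, 32)
  want <- x * oracle_enhancement_map(pred, 8, 0.25, 1.4)
  expect_equal(enhance_step(pred, x, cfg), want)
})

test_that("enhancement is monotone and epsilon = 1 disables it", {
  set.seed(13)
  pred <- matrix(runif(16 * 16), 16, 16)
  x <- matrix(runif(16 * 16), 16, 16)
  cfg <- asc_config(4, 0.25, 1.4)
  y <- enhance_step(pred, x, cfg)
  expect_true(all(y >= x - 1e-15))  # EF >= 1 never darkens
  x2 <- x; x2[5, 5] <- x[5, 5] + 0.3
  y2 <- enhance_step(pred, x2, cfg)
  expect_gte(y2[5, 5], y[5, 5])
  # threshold at 1 can never be strictly exceeded by probabilities
  expect_identical(enhance_step(pred, x, asc_config(4, 1, 1.4)), x)
  expect_identical(enhance_step(matrix(1, 16, 16), x, asc_config(4, 1, 1.4)), x)
})

test_that("binarize_first thresholds the prediction before kernel means", {
  pred <- matrix(0.6, 8, 8)  # soft mean 0.6; binarized mean 1
  em_soft <- build_enhancement_map(pred, asc_config(8, 0.7, 1.4))
  expect_true(all(em_soft == 1.0))
  em_bin <- build_enhancement_map(pred, asc_config(8, 0.7, 1.4,
                                                   binarize_first = TRUE))
  expect_true(all(em_bin == 1.4))
})

test_that("asc_config validates its domain", {
  expect_error(asc_config(0), "kernel_size")
  expect_error(asc_config(16, -0.1), "epsilon")
  expect_error(asc_config(16, 1.5), "epsilon")
  expect_error(asc_config(16, 0.5, 0.9), "factor")
})
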