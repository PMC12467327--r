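test_that("confusion counts are exact indicator sums", {
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
  expect_identical(confusion_counts(ones, ones),
                   c(TP = 4L, FP = 0L, FN = 0L, TN = 0L))
  # complement: no agreement anywhere
  set.seed(2)
  G <- matrix(rbinom(16, 1, 0.5), 4, 4)
  cc <- confusion_counts(1 - G, G)
  expect_identical(cc[["TP"]], 0L)
  expect_identical(cc[["TN"]], 0L)
  # random case equals a per-pixel loop oracle
  for (rep in 1:5) {
    P <- matrix(rbinom(256, 1, 0.3), 16, 16)
    G <- matrix(rbinom(256, 1, 0.3), 16, 16)
    expect_identical(confusion_counts(P, G), oracle_confusion(P, G))
  }
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(0, 2, 2)),
               "non-binary")
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape mismatch")
})

test_that("DSC and IoU follow their formulas and conventions", {
  # TP = 2, FP = 1, FN = 1 -> DSC = 4/6, IoU = 2/4
  P <- matrix(c(1, 1, 1, 0), 2); G <- matrix(c(1, 1, 0, 1), 2)
  expect_equal(dsc(P, G), 2 / 3)
  expect_equal(iou(P, G), 0.5)
  ones <- matrix(1, 3, 3); zeros <- matrix(0, 3, 3)
  expect_identical(dsc(ones, ones), 1.0)
  expect_identical(iou(ones, ones), 1.0)
  # disjoint non-empty masks
  A <- matrix(c(1, 0, 0, 0), 2); B <- matrix(c(0, 0, 0, 1), 2)
  expect_identical(dsc(A, B), 0)
  expect_identical(iou(A, B), 0)
  # empty vs empty = perfect agreement on absence; empty vs non-empty = 0
  expect_identical(dsc(zeros, zeros), 1.0)
  expect_identical(iou(zeros, zeros), 1.0)
  expect_identical(dsc(zeros, ones), 0)
  expect_identical(iou(ones, zeros), 0)
})

test_that("metric identities hold over random masks", {
  set.seed(14)
  for (rep in 1:50) {
    P <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    G <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    d <- dsc(P, G); j <- iou(P, G)
    expect_gte(d, j)
    expect_equal(d, 2 * j / (1 + j))           # DSC = 2 IoU / (1 + IoU)
    expect_identical(d, dsc(G, P))             # symmetry
    expect_identical(j, iou(G, P))
    if (d %in% c(0, 1)) expect_identical(d, j) # equality only at the extremes
    else expect_gt(d, j)
  }
})

test_that("metrics_result bundles counts and enforces the pixel identity", {
  m <- metrics_result(TP = 2, FP = 1, FN = 1, TN = 12)
  expect_equal(m$N, 16)
  expect_equal(m$DSC, 2 / 3)
  expect_equal(m$IoU, 0.5)
  expect_equal(m$TP + m$FP + m$FN + m$TN, m$N)
})

test_that("difference maps categorize pixels consistently with the counts", {
  set.seed(15)
  P <- matrix(rbinom(64, 1, 0.4), 8, 8)
  G <- matrix(rbinom(64, 1, 0.4), 8, 8)
  dm <- difference_map(P, G)
  cc <- confusion_counts(P, G)
  expect_identical(sum(dm == 1L), cc[["TP"]])
  expect_identical(sum(dm == 2L), cc[["FN"]])
  expect_identical(sum(dm == 3L), cc[["FP"]])
  expect_identical(sum(dm == 0L), cc[["TN"]])
  # agreement leaves only TN/TP categories
  expect_true(all(difference_map(G, G) %in% c(0L, 1L)))
  # all-foreground prediction on empty truth is all false positive (red)
  dm2 <- difference_map(matrix(1, 4, 4), matrix(0, 4, 4))
  expect_true(all(dm2 == 3L))
  rgb <- render_difference_map(dm2)
  expect_equal(rgb[1, 1, ], c(1, 0, 0))  # red
  rgb3 <- render_difference_map(difference_map(matrix(1, 2, 2),
                                               matrix(1, 2, 2)))
  expect_equal(rgb3[1, 1, ], c(1, 1, 1))  # white TP
  p <- withr::local_tempfile(fileext = ".png")
  render_difference_map(dm, p)
  expect_true(file.exists(p) && file.size(p) > 0)
})

test_that("Dice false-positive sensitivity is the exact derivative", {
  expect_equal(dsc_fp_sensitivity(1, 0, 0), -0.5)
  expect_identical(dsc_fp_sensitivity(0, 5, 3), 0)   # numerator zero
  expect_error(dsc_fp_sensitivity(0, 0, 0), "all-zero")
  dsc_c <- function(TP, FP, FN) 2 * TP / (2 * TP + FP + FN)
  set.seed(16)
  for (rep in 1:30) {
    TP <- sample(0:200, 1); FP <- sample(0:100, 1); FN <- sample(0:100, 1)
    den <- 2 * TP + FP + FN
    if (den == 0) next
    s <- dsc_fp_sensitivity(TP, FP, FN)
    expect_lte(s, 0)  # adding a false positive never raises DSC
    fd <- dsc_c(TP, FP + 1, FN) - dsc_c(TP, FP, FN)
    expect_lte(abs(fd - s), 1 / den^2)
  }
})
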