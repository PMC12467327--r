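test_that("identical spec and seed reproduce the phantom bit for bit", {
  a <- tiny_phantom(seed = 9, noise_sd = 15)
  b <- tiny_phantom(seed = 9, noise_sd = 15)
  expect_identical(a$volume$slices, b$volume$slices)
  expect_identical(a$mask$masks, b$mask$masks)
  c <- tiny_phantom(seed = 10, noise_sd = 15)
  expect_false(identical(a$volume$slices, c$volume$slices))
})

test_that("noiseless phantoms classify into their requested level exactly", {
  for (seed in 1:4) {
    for (lev in c(1, 2)) {
      ph <- tiny_phantom(seed = seed, level = lev, size = 32)
      expect_identical(classify_level(ph$volume, ph$mask), as.character(lev))
      fg <- ph$volume$slices[ph$mask$masks == 1L]
      if (lev == 1) expect_gt(mean(fg), 250)
      else expect_true(mean(fg) >= 100 && mean(fg) <= 250)
    }
  }
})

test_that("zero drift and zero branching give a static cross-section", {
  ph <- tiny_phantom(seed = 5, drift_per_slice = 0, branch_probability = 0,
                     radius_walk_sd = 0)
  cents <- lapply(seq_len(8), function(s) mask_centroid(ph$mask$masks[s, , ]))
  for (s in 2:8) expect_equal(cents[[s]], cents[[1]])
  expect_identical(ph$mask$masks[1, , ], ph$mask$masks[5, , ])
})

test_that("inter-slice centroid displacement respects the drift bound", {
  for (seed in 1:5) {
    ph <- tiny_phantom(seed = seed, drift_per_slice = 2, radius_walk_sd = 0,
                       branch_probability = 0)
    for (s in 2:8) {
      # exact generating centers obey the bound strictly
      d <- sqrt(sum((ph$centers[[s]][1, ] - ph$centers[[s - 1]][1, ])^2))
      expect_lte(d, 2)
      # rasterized mask centroid tracks the center to sub-pixel accuracy
      mc <- mask_centroid(ph$mask$masks[s, , ])
      expect_lt(sqrt(sum((mc - ph$centers[[s]][1, ])^2)), 0.75)
    }
  }
})

test_that("two vessels yield one or two connected components per slice", {
  ph <- tiny_phantom(seed = 21, n_vessels = 2, size = 64, n_slices = 8)
  counts <- vapply(1:8, function(s) component_count(ph$mask$masks[s, , ]), 0L)
  expect_true(all(counts %in% c(1L, 2L)))
})

test_that("branching produces splitting and merging cross-sections", {
  ph <- tiny_phantom(seed = 31, branch_probability = 0.5, n_slices = 12)
  counts <- vapply(1:12, function(s) component_count(ph$mask$masks[s, , ]), 0L)
  expect_true(all(counts >= 1L & counts <= 2L))
  expect_true(length(unique(counts)) > 1L)  # at least one split/merge event
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(level = 3), "level")
  expect_error(phantom_spec(drift_per_slice = -1), "drift")
  expect_error(phantom_spec(branch_probability = 1.5), "branch")
  expect_error(phantom_spec(vessel_radius = 40, height = 32, width = 32),
               "radius exceeding image bounds")
})

test_that("generate_dataset writes classified NRRD pairs deterministically", {
  specs <- list(phantom_spec(level = 1, seed = 41, height = 32, width = 32),
                phantom_spec(level = 2, seed = 42, height = 32, width = 32),
                phantom_spec(level = 2, seed = 43, height = 32, width = 32,
                             noise_sd = 0))
  d1 <- withr::local_tempdir()
  man <- generate_dataset(specs, d1)
  expect_s3_class(man, "case_manifest")
  expect_equal(nrow(man), 3L)
  expect_equal(anyDuplicated(man$case_id), 0L)
  expect_identical(man$level, c("1", "2", "2"))
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(man$mask_path)))
  # levels in the manifest are re-derived from the written files
  for (i in 1:3) {
    v <- read_volume(man$path[i]); m <- read_mask(man$mask_path[i])
    expect_identical(classify_level(v, m), man$level[i])
  }
  # rerun with the same seeds: byte-identical files
  d2 <- withr::local_tempdir()
  generate_dataset(specs, d2)
  for (f in basename(c(man$path, man$mask_path))) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
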