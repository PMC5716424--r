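test_that("phantom generation is deterministic and piecewise-constant without texture", {
  spec <- small_spec(seed = 11, texture = 0, jitter = 0)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$voxels, b$voxels)
  expect_setequal(unique(as.vector(a$voxels)), c(-1000, 40, 700))
})

test_that("textured phantom keeps its histogram modes at the material HUs", {
  vol <- small_phantom(seed = 2)
  v <- as.vector(vol$voxels)
  expect_identical(as.numeric(names(which.max(table(v)))), -1000)
  soft <- v[v > -100 & v < 200]
  expect_lte(abs(as.numeric(names(which.max(table(soft)))) - 40), 1)
  bone <- v[v > 500]
  expect_lte(abs(as.numeric(names(which.max(table(bone)))) - 700), 2)
})

test_that("a spine insert outside the body ellipse is rejected", {
  expect_error(
    phantom_spec(n_slices = 4, n_rows = 64, n_cols = 64,
                 spine_center = c(63, 32)),
    "outside the body")
  expect_error(
    phantom_spec(n_slices = 4, n_rows = 64, n_cols = 64,
                 spine_center = c(20, 32)),
    "posterior")
})

test_that("a clean split is a pair of exact crops with identical overlap columns", {
  full <- small_phantom()
  sp <- split_phantom(full, split_spec(overlap_cols = 48))
  wl <- dim(sp$left$voxels)[3]
  expect_identical(sp$left$side, "left")
  expect_identical(sp$right$side, "right")
  expect_identical(sp$left$voxels[, , seq.int(wl - 47, wl)],
                   sp$right$voxels[, , 1:48])
  expect_identical(sp$truth$delta_rl, 48L)
  ## left covers the first columns, right the last ones
  expect_identical(sp$left$voxels, full$voxels[, , 1:wl, drop = FALSE])
})

test_that("a half-width overlap reproduces the three-quarter crop protocol", {
  full <- small_phantom()
  sp <- split_phantom(full, split_spec(overlap_cols = 80))
  expect_identical(dim(sp$left$voxels)[3], 120L)   # 0.75 * 160
  expect_identical(dim(sp$right$voxels)[3], 120L)
})

test_that("AP shift displaces the right scan by whole rows with air fill", {
  full <- small_phantom()
  plain <- split_phantom(full, split_spec(overlap_cols = 48))
  shifted <- split_phantom(full, split_spec(overlap_cols = 48, ap_shift = 1))
  nr <- dim(full$voxels)[2]
  expect_identical(shifted$right$voxels[, seq_len(nr - 1), ],
                   plain$right$voxels[, seq.int(2, nr), ])
  expect_true(all(shifted$right$voxels[, nr, ] == -1000))
  expect_identical(shifted$left$voxels, plain$left$voxels)
})

test_that("SI shift drops unacquired edge slices", {
  full <- small_phantom()
  sp <- split_phantom(full, split_spec(overlap_cols = 48, si_shift = 2))
  expect_identical(dim(sp$right$voxels)[1], dim(full$voxels)[1] - 2L)
  ## right slice i holds the anatomy of full slice i + 2
  expect_identical(sp$right$voxels[1, , ],
                   full$voxels[3, , seq.int(160 - 104 + 1, 160)])
  sp2 <- split_phantom(full, split_spec(overlap_cols = 48, si_shift = -2))
  expect_identical(dim(sp2$left$voxels)[1], dim(full$voxels)[1] - 2L)
})

test_that("edge deformation touches only the truncated band", {
  full <- small_phantom()
  clean <- split_phantom(full, split_spec(overlap_cols = 48))
  warped <- split_phantom(full, split_spec(overlap_cols = 48,
                                           deform_margin = 8,
                                           deform_strength = 0.5))
  wl <- dim(clean$left$voxels)[3]
  expect_identical(warped$left$voxels[, , seq_len(wl - 8)],
                   clean$left$voxels[, , seq_len(wl - 8)])
  expect_false(identical(warped$left$voxels[, , seq.int(wl - 7, wl)],
                         clean$left$voxels[, , seq.int(wl - 7, wl)]))
  wr <- dim(clean$right$voxels)[3]
  expect_identical(warped$right$voxels[, , seq.int(9, wr)],
                   clean$right$voxels[, , seq.int(9, wr)])
  expect_false(identical(warped$right$voxels[, , 1:8],
                         clean$right$voxels[, , 1:8]))
})

test_that("an overlap too narrow for the deformed bands is rejected", {
  full <- small_phantom()
  expect_error(split_phantom(full, split_spec(overlap_cols = 16,
                                              deform_margin = 8)),
               "no clean region")
})

test_that("per-scan noise is independent and at the requested level", {
  full <- small_phantom()
  clean <- split_phantom(full, split_spec(overlap_cols = 48))
  noisy <- split_phantom(full, split_spec(overlap_cols = 48,
                                          noise_sigma = 20, seed = 5))
  rl <- noisy$left$voxels - clean$left$voxels
  rr <- noisy$right$voxels - clean$right$voxels
  expect_gt(sd(rl), 18); expect_lt(sd(rl), 22)
  ## overlap noise of the two scans is uncorrelated
  wl <- dim(clean$left$voxels)[3]
  a <- as.vector(rl[, , seq.int(wl - 47, wl)])
  b <- as.vector(rr[, , 1:48])
  expect_lt(abs(cor(a, b)), 0.05)
  ## same seed reproduces the same noise
  again <- split_phantom(full, split_spec(overlap_cols = 48,
                                          noise_sigma = 20, seed = 5))
  expect_identical(again$left$voxels, noisy$left$voxels)
})
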