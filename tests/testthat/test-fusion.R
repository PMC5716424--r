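test_that("SI alignment drops exactly the unpaired slices", {
  full <- generate_phantom(phantom_spec(n_slices = 20, n_rows = 64,
                                        n_cols = 96))
  l <- crop_volume(full, 0.75, "left")
  r <- crop_volume(full, 0.75, "right")
  al0 <- align_si(l, r, 0)
  expect_identical(al0$left$voxels, l$voxels)
  expect_identical(al0$right$voxels, r$voxels)

  al1 <- align_si(l, r, 1)
  expect_identical(dim(al1$left$voxels)[1], 19L)
  expect_identical(dim(al1$right$voxels)[1], 19L)

  expect_error(align_si(l, r, 20), "consumes all slices")
})

test_that("re-estimating on SI-aligned scans yields a zero slice shift", {
  full <- small_phantom(seed = 16)
  sp <- split_phantom(full, split_spec(overlap_cols = 48, si_shift = 2))
  al <- align_si(sp$left, sp$right, 2)
  est <- estimate_offsets(al$left, al$right, locate_spine(al$left),
                          locate_spine(al$right))
  expect_identical(est$delta_si, 0L)
  expect_identical(est$delta_rl, 48L)
})

test_that("AP alignment displaces rows with fill and near-inverts", {
  vol <- small_phantom(seed = 17)
  expect_identical(align_ap(vol, 0)$voxels, vol$voxels)
  back <- align_ap(align_ap(vol, 1), -1)
  nr <- dim(vol$voxels)[2]
  expect_identical(back$voxels[, seq_len(nr - 1), ],
                   vol$voxels[, seq_len(nr - 1), ])
  expect_true(all(back$voxels[, nr, ] == -1000))
})

test_that("AP alignment restores row correspondence on a shifted split", {
  full <- small_phantom(seed = 18)
  sp <- split_phantom(full, split_spec(overlap_cols = 48, ap_shift = 1))
  aligned <- align_ap(sp$right, 1)
  wl <- dim(sp$left$voxels)[3]
  nr <- dim(sp$left$voxels)[2]
  expect_identical(aligned$voxels[, 2:nr, 1:48],
                   sp$left$voxels[, 2:nr, seq.int(wl - 47, wl)])
})

test_that("stitching clean three-quarter crops reproduces the original exactly", {
  full <- small_phantom(seed = 19)
  l <- crop_volume(full, 0.75, "left")
  r <- crop_volume(full, 0.75, "right")
  est <- estimate_offsets(l, r, locate_spine(l), locate_spine(r))
  for (mode in c("left_centered", "right_centered", "average")) {
    fused <- fuse(l, r, est, fusion_config(mode))
    expect_identical(fused$voxels, full$voxels)
    expect_identical(fused$side, "full")
  }
})

test_that("fusion modes differ only where the two scans disagree", {
  dims <- c(3, 5, 20)
  l <- ct_volume(array(100, dim = dims), side = "left")
  r <- ct_volume(array(200, dim = dims), side = "right")
  off <- offset_estimate(0, 0, 8)
  fl <- fuse(l, r, off, fusion_config("left_centered"))
  fr <- fuse(l, r, off, fusion_config("right_centered"))
  fa <- fuse(l, r, off, fusion_config("average"))
  expect_identical(dim(fa$voxels)[3], 32L)       # 20 + 20 - 8
  ov <- 13:20                                     # overlap columns
  expect_true(all(fl$voxels[, , ov] == 100))
  expect_true(all(fr$voxels[, , ov] == 200))
  expect_true(all(fa$voxels[, , ov] == 150))
  ## outside the overlap all modes copy the sole source
  expect_identical(fl$voxels[, , -ov], fa$voxels[, , -ov])

  same <- fuse(l, ct_volume(array(100, dim = dims), side = "right"), off,
               fusion_config("average"))
  expect_true(all(same$voxels == 100))
})

test_that("fused width is conserved for arbitrary geometries", {
  withr::local_seed(20)
  for (i in 1:10) {
    wl <- sample(12:30, 1); wr <- sample(12:30, 1)
    o <- sample(4:min(wl, wr), 1)
    m <- sample(0:min(2, (o - 1) %/% 2), 1)
    l <- ct_volume(array(rnorm(2 * 3 * wl), dim = c(2, 3, wl)), side = "left")
    r <- ct_volume(array(rnorm(2 * 3 * wr), dim = c(2, 3, wr)), side = "right")
    fused <- fuse(l, r, offset_estimate(0, 0, o),
                  fusion_config("average", margin = m))
    expect_identical(dim(fused$voxels)[3], as.integer(wl + wr - o))
  }
})

test_that("margin fusion never copies a deformed column", {
  full <- small_phantom(seed = 22)
  sp <- split_phantom(full, split_spec(overlap_cols = 48, deform_margin = 8,
                                       deform_strength = 0.5))
  cfg <- stitch_config(margin = 8)
  est <- estimate_offsets(sp$left, sp$right, locate_spine(sp$left),
                          locate_spine(sp$right), cfg)
  expect_identical(est$delta_rl, 48L)
  fused <- fuse(sp$left, sp$right, est, fusion_config("average", margin = 8))
  ## deformed bands lived only in the subtracted margins, so the output
  ## is the clean original
  expect_identical(fused$voxels, full$voxels)
})

test_that("degenerate fusion geometry is rejected", {
  l <- ct_volume(array(0, dim = c(2, 3, 10)), side = "left")
  r <- ct_volume(array(0, dim = c(2, 3, 10)), side = "right")
  expect_error(fuse(l, r, offset_estimate(0, 0, 4),
                    fusion_config("average", margin = 2)),
               "no overlap remains")
  bad_rows <- ct_volume(array(0, dim = c(2, 4, 10)), side = "right")
  expect_error(fuse(l, bad_rows, offset_estimate(0, 0, 4), fusion_config()),
               "mismatched row")
})
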