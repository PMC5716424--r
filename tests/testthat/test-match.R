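test_that("an exact suffix-prefix overlap is found with zero RMSE", {
  withr::local_seed(21)
  x <- round(rnorm(96, 0, 100))
  left <- line_profile(x[1:72], 1, 1, "left")
  right <- line_profile(x[25:96], 1, 1, "right")
  mc <- match_varied(left, right, delta_min = 2)
  expect_identical(mc$delta_star, 48L)
  expect_identical(mc$rmse_min, 0)
})

test_that("a strict ramp only matches itself at full overlap", {
  ramp <- line_profile(as.double(0:47), 1, 1, "left")
  mc <- match_varied(ramp, line_profile(as.double(0:47), 1, 1, "right"),
                     delta_min = 2)
  expect_identical(mc$delta_star, 48L)
  expect_identical(sum(mc$rmse == 0), 1L)
})

test_that("constant profiles tie everywhere and resolve to the largest overlap", {
  flat <- rep(100, 30)
  mc <- match_varied(flat, flat, delta_min = 2)
  expect_true(all(mc$rmse == 0))
  expect_identical(mc$delta_star, 30L)
  mf <- match_fixed(flat, flat, query_center = 15, query_len = 8)
  expect_true(all(mf$rmse == 0))
  expect_identical(mf$delta_star, max(mf$delta))
})

test_that("the fixed query locks onto an identical plateau", {
  withr::local_seed(5)
  lv <- rep(0, 60); lv[30:44] <- round(rnorm(15, 700, 10))
  rv <- rep(0, 50); rv[10:24] <- lv[30:44]
  mc <- match_fixed(lv, rv, query_center = 37, query_len = 19)
  expect_identical(mc$rmse_min, 0)
  ## alignment: left col 30 = right col 10 -> overlap = 60 - 30 + 10 = 40
  expect_identical(mc$delta_star, 40L)
})

test_that("fixed- and varied-length matching agree on clean splits", {
  full <- small_phantom(seed = 6)
  sp <- split_phantom(full, split_spec(overlap_cols = 48))
  rect <- locate_spine(sp$left)
  lp <- preprocess_profile(extract_profile(sp$left, rect$slice, rect$row))
  rp <- preprocess_profile(extract_profile(sp$right, rect$slice, rect$row))
  mv <- match_varied(lp, rp)
  mf <- match_fixed(lp, rp, query_center = rect$col, query_len = 32)
  expect_identical(mv$delta_star, 48L)
  expect_identical(mf$delta_star, 48L)
})

test_that("matching margins discard deformed edges and recover the truth", {
  full <- small_phantom(seed = 7)
  sp <- split_phantom(full, split_spec(overlap_cols = 48, deform_margin = 6,
                                       deform_strength = 0.6))
  rect <- locate_spine(sp$left)
  lp <- extract_profile(sp$left, rect$slice, rect$row)
  rp <- extract_profile(sp$right, rect$slice, rect$row)
  mc <- match_varied(lp, rp, margin = 6)
  ## the curve is on the trimmed profiles: truth = 48 - 2*6
  expect_identical(mc$delta_star, 36L)
  expect_identical(mc$rmse_min, 0)
})

test_that("matcher outputs equal the brute-force recomputation", {
  withr::local_seed(31)
  for (i in 1:10) {
    lv <- random_profile_values(sample(30:60, 1))
    rv <- random_profile_values(sample(30:60, 1))
    mv <- match_varied(lv, rv, delta_min = 4)
    ov <- oracle_match_varied(lv, rv, 4)
    expect_identical(mv$delta_star, as.integer(ov$delta_star))
    expect_equal(mv$rmse, ov$rmse, tolerance = 1e-12)
    qc <- length(lv) %/% 2
    mf <- match_fixed(lv, rv, query_center = qc, query_len = 12)
    of <- oracle_match_fixed(lv, rv, qc, 12)
    expect_identical(mf$delta_star, as.integer(of$delta_star))
    expect_equal(mf$rmse, of$rmse, tolerance = 1e-12)
  }
})

test_that("the match curve is invariant to intensity shift and equivariant to scale", {
  withr::local_seed(8)
  lv <- random_profile_values(50)
  rv <- random_profile_values(45)
  base <- match_varied(lv, rv, delta_min = 4)
  shifted <- match_varied(lv + 300, rv + 300, delta_min = 4)
  expect_identical(shifted$rmse, base$rmse)
  expect_identical(shifted$delta_star, base$delta_star)
  scaled <- match_varied(lv * 2.5, rv * 2.5, delta_min = 4)
  expect_equal(scaled$rmse, base$rmse * 2.5, tolerance = 1e-12)
  expect_identical(scaled$delta_star, base$delta_star)
})

test_that("the argmin is unchanged by the square root", {
  withr::local_seed(9)
  lv <- random_profile_values(40)
  rv <- random_profile_values(40)
  mc <- match_varied(lv, rv, delta_min = 4)
  mse <- mc$rmse^2
  expect_identical(which.min(mse), which.min(mc$rmse))
})

test_that("degenerate matcher inputs are rejected", {
  expect_error(match_varied(rep(1, 5), rep(1, 40), delta_min = 8),
               "delta_min")
  expect_error(match_varied(rep(1, 20), rep(1, 20), delta_min = 1),
               "at least 2")
  expect_error(match_fixed(rep(1, 20), rep(1, 20), query_center = 2,
                           query_len = 10),
               "outside the left profile")
  expect_error(match_fixed(rep(1, 40), rep(1, 8), query_center = 20,
                           query_len = 10),
               "longer than the right profile")
})
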