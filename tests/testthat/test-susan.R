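test_that("constant images pass through unchanged", {
  img <- volume_image(array(7, c(6, 6, 6)))
  mask <- array(TRUE, c(6, 6, 6))
  out <- susan_smooth(img, mask, sigma_mm = 1)
  expect_equal(as.numeric(out), rep(7, 216))
})

test_that("smoothing matches direct summation and preserves a sharp edge", {
  set.seed(21)
  arr <- array(0, c(10, 6, 6))
  arr[1:5, , ] <- 10 + rnorm(180, sd = 0.3)
  arr[6:10, , ] <- 100 + rnorm(180, sd = 0.3)
  img <- volume_image(arr)
  mask <- array(TRUE, dim = dim(arr))
  t_br <- 2
  out <- susan_smooth(img, mask, sigma_mm = 1, brightness_threshold = t_br)
  oracle <- susan_oracle(img, mask, 1, t_br)
  expect_equal(as.numeric(out), oracle, tolerance = 1e-12)
  # step of 90 with t = 2: cross-edge weights < 1e-6, each side stays
  # within its own input range
  side <- rep(c(TRUE, FALSE), times = c(180, 180))
  low <- arr[mask][side]
  high <- arr[mask][!side]
  expect_true(all(out[side] >= min(low) & out[side] <= max(low)))
  expect_true(all(out[!side] >= min(high) & out[!side] <= max(high)))
})

test_that("an isolated masked voxel is returned unchanged", {
  arr <- array(rnorm(125), c(5, 5, 5))
  mask <- array(FALSE, c(5, 5, 5))
  mask[3, 3, 3] <- TRUE
  out <- susan_smooth(volume_image(arr), mask, sigma_mm = 1)
  expect_equal(as.numeric(out), arr[3, 3, 3])
})

test_that("output is a convex combination of masked neighbour values", {
  set.seed(31)
  for (rep in 1:5) {
    arr <- array(rnorm(343, 50, 20), c(7, 7, 7))
    mask <- array(runif(343) < 0.6, c(7, 7, 7))
    if (!any(mask)) next
    out <- susan_smooth(volume_image(arr), mask, sigma_mm = 1.5)
    vals <- arr[mask]
    expect_true(all(out >= min(vals) - 1e-12 & out <= max(vals) + 1e-12))
  }
})

test_that("anisotropic voxels use millimetre distances", {
  set.seed(41)
  arr <- array(rnorm(150, 10), c(5, 5, 6))
  img <- volume_image(arr, voxel_size = c(1, 1, 2))
  mask <- array(TRUE, dim = dim(arr))
  out <- susan_smooth(img, mask, sigma_mm = 1.2, brightness_threshold = 5)
  expect_equal(as.numeric(out), susan_oracle(img, mask, 1.2, 5),
               tolerance = 1e-12)
})

test_that("invalid parameters are rejected", {
  img <- volume_image(array(1, c(4, 4, 4)))
  mask <- array(TRUE, c(4, 4, 4))
  expect_error(susan_smooth(img, mask, sigma_mm = 0), "sigma_mm")
  expect_error(susan_smooth(img, mask, sigma_mm = 1,
                            brightness_threshold = -2),
               "brightness_threshold")
  expect_error(susan_smooth(img, array(FALSE, c(4, 4, 4))), "empty")
})
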