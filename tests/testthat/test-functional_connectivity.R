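test_that("buffering is the identity at distance 0 and on full masks", {
  set.seed(3)
  m <- random_mask(16, 16, p = 0.2)
  expect_identical(buffer_mask(m, 0), m)
  full <- stratum_mask(matrix(TRUE, 8, 8), "grass", 1.5)
  expect_identical(buffer_mask(full, 100)$values, full$values)
})

test_that("buffering one pixel reaches exactly the centers within range", {
  v <- matrix(FALSE, 9, 9); v[5, 5] <- TRUE
  m <- stratum_mask(v, "tree", 1.5)
  b <- buffer_mask(m, 3.0)
  rr <- row(v); cc <- col(v)
  expected <- ((rr - 5)^2 + (cc - 5)^2) * 1.5^2 <= 3.0^2
  expect_identical(b$values, expected)
  # 3.0 m at 1.5 m pixels: orthogonal offset 2 (= 3.0 m) is inside,
  # diagonal offset (2,1) (= 3.354 m) is not
  expect_true(b$values[5, 7])
  expect_false(b$values[4, 7])
})

test_that("buffers nest and agree with the brute-force dilation oracle", {
  set.seed(17)
  for (i in 1:5) {
    m <- random_mask(24, 24, p = 0.05)
    if (!any(m$values)) next
    d2_oracle <- brute_distmap_sq(m)
    prev <- NULL
    for (d in seq(0, 10, by = 2)) {
      b <- buffer_mask(m, d)
      expect_identical(b$values, d2_oracle <= d^2)
      if (!is.null(prev)) expect_true(all(b$values[prev]))
      prev <- b$values
    }
  }
})

test_that("functional curves run from the structural CI down to full cover", {
  full <- stratum_mask(matrix(TRUE, 6, 6), "green2d", 1.5)
  cv <- functional_curve(full)
  expect_equal(cv$distances_m, 0)
  expect_equal(cv$ci_values, 0)
  expect_true(cv$terminated_full_cover)

  empty <- stratum_mask(matrix(FALSE, 6, 6), "grass", 1.5)
  expect_error(functional_curve(empty), "empty mask")

  # two single-pixel patches 10 px apart on a 32x32 grid, verified per step
  v <- matrix(FALSE, 32, 32); v[16, 10] <- TRUE; v[16, 20] <- TRUE
  m <- stratum_mask(v, "shrub", 1.5)
  cv <- functional_curve(m, step_m = 1)
  expect_equal(cv$ci_values[1], connectivity_index(label_patches(m)))
  d2_oracle <- brute_distmap_sq(m)
  for (k in seq_along(cv$distances_m)) {
    bm <- stratum_mask(d2_oracle <= cv$distances_m[k]^2, "shrub", 1.5)
    expect_equal(cv$ci_values[k], connectivity_index(label_patches(bm)))
  }
  expect_true(cv$terminated_full_cover)
  expect_equal(cv$ci_values[length(cv$ci_values)], 0)
  expect_true(all(diff(cv$ci_values) <= 1e-12))

  # the two patches merge once buffers of d >= half the 15 m gap meet
  merge_d <- cv$distances_m[which(vapply(cv$distances_m, function(d)
    length(label_patches(stratum_mask(d2_oracle <= d^2, "shrub",
                                      1.5))$patch_areas_m2),
    numeric(1)) == 1)][1]
  expect_equal(merge_d, 8)  # first integer step with 2 d >= 15 m
})

test_that("a max-distance cap stops the curve with a warning", {
  v <- matrix(FALSE, 32, 32); v[1, 1] <- TRUE; v[32, 32] <- TRUE
  m <- stratum_mask(v, "tree", 1.5)
  expect_warning(cv <- functional_curve(m, max_distance_m = 3), "max_distance")
  expect_false(cv$terminated_full_cover)
  expect_gt(cv$ci_values[length(cv$ci_values)], 0)
})

test_that("threshold distances use the first strict crossing", {
  cv <- connectivity_curve("green2d", 0:3, c(0.9, 0.3, 0.14, 0), TRUE)
  expect_equal(threshold_distance(cv), 2)
  cv0 <- connectivity_curve("grass", c(0, 1), c(0.10, 0), TRUE)
  expect_equal(threshold_distance(cv0), 0)
  high <- connectivity_curve("tree", c(0, 1), c(0.9, 0.8), FALSE)
  expect_true(is.na(threshold_distance(high)))
})

test_that("bias curves difference the stratum against the 2D layer", {
  a <- connectivity_curve("grass", 0:3, c(0.9, 0.3, 0.14, 0), TRUE)
  expect_equal(bias_curve(a, a)$delta_ci, rep(0, 4))

  g2 <- connectivity_curve("green2d", 0:1, c(0.5, 0), TRUE)
  b <- bias_curve(a, g2)
  expect_equal(b$distances_m, 0:3)
  expect_equal(b$delta_ci, c(0.4, 0.3, 0.14, 0))  # trailing zeros for 2D
  expect_equal(unname(peak_bias(b)), c(0, 0.4))

  expect_error(bias_curve(a, connectivity_curve("green2d", c(0, 2), c(0.5, 0),
                                                TRUE)), "same step")

  zero <- bias_curve(g2, g2)
  expect_equal(unname(peak_bias(zero)), c(0, 0))  # tie broken to distance 0
})

test_that("stratum bias is non-negative on synthetic scenes", {
  cfg <- archetype_params("planned_green", 48, 48, seed = 2)
  masks <- stratify_scene2(cfg)
  cv2d <- functional_curve(masks$green2d)
  for (s in c("grass", "shrub", "tree")) {
    if (!any(masks[[s]]$values)) next
    b <- bias_curve(functional_curve(masks[[s]]), cv2d)
    expect_true(all(b$delta_ci >= -1e-12))
  }
})
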