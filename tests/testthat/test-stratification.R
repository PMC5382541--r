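test_that("NDVI follows (nir - red)/(nir + red) with a zero fill", {
  p <- reflectance_pair(matrix(c(0.05, 0.3, 0), 1), matrix(c(0.45, 0.3, 0), 1))
  expect_equal(compute_ndvi(p)$values, matrix(c(0.8, 0, 0), 1))
  expect_error(reflectance_pair(matrix(0.1, 2, 2), matrix(0.1, 2, 3)),
               "shape")
  expect_error(reflectance_pair(matrix(1.2), matrix(0.4)), "\\[0, 1\\]")
})

test_that("vegetation and voxel presence thresholds are inclusive", {
  nd <- ndvi_grid(matrix(c(0.2, 0.199, -0.5, 0.9), 2), 1.5)
  veg <- vegetation_mask(nd)
  expect_identical(veg$values, matrix(c(TRUE, FALSE, FALSE, TRUE), 2))

  allneg <- vegetation_mask(ndvi_grid(matrix(runif(16, -1, -0.1), 4), 1.5))
  expect_equal(landscape_proportion(label_patches(allneg)), 0)

  can <- voxel_canopy(array(c(0.01, 0.0099, 0, 1), c(2, 2, 1)))
  expect_identical(voxel_presence(can)[, , 1],
                   matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
  expect_false(any(voxel_presence(voxel_canopy(array(0, c(3, 3, 4))))))
})

# one-column canopy helper: TRUE at the given level indices (1-based)
column_canopy <- function(levels_true, n_levels = 16) {
  a <- array(0, c(1, 1, n_levels))
  a[1, 1, levels_true] <- 0.5
  voxel_canopy(a)
}

test_that("strata are assigned by voxel-center height bands", {
  g2 <- stratum_mask(matrix(TRUE, 1, 1), "green2d", 1.5)
  th <- strata_thresholds()

  # level centers: 0.25, 0.75, ..., (k - 0.5) * 0.5
  grass_only <- project_strata(voxel_presence(column_canopy(1)), g2)
  expect_true(grass_only$grass$values[1, 1])
  expect_false(grass_only$shrub$values[1, 1] || grass_only$tree$values[1, 1])

  # vegetation at 0.4 m (level 1), 3.2 m (level 7), 6.1 m (level 13)
  st <- project_strata(voxel_presence(column_canopy(c(1, 7, 13))), g2)
  expect_true(st$grass$values && st$shrub$values && st$tree$values)

  # understorey: grass at 0.2 m plus crown at 6 m -> both layers
  st <- project_strata(voxel_presence(column_canopy(c(1, 13))), g2)
  expect_true(st$grass$values && st$tree$values)
  expect_false(st$shrub$values[1, 1])

  # shrub band is closed: centers at exactly 0.5 and 4.0 m are shrub
  th2 <- strata_thresholds(grass_max_h = 0.75)  # center 0.75 = grass_max_h
  st <- project_strata(voxel_presence(column_canopy(2)), g2, thresholds = th2)
  expect_true(st$shrub$values[1, 1])
  expect_false(st$grass$values[1, 1])

  # voxel vegetation with green2d FALSE is excluded everywhere
  g0 <- stratum_mask(matrix(FALSE, 1, 1), "green2d", 1.5)
  st <- project_strata(voxel_presence(column_canopy(c(1, 7, 13))), g0)
  expect_false(st$grass$values || st$shrub$values || st$tree$values)
})

test_that("stratified layers are subsets of green2d and threshold-monotone", {
  cfg <- archetype_params("planned_green", 48, 48, seed = 9)
  sc <- generate_scene(cfg)
  masks <- stratify_scene(sc$reflectance, sc$canopy)
  for (s in c("grass", "shrub", "tree"))
    expect_true(all(masks$green2d$values[masks[[s]]$values]))

  # projection is idempotent wrt re-running on the same inputs
  masks2 <- stratify_scene(sc$reflectance, sc$canopy)
  expect_identical(masks, masks2)

  # raising cover_min never adds pixels to any stratum
  strict <- stratify_scene(sc$reflectance, sc$canopy,
                           strata_thresholds(cover_min = 0.3))
  for (s in c("grass", "shrub", "tree"))
    expect_true(all(masks[[s]]$values[strict[[s]]$values]))
})

test_that("NDVI grids on a different resolution are resampled to the voxels", {
  v <- matrix(1:4, 2, 2)
  r <- resample_nearest(v, 4, 4)
  expect_equal(dim(r), c(4L, 4L))
  expect_equal(r[1:2, 1:2], matrix(1L, 2, 2))
  expect_equal(r[3:4, 3:4], matrix(4L, 2, 2))
  expect_identical(resample_nearest(v, 2, 2), v)

  # coarser NDVI combined with a finer voxel grid
  g2 <- stratum_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2), "green2d", 3)
  pres <- array(TRUE, c(4, 4, 1))
  st <- project_strata(pres, g2, pixel_size_m = 1.5)
  expect_identical(st$grass$values, resample_nearest(g2$values, 4, 4))
})
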