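#' Stratification thresholds
#'
#' The thresholds that turn reflectance and voxel cover into binary
#' vegetation layers: the NDVI cut-off for vegetation presence, the minimum
#' fractional cover for a voxel to count as vegetated, and the height bands
#' separating grass, shrub and tree strata.
#'
#' Band membership is decided by the voxel-center height `h`:
#' grass `h < grass_max_h`; shrub `grass_max_h <= h <= shrub_max_h`
#' (closed interval); tree `h > shrub_max_h`. Every vegetated voxel thus
#' belongs to exactly one band.
#'
#' @param ndvi_min Minimum NDVI for vegetation, inclusive (default 0.2).
#' @param cover_min Minimum fractional voxel cover, inclusive (default 0.01,
#'   i.e. 1%).
#' @param grass_max_h Upper height bound of the grass band, metres
#'   (default 0.5).
#' @param shrub_max_h Upper height bound of the shrub band, metres
#'   (default 4).
#' @return An object of class `strata_thresholds`.
#' @export
strata_thresholds <- function(ndvi_min = 0.2, cover_min = 0.01,
                              grass_max_h = 0.5, shrub_max_h = 4) {
  if (!is.numeric(ndvi_min) || ndvi_min < -1 || ndvi_min > 1)
    stop("ndvi_min must lie in [-1, 1]")
  if (!is.numeric(cover_min) || cover_min <= 0 || cover_min >= 1)
    stop("cover_min must lie in (0, 1)")
  if (!(grass_max_h > 0 && grass_max_h < shrub_max_h))
    stop("height bands require 0 < grass_max_h < shrub_max_h")
  structure(list(ndvi_min = ndvi_min, cover_min = cover_min,
                 grass_max_h = grass_max_h, shrub_max_h = shrub_max_h),
            class = "strata_thresholds")
}

#' Compute NDVI from a red/NIR reflectance pair
#'
#' Elementwise `(nir - red) / (nir + red)`. Pixels where both bands are zero
#' have no defined ratio; they are filled with 0, which classifies them as
#' non-vegetated under any positive NDVI threshold.
#'
#' @param pair A [reflectance_pair()].
#' @return An [ndvi_grid()].
#' @examples
#' p <- reflectance_pair(matrix(0.05), matrix(0.45))
#' compute_ndvi(p)$values  # 0.8
#' @export
compute_ndvi <- function(pair) {
  stopifnot(inherits(pair, "reflectance_pair"))
  s <- pair$nir + pair$red
  v <- ifelse(s == 0, 0, (pair$nir - pair$red) / s)
  ndvi_grid(v, pair$pixel_size_m)
}

#' NDVI vegetation mask (the 2D green-cover layer)
#'
#' A pixel is vegetated iff its NDVI is greater than or equal to the
#' threshold (0.2 by default), giving the 2D greenspace map that an optical
#' sensor alone can provide.
#'
#' @param ndvi An [ndvi_grid()].
#' @param thresholds A [strata_thresholds()].
#' @return A [stratum_mask()] with stratum `"green2d"`.
#' @export
vegetation_mask <- function(ndvi, thresholds = strata_thresholds()) {
  stopifnot(inherits(ndvi, "ndvi_grid"))
  stratum_mask(ndvi$values >= thresholds$ndvi_min, "green2d",
               ndvi$pixel_size_m)
}

#' Voxel presence/absence from fractional cover
#'
#' A voxel is vegetated iff its fractional cover meets the minimum
#' (1% by default); voxels with less are treated as empty.
#'
#' @param canopy A [voxel_canopy()].
#' @param thresholds A [strata_thresholds()].
#' @return 3D logical array of the same shape as `canopy$cover`.
#' @export
voxel_presence <- function(canopy, thresholds = strata_thresholds()) {
  stopifnot(inherits(canopy, "voxel_canopy"))
  canopy$cover >= thresholds$cover_min
}

#' Project voxel presence into per-stratum 2D masks
#'
#' Collapses the 3D presence grid onto the ground: a column belongs to a
#' stratum iff (a) the 2D NDVI mask marks it vegetated and (b) at least one
#' vegetated voxel's center height falls in that stratum's band. A column
#' may belong to several strata at once — grass under a tree crown shows up
#' in both the grass and tree layers (understorey detection is the point of
#' a waveform sensor). Columns vegetated in the voxel grid but not in the
#' NDVI mask are excluded from every stratum.
#'
#' If the NDVI mask's shape differs from the voxel grid it is resampled to
#' the voxel grid by nearest neighbour first.
#'
#' @param presence 3D logical array from [voxel_presence()].
#' @param green2d The NDVI-derived [stratum_mask()] (`"green2d"`).
#' @param voxel_height_m,base_height_m Vertical geometry of the voxel grid.
#' @param pixel_size_m Horizontal cell size of the voxel grid, metres.
#' @param thresholds A [strata_thresholds()].
#' @return Named list of [stratum_mask()]s: `grass`, `shrub`, `tree`.
#' @export
project_strata <- function(presence, green2d, voxel_height_m = 0.5,
                           base_height_m = 0, pixel_size_m = green2d$pixel_size_m,
                           thresholds = strata_thresholds()) {
  stopifnot(is.array(presence), length(dim(presence)) == 3L,
            inherits(green2d, "stratum_mask"))
  d <- dim(presence)
  g2 <- green2d$values
  if (!identical(dim(g2), d[1:2])) {
    g2 <- resample_nearest(g2, d[1], d[2])
    if (!identical(dim(g2), d[1:2]))
      stop("green2d mask cannot be mapped onto the voxel grid")
  }
  centers <- base_height_m + (seq_len(d[3]) - 0.5) * voxel_height_m
  band <- list(
    grass = centers < thresholds$grass_max_h,
    shrub = centers >= thresholds$grass_max_h & centers <= thresholds$shrub_max_h,
    tree  = centers > thresholds$shrub_max_h
  )
  out <- lapply(names(band), function(s) {
    lv <- which(band[[s]])
    hit <- if (length(lv) == 0L) {
      matrix(FALSE, d[1], d[2])
    } else {
      apply(presence[, , lv, drop = FALSE], c(1, 2), any)
    }
    stratum_mask(hit & g2, s, pixel_size_m)
  })
  names(out) <- names(band)
  out
}

#' Stratify a scene into the four analysis layers
#'
#' Convenience wrapper running the full stratification chain: NDVI from the
#' reflectance pair, the 2D vegetation mask, voxel presence, and the
#' per-stratum projections.
#'
#' @param pair A [reflectance_pair()].
#' @param canopy A [voxel_canopy()].
#' @param thresholds A [strata_thresholds()].
#' @return Named list of [stratum_mask()]s: `green2d`, `grass`, `shrub`,
#'   `tree`.
#' @export
stratify_scene <- function(pair, canopy, thresholds = strata_thresholds()) {
  ndvi <- compute_ndvi(pair)
  green2d <- vegetation_mask(ndvi, thresholds)
  presence <- voxel_presence(canopy, thresholds)
  strata <- project_strata(presence, green2d,
                           voxel_height_m = canopy$voxel_height_m,
                           base_height_m = canopy$base_height_m,
                           pixel_size_m = canopy$pixel_size_m,
                           thresholds = thresholds)
  c(list(green2d = green2d), strata)
}
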