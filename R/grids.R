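#' Vegetation layer names
#'
#' The four binary layers the pipeline analyses: the NDVI-derived 2D green
#' cover and the three height strata projected from the voxel canopy.
#' @export
STRATA <- c("green2d", "grass", "shrub", "tree")

#' Binary stratum mask
#'
#' A single vegetation layer as a binary raster: `TRUE` pixels carry
#' vegetation of the given stratum. This is the common currency of the
#' package: stratification produces masks, and all connectivity metrics and
#' buffering operate on them.
#'
#' @param values Logical matrix (or 0/1 numeric matrix, coerced). Rows are
#'   map rows, row 1 at the top.
#' @param stratum One of `"green2d"`, `"grass"`, `"shrub"`, `"tree"`.
#' @param pixel_size_m Pixel edge length in metres (default 1.5, the
#'   horizontal voxel resolution).
#' @return An object of class `stratum_mask`.
#' @examples
#' m <- stratum_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2), "grass")
#' @export
stratum_mask <- function(values, stratum = STRATA, pixel_size_m = 1.5) {
  stratum <- match.arg(stratum)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1))) stop("numeric mask values must be 0/1")
    values <- values == 1
  }
  if (!is.logical(values)) stop("`values` must be logical or 0/1 numeric")
  if (anyNA(values)) stop("mask values must not contain NA")
  check_pixel_size(pixel_size_m)
  structure(
    list(values = values, stratum = stratum, pixel_size_m = pixel_size_m),
    class = "stratum_mask"
  )
}

#' @export
print.stratum_mask <- function(x, ...) {
  cat(sprintf(
    "<stratum_mask> %s: %d x %d px @ %g m, %.1f%% vegetated\n",
    x$stratum, nrow(x$values), ncol(x$values), x$pixel_size_m,
    100 * mean(x$values)
  ))
  invisible(x)
}

#' @export
dim.stratum_mask <- function(x) dim(x$values)

#' Paired red / near-infrared reflectance grids
#'
#' Mean reflectance in the visible red and near-infrared bands, as produced
#' by an imaging spectrometer (or by [generate_scene()]), from which NDVI is
#' computed.
#'
#' @param red,nir Numeric matrices of reflectance in \[0, 1\], same shape.
#' @param pixel_size_m Pixel edge length in metres.
#' @return An object of class `reflectance_pair`.
#' @export
reflectance_pair <- function(red, nir, pixel_size_m = 1.5) {
  if (!is.matrix(red) || !is.matrix(nir)) stop("red and nir must be matrices")
  if (!identical(dim(red), dim(nir)))
    stop("red and nir grids must share the same shape")
  for (g in list(red, nir)) {
    if (!all(is.finite(g))) stop("reflectance values must be finite")
    if (any(g < 0 | g > 1)) stop("reflectance values must lie in [0, 1]")
  }
  check_pixel_size(pixel_size_m)
  structure(list(red = red, nir = nir, pixel_size_m = pixel_size_m),
            class = "reflectance_pair")
}

#' Voxelized fractional canopy cover
#'
#' A 3D grid of fractional vegetation cover, the raster form of a waveform
#' lidar canopy product: horizontal cells of `pixel_size_m` and vertical
#' bins of `voxel_height_m`. Level `k` (0-based) spans heights
#' `[base + k * vh, base + (k + 1) * vh)` above ground.
#'
#' @param cover 3D numeric array `rows x cols x levels`, values in \[0, 1\].
#' @param pixel_size_m Horizontal cell size, metres (default 1.5).
#' @param voxel_height_m Vertical bin height, metres (default 0.5).
#' @param base_height_m Height of the bottom of level 0 (default 0).
#' @return An object of class `voxel_canopy`.
#' @export
voxel_canopy <- function(cover, pixel_size_m = 1.5, voxel_height_m = 0.5,
                         base_height_m = 0) {
  if (!is.array(cover) || length(dim(cover)) != 3L)
    stop("`cover` must be a 3D array (rows x cols x levels)")
  if (!all(is.finite(cover))) stop("cover values must be finite")
  if (any(cover < 0 | cover > 1)) stop("cover values must lie in [0, 1]")
  check_pixel_size(pixel_size_m)
  if (!is.numeric(voxel_height_m) || voxel_height_m <= 0)
    stop("voxel_height_m must be a positive number")
  structure(
    list(cover = cover, pixel_size_m = pixel_size_m,
         voxel_height_m = voxel_height_m, base_height_m = base_height_m),
    class = "voxel_canopy"
  )
}

#' @export
print.voxel_canopy <- function(x, ...) {
  d <- dim(x$cover)
  cat(sprintf(
    "<voxel_canopy> %d x %d px @ %g m, %d levels x %g m (heights %g-%g m)\n",
    d[1], d[2], x$pixel_size_m, d[3], x$voxel_height_m,
    x$base_height_m, x$base_height_m + d[3] * x$voxel_height_m
  ))
  invisible(x)
}

#' Heights of voxel-level centers
#'
#' @param canopy A [voxel_canopy()] (or anything with `voxel_height_m`,
#'   `base_height_m` and a 3D `cover`).
#' @return Numeric vector: center height of each level, metres above ground.
#' @export
voxel_level_centers <- function(canopy) {
  k <- seq_len(dim(canopy$cover)[3]) - 1L
  canopy$base_height_m + (k + 0.5) * canopy$voxel_height_m
}

#' NDVI grid
#'
#' @param values Numeric matrix of NDVI values in \[-1, 1\].
#' @param pixel_size_m Pixel edge length in metres.
#' @return An object of class `ndvi_grid`.
#' @export
ndvi_grid <- function(values, pixel_size_m = 1.5) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!all(is.finite(values))) stop("NDVI values must be finite")
  if (any(values < -1 | values > 1)) stop("NDVI values must lie in [-1, 1]")
  check_pixel_size(pixel_size_m)
  structure(list(values = values, pixel_size_m = pixel_size_m),
            class = "ndvi_grid")
}

#' Nearest-neighbour resampling of a grid
#'
#' Maps a grid onto a target shape by nearest-neighbour lookup of pixel
#' centers. Used to bring an NDVI grid onto the voxel grid when the two were
#' produced at different resolutions; nearest-neighbour is used because it
#' preserves the semantics of thresholded (effectively categorical) values.
#'
#' @param values Numeric or logical matrix.
#' @param nrow_out,ncol_out Target shape.
#' @return Matrix of shape `nrow_out x ncol_out`.
#' @export
resample_nearest <- function(values, nrow_out, ncol_out) {
  ri <- pmin(nrow(values), pmax(1L, ceiling((seq_len(nrow_out) - 0.5) *
                                              nrow(values) / nrow_out)))
  ci <- pmin(ncol(values), pmax(1L, ceiling((seq_len(ncol_out) - 0.5) *
                                              ncol(values) / ncol_out)))
  values[ri, ci, drop = FALSE]
}

check_pixel_size <- function(pixel_size_m) {
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1L ||
      !is.finite(pixel_size_m) || pixel_size_m <= 0)
    stop("pixel_size_m must be a single positive number")
  invisible(pixel_size_m)
}
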