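#' Label connected patches in a binary mask
#'
#' Finds maximal connected components of vegetated pixels under 4- (rook) or
#' 8- (queen) adjacency. Labels are dense `1..n` and assigned in row-major
#' first-pixel order, so the labeling is deterministic. The default is
#' 8-connectivity, the common choice of raster landscape-metric tools; it is
#' exposed so sensitivity to the adjacency rule can be checked.
#'
#' @param mask A [stratum_mask()].
#' @param neighborhood 4 or 8 (default 8).
#' @return An object of class `patch_labeling`: `labels` (integer matrix,
#'   0 = background), `patch_areas_m2` (area of each patch, m^2),
#'   `landscape_area_m2` (full raster extent, m^2, vegetated or not),
#'   `neighborhood`, `pixel_size_m`.
#' @export
label_patches <- function(mask, neighborhood = 8) {
  stopifnot(inherits(mask, "stratum_mask"))
  neighborhood <- match_neighborhood(neighborhood)
  res <- .label_cc(mask$values, neighborhood)
  px_area <- mask$pixel_size_m^2
  structure(
    list(labels = res$labels,
         patch_areas_m2 = as.numeric(res$sizes) * px_area,
         landscape_area_m2 = length(mask$values) * px_area,
         neighborhood = neighborhood,
         pixel_size_m = mask$pixel_size_m),
    class = "patch_labeling"
  )
}

#' @export
print.patch_labeling <- function(x, ...) {
  cat(sprintf("<patch_labeling> %d patches, %d-connected, landscape %g m^2\n",
              length(x$patch_areas_m2), x$neighborhood, x$landscape_area_m2))
  invisible(x)
}

match_neighborhood <- function(neighborhood) {
  neighborhood <- as.integer(neighborhood)
  if (!neighborhood %in% c(4L, 8L)) stop("neighborhood must be 4 or 8")
  neighborhood
}

#' Landscape proportion
#'
#' Fraction of the landscape covered by vegetation: `sum(a_ij) / A`, with
#' `A` the full raster extent.
#'
#' @param labeling A [label_patches()] result.
#' @return Fraction in \[0, 1\].
#' @export
landscape_proportion <- function(labeling) {
  stopifnot(inherits(labeling, "patch_labeling"))
  sum(labeling$patch_areas_m2) / labeling$landscape_area_m2
}

#' Small patch density
#'
#' Number of disjunct patches strictly smaller than `max_area_m2`
#' (30 m^2 by default — small enough to resolve private gardens and
#' fine-grained green features) per hectare of landscape. Higher values
#' indicate a more fragmented landscape.
#'
#' @param labeling A [label_patches()] result.
#' @param max_area_m2 Strict upper area bound for a "small" patch (m^2).
#' @return Patches per hectare.
#' @export
small_patch_density <- function(labeling, max_area_m2 = 30) {
  stopifnot(inherits(labeling, "patch_labeling"))
  n_small <- sum(labeling$patch_areas_m2 < max_area_m2)
  n_small / (labeling$landscape_area_m2 / 1e4)
}

#' Largest patch index
#'
#' Percentage of the landscape occupied by the single largest patch;
#' 0 for an empty landscape.
#'
#' @param labeling A [label_patches()] result.
#' @return Percent in \[0, 100\].
#' @export
largest_patch_index <- function(labeling) {
  stopifnot(inherits(labeling, "patch_labeling"))
  if (length(labeling$patch_areas_m2) == 0L) return(0)
  100 * max(labeling$patch_areas_m2) / labeling$landscape_area_m2
}

#' Connectivity index (landscape division index)
#'
#' `CI = 1 - sum((a_ij / A)^2)`: the probability that two randomly chosen
#' pixels of the landscape (vegetated or not) do not lie in the same patch.
#' The higher the index, the lower the connectivity. A single patch covering
#' the whole landscape gives 0; an empty landscape gives 1 (no pair can
#' share a patch).
#'
#' @param labeling A [label_patches()] result.
#' @return CI in \[0, 1\].
#' @export
connectivity_index <- function(labeling) {
  stopifnot(inherits(labeling, "patch_labeling"))
  1 - sum((labeling$patch_areas_m2 / labeling$landscape_area_m2)^2)
}

#' Structural connectivity summary for one layer
#'
#' Computes the four structural metrics from a single labeling pass:
#' landscape proportion, small patch density (per ha), largest patch index
#' (percent) and the connectivity index.
#'
#' @param mask A [stratum_mask()].
#' @param neighborhood 4 or 8 (default 8).
#' @param small_patch_max_m2 Strict area bound for small patches (m^2).
#' @return One-row [tibble::tibble] with columns `layer`, `proportion`,
#'   `small_patch_density_per_ha`, `lpi_percent`, `ci`.
#' @examples
#' m <- stratum_mask(matrix(TRUE, 4, 4), "green2d", 1.5)
#' structural_summary(m)  # proportion 1, CI 0
#' @export
structural_summary <- function(mask, neighborhood = 8,
                               small_patch_max_m2 = 30) {
  lab <- label_patches(mask, neighborhood)
  tibble::tibble(
    layer = mask$stratum,
    proportion = landscape_proportion(lab),
    small_patch_density_per_ha = small_patch_density(lab, small_patch_max_m2),
    lpi_percent = largest_patch_index(lab),
    ci = connectivity_index(lab)
  )
}
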