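#' Squared center-to-center distance map
#'
#' For every pixel, the squared Euclidean distance (m^2) from its center to
#' the center of the nearest vegetated pixel. Exact on the lattice: squared
#' pixel offsets are integers, so thresholding against a squared buffer
#' distance is float-safe. `Inf` everywhere if the mask is empty.
#'
#' @param mask A [stratum_mask()].
#' @return Numeric matrix of squared distances in m^2.
#' @export
distance_map_sq <- function(mask) {
  stopifnot(inherits(mask, "stratum_mask"))
  .edt_squared(mask$values) * mask$pixel_size_m^2
}

#' Buffer (dilate) a vegetation mask
#'
#' Expands the vegetated surface isotropically: a pixel is in the buffered
#' mask iff its center lies within `distance_m` (inclusive) of the center of
#' some originally vegetated pixel. Buffers expand over all land cover —
#' built surfaces are not barriers, matching a plain GIS buffer of the
#' vegetated surface.
#'
#' @param mask A [stratum_mask()].
#' @param distance_m Buffer distance in metres, >= 0.
#' @return A buffered [stratum_mask()] of the same stratum.
#' @export
buffer_mask <- function(mask, distance_m) {
  stopifnot(inherits(mask, "stratum_mask"))
  if (!is.numeric(distance_m) || length(distance_m) != 1L || distance_m < 0)
    stop("distance_m must be a single non-negative number")
  if (distance_m == 0) return(mask)
  d2 <- distance_map_sq(mask)
  stratum_mask(d2 <= distance_m^2, mask$stratum, mask$pixel_size_m)
}

#' Functional connectivity curve
#'
#' Models functional connectivity by computing the connectivity index on the
#' vegetated surface buffered at every `step_m` increment of dispersal
#' distance, starting at 0 (the structural CI of the input), until the
#' buffer composes a completely connected, fully vegetated map (CI = 0) or a
#' maximum distance is hit. Buffered pixels count as vegetated patch area,
#' and CI is always computed against the same fixed landscape extent.
#'
#' The buffer increment is interpreted as the dispersal capacity of an
#' organism moving between green patches, so the curve reads as "how
#' connected is this layer for an organism that can cross `d` metres of
#' non-habitat".
#'
#' @param mask A [stratum_mask()] with at least one vegetated pixel.
#' @param step_m Buffer increment in metres (default 1, independent of the
#'   pixel size; sub-pixel steps may repeat identical masks and are kept so
#'   the distance axis stays regular).
#' @param neighborhood 4 or 8 (default 8).
#' @param max_distance_m Safety cap; default the grid diagonal, which
#'   guarantees full cover is reached. If the cap stops the curve early a
#'   warning is raised and `terminated_full_cover` is `FALSE`.
#' @return An object of class `connectivity_curve`: `layer`, `distances_m`,
#'   `ci_values`, `terminated_full_cover`.
#' @export
functional_curve <- function(mask, step_m = 1, neighborhood = 8,
                             max_distance_m = NULL) {
  stopifnot(inherits(mask, "stratum_mask"))
  if (!any(mask$values))
    stop("functional curve is undefined for an empty mask")
  if (!is.numeric(step_m) || step_m <= 0)
    stop("step_m must be a positive number")
  neighborhood <- match_neighborhood(neighborhood)
  if (is.null(max_distance_m)) {
    max_distance_m <- mask$pixel_size_m *
      sqrt(nrow(mask$values)^2 + ncol(mask$values)^2)
  }
  d2 <- distance_map_sq(mask)
  distances <- numeric(0)
  ci <- numeric(0)
  d <- 0
  full <- FALSE
  repeat {
    vals <- d2 <= d^2
    m_d <- stratum_mask(vals, mask$stratum, mask$pixel_size_m)
    distances <- c(distances, d)
    ci <- c(ci, connectivity_index(label_patches(m_d, neighborhood)))
    if (all(vals)) { full <- TRUE; break }
    if (d + step_m > max_distance_m) break
    d <- d + step_m
  }
  if (!full)
    warning("max_distance_m reached before the surface became fully connected")
  connectivity_curve(mask$stratum, distances, ci, full)
}

#' Connectivity curve object
#'
#' @param layer Layer name (one of [STRATA]).
#' @param distances_m Increasing distances starting at 0, metres.
#' @param ci_values CI at each distance, same length, non-increasing.
#' @param terminated_full_cover `TRUE` iff the last buffer covered the whole
#'   landscape (equivalently, the last CI is exactly 0).
#' @return An object of class `connectivity_curve`.
#' @export
connectivity_curve <- function(layer, distances_m, ci_values,
                               terminated_full_cover) {
  layer <- match.arg(layer, STRATA)
  if (length(distances_m) != length(ci_values) || length(distances_m) == 0L)
    stop("distances and CI values must be non-empty and of equal length")
  if (distances_m[1] != 0) stop("curve must start at distance 0")
  if (is.unsorted(distances_m, strictly = TRUE))
    stop("distances must be strictly increasing")
  if (any(diff(ci_values) > 1e-12))
    stop("CI values must be non-increasing along the curve")
  if (any(ci_values < -1e-12 | ci_values > 1 + 1e-12))
    stop("CI values must lie in [0, 1]")
  last0 <- ci_values[length(ci_values)] == 0
  if (isTRUE(terminated_full_cover) != last0)
    stop("terminated_full_cover must agree with the final CI being 0")
  structure(list(layer = layer, distances_m = as.numeric(distances_m),
                 ci_values = as.numeric(ci_values),
                 terminated_full_cover = isTRUE(terminated_full_cover)),
            class = "connectivity_curve")
}

#' @export
print.connectivity_curve <- function(x, ...) {
  cat(sprintf(
    "<connectivity_curve> %s: %d steps, d = %g..%g m, CI %0.3f -> %0.3f%s\n",
    x$layer, length(x$distances_m), min(x$distances_m), max(x$distances_m),
    x$ci_values[1], x$ci_values[length(x$ci_values)],
    if (x$terminated_full_cover) " (full cover)" else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.connectivity_curve <- function(x, ...) {
  data.frame(layer = x$layer, distance_m = x$distances_m, ci = x$ci_values,
             stringsAsFactors = FALSE)
}

#' Dispersal distance at which a connectivity threshold is reached
#'
#' The smallest sampled buffer distance whose CI falls strictly below the
#' threshold. The default threshold CI < 0.15 marks high connectivity: a
#' greater than 85% probability that two randomly chosen locations are
#' connected.
#'
#' @param curve A [connectivity_curve()].
#' @param ci_threshold Strict CI threshold (default 0.15).
#' @return Distance in metres, or `NA` if the curve never attains the
#'   threshold.
#' @export
threshold_distance <- function(curve, ci_threshold = 0.15) {
  stopifnot(inherits(curve, "connectivity_curve"))
  i <- which(curve$ci_values < ci_threshold)
  if (length(i) == 0L) return(NA_real_)
  curve$distances_m[i[1]]
}

#' 2D-versus-stratum bias curve
#'
#' The difference `CI_stratum(d) - CI_green2d(d)` at each buffer distance:
#' how much connectivity the flat 2D green-cover perspective overstates for
#' organisms confined to one vertical stratum. Whenever the stratum mask is
#' a subset of the 2D mask the difference is non-negative at every distance.
#' The shorter curve is extended with trailing zeros (after full cover the
#' CI stays 0).
#'
#' @param stratum_curve [connectivity_curve()] of a stratum layer.
#' @param green2d_curve [connectivity_curve()] of the 2D green-cover layer,
#'   sampled with the same step.
#' @return An object of class `bias_curve`: `layer`, `distances_m`,
#'   `delta_ci`.
#' @export
bias_curve <- function(stratum_curve, green2d_curve) {
  stopifnot(inherits(stratum_curve, "connectivity_curve"),
            inherits(green2d_curve, "connectivity_curve"))
  step_of <- function(cv)
    if (length(cv$distances_m) > 1L) cv$distances_m[2] - cv$distances_m[1] else NA_real_
  s1 <- step_of(stratum_curve); s2 <- step_of(green2d_curve)
  if (!is.na(s1) && !is.na(s2) && abs(s1 - s2) > 1e-9)
    stop("curves must be sampled on the same step")
  step <- if (!is.na(s1)) s1 else if (!is.na(s2)) s2 else 1
  n <- max(length(stratum_curve$ci_values), length(green2d_curve$ci_values))
  pad <- function(v) c(v, rep(0, n - length(v)))
  structure(list(layer = stratum_curve$layer,
                 distances_m = (seq_len(n) - 1) * step,
                 delta_ci = pad(stratum_curve$ci_values) -
                   pad(green2d_curve$ci_values)),
            class = "bias_curve")
}

#' @export
as.data.frame.bias_curve <- function(x, ...) {
  data.frame(layer = x$layer, distance_m = x$distances_m,
             delta_ci = x$delta_ci, stringsAsFactors = FALSE)
}

#' Peak of a bias curve
#'
#' Distance at which the 2D-versus-stratum CI difference is largest; ties
#' are broken toward the smallest distance.
#'
#' @param bias A [bias_curve()].
#' @return Named numeric vector `c(distance_m = , delta = )`.
#' @export
peak_bias <- function(bias) {
  stopifnot(inherits(bias, "bias_curve"))
  if (length(bias$delta_ci) == 0L) stop("bias curve is empty")
  i <- which.max(bias$delta_ci)  # which.max returns the first maximum
  c(distance_m = bias$distances_m[i], delta = bias$delta_ci[i])
}
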