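#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: either a [scene_config()] for
#' a synthetic scene or paths to reflectance/canopy inputs on disk, the
#' stratification thresholds, the patch adjacency rule, the buffer step, the
#' CI threshold defining "high connectivity", and the output directory.
#' All parameters are validated up front, before any computation.
#'
#' @param scene A [scene_config()], or `NULL` when reading inputs from
#'   files.
#' @param red_path,nir_path ASCII-grid reflectance inputs (ignored when
#'   `scene` is given). Both are read with [read_mask()]-style grid headers
#'   but hold continuous reflectance; any numeric grid is accepted.
#' @param canopy_path Voxel canopy input ([read_canopy()] format).
#' @param thresholds A [strata_thresholds()].
#' @param neighborhood 4 or 8.
#' @param step_m Buffer increment, metres.
#' @param ci_threshold CI threshold for [threshold_distance()]
#'   (default 0.15).
#' @param outdir Output directory, created if needed.
#' @param seed Integer seed for the synthetic scene (overrides the seed in
#'   `scene` when given).
#' @param plots Render curve plots to PDF (default `TRUE`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(scene = NULL, red_path = NULL, nir_path = NULL,
                       canopy_path = NULL, thresholds = strata_thresholds(),
                       neighborhood = 8, step_m = 1, ci_threshold = 0.15,
                       outdir, seed = NULL, plots = TRUE) {
  if (is.null(scene)) {
    if (is.null(red_path) || is.null(nir_path) || is.null(canopy_path))
      stop("either a scene_config or red/nir/canopy input paths are required")
    for (p in c(red_path, nir_path, canopy_path))
      if (!file.exists(p)) stop("input file does not exist: ", p)
  } else {
    stopifnot(inherits(scene, "scene_config"))
    if (!is.null(seed)) scene$seed <- as.integer(seed)
  }
  stopifnot(inherits(thresholds, "strata_thresholds"))
  neighborhood <- match_neighborhood(neighborhood)
  if (!is.numeric(step_m) || step_m <= 0) stop("step_m must be positive")
  if (!is.numeric(ci_threshold) || ci_threshold <= 0 || ci_threshold > 1)
    stop("ci_threshold must lie in (0, 1]")
  if (missing(outdir)) stop("outdir is required")
  structure(list(scene = scene, red_path = red_path, nir_path = nir_path,
                 canopy_path = canopy_path, thresholds = thresholds,
                 neighborhood = neighborhood, step_m = step_m,
                 ci_threshold = ci_threshold, outdir = outdir,
                 plots = isTRUE(plots)),
            class = "run_config")
}

read_reflectance_grid <- function(path) {
  lines <- readLines(path)
  hdr <- parse_grid_header(lines, path)
  body <- lines[-seq_len(hdr$n_header)]
  vals <- t(vapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(hdr$ncols), USE.NAMES = FALSE))
  list(values = matrix(vals, hdr$nrows, hdr$ncols), pixel_size_m = hdr$cellsize)
}

#' Write a continuous grid as an ESRI ASCII grid
#'
#' Companion to [write_mask()] for reflectance / NDVI grids.
#'
#' @param values Numeric matrix.
#' @param pixel_size_m Cell size in metres.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(values, pixel_size_m, path) {
  header <- c(paste("ncols", ncol(values)), paste("nrows", nrow(values)),
              "xllcorner 0", "yllcorner 0",
              paste("cellsize", format(pixel_size_m, digits = 15)),
              "NODATA_value -9999")
  rows <- apply(values, 1L, function(r)
    paste(formatC(r, digits = 9, format = "g"), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Run the full connectivity pipeline
#'
#' End-to-end analysis: obtain the scene (synthetic or from files),
#' stratify it into the four layers, compute the structural metrics per
#' layer, build the functional connectivity curve per layer, derive the
#' 2D-versus-stratum bias curves and threshold dispersal distances, and
#' write everything to `outdir`:
#'
#' * `mask_<layer>.asc` — the four binary layers;
#' * `structural_metrics.csv` — one row per layer;
#' * `functional_curves.csv` — `layer, distance_m, ci`;
#' * `bias_curves.csv` — `layer, distance_m, delta_ci`;
#' * `threshold_distances.csv` — distance at which each layer's CI first
#'   drops below the configured threshold;
#' * `functional_curves.pdf`, `bias_curves.pdf` — unless `plots = FALSE`;
#' * `summary.json` — all parameters and headline results, timestamps
#'   excluded so reruns of the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return Invisibly, a list with `masks`, `metrics`, `curves`, `bias`,
#'   `thresholds` and `summary`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  if (!is.null(config$scene)) {
    say("generating synthetic scene (seed ", config$scene$seed, ")")
    scene <- generate_scene(config$scene)
    pair <- scene$reflectance
    canopy <- scene$canopy
  } else {
    say("reading inputs")
    red <- read_reflectance_grid(config$red_path)
    nir <- read_reflectance_grid(config$nir_path)
    if (!identical(dim(red$values), dim(nir$values)))
      stop("red and nir grids have mismatched geometry")
    pair <- reflectance_pair(red$values, nir$values, red$pixel_size_m)
    canopy <- read_canopy(config$canopy_path)
  }

  say("stratifying")
  masks <- stratify_scene(pair, canopy, config$thresholds)

  say("structural metrics")
  metrics <- do.call(rbind, lapply(masks, structural_summary,
                                   neighborhood = config$neighborhood))

  say("functional connectivity curves")
  curves <- lapply(masks, function(m) {
    if (!any(m$values)) return(NULL)
    functional_curve(m, step_m = config$step_m,
                     neighborhood = config$neighborhood)
  })
  bias <- lapply(setdiff(names(curves), "green2d"), function(s) {
    if (is.null(curves[[s]]) || is.null(curves$green2d)) return(NULL)
    bias_curve(curves[[s]], curves$green2d)
  })
  names(bias) <- setdiff(names(curves), "green2d")

  thresholds_tab <- tibble::tibble(
    layer = names(curves),
    threshold_distance_m = vapply(curves, function(cv)
      if (is.null(cv)) NA_real_ else
        threshold_distance(cv, config$ci_threshold), numeric(1))
  )

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  for (s in names(masks)) write_mask(masks[[s]], out(paste0("mask_", s, ".asc")))
  write.csv(metrics, out("structural_metrics.csv"), row.names = FALSE)
  curve_df <- do.call(rbind, lapply(Filter(Negate(is.null), curves),
                                    as.data.frame))
  write.csv(curve_df, out("functional_curves.csv"), row.names = FALSE)
  bias_df <- do.call(rbind, lapply(Filter(Negate(is.null), bias),
                                   as.data.frame))
  write.csv(bias_df, out("bias_curves.csv"), row.names = FALSE)
  write.csv(thresholds_tab, out("threshold_distances.csv"), row.names = FALSE)

  if (config$plots && !is.null(curve_df)) {
    say("plots")
    ggplot2::ggsave(out("functional_curves.pdf"),
                    plot_connectivity_curves(curves,
                                             ci_threshold = config$ci_threshold),
                    width = 7, height = 5)
    if (!is.null(bias_df))
      ggplot2::ggsave(out("bias_curves.pdf"), plot_bias_curves(bias),
                      width = 7, height = 5)
  }

  summary <- list(
    parameters = list(
      scene = if (!is.null(config$scene)) unclass(config$scene) else NULL,
      inputs = if (is.null(config$scene))
        list(red = config$red_path, nir = config$nir_path,
             canopy = config$canopy_path) else NULL,
      thresholds = unclass(config$thresholds),
      neighborhood = config$neighborhood,
      step_m = config$step_m,
      ci_threshold = config$ci_threshold
    ),
    structural = metrics,
    threshold_distances = thresholds_tab,
    peak_bias = lapply(Filter(Negate(is.null), bias),
                       function(b) as.list(peak_bias(b)))
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(masks = masks, metrics = metrics, curves = curves,
                 bias = bias, thresholds = thresholds_tab, summary = summary))
}
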