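#' Read and write binary masks as ESRI ASCII grids
#'
#' Masks are stored as plain-text ESRI ASCII grids (`ncols/nrows/.../cellsize`
#' header, then rows of 0/1, top row first): diffable, dependency-free and
#' readable by any GIS. The stratum is encoded as a filename suffix
#' (`_green2d`, `_grass`, `_shrub`, `_tree`) unless given explicitly.
#' Write-then-read round-trips are lossless.
#'
#' @param mask A [stratum_mask()].
#' @param path File path (conventionally `*.asc`).
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   [stratum_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "stratum_mask"))
  v <- mask$values
  header <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", format(mask$pixel_size_m, digits = 15)),
    "NODATA_value -9999"
  )
  rows <- apply(v * 1L, 1L, paste, collapse = " ")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @param stratum Stratum of the mask being read; by default inferred from
#'   a `_<stratum>` filename suffix, falling back to `"green2d"`.
#' @rdname write_mask
#' @export
read_mask <- function(path, stratum = NULL) {
  lines <- readLines(path)
  hdr <- parse_grid_header(lines, path)
  body <- lines[-seq_len(hdr$n_header)]
  if (length(body) != hdr$nrows)
    stop("malformed mask file ", path, ": expected ", hdr$nrows,
         " data rows, found ", length(body))
  vals <- t(vapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(hdr$ncols), USE.NAMES = FALSE))
  vals <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols)
  if (is.null(stratum)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    hit <- STRATA[vapply(STRATA, function(s) grepl(paste0("_", s, "$"), stem),
                         logical(1))]
    stratum <- if (length(hit) == 1L) hit else "green2d"
  }
  stratum_mask(vals, stratum, hdr$cellsize)
}

parse_grid_header <- function(lines, path) {
  kv <- list()
  n <- 0L
  for (l in lines) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[a-zA-Z_]+$", parts[1])) {
      kv[[tolower(parts[1])]] <- parts[2]
      n <- n + 1L
    } else break
  }
  for (need in c("ncols", "nrows", "cellsize"))
    if (is.null(kv[[need]]))
      stop("malformed grid file ", path, ": missing header field ", need)
  list(ncols = as.integer(kv$ncols), nrows = as.integer(kv$nrows),
       cellsize = as.numeric(kv$cellsize), n_header = n)
}

#' Read and write voxel canopies as plain text
#'
#' A simple multi-level text format: a header of `key value` lines
#' (`rows`, `cols`, `levels`, `pixel_size_m`, `voxel_height_m`,
#' `base_height_m`) followed by one `level <k>` block per vertical level,
#' each holding `rows` lines of fractional cover, top map row first.
#' Cover values are written with 9 significant digits, so round-trips
#' preserve them to better than 1e-8 relative precision.
#'
#' @param canopy A [voxel_canopy()].
#' @param path File path (conventionally `*.vox.txt`).
#' @return `write_canopy` returns `path` invisibly; `read_canopy` a
#'   [voxel_canopy()].
#' @export
write_canopy <- function(canopy, path) {
  stopifnot(inherits(canopy, "voxel_canopy"))
  d <- dim(canopy$cover)
  out <- c(
    paste("rows", d[1]), paste("cols", d[2]), paste("levels", d[3]),
    paste("pixel_size_m", format(canopy$pixel_size_m, digits = 15)),
    paste("voxel_height_m", format(canopy$voxel_height_m, digits = 15)),
    paste("base_height_m", format(canopy$base_height_m, digits = 15))
  )
  for (k in seq_len(d[3])) {
    out <- c(out, paste("level", k - 1L),
             apply(canopy$cover[, , k, drop = FALSE], 1L,
                   function(r) paste(formatC(r, digits = 9, format = "g"),
                                     collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_canopy
#' @export
read_canopy <- function(path) {
  lines <- readLines(path)
  kv <- list()
  i <- 1L
  while (i <= length(lines) && !grepl("^level ", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2L) kv[[parts[1]]] <- parts[2]
    i <- i + 1L
  }
  for (need in c("rows", "cols", "levels", "pixel_size_m", "voxel_height_m",
                 "base_height_m"))
    if (is.null(kv[[need]]))
      stop("malformed canopy file ", path, ": missing header field ", need)
  nr <- as.integer(kv$rows); nc <- as.integer(kv$cols)
  nl <- as.integer(kv$levels)
  cover <- array(0, dim = c(nr, nc, nl))
  for (k in seq_len(nl)) {
    if (i > length(lines) || !identical(lines[i], paste("level", k - 1L)))
      stop("malformed canopy file ", path, ": expected 'level ", k - 1L,
           "' at line ", i)
    block <- lines[i + seq_len(nr)]
    cover[, , k] <- t(vapply(block,
                             function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                             numeric(nc), USE.NAMES = FALSE))
    i <- i + nr + 1L
  }
  voxel_canopy(cover, as.numeric(kv$pixel_size_m),
               as.numeric(kv$voxel_height_m), as.numeric(kv$base_height_m))
}

#' Read and write connectivity curves as CSV
#'
#' Curves are stored as tidy CSV with columns `layer`, `distance_m`, `ci`.
#' On read, distances must be strictly increasing within each layer;
#' anything else is rejected as malformed.
#'
#' @param curve A [connectivity_curve()].
#' @param path CSV file path.
#' @return `write_curve` returns `path` invisibly; `read_curve` a
#'   [connectivity_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "connectivity_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (need in c("layer", "distance_m", "ci"))
    if (!need %in% names(df))
      stop("malformed curve file ", path, ": missing column ", need)
  if (length(unique(df$layer)) != 1L)
    stop("malformed curve file ", path, ": expected a single layer")
  if (is.unsorted(df$distance_m, strictly = TRUE))
    stop("malformed curve file ", path,
         ": distances must be strictly increasing")
  connectivity_curve(df$layer[1], df$distance_m, df$ci,
                     df$ci[nrow(df)] == 0)
}

#' Read and write scene configurations as YAML
#'
#' @param config A [scene_config()].
#' @param path YAML file path.
#' @return `write_scene_config` returns `path` invisibly;
#'   `read_scene_config` a validated [scene_config()].
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  yaml::write_yaml(list(
    width_px = config$width_px, height_px = config$height_px,
    pixel_size_m = config$pixel_size_m,
    voxel_height_m = config$voxel_height_m,
    max_height_m = config$max_height_m, archetype = config$archetype,
    target_cover = as.list(config$target_cover),
    fragmentation = config$fragmentation, seed = config$seed
  ), path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  y <- yaml::read_yaml(path)
  scene_config(width_px = y$width_px, height_px = y$height_px,
               pixel_size_m = y$pixel_size_m %||% 1.5,
               voxel_height_m = y$voxel_height_m %||% 0.5,
               max_height_m = y$max_height_m %||% 12,
               archetype = y$archetype,
               target_cover = unlist(y$target_cover),
               fragmentation = y$fragmentation %||% 0.4,
               seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
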