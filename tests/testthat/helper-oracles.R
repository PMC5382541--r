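# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: the Monte-Carlo CI estimator samples pixel
# pairs, and the brute-force distance map enumerates all vegetated pixels.

random_mask <- function(nr, nc, p = 0.2, pixel_size_m = 1.5,
                        stratum = "green2d") {
  stratum_mask(matrix(runif(nr * nc) < p, nr, nc), stratum, pixel_size_m)
}

mask_from_rows <- function(..., pixel_size_m = 1.5, stratum = "green2d") {
  stratum_mask(rbind(...) == 1, stratum, pixel_size_m)
}

# P(two uniformly random ordered pixels, background included, lie in the
# same patch), estimated by sampling with replacement; CI = 1 - P.
mc_ci <- function(labeling, n_pairs = 1e5) {
  labs <- labeling$labels
  i <- sample.int(length(labs), n_pairs, replace = TRUE)
  j <- sample.int(length(labs), n_pairs, replace = TRUE)
  p_same <- mean(labs[i] != 0L & labs[i] == labs[j])
  list(ci = 1 - p_same, n = n_pairs)
}

# All-pairs squared center-to-center distances (m^2) to the nearest
# vegetated pixel: a direct transcription of the buffer definition.
brute_distmap_sq <- function(mask) {
  v <- mask$values
  rr <- row(v); cc <- col(v)
  d2 <- matrix(Inf, nrow(v), ncol(v))
  for (k in which(v)) d2 <- pmin(d2, (rr - rr[k])^2 + (cc - cc[k])^2)
  d2 * mask$pixel_size_m^2
}

# Closed-form same-patch probability for the 3-SE Monte-Carlo band.
same_patch_prob <- function(labeling) {
  sum((labeling$patch_areas_m2 / labeling$landscape_area_m2)^2)
}

tiny_thresholds <- strata_thresholds()

# generate a scene from a config and stratify it in one go
stratify_scene2 <- function(cfg, thresholds = strata_thresholds()) {
  sc <- generate_scene(cfg)
  stratify_scene(sc$reflectance, sc$canopy, thresholds)
}
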