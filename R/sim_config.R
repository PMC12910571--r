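#' Simulation configuration for synthetic islet images
#'
#' Builds and validates the parameter set that drives the synthetic islet
#' image generator. The defaults describe an idealised immunofluorescence
#' field of human islet tissue: elliptical islets tiled by touching
#' polygonal cells (a nearest-seed partition of dart-thrown nuclei seeds),
#' cell-type-dependent lognormal marker intensities, a small bi-hormonal
#' population, Gaussian point-spread blur, and Poisson-Gaussian camera
#' noise.
#'
#' @param image_shape integer vector `c(rows, cols)` of the output field.
#' @param n_islets number of islets to place (non-overlapping ellipses).
#' @param cells_per_islet integer range `c(min, max)`; the cell count of
#'   each islet is drawn uniformly from this range.
#' @param type_frequencies named probabilities over `alpha`, `beta`,
#'   `other`; must sum to 1.
#' @param bihormonal_rate probability that a cell is bi-hormonal
#'   (insulin- and glucagon-positive), drawn independently of arrangement.
#'   Default 0.00473 (0.473%), the prevalence scale reported for aged
#'   human donor cohorts.
#' @param arrangement `"jumbled"` (types drawn i.i.d. over cells) or
#'   `"mantle_core"` (alpha cells on the outermost radial quantile, beta
#'   cells in the core, the canonical mantle-core islet architecture).
#' @param cell_radius nominal cell radius in pixels; sets islet area and
#'   seed spacing.
#' @param nucleus_radius radius of the rendered nuclear (DAPI) disc, px.
#' @param intensity_params nested list `channel -> cell type ->
#'   c(meanlog, sdlog)` of lognormal intensity parameters in arbitrary
#'   units. See [default_intensity_params()].
#' @param ratio_tier_params per OXPHOS marker, a 3-component lognormal
#'   mixture (`weights`, `meanlog`, `sdlog`) for the marker/VDAC1 ratio of
#'   insulin-positive cells. See [default_tier_params()].
#' @param noise list with `poisson_gain` (photon gain; 0 disables shot
#'   noise) and `gaussian_sd` (additive read noise).
#' @param psf_sigma Gaussian point-spread-function sigma in pixels.
#' @param background background intensity level added to every channel.
#' @param rng_seed integer seed; generation is fully deterministic given
#'   the seed.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(image_shape = c(512L, 512L),
                       n_islets = 3L,
                       cells_per_islet = c(50L, 80L),
                       type_frequencies = c(alpha = 0.40, beta = 0.45,
                                            other = 0.15),
                       bihormonal_rate = 0.00473,
                       arrangement = c("jumbled", "mantle_core"),
                       cell_radius = 5.5,
                       nucleus_radius = 2.2,
                       intensity_params = default_intensity_params(),
                       ratio_tier_params = default_tier_params(),
                       noise = list(poisson_gain = 0.5, gaussian_sd = 2),
                       psf_sigma = 1,
                       background = 2,
                       rng_seed = 1L) {
  arrangement <- match.arg(arrangement)
  cfg <- list(image_shape = as.integer(image_shape), n_islets = as.integer(n_islets),
              cells_per_islet = as.integer(cells_per_islet),
              type_frequencies = type_frequencies,
              bihormonal_rate = bihormonal_rate, arrangement = arrangement,
              cell_radius = cell_radius, nucleus_radius = nucleus_radius,
              intensity_params = intensity_params,
              ratio_tier_params = ratio_tier_params,
              noise = noise, psf_sigma = psf_sigma, background = background,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  tf <- cfg$type_frequencies
  if (!all(c("alpha", "beta", "other") %in% names(tf)))
    stopf("type_frequencies must name alpha, beta and other")
  if (any(tf < 0)) stopf("type_frequencies must be nonnegative")
  if (abs(sum(tf) - 1) > 1e-9)
    stopf("type_frequencies must sum to 1 (got %.12f)", sum(tf))
  if (cfg$bihormonal_rate < 0 || cfg$bihormonal_rate > 1)
    stopf("bihormonal_rate must lie in [0, 1]")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 1L))
    stopf("image_shape must be two positive integers")
  if (cfg$n_islets < 0L) stopf("n_islets must be >= 0")
  if (length(cfg$cells_per_islet) != 2L ||
      cfg$cells_per_islet[1] > cfg$cells_per_islet[2] ||
      cfg$cells_per_islet[1] < 1L)
    stopf("cells_per_islet must be an increasing positive range c(min, max)")
  for (mk in names(cfg$ratio_tier_params)) {
    tp <- cfg$ratio_tier_params[[mk]]
    if (abs(sum(tp$weights) - 1) > 1e-9)
      stopf("tier mixture weights for %s must sum to 1", mk)
    if (any(tp$sdlog < 0)) stopf("tier sdlog for %s must be >= 0", mk)
    if (length(tp$weights) != length(tp$meanlog) ||
        length(tp$weights) != length(tp$sdlog))
      stopf("tier mixture parameter lengths differ for %s", mk)
  }
  for (ch in names(cfg$intensity_params))
    for (ty in names(cfg$intensity_params[[ch]]))
      if (cfg$intensity_params[[ch]][[ty]][2] < 0)
        stopf("sdlog for %s/%s must be >= 0", ch, ty)
  if (cfg$noise$poisson_gain < 0 || cfg$noise$gaussian_sd < 0 ||
      cfg$psf_sigma < 0)
    stopf("noise parameters and psf_sigma must be >= 0")
  invisible(cfg)
}

#' Default lognormal intensity parameters
#'
#' Per channel and cell type, `c(meanlog, sdlog)` in arbitrary intensity
#' units. Marker-positive populations sit at ~300 units (sdlog 0.2) and
#' marker-negative background populations at ~20 units (sdlog 0.4), a
#' separation at which donor-adaptive thresholding resolves positives
#' cleanly; VDAC1 (mitochondrial mass) is expressed by every endocrine
#' cell type.
#'
#' @return nested list `channel -> type -> c(meanlog, sdlog)`.
#' @export
default_intensity_params <- function() {
  pos <- c(log(300), 0.2)
  neg <- c(log(20), 0.4)
  list(
    DAPI  = list(alpha = c(log(500), 0.15), beta = c(log(500), 0.15),
                 bihormonal = c(log(500), 0.15), other = c(log(500), 0.15)),
    ECAD  = list(alpha = c(log(400), 0.10), beta = c(log(400), 0.10),
                 bihormonal = c(log(400), 0.10), other = c(log(400), 0.10)),
    INS   = list(alpha = neg, beta = pos, bihormonal = pos, other = neg),
    GCG   = list(alpha = pos, beta = neg, bihormonal = pos, other = neg),
    VDAC1 = list(alpha = c(log(150), 0.2), beta = c(log(150), 0.2),
                 bihormonal = c(log(150), 0.2), other = c(log(150), 0.2))
  )
}

#' Default OXPHOS ratio tier mixtures
#'
#' Three-component lognormal mixtures for the marker/VDAC1 ratio of
#' insulin-positive cells. Component centres are anchored to published
#' cluster means for the two markers (NDUFB8/VDAC1: 0.907 / 1.42 / 2.30;
#' MTCO1/VDAC1: 7.03 / 7.74 / 10.8); component spreads are chosen narrow
#' enough that the three tiers are well separated, giving the generator
#' recoverable tier ground truth. Default weights are the
#' without-diabetes tier proportions (see [cohort_group_effects()] for
#' the diabetes-shifted weights).
#'
#' @return list per marker with `weights`, `meanlog`, `sdlog`.
#' @export
default_tier_params <- function() {
  list(
    NDUFB8 = list(weights = c(0.460, 0.484, 0.0557) / sum(c(0.460, 0.484, 0.0557)),
                  meanlog = log(c(0.907, 1.42, 2.30)),
                  sdlog = c(0.08, 0.08, 0.08)),
    MTCO1 = list(weights = c(0.607, 0.237, 0.155) / sum(c(0.607, 0.237, 0.155)),
                 meanlog = log(c(7.03, 7.74, 10.8)),
                 sdlog = c(0.012, 0.012, 0.012))
  )
}

#' Default two-group cohort effects
#'
#' Per-group generative overrides emulating a without-diabetes versus
#' type-2-diabetes donor contrast: group B shifts composition toward
#' alpha cells, raises the bi-hormonal rate (70.7/29.3 split of a 0.473%
#' overall prevalence), and re-weights the OXPHOS ratio tiers toward low
#' complex I and high complex IV expression.
#'
#' @return named list of per-group override lists, suitable for
#'   [generate_cohort()]'s `group_effects` argument.
#' @export
cohort_group_effects <- function() {
  list(
    A = list(
      type_frequencies = c(alpha = 0.30, beta = 0.55, other = 0.15),
      bihormonal_rate = 0.00277,
      tier_weights = list(
        NDUFB8 = c(0.460, 0.484, 0.0557) / sum(c(0.460, 0.484, 0.0557)),
        MTCO1 = c(0.607, 0.237, 0.155) / sum(c(0.607, 0.237, 0.155)))
    ),
    B = list(
      type_frequencies = c(alpha = 0.47, beta = 0.38, other = 0.15),
      bihormonal_rate = 0.00669,
      tier_weights = list(
        NDUFB8 = c(0.684, 0.298, 0.0177) / sum(c(0.684, 0.298, 0.0177)),
        MTCO1 = c(0.452, 0.120, 0.427) / sum(c(0.452, 0.120, 0.427)))
    )
  )
}
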