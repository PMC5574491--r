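#' Screen configuration
#'
#' Builds the configuration list that drives the synthetic screen generator
#' and the analysis pipeline. Defaults describe a full production screen:
#' a 384-well plate imaged as ~25 focal planes spaced 50 um apart with a
#' 4x wide-field objective, 100-150 cysts per well, forskolin-driven
#' swelling, and quadruplicate test wells at 0.1 and 1 uM.
#'
#' Geometry is expressed in pixels; the anisotropic z axis is handled by
#' converting the plane spacing to pixel units (`z_interval_um /
#' pixel_size_um`), so a cyst of typical radius intersects 1-3 focal
#' planes, as in wide-field acquisition of gels.
#'
#' @param ... Named overrides of any default listed below.
#'
#' @section Key parameters:
#' \describe{
#'   \item{plate_shape}{`c(rows, cols)` of the plate (default 16 x 24).}
#'   \item{n_planes}{Focal planes per well (default 25).}
#'   \item{z_interval_um}{Spacing between planes in microns (default 50).}
#'   \item{pixel_size_um}{Lateral pixel size in microns (default 3.25).}
#'   \item{image_size}{`c(height, width)` in pixels (default 1024 x 1024,
#'     a 4x wide-field frame covering most of a 384-well base).}
#'   \item{background, noise_sd}{Constant background level and additive
#'     Gaussian noise SD, in 16-bit intensity units.}
#'   \item{swelling_factor}{Multiplicative radius increase under forskolin
#'     stimulation (default 1.6).}
#'   \item{cysts_per_well}{`c(min, max)` cysts seeded per well.}
#'   \item{radius_mean_px, radius_sd_px, radius_min_px}{Unstimulated cyst
#'     radius distribution (truncated normal, pixels).}
#'   \item{wall_thickness_px}{Actin ring thickness (pixels).}
#'   \item{wall_intensity, wall_intensity_sd, lumen_intensity}{Fluorescence
#'     levels of the actin ring and the dim lumen.}
#'   \item{nuclei_per_radius}{Expected nuclei per cyst per pixel of radius
#'     (nuclei counts are Poisson with mean `nuclei_per_radius * radius`).}
#'   \item{controls}{Named counts of control wells per plate
#'     (`unstimulated`, `stimulated`, `reference_inhibitor`).}
#'   \item{doses_um, replicates}{Test doses (uM) and technical replicates
#'     per compound-dose.}
#'   \item{tox_integrity_loss, tox_nuclei_loss, tox_radius_loss}{Maximal
#'     fractional loss of wall integrity, nuclei and radius for a toxic
#'     compound at full effect.}
#'   \item{seed}{Master seed; every well derives its own substream from it
#'     (see [well_seed()]), so layouts and renders are independently
#'     reproducible.}
#' }
#'
#' @return A list of class `screen_config`.
#' @seealso [demo_screen_config()], [read_screen_config()]
#' @export
#' @examples
#' cfg <- screen_config(noise_sd = 0, seed = 7)
#' cfg$swelling_factor
screen_config <- function(...) {
  cfg <- list(
    plate_shape        = c(16L, 24L),
    n_planes           = 25L,
    z_interval_um      = 50,
    pixel_size_um      = 3.25,
    image_size         = c(1024L, 1024L),
    max_intensity      = 65535,
    background         = 400,
    noise_sd           = 300,
    illumination_gradient = 0,
    swelling_factor    = 1.6,
    cysts_per_well     = c(100L, 150L),
    radius_mean_px     = 16,
    radius_sd_px       = 3,
    radius_min_px      = 5,
    wall_thickness_px  = 3,
    wall_intensity     = 20000,
    wall_intensity_sd  = 2000,
    lumen_intensity    = 3000,
    nuclei_per_radius  = 0.5,
    nucleus_sigma_px   = 2,
    nucleus_intensity  = 15000,
    forskolin_um       = 2.5,
    controls = list(unstimulated = 16L, stimulated = 16L,
                    reference_inhibitor = 0L),
    doses_um           = c(0.1, 1),
    replicates         = 4L,
    tox_integrity_loss = 0.6,
    tox_nuclei_loss    = 0.7,
    tox_radius_loss    = 0.25,
    seed               = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      abort(paste0("Unknown screen_config field(s): ",
                   paste(bad, collapse = ", ")),
            class = "cystscreen_config_error")
    }
    cfg <- modifyList(cfg, overrides)
  }
  cfg <- validate_screen_config(cfg)
  structure(cfg, class = "screen_config")
}

#' Desk-scale demo configuration
#'
#' A small configuration used throughout the examples, tests and the
#' bundled demo pipeline: a 4 x 8 mini-plate, 5 focal planes, 192 px
#' images and 6-10 cysts per well. It exercises every stage of the
#' pipeline in seconds on one CPU while keeping the same statistical
#' structure (swelling, dose response, controls) as the full-scale
#' defaults.
#'
#' @param seed Master seed.
#' @param ... Further overrides passed to [screen_config()].
#' @return A `screen_config`.
#' @export
#' @examples
#' demo_screen_config(seed = 42)$plate_shape
demo_screen_config <- function(seed = 1L, ...) {
  screen_config(
    plate_shape    = c(4L, 8L),
    n_planes       = 5L,
    image_size     = c(192L, 192L),
    cysts_per_well = c(6L, 10L),
    radius_mean_px = 14,
    radius_sd_px   = 2.5,
    controls = list(unstimulated = 4L, stimulated = 4L,
                    reference_inhibitor = 0L),
    seed = seed,
    ...
  )
}

#' Read a screen configuration from a YAML file
#'
#' Keys present in the file override the [screen_config()] defaults;
#' everything else keeps its default. Nested keys (e.g. `controls`) are
#' merged recursively.
#'
#' @param path Path to a YAML file.
#' @return A `screen_config`.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "cystscreen_config_error")
  }
  vals <- yaml::read_yaml(path)
  do.call(screen_config, vals %||% list())
}

validate_screen_config <- function(cfg) {
  stopifnot(length(cfg$plate_shape) == 2, length(cfg$image_size) == 2)
  cfg$plate_shape <- as.integer(cfg$plate_shape)
  cfg$image_size <- as.integer(cfg$image_size)
  cfg$n_planes <- as.integer(cfg$n_planes)
  cfg$replicates <- as.integer(cfg$replicates)
  if (cfg$n_planes < 1L) {
    abort("n_planes must be >= 1", class = "cystscreen_config_error")
  }
  if (any(cfg$image_size < 1L)) {
    abort("image_size must be positive", class = "cystscreen_config_error")
  }
  if (cfg$replicates < 1L) {
    abort("replicates must be >= 1", class = "cystscreen_config_error")
  }
  if (cfg$swelling_factor <= 0) {
    abort("swelling_factor must be positive",
          class = "cystscreen_config_error")
  }
  if (cfg$radius_mean_px <= cfg$wall_thickness_px) {
    abort("radius_mean_px must exceed wall_thickness_px",
          class = "cystscreen_config_error")
  }
  needed <- c("unstimulated", "stimulated")
  missing_roles <- setdiff(needed, names(cfg$controls))
  if (length(missing_roles)) {
    abort(paste0("controls must name counts for: ",
                 paste(missing_roles, collapse = ", ")),
          class = "cystscreen_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Per-well random substream seed
#'
#' Derives the seed of well `i` from the master seed by a fixed
#' affine-modular counter scheme, so any single well can be regenerated
#' without replaying the whole screen.
#'
#' @param seed Master seed (integer).
#' @param well_index 1-based well counter within the screen.
#' @return An integer seed.
#' @export
well_seed <- function(seed, well_index) {
  as.integer((as.double(seed %% 1000003L) * 2011 +
                as.double(well_index) * 7919) %% 214748329) + 1L
}

z_step_px <- function(config) config$z_interval_um / config$pixel_size_um

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
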