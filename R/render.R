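#' Image stack container
#'
#' One well, one channel: an ordered set of focal planes along z. Planes
#' are stored as a numeric `height x width x n_planes` array in 16-bit
#' intensity units (0..65535), plane order being acquisition order.
#'
#' @param planes 3-D numeric array (`y`, `x`, `z`) or a list of equally
#'   sized matrices.
#' @param z_interval_um Plane spacing in microns.
#' @param channel `"actin"` or `"nuclei"`.
#' @param well_id Plate coordinate (e.g. `"A01"`).
#' @return An `image_stack`.
#' @export
image_stack <- function(planes, z_interval_um = 50, channel = "actin",
                        well_id = NA_character_) {
  if (is.list(planes)) {
    dims <- unique(lapply(planes, dim))
    if (length(dims) != 1L) {
      abort("all planes must share dimensions",
            class = "cystscreen_stack_error")
    }
    planes <- array(unlist(planes, use.names = FALSE),
                    dim = c(dims[[1]], length(planes)))
  }
  if (length(dim(planes)) == 2L) dim(planes) <- c(dim(planes), 1L)
  stopifnot(length(dim(planes)) == 3L)
  structure(list(planes = planes, z_interval_um = z_interval_um,
                 channel = channel, well_id = well_id),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("<image_stack> well %s, channel %s: %d plane(s) of %d x %d px, dz = %g um\n",
              x$well_id, x$channel, d[3], d[1], d[2], x$z_interval_um))
  invisible(x)
}

n_planes <- function(stack) dim(stack$planes)[3]

#' Maximum intensity projection
#'
#' Collapses a z-stack to a single 2-D image by taking the per-pixel
#' maximum over all focal planes.
#'
#' @param stack An [image_stack()] (or a 3-D array).
#' @return A numeric matrix with the plane dimensions.
#' @export
#' @examples
#' s <- image_stack(list(matrix(1, 4, 4), matrix(3, 4, 4)))
#' max_projection(s)[1, 1]
max_projection <- function(stack) {
  planes <- if (inherits(stack, "image_stack")) stack$planes else stack
  if (length(dim(planes)) == 2L) return(planes)
  if (dim(planes)[3] < 1L) {
    abort("stack has no planes", class = "cystscreen_stack_error")
  }
  apply(planes, c(1, 2), max)
}

#' Draw the ground-truth cyst population of one well
#'
#' Samples the cysts of a single well from its own random substream
#' (derived from the master seed and the well index, see [well_seed()]).
#' Base radii are drawn from the unstimulated distribution and then
#' scaled deterministically by the well's growth factor, so a test well
#' at full effect reproduces the unstimulated draw exactly under the
#' same stream.
#'
#' Growth acts linearly on cyst *area* (the measured size): a well with
#' effect `E` has median area `(1 + (f^2 - 1) * (1 - E))` times the
#' unstimulated median, where `f` is the configured radius swelling
#' factor, i.e. radii scale by the square root of that factor. Toxic
#' compounds additionally shrink radii, fragment the actin wall
#' (integrity < 1) and deplete nuclei in proportion to their effect.
#'
#' @param well One layout row (see [plate_layout()]).
#' @param config A [screen_config()].
#' @return A tibble of cyst specifications: centre coordinates (`cx`,
#'   `cy` in pixels, `cz` in fractional plane index), `radius_px`,
#'   `wall_thickness_px`, `wall_intensity`, `lumen_intensity`,
#'   `n_nuclei`, `integrity`, gap placement angles, the analytic
#'   equatorial area `true_area_px`, and a `nuclei` list-column of spot
#'   positions.
#' @export
draw_well_cysts <- function(well, config) {
  stopifnot(nrow(well) == 1L)
  set.seed(well_seed(config$seed, well$well_index))
  draw_well_cysts_impl(well, config)
}

draw_well_cysts_impl <- function(well, config) {
  lo <- config$cysts_per_well[1]; hi <- config$cysts_per_well[2]
  n <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
  h <- config$image_size[1]; w <- config$image_size[2]
  margin <- config$radius_mean_px * max(config$swelling_factor, 1) +
    3 * config$radius_sd_px

  r_base <- pmax(rnorm(n, config$radius_mean_px, config$radius_sd_px),
                 config$radius_min_px)
  wall_int <- pmax(rnorm(n, config$wall_intensity, config$wall_intensity_sd),
                   config$lumen_intensity * 2)
  gap_start1 <- runif(n, 0, 2 * pi)
  gap_start2 <- runif(n, 0, 2 * pi)

  eff <- well$effect_raw
  growth <- if (isTRUE(well$stimulated)) {
    sqrt(pmax(1 + (config$swelling_factor^2 - 1) * (1 - eff), 0.04))
  } else 1
  tox_e <- if (isTRUE(well$toxic)) clamp(eff, 0, 1) else 0
  radius <- pmax(r_base * growth * (1 - config$tox_radius_loss * tox_e),
                 config$wall_thickness_px + 1)
  integrity <- rep(1 - config$tox_integrity_loss * tox_e, n)

  # Sequential placement with 3-D sphere exclusion: cysts are solid
  # structures in a gel and cannot interpenetrate. Best effort: after
  # max_try rejections the least-overlapping candidate is accepted.
  zs <- z_step_px(config)
  cx <- cy <- cz <- numeric(n)
  max_try <- 200L
  for (i in seq_len(n)) {
    best <- NULL; best_sep <- -Inf
    for (t in seq_len(max_try)) {
      px <- runif(1, margin, w - margin)
      py <- runif(1, margin, h - margin)
      pz <- runif(1, 1, config$n_planes)
      if (i == 1L) { best <- c(px, py, pz); break }
      j <- seq_len(i - 1L)
      d3 <- sqrt((px - cx[j])^2 + (py - cy[j])^2 + ((pz - cz[j]) * zs)^2)
      sep <- min(d3 - 0.95 * (radius[i] + radius[j]))
      if (sep >= 0) { best <- c(px, py, pz); break }
      if (sep > best_sep) { best_sep <- sep; best <- c(px, py, pz) }
    }
    cx[i] <- best[1]; cy[i] <- best[2]; cz[i] <- best[3]
  }
  lambda <- config$nuclei_per_radius * radius *
    (1 - config$tox_nuclei_loss * tox_e)
  n_nuclei <- vapply(lambda, function(l) stats::rpois(1, max(l, 0)),
                     integer(1))

  nuclei <- lapply(seq_len(n), function(i) {
    k <- n_nuclei[i]
    if (k == 0L) return(matrix(numeric(0), ncol = 3))
    theta <- runif(k, 0, 2 * pi)
    u <- runif(k, -1, 1)                       # cos(polar angle)
    rr <- radius[i]
    x <- cx[i] + rr * sqrt(1 - u^2) * cos(theta)
    y <- cy[i] + rr * sqrt(1 - u^2) * sin(theta)
    p <- clamp(round(cz[i] + rr * u / zs), 1, config$n_planes)
    cbind(x = clamp(x, 2, w - 1), y = clamp(y, 2, h - 1), plane = p)
  })

  tibble(
    cyst = seq_len(n), cx = cx, cy = cy, cz = cz,
    radius_px = radius,
    wall_thickness_px = rep(config$wall_thickness_px, n),
    wall_intensity = wall_int,
    lumen_intensity = rep(config$lumen_intensity, n),
    n_nuclei = n_nuclei, integrity = integrity,
    gap_start1 = gap_start1, gap_start2 = gap_start2,
    true_area_px = pi * radius^2,
    nuclei = nuclei
  )
}

#' Render one well into actin and nuclei z-stacks
#'
#' Rasterizes a well's cysts as spheres sampled by the focal planes:
#' in every plane a cyst intersects, the actin channel shows a bright
#' ring (wall) of the configured thickness around a dim lumen, and the
#' nuclei channel shows Gaussian spots at the nuclei positions sampled
#' on the cyst surface. Wall integrity below 1 removes two arc segments
#' totalling `(1 - integrity)` of the ring (lumen signal is kept).
#' Additive Gaussian noise (`noise_sd`) is applied last and intensities
#' are clipped to the 16-bit dynamic range and quantized.
#'
#' @param well One layout row.
#' @param cysts Cyst tibble from [draw_well_cysts()]; drawn afresh when
#'   `NULL`.
#' @param config A [screen_config()].
#' @param noise_seed Seed of the noise substream; defaults to the well's
#'   substream seed plus one.
#' @return A list with `actin` and `nuclei` [image_stack()]s.
#' @export
render_well <- function(well, cysts = NULL, config, noise_seed = NULL) {
  stopifnot(nrow(well) == 1L)
  if (any(config$image_size < 1L) || config$n_planes < 1L) {
    abort("image size and plane count must be positive",
          class = "cystscreen_render_error")
  }
  if (is.null(cysts)) cysts <- draw_well_cysts(well, config)
  h <- config$image_size[1]; w <- config$image_size[2]
  if (nrow(cysts) &&
      any(cysts$cx < 1 | cysts$cx > w | cysts$cy < 1 | cysts$cy > h |
            cysts$cz < 1 | cysts$cz > config$n_planes)) {
    abort(paste0("cyst centres outside the image volume in well ",
                 well$well_id),
          class = "cystscreen_render_error")
  }

  actin <- array(config$background, dim = c(h, w, config$n_planes))
  nucl <- array(config$background, dim = c(h, w, config$n_planes))
  zs <- z_step_px(config)

  for (i in seq_len(nrow(cysts))) {
    cy_ <- cysts$cy[i]; cx_ <- cysts$cx[i]; cz_ <- cysts$cz[i]
    r <- cysts$radius_px[i]; wall <- cysts$wall_thickness_px[i]
    for (p in seq_len(config$n_planes)) {
      dz <- (p - cz_) * zs
      if (abs(dz) >= r) next
      rp <- sqrt(r^2 - dz^2)
      if (rp < 0.5) next
      disc <- raster_annulus(h, w, cx_, cy_, rp, wall,
                             cysts$wall_intensity[i],
                             cysts$lumen_intensity[i],
                             cysts$integrity[i],
                             cysts$gap_start1[i], cysts$gap_start2[i])
      actin[disc$rows, disc$cols, p] <-
        pmax(actin[disc$rows, disc$cols, p], disc$patch)
    }
    spots <- cysts$nuclei[[i]]
    for (j in seq_len(nrow(spots))) {
      nucl <- add_spot(nucl, spots[j, "x"], spots[j, "y"],
                       spots[j, "plane"], config$nucleus_sigma_px,
                       config$nucleus_intensity, config$background)
    }
  }

  if (config$illumination_gradient != 0) {
    grad <- 1 + config$illumination_gradient *
      (matrix(seq_len(w), h, w, byrow = TRUE) / w - 0.5)
    for (p in seq_len(config$n_planes)) {
      actin[, , p] <- actin[, , p] * grad
      nucl[, , p] <- nucl[, , p] * grad
    }
  }

  if (config$noise_sd > 0) {
    if (is.null(noise_seed)) {
      noise_seed <- well_seed(config$seed, well$well_index) + 1L
    }
    set.seed(noise_seed)
    actin <- actin + rnorm(length(actin), 0, config$noise_sd)
    nucl <- nucl + rnorm(length(nucl), 0, config$noise_sd)
  }
  actin <- round(clamp(actin, 0, config$max_intensity))
  nucl <- round(clamp(nucl, 0, config$max_intensity))

  list(
    actin = image_stack(actin, config$z_interval_um, "actin", well$well_id),
    nuclei = image_stack(nucl, config$z_interval_um, "nuclei", well$well_id)
  )
}

# Rasterize one plane's annulus + lumen patch; returns the bounding-box
# rows/cols and the intensity patch (background where empty).
raster_annulus <- function(h, w, cx, cy, rp, wall, wall_int, lumen_int,
                           integrity, gap1, gap2) {
  x0 <- max(1L, floor(cx - rp - 1)); x1 <- min(w, ceiling(cx + rp + 1))
  y0 <- max(1L, floor(cy - rp - 1)); y1 <- min(h, ceiling(cy + rp + 1))
  rows <- y0:y1; cols <- x0:x1
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(rows - cy, length(rows), length(cols))
  d <- sqrt(dx^2 + dy^2)
  patch <- matrix(0, length(rows), length(cols))
  inner <- max(rp - wall, 0)
  patch[d <= inner] <- lumen_int
  ring <- d <= rp & d > inner
  if (integrity < 1) {
    gap_total <- 2 * pi * (1 - integrity)
    ang <- atan2(dy, dx) %% (2 * pi)
    in_gap <- angle_in_arc(ang, gap1, gap_total / 2) |
      angle_in_arc(ang, gap2, gap_total / 2)
    ring <- ring & !in_gap
  }
  patch[ring] <- wall_int
  list(rows = rows, cols = cols, patch = patch)
}

angle_in_arc <- function(ang, start, width) {
  ((ang - start) %% (2 * pi)) < width
}

add_spot <- function(arr, x, y, plane, sigma, amp, background) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  ext <- ceiling(3 * sigma)
  x0 <- max(1L, floor(x - ext)); x1 <- min(w, ceiling(x + ext))
  y0 <- max(1L, floor(y - ext)); y1 <- min(h, ceiling(y + ext))
  rows <- y0:y1; cols <- x0:x1
  dx <- matrix(cols - x, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(rows - y, length(rows), length(cols))
  spot <- background + amp * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  arr[rows, cols, plane] <- pmax(arr[rows, cols, plane], spot)
  arr
}
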