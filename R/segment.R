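#' Segmentation parameters
#'
#' Tunable parameters of the plane segmentation, vertical linking, wall
#' measurement and nuclei counting steps.
#'
#' @param smooth_sigma Gaussian smoothing scale (px) before thresholding.
#' @param threshold_method `"otsu"` (on the smoothed, range-normalized
#'   plane histogram) or `"fixed"`.
#' @param fixed_threshold Absolute intensity threshold for
#'   `threshold_method = "fixed"`.
#' @param threshold_floor Absolute intensity floor: the effective
#'   threshold never drops below it, which guards near-empty planes where
#'   Otsu would split the background noise. Set to the expected
#'   background plus a few noise SDs.
#' @param min_area,max_area Object size filter (px).
#' @param fill_holes Close the dim lumen into a filled cyst mask.
#' @param link_overlap Minimum overlap fraction (of the smaller mask)
#'   linking objects in adjacent planes into one cyst.
#' @param wall_search Erosion radius (px) used to reach the object
#'   interior when setting the wall intensity threshold.
#' @param nuclei_sigma Smoothing scale for the nuclei projection.
#' @param spot_tolerance Watershed tolerance (range-normalized intensity
#'   units) when splitting merged nuclear spots.
#' @param min_spot_area Minimum nuclear spot size (px).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma = 0.7,
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       threshold_floor = 2000,
                       min_area = 30, max_area = Inf,
                       fill_holes = TRUE,
                       link_overlap = 0.5,
                       wall_search = 5,
                       nuclei_sigma = 0.5,
                       spot_tolerance = 0.008,
                       min_spot_area = 4) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    abort("fixed_threshold required for threshold_method = 'fixed'",
          class = "cystscreen_segment_error")
  }
  structure(as.list(environment()), class = "seg_params")
}

empty_objects <- function() {
  tibble(object = integer(), area_px = double(),
         centroid_x = double(), centroid_y = double(),
         on_border = logical(), pixels = list())
}

#' Segment one focal plane into cyst masks
#'
#' Generates the monochrome foreground mask of a single actin plane:
#' Gaussian smoothing, histogram thresholding (Otsu by default, with an
#' absolute floor), hole filling (so the dim lumen is part of the cyst),
#' connected components and a size filter. Objects touching the image
#' border are flagged. A constant plane yields no objects.
#'
#' Because Otsu is computed on the range-normalized histogram, the
#' segmentation of a noise-free image is invariant to multiplying its
#' intensities by a constant (as long as the floor is not hit).
#'
#' @param plane Numeric intensity matrix.
#' @param params A [seg_params()].
#' @return A tibble with one row per object: `object`, `area_px`,
#'   `centroid_x`, `centroid_y`, `on_border`, and a `pixels` list-column
#'   of linear pixel indices into `plane` (column-major, as in R
#'   matrices; pixel coordinates are 1-based).
#' @export
segment_plane <- function(plane, params = seg_params()) {
  stopifnot(is.matrix(plane), length(plane) > 0)
  rng <- range(plane)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(empty_objects())

  x <- (plane - rng[1]) / diff(rng)
  xs <- if (params$smooth_sigma > 0) {
    clamp(EBImage::gblur(x, sigma = params$smooth_sigma), 0, 1)
  } else x

  if (params$threshold_method == "fixed") {
    thr <- (params$fixed_threshold - rng[1]) / diff(rng)
  } else {
    thr <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
  }
  floor_rel <- (params$threshold_floor - rng[1]) / diff(rng)
  mask <- xs > max(thr, floor_rel)
  if (!any(mask)) return(empty_objects())

  m <- EBImage::Image(mask * 1)
  if (params$fill_holes) m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  labm <- EBImage::imageData(lab)
  n_obj <- max(labm)
  if (n_obj == 0) return(empty_objects())

  sizes <- tabulate(labm[labm > 0], nbins = n_obj)
  keep <- which(sizes >= params$min_area & sizes <= params$max_area)
  if (!length(keep)) return(empty_objects())

  h <- nrow(plane); w <- ncol(plane)
  border_labels <- unique(c(labm[1, ], labm[h, ], labm[, 1], labm[, w]))
  idx_by_label <- split(which(labm > 0), labm[labm > 0])

  rows <- lapply(seq_along(keep), function(k) {
    lb <- keep[k]
    idx <- idx_by_label[[as.character(lb)]]
    rr <- ((idx - 1L) %% h) + 1L
    cc <- ((idx - 1L) %/% h) + 1L
    tibble(object = k, area_px = length(idx),
           centroid_x = mean(cc), centroid_y = mean(rr),
           on_border = lb %in% border_labels,
           pixels = list(idx))
  })
  bind_rows(rows)
}

# Crofton-corrected perimeter estimate: exposed 4-neighbour edge count
# scaled by pi/4 (exact in expectation for smooth convex digital shapes).
perimeter_crofton <- function(idx, dims) {
  h <- dims[1]; w <- dims[2]
  m <- matrix(FALSE, h + 2L, w + 2L)
  rr <- ((idx - 1L) %% h) + 2L
  cc <- ((idx - 1L) %/% h) + 2L
  m[cbind(rr, cc)] <- TRUE
  inner <- m[2:(h + 1), 2:(w + 1)]
  exposed <- sum(inner & !m[1:h, 2:(w + 1)]) +
    sum(inner & !m[3:(h + 2), 2:(w + 1)]) +
    sum(inner & !m[2:(h + 1), 1:w]) +
    sum(inner & !m[2:(h + 1), 3:(w + 2)])
  exposed * pi / 4
}

#' Measure the actin-dense wall of a cyst mask
#'
#' The wall band is the set of pixels of the mask (plus a one-pixel
#' dilation margin) whose intensity exceeds a threshold set from the
#' object's interior statistics: the midpoint between the median interior
#' intensity (the lumen, reached by eroding the mask) and the brightest
#' band pixel. The mean wall thickness is the wall area divided by the
#' object perimeter. A uniform-intensity object (no actin-dense rim) has
#' thickness 0; a mask below `min_area` is flagged and gets thickness 0.
#'
#' @param mask Logical matrix, or a vector of linear pixel indices into
#'   `plane`.
#' @param plane The intensity plane the mask was derived from.
#' @param params A [seg_params()].
#' @return A list: `wall_pixels` (linear indices), `wall_area_px`,
#'   `wall_mean_thickness_px`, `perimeter_px`, `flagged`.
#' @export
measure_wall <- function(mask, plane, params = seg_params()) {
  h <- nrow(plane); w <- ncol(plane)
  if (is.logical(mask) && is.matrix(mask)) {
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
  }
  out0 <- list(wall_pixels = integer(), wall_area_px = 0,
               wall_mean_thickness_px = 0,
               perimeter_px = perimeter_crofton(idx, c(h, w)),
               flagged = TRUE)
  if (length(idx) < params$min_area) return(out0)

  m <- matrix(FALSE, h, w)
  m[idx] <- TRUE
  mi <- EBImage::Image(m * 1)
  band <- EBImage::imageData(
    EBImage::dilate(mi, EBImage::makeBrush(3, "diamond"))) > 0

  equiv_r <- sqrt(length(idx) / pi)
  er <- min(params$wall_search, max(2, floor(equiv_r / 2)))
  interior <- EBImage::imageData(
    EBImage::erode(mi, EBImage::makeBrush(2L * er + 1L, "disc"))) > 0
  int_px <- plane[interior]
  if (!length(int_px)) int_px <- plane[band & !m]   # margin fallback
  if (!length(int_px)) int_px <- plane[m]

  thr <- (median(int_px) + max(plane[band])) / 2
  wall <- band & (plane > thr)
  perim <- perimeter_crofton(idx, c(h, w))
  list(wall_pixels = which(wall),
       wall_area_px = sum(wall),
       wall_mean_thickness_px = if (perim > 0) sum(wall) / perim else 0,
       perimeter_px = perim,
       flagged = FALSE)
}

#' Detect individual cysts in an actin z-stack
#'
#' Segments every focal plane ([segment_plane()]) and links objects in
#' adjacent planes whose masks overlap by at least `link_overlap` of the
#' smaller mask (greedy one-to-one matching per plane pair, largest
#' overlap first, ties toward the lower plane index). Each linked group
#' becomes one cyst whose defining plane is the plane of maximal area
#' (best focus). Objects that coincide in x,y but appear only in
#' non-adjacent planes therefore stay distinct — the vertically
#' overlapping case that per-projection analysis would merge.
#'
#' @param stack Actin-channel [image_stack()].
#' @param params A [seg_params()].
#' @return A tibble with one row per cyst: `object_id`, `well_id`,
#'   `plane_index` (defining plane), `area_px`, `perimeter_px`,
#'   `centroid_x`, `centroid_y`, `on_border`, `n_planes_spanned`,
#'   `wall_area_px`, `wall_mean_thickness_px`, `wall_flagged`, and a
#'   `pixels` list-column (defining-plane mask, linear indices).
#' @export
#' @examples
#' \donttest{
#' cfg <- demo_screen_config(seed = 2, noise_sd = 0)
#' lay <- plate_layout(cfg, demo_compounds())
#' sim <- simulate_well(lay[1, ], cfg)
#' detect_cysts(sim$actin, seg_params())
#' }
detect_cysts <- function(stack, params = seg_params()) {
  stopifnot(inherits(stack, "image_stack"))
  np <- n_planes(stack)
  if (np < 1) abort("stack has no planes", class = "cystscreen_stack_error")

  per_plane <- lapply(seq_len(np), function(p) {
    obj <- segment_plane(stack$planes[, , p], params)
    if (nrow(obj)) obj$plane <- p
    obj
  })
  all_obj <- bind_rows(per_plane)
  if (!nrow(all_obj)) return(empty_cysts())
  all_obj$gid <- seq_len(nrow(all_obj))

  parent <- seq_len(nrow(all_obj))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }

  for (p in seq_len(np - 1L)) {
    a <- all_obj[all_obj$plane == p, ]
    b <- all_obj[all_obj$plane == p + 1L, ]
    if (!nrow(a) || !nrow(b)) next
    cand <- list()
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        ov <- length(intersect(a$pixels[[i]], b$pixels[[j]]))
        frac <- ov / min(a$area_px[i], b$area_px[j])
        if (frac >= params$link_overlap) {
          cand[[length(cand) + 1L]] <- c(i = i, j = j, frac = frac)
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, "frac"], cand[, "i"]), , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, "i"]; j <- cand[k, "j"]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      union_(a$gid[i], b$gid[j])
    }
  }

  groups <- split(seq_len(nrow(all_obj)),
                  vapply(seq_len(nrow(all_obj)), find, integer(1)))
  rows <- lapply(seq_along(groups), function(g) {
    members <- all_obj[groups[[g]], ]
    best <- members[order(-members$area_px, members$plane), ][1, ]
    plane_img <- stack$planes[, , best$plane]
    wallm <- measure_wall(best$pixels[[1]], plane_img, params)
    tibble(object_id = g, well_id = stack$well_id,
           plane_index = best$plane, area_px = best$area_px,
           perimeter_px = wallm$perimeter_px,
           centroid_x = best$centroid_x, centroid_y = best$centroid_y,
           on_border = any(members$on_border),
           n_planes_spanned = nrow(members),
           wall_area_px = wallm$wall_area_px,
           wall_mean_thickness_px = wallm$wall_mean_thickness_px,
           wall_flagged = wallm$flagged,
           pixels = best$pixels)
  })
  out <- bind_rows(rows) %>% arrange(.data$plane_index, .data$centroid_x)
  out$object_id <- seq_len(nrow(out))
  out
}

empty_cysts <- function() {
  tibble(object_id = integer(), well_id = character(),
         plane_index = integer(), area_px = double(),
         perimeter_px = double(), centroid_x = double(),
         centroid_y = double(), on_border = logical(),
         n_planes_spanned = integer(), wall_area_px = double(),
         wall_mean_thickness_px = double(), wall_flagged = logical(),
         pixels = list())
}

#' Count nuclei in a nuclei-channel z-stack
#'
#' The stack is collapsed to a maximum intensity projection (nuclear
#' shape is not resolved at low magnification, only spot counts), then
#' smoothed, thresholded (Otsu with the absolute floor) and split into
#' individual spots by an intensity watershed so touching nuclei are
#' separated. Deterministic for fixed input and parameters.
#'
#' @param stack Nuclei-channel [image_stack()].
#' @param params A [seg_params()].
#' @return Integer spot count (0 for a constant projection).
#' @export
count_nuclei <- function(stack, params = seg_params()) {
  proj <- max_projection(stack)
  rng <- range(proj)
  if (diff(rng) <= 0) return(0L)
  x <- (proj - rng[1]) / diff(rng)
  xs <- if (params$nuclei_sigma > 0) {
    clamp(EBImage::gblur(x, sigma = params$nuclei_sigma), 0, 1)
  } else x
  thr <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
  floor_rel <- (params$threshold_floor - rng[1]) / diff(rng)
  mask <- xs > max(thr, floor_rel)
  if (!any(mask)) return(0L)
  lab <- EBImage::watershed(EBImage::Image(xs * mask),
                            tolerance = params$spot_tolerance, ext = 1)
  labm <- EBImage::imageData(lab)
  n_obj <- max(labm)
  if (n_obj == 0) return(0L)
  sizes <- tabulate(labm[labm > 0], nbins = n_obj)
  sum(sizes >= params$min_spot_area)
}
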