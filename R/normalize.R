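#' Z-score well features to plate medians
#'
#' Per plate and per feature, centers on the plate median and divides by
#' a robust scale (MAD x 1.4826 by default; sample SD selectable for
#' classical z-scores). A feature with zero spread on a plate is flagged
#' constant and set missing rather than producing infinities.
#'
#' @param tbl Well-feature tibble (needs a `plate` column).
#' @param features Feature columns; defaults to [feature_columns()].
#' @param scale `"mad"` or `"sd"`.
#' @return The tibble with the named features replaced by their plate
#'   z-scores; attributes `normalization = "plate_z"` and `provenance`
#'   (per-plate centers/scales and constant flags).
#' @export
#' @examples
#' tbl <- tibble::tibble(plate = "P1", well_id = sprintf("A%02d", 1:5),
#'                       area_px_med = c(1, 2, 3, 4, 5))
#' normalize_plate_median(tbl, "area_px_med")$area_px_med
normalize_plate_median <- function(tbl, features = NULL,
                                   scale = c("mad", "sd")) {
  scale <- match.arg(scale)
  features <- features %||% feature_columns(tbl)
  if (!"plate" %in% names(tbl)) tbl$plate <- "P1"
  small <- dplyr::count(tbl, .data$plate) %>% filter(n < 2)
  if (nrow(small)) {
    abort(paste0("plate(s) with fewer than 2 wells: ",
                 paste(small$plate, collapse = ", ")),
          class = "cystscreen_normalize_error")
  }
  scale_stats_apply(tbl, features, scale, tag = "plate_z",
                    ref_rows = function(sub) rep(TRUE, nrow(sub)))
}

#' Z-score well features to the unstimulated-control median
#'
#' The second normalization layer: per plate and per feature, centers on
#' the median of the wells with the given control role and divides by
#' their robust spread, so the unstimulated-control median maps to 0.
#' Usually applied on top of [normalize_plate_median()].
#'
#' @inheritParams normalize_plate_median
#' @param control_role Role of the anchoring control wells.
#' @return The tibble with features replaced by control z-scores;
#'   attribute `normalization = "control_z"`.
#' @export
normalize_to_control <- function(tbl, features = NULL,
                                 control_role = "unstimulated",
                                 scale = c("mad", "sd")) {
  scale <- match.arg(scale)
  features <- features %||% feature_columns(tbl)
  if (!"plate" %in% names(tbl)) tbl$plate <- "P1"
  n_ctrl <- tbl %>% group_by(.data$plate) %>%
    summarise(n = sum(.data$role == control_role), .groups = "drop")
  if (any(n_ctrl$n < 2)) {
    abort(paste0("plate(s) without >= 2 '", control_role, "' control wells: ",
                 paste(n_ctrl$plate[n_ctrl$n < 2], collapse = ", ")),
          class = "cystscreen_normalize_error")
  }
  scale_stats_apply(tbl, features, scale, tag = "control_z",
                    ref_rows = function(sub) sub$role == control_role)
}

scale_stats_apply <- function(tbl, features, scale, tag, ref_rows) {
  prov <- list()
  out <- tbl
  for (pl in unique(tbl$plate)) {
    sel <- which(tbl$plate == pl)
    ref <- sel[ref_rows(tbl[sel, ])]
    for (f in features) {
      v_ref <- tbl[[f]][ref]
      ctr <- median(v_ref, na.rm = TRUE)
      sc <- if (scale == "mad") mad(v_ref, na.rm = TRUE) else sd(v_ref, na.rm = TRUE)
      if (!is.finite(sc) || sc <= 0) {
        out[[f]][sel] <- NA_real_
        prov[[pl]]$constant <- c(prov[[pl]]$constant, f)
      } else {
        out[[f]][sel] <- (tbl[[f]][sel] - ctr) / sc
        prov[[pl]]$center[f] <- ctr
        prov[[pl]]$scale[f] <- sc
      }
    }
  }
  attr(out, "normalization") <- tag
  attr(out, "provenance") <- prov
  out
}

#' Percent inhibition scaling
#'
#' Linear rescaling anchored on the two control medians: the
#' forskolin-stimulated control median maps to 0 and the unstimulated
#' control median to 100. Values are deliberately not clamped —
#' over-inhibition (> 100%, smaller than the unstimulated median) is a
#' meaningful readout.
#'
#' @param values Raw feature values.
#' @param unstim_median,stim_median Control anchors (must differ).
#' @return Numeric vector of percent inhibition.
#' @export
#' @examples
#' percent_inhibition(c(100, 150, 200), unstim_median = 100,
#'                    stim_median = 200)
percent_inhibition <- function(values, unstim_median, stim_median) {
  if (isTRUE(all.equal(unstim_median, stim_median))) {
    abort("control anchors are equal; percent inhibition undefined",
          class = "cystscreen_normalize_error")
  }
  100 * (values - stim_median) / (unstim_median - stim_median)
}

#' Percent-inhibition normalization of a well table
#'
#' Applies [percent_inhibition()] to the named features, per plate, with
#' anchors taken from the medians of the unstimulated and stimulated
#' control wells.
#'
#' @inheritParams normalize_plate_median
#' @return The tibble with features on the percent-inhibition scale;
#'   attribute `normalization = "percent_inhibition"`.
#' @export
normalize_percent_inhibition <- function(tbl, features = NULL) {
  features <- features %||% feature_columns(tbl)
  if (!"plate" %in% names(tbl)) tbl$plate <- "P1"
  out <- tbl
  prov <- list()
  for (pl in unique(tbl$plate)) {
    sel <- which(tbl$plate == pl)
    sub <- tbl[sel, ]
    for (f in features) {
      u <- median(sub[[f]][sub$role == "unstimulated"], na.rm = TRUE)
      s <- median(sub[[f]][sub$role == "stimulated"], na.rm = TRUE)
      out[[f]][sel] <- percent_inhibition(tbl[[f]][sel], u, s)
      prov[[pl]][[f]] <- c(unstim_median = u, stim_median = s)
    }
  }
  attr(out, "normalization") <- "percent_inhibition"
  attr(out, "provenance") <- prov
  out
}

#' Replicate-adjusted Z'-factor
#'
#' Assay-quality statistic between a high (stimulated, `max`) and a low
#' (unstimulated, `min`) control group, with the 3-SD bands shrunk by
#' the square root of the number of technical replicates:
#'
#' \deqn{Z' = \frac{(AVG_{max} - 3\,SD_{max}/\sqrt{n}) -
#'                 (AVG_{min} + 3\,SD_{min}/\sqrt{n})}
#'                {AVG_{max} - AVG_{min}}}
#'
#' At `n = 1` this is the classical Z'-factor; it is always <= 1, equals
#' 1 for noiseless controls, and increases with `n` (the separation
#' relevant to a screen read out as replicate means).
#'
#' @param avg_max,sd_max Mean and SD of the stimulated (max) controls.
#' @param avg_min,sd_min Mean and SD of the unstimulated (min) controls.
#' @param n Number of technical replicates.
#' @return Numeric Z' value(s); vectorized over all arguments.
#' @export
#' @examples
#' zprime(100, 10, 0, 10, n = 4)  # 0.70
#' zprime(100, 10, 0, 10, n = 1)  # 0.40
zprime <- function(avg_max, sd_max, avg_min, sd_min, n = 1) {
  if (any(sd_max < 0 | sd_min < 0, na.rm = TRUE)) {
    abort("standard deviations must be non-negative",
          class = "cystscreen_zprime_error")
  }
  if (any(n < 1, na.rm = TRUE)) {
    abort("n must be >= 1", class = "cystscreen_zprime_error")
  }
  if (any(avg_max == avg_min, na.rm = TRUE)) {
    abort("control means are equal; Z' separation undefined",
          class = "cystscreen_zprime_error")
  }
  ((avg_max - 3 * sd_max / sqrt(n)) - (avg_min + 3 * sd_min / sqrt(n))) /
    (avg_max - avg_min)
}

#' Per-plate control Z' of a well table
#'
#' Computes the replicate-adjusted [zprime()] of one feature between two
#' control-role groups on every plate (the max/min roles are taken from
#' the group means, so the statistic does not depend on which group
#' swells).
#'
#' @param tbl Well-feature tibble.
#' @param feature Feature column (default: median cyst area).
#' @param role_a,role_b The two control roles to separate.
#' @param n Technical replicates; defaults to the smaller group size.
#' @return A tibble: `plate`, `feature`, `zprime`, `n`, group means/SDs.
#' @export
zprime_controls <- function(tbl, feature = "area_px_med",
                            role_a = "stimulated", role_b = "unstimulated",
                            n = NULL) {
  if (!"plate" %in% names(tbl)) tbl$plate <- "P1"
  tbl %>%
    filter(.data$role %in% c(role_a, role_b)) %>%
    group_by(.data$plate) %>%
    summarise(
      avg_a = mean(.data[[feature]][.data$role == role_a], na.rm = TRUE),
      sd_a = sd(.data[[feature]][.data$role == role_a], na.rm = TRUE),
      n_a = sum(.data$role == role_a & !is.na(.data[[feature]])),
      avg_b = mean(.data[[feature]][.data$role == role_b], na.rm = TRUE),
      sd_b = sd(.data[[feature]][.data$role == role_b], na.rm = TRUE),
      n_b = sum(.data$role == role_b & !is.na(.data[[feature]])),
      .groups = "drop"
    ) %>%
    mutate(
      feature = feature,
      n = n %||% pmin(.data$n_a, .data$n_b),
      zprime = zprime(
        avg_max = pmax(.data$avg_a, .data$avg_b),
        sd_max = if_else(.data$avg_a >= .data$avg_b, .data$sd_a, .data$sd_b),
        avg_min = pmin(.data$avg_a, .data$avg_b),
        sd_min = if_else(.data$avg_a >= .data$avg_b, .data$sd_b, .data$sd_a),
        n = .data$n
      )
    ) %>%
    select("plate", "feature", "zprime", "n", "avg_a", "sd_a", "n_a",
           "avg_b", "sd_b", "n_b")
}

#' Call hits by the cyst-size rule
#'
#' A compound is a hit when the replicate-mean control z-score of the
#' size feature is at or below the threshold (default 0, i.e. equal to
#' or smaller than the unstimulated control median) at *any* tested
#' dose. Means are taken over non-missing replicate wells with a
#' minimum-replicate floor; a compound-dose with fewer evaluable wells
#' is flagged unevaluable and can never make a compound a hit.
#'
#' @param tbl Control-z normalized well table (see
#'   [normalize_to_control()]), with `role == "test"` wells.
#' @param size_feature Size feature column (default median cyst area).
#' @param threshold Hit threshold on the replicate-mean z-score.
#' @param min_replicates Minimum evaluable replicate wells per dose.
#' @return A tibble with one row per compound-dose: `compound`,
#'   `concentration_um`, `mean_size_z`, `n_wells`, `evaluable`,
#'   `dose_hit`, and the per-compound `hit` flag.
#' @export
call_hits <- function(tbl, size_feature = "area_px_med", threshold = 0,
                      min_replicates = 2L) {
  test <- filter(tbl, .data$role == "test")
  if (!nrow(test)) {
    abort("no test wells in the table", class = "cystscreen_hits_error")
  }
  per_dose <- test %>%
    group_by(.data$compound, .data$concentration_um) %>%
    summarise(
      mean_size_z = mean(.data[[size_feature]], na.rm = TRUE),
      n_wells = sum(!is.na(.data[[size_feature]])),
      .groups = "drop"
    ) %>%
    mutate(
      evaluable = .data$n_wells >= min_replicates,
      mean_size_z = if_else(.data$n_wells > 0, .data$mean_size_z, NA_real_),
      dose_hit = .data$evaluable & !is.na(.data$mean_size_z) &
        .data$mean_size_z <= threshold
    )
  per_dose %>%
    group_by(.data$compound) %>%
    mutate(hit = any(.data$dose_hit)) %>%
    ungroup() %>%
    arrange(.data$compound, .data$concentration_um)
}
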