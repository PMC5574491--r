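#' Scale raw cyst sizes to fractional effects
#'
#' Maps a raw size to the inhibition-of-swelling scale required by the
#' Bliss model: 0 at the stimulated-control median (no inhibition), 1 at
#' the unstimulated-control median (maximum effect), clamped to \[0, 1\]
#' because Bliss treats effects as probabilities.
#'
#' @param values Raw sizes (replicate means, typically).
#' @param unstim_median,stim_median Control anchors (must differ).
#' @return Effects in \[0, 1\].
#' @export
#' @examples
#' scale_effect(c(200, 150, 90), unstim_median = 100, stim_median = 200)
scale_effect <- function(values, unstim_median, stim_median) {
  clamp(percent_inhibition(values, unstim_median, stim_median) / 100, 0, 1)
}

#' Bliss-independence predicted combined effect
#'
#' `E = E_A + E_B - E_A * E_B`, the combined response expected when two
#' drugs act independently; equivalently `1 - (1 - E_A)(1 - E_B)`.
#'
#' @param e_a,e_b Single-agent effects in \[0, 1\].
#' @return Predicted combined effects; symmetric in the arguments and
#'   never below `max(e_a, e_b)`.
#' @export
#' @examples
#' bliss_predicted(0.3, 0.4)  # 0.58
bliss_predicted <- function(e_a, e_b) {
  if (any(e_a < 0 | e_a > 1 | e_b < 0 | e_b > 1, na.rm = TRUE)) {
    abort("effects must lie in [0, 1]", class = "cystscreen_synergy_error")
  }
  e_a + e_b - e_a * e_b
}

#' Combination index
#'
#' `CI = (E_A + E_B - E_A * E_B) / E_AB`: the Bliss-predicted combined
#' effect over the observed one. `CI < 1` means the observed response
#' exceeds the prediction (synergy), `CI > 1` falls short (antagonism).
#' An observed effect of 0 leaves CI undefined (`NA`), not infinite.
#'
#' @param e_a,e_b Single-agent effects in \[0, 1\].
#' @param e_ab Observed combined effect.
#' @return Combination index values (`NA` where `e_ab <= 0`).
#' @export
#' @examples
#' combination_index(0.5, 0.5, 1.0)   # 0.75
#' combination_index(0.3, 0.4, 0.29)  # 2.0
combination_index <- function(e_a, e_b, e_ab) {
  pred <- bliss_predicted(e_a, e_b)
  ifelse(is.na(e_ab) | e_ab <= 0, NA_real_, pred / e_ab)
}

#' Classify a drug-drug interaction from its combination index
#'
#' @param ci Combination index ([combination_index()]).
#' @param tolerance Half-width of the additivity band around `CI = 1`.
#' @return `"synergistic"` (`CI < 1 - tolerance`), `"antagonistic"`
#'   (`CI > 1 + tolerance`) or `"additive"`; `NA` where CI is undefined.
#' @export
#' @examples
#' classify_interaction(c(0.5, 1.0, 2.0))
classify_interaction <- function(ci, tolerance = 0.05) {
  case_when(
    is.na(ci) ~ NA_character_,
    ci < 1 - tolerance ~ "synergistic",
    ci > 1 + tolerance ~ "antagonistic",
    TRUE ~ "additive"
  )
}

#' Bliss analysis of a two-compound dose grid
#'
#' Takes replicate well sizes of a checkerboard combination experiment
#' in long form, averages replicates, scales sizes to effects
#' ([scale_effect()]) and, for every dose pair with both doses > 0,
#' reports the single-agent effects, the Bliss prediction, the
#' combination index and the interaction call.
#'
#' @param df Long tibble with columns `dose_a_um`, `dose_b_um`, `size`,
#'   one row per well; single-agent wells have the partner dose 0.
#'   Control rows (`role` of `unstimulated`/`stimulated`) supply the
#'   anchors when `unstim_median`/`stim_median` are not given.
#' @param unstim_median,stim_median Control anchors; computed from the
#'   control rows of `df` when `NULL`.
#' @param tolerance Additivity band for [classify_interaction()].
#' @return A tibble of class `synergy_grid`: `dose_a_um`, `dose_b_um`,
#'   `e_a`, `e_b`, `e_ab`, `e_pred`, `ci`, `label`.
#' @export
analyze_synergy <- function(df, unstim_median = NULL, stim_median = NULL,
                            tolerance = 0.05) {
  need <- c("dose_a_um", "dose_b_um", "size")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
          class = "cystscreen_synergy_error")
  }
  if (is.null(unstim_median) || is.null(stim_median)) {
    if (!"role" %in% names(df)) {
      abort("anchors not given and no control rows ('role') available",
            class = "cystscreen_synergy_error")
    }
    unstim_median <- unstim_median %||%
      median(df$size[df$role == "unstimulated"], na.rm = TRUE)
    stim_median <- stim_median %||%
      median(df$size[df$role == "stimulated"], na.rm = TRUE)
  }
  test <- if ("role" %in% names(df)) filter(df, .data$role == "test") else df
  means <- test %>%
    group_by(.data$dose_a_um, .data$dose_b_um) %>%
    summarise(size = mean(.data$size, na.rm = TRUE), .groups = "drop") %>%
    mutate(effect = scale_effect(.data$size, unstim_median, stim_median))

  singles_a <- means %>% filter(.data$dose_b_um == 0, .data$dose_a_um > 0) %>%
    select(dose_a_um = "dose_a_um", e_a = "effect")
  singles_b <- means %>% filter(.data$dose_a_um == 0, .data$dose_b_um > 0) %>%
    select(dose_b_um = "dose_b_um", e_b = "effect")

  grid <- means %>%
    filter(.data$dose_a_um > 0, .data$dose_b_um > 0) %>%
    left_join(singles_a, by = "dose_a_um") %>%
    left_join(singles_b, by = "dose_b_um") %>%
    rename(e_ab = "effect") %>%
    mutate(e_pred = bliss_predicted(.data$e_a, .data$e_b),
           ci = combination_index(.data$e_a, .data$e_b, .data$e_ab),
           label = classify_interaction(.data$ci, tolerance)) %>%
    select("dose_a_um", "dose_b_um", "e_a", "e_b", "e_ab", "e_pred",
           "ci", "label")
  structure(grid, class = c("synergy_grid", class(grid)),
            anchors = c(unstim_median = unstim_median,
                        stim_median = stim_median))
}

#' @describeIn analyze_synergy Combination-index heat map of the grid.
#' @param object A `synergy_grid`.
#' @param ... Unused.
#' @export
autoplot.synergy_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$dose_a_um),
                                       factor(.data$dose_b_um),
                                       fill = .data$ci)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ci)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  name = "CI") +
    ggplot2::labs(x = "compound A dose (uM)", y = "compound B dose (uM)",
                  title = "Bliss combination index (CI < 1: synergy)")
}
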