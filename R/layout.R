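#' Compound dose-response specifications
#'
#' A compound table drives the synthetic screen: each row gives the Hill
#' dose-response of one test compound. `max_inhibition` may exceed 1 for
#' compounds that also suppress forskolin-independent cyst growth
#' ("over-inhibition": the well ends up smaller than the unstimulated
#' median, as the strongest actives in a real screen do). `toxic`
#' compounds additionally fragment cyst walls and deplete nuclei in
#' proportion to their effect.
#'
#' @param compound Character, compound names.
#' @param ec50_um Half-maximal concentration (uM). `Inf` makes the
#'   compound inert at any dose.
#' @param hill_slope Hill coefficient.
#' @param max_inhibition Maximal fractional inhibition of the
#'   forskolin-induced size increase (may exceed 1, see above).
#' @param toxic Logical, cytotoxic "novel phenotype" compound.
#' @return A tibble with one row per compound.
#' @export
#' @examples
#' compound_table("rapalog-1", ec50_um = 0.005)
compound_table <- function(compound, ec50_um, hill_slope = 2,
                           max_inhibition = 1, toxic = FALSE) {
  tbl <- tibble(
    compound = as.character(compound),
    ec50_um = as.double(ec50_um),
    hill_slope = rep_len(as.double(hill_slope), length(compound)),
    max_inhibition = rep_len(as.double(max_inhibition), length(compound)),
    toxic = rep_len(as.logical(toxic), length(compound))
  )
  if (anyDuplicated(tbl$compound)) {
    abort("compound names must be unique", class = "cystscreen_layout_error")
  }
  tbl
}

#' Demo compound set
#'
#' Three archetypes used by the demo screen: a potent active that fully
#' blocks (and slightly overshoots) forskolin-induced swelling, an inert
#' compound, and a cytotoxic compound that shrinks and fragments cysts
#' while depleting nuclei.
#'
#' @return A compound tibble (see [compound_table()]).
#' @export
demo_compounds <- function() {
  compound_table(
    compound       = c("active-1", "inert-1", "toxic-1"),
    ec50_um        = c(0.005, Inf, 0.02),
    hill_slope     = c(2, 2, 2),
    max_inhibition = c(1.1, 0, 1),
    toxic          = c(FALSE, FALSE, TRUE)
  )
}

#' Hill dose-response effect
#'
#' Fractional inhibition at a given concentration,
#' `max_inhibition * c^h / (ec50^h + c^h)`. Zero at concentration 0 or
#' for `ec50 = Inf`.
#'
#' @param conc_um Concentration (uM).
#' @param ec50_um,hill_slope,max_inhibition Hill parameters.
#' @return Numeric vector of effects.
#' @export
#' @examples
#' hill_effect(c(0, 0.005, 1), ec50_um = 0.005)
hill_effect <- function(conc_um, ec50_um, hill_slope = 2,
                        max_inhibition = 1) {
  e <- ifelse(conc_um <= 0 | is.infinite(ec50_um), 0,
              max_inhibition * conc_um^hill_slope /
                (ec50_um^hill_slope + conc_um^hill_slope))
  as.double(e)
}

#' Generate an annotated plate layout
#'
#' Lays out a simulated screen on one plate: the configured numbers of
#' unstimulated, stimulated and (optionally) reference-inhibitor control
#' wells, plus every test compound at every dose with the configured
#' replicate count. Well positions are a seed-determined permutation of
#' the plate, so the same `(config, seed)` always yields the same layout.
#'
#' All test and control wells except the unstimulated group are
#' forskolin-stimulated. Each well's deterministic true effect
#' (`effect_raw`, the Hill effect of its compound at its dose; and
#' `true_effect`, the same clipped to \[0, 1\]) is recorded as ground
#' truth.
#'
#' @param config A [screen_config()].
#' @param compounds A compound tibble ([compound_table()]).
#' @param plate Plate identifier used in well annotations and filenames.
#' @return A tibble with one row per well: `well_index`, `plate`,
#'   `well_id` (A01 form), `row`, `col`, `role` (one of `unstimulated`,
#'   `stimulated`, `reference_inhibitor`, `test`), `compound`,
#'   `concentration_um`, `stimulated`, `replicate`, `effect_raw`,
#'   `true_effect`, `toxic`.
#' @export
#' @examples
#' layout <- plate_layout(demo_screen_config(seed = 1), demo_compounds())
#' dplyr::count(layout, role)
plate_layout <- function(config, compounds, plate = "P1") {
  stopifnot(inherits(config, "screen_config"))
  ctrl <- config$controls
  n_ctrl <- vapply(ctrl, as.integer, integer(1))
  if (sum(n_ctrl[c("unstimulated", "stimulated")] > 0L) < 2L) {
    abort("layout needs at least one unstimulated and one stimulated control well",
          class = "cystscreen_layout_error")
  }

  ctrl_rows <- list(
    tibble(role = "unstimulated", compound = "DMSO",
           concentration_um = 0, stimulated = FALSE,
           replicate = seq_len(n_ctrl[["unstimulated"]]),
           effect_raw = 0, toxic = FALSE),
    tibble(role = "stimulated", compound = "forskolin",
           concentration_um = 0, stimulated = TRUE,
           replicate = seq_len(n_ctrl[["stimulated"]]),
           effect_raw = 0, toxic = FALSE)
  )
  n_ref <- ctrl[["reference_inhibitor"]] %||% 0L
  if (n_ref > 0L) {
    ctrl_rows <- c(ctrl_rows, list(
      tibble(role = "reference_inhibitor", compound = "rapamycin",
             concentration_um = 0.01, stimulated = TRUE,
             replicate = seq_len(n_ref), effect_raw = 1, toxic = FALSE)
    ))
  }

  test <- crossing(compound = compounds$compound,
                   concentration_um = config$doses_um,
                   replicate = seq_len(config$replicates)) %>%
    left_join(compounds, by = "compound") %>%
    mutate(role = "test", stimulated = TRUE,
           effect_raw = hill_effect(.data$concentration_um, .data$ec50_um,
                                    .data$hill_slope, .data$max_inhibition)) %>%
    select("role", "compound", "concentration_um", "stimulated",
           "replicate", "effect_raw", "toxic")

  wells <- bind_rows(c(ctrl_rows, list(test)))
  n_positions <- prod(config$plate_shape)
  if (nrow(wells) > n_positions) {
    abort(paste0("layout overflow: ", nrow(wells), " wells requested but the plate has ",
                 n_positions, " positions"),
          class = "cystscreen_layout_error")
  }

  set.seed(config$seed)
  pos <- sample.int(n_positions, nrow(wells))
  row <- ((pos - 1L) %% config$plate_shape[1]) + 1L
  col <- ((pos - 1L) %/% config$plate_shape[1]) + 1L

  wells %>%
    mutate(well_index = row_number(), plate = plate,
           row = row, col = col,
           well_id = paste0(LETTERS[row], sprintf("%02d", col)),
           true_effect = clamp(.data$effect_raw, 0, 1)) %>%
    select("well_index", "plate", "well_id", "row", "col", "role",
           "compound", "concentration_um", "stimulated", "replicate",
           "effect_raw", "true_effect", "toxic") %>%
    arrange(.data$well_index)
}
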