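#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  planes <- lapply(seq_len(n_planes(stack)), function(p) {
    stack$planes[, , p] / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file (all pages are read, in order).
#' @param z_interval_um,channel,well_id Stack metadata; `channel` and
#'   `well_id` default to the `<plate>_<well>_<channel>.tif` filename
#'   convention when parseable.
#' @return An [image_stack()] in 16-bit intensity units.
#' @export
read_image_stack <- function(path, z_interval_um = 50, channel = NULL,
                             well_id = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  parts <- strsplit(sub("\\.tiff?$", "", basename(path)), "_")[[1]]
  if (is.null(channel)) {
    channel <- if (length(parts) >= 3) parts[length(parts)] else NA_character_
  }
  if (is.null(well_id)) {
    well_id <- if (length(parts) >= 3) parts[length(parts) - 1] else NA_character_
  }
  image_stack(lapply(pages, function(m) round(m * 65535)),
              z_interval_um = z_interval_um, channel = channel,
              well_id = well_id)
}

stack_filename <- function(plate, well_id, channel) {
  paste0(plate, "_", well_id, "_", channel, ".tif")
}

#' Simulate one well (truth + rendered stacks)
#'
#' @param well One layout row.
#' @param config A [screen_config()].
#' @return A list: `cysts` (ground truth, see [draw_well_cysts()]),
#'   `actin` and `nuclei` stacks.
#' @export
simulate_well <- function(well, config) {
  cysts <- draw_well_cysts(well, config)
  imgs <- render_well(well, cysts, config)
  c(list(cysts = cysts), imgs)
}

#' Simulate a whole screen
#'
#' Generates the plate layout, draws every well's ground-truth cyst
#' population and renders both channels, fully determined by the master
#' seed. Images are kept in memory, written to `outdir` as multi-page
#' TIFFs (`<plate>_<well>_<channel>.tif`) alongside the truth tables
#' (`truth_wells.csv`, `truth_cysts.csv`), or both.
#'
#' @param config A [screen_config()].
#' @param compounds A compound tibble ([compound_table()]).
#' @param outdir Output directory for images and truth tables, or `NULL`
#'   to keep everything in memory.
#' @param keep_images Keep the rendered stacks in the return value
#'   (default: only when not writing to disk).
#' @param plate Plate identifier.
#' @return A list of class `cyst_screen_sim`: `wells` (layout + cyst
#'   counts), `cysts` (all wells' ground truth), `stacks` (named list of
#'   per-well `list(actin, nuclei)`, or `NULL`), `config`, `outdir`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_screen(demo_screen_config(seed = 3), demo_compounds())
#' nrow(sim$wells)
#' }
simulate_screen <- function(config, compounds, outdir = NULL,
                            keep_images = is.null(outdir), plate = "P1") {
  layout <- plate_layout(config, compounds, plate = plate)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stacks <- if (keep_images) vector("list", nrow(layout)) else NULL
  cysts_all <- vector("list", nrow(layout))
  n_cysts <- integer(nrow(layout))

  for (i in seq_len(nrow(layout))) {
    well <- layout[i, ]
    sim <- tryCatch(simulate_well(well, config), error = function(e) {
      abort(paste0("simulation failed in well ", well$well_id, ": ",
                   conditionMessage(e)),
            class = "cystscreen_render_error", parent = e)
    })
    n_cysts[i] <- nrow(sim$cysts)
    cysts_all[[i]] <- sim$cysts %>%
      select(-"nuclei") %>%
      mutate(plate = well$plate, well_id = well$well_id, .before = 1)
    if (!is.null(outdir)) {
      write_image_stack(sim$actin,
                        file.path(outdir, stack_filename(plate, well$well_id, "actin")))
      write_image_stack(sim$nuclei,
                        file.path(outdir, stack_filename(plate, well$well_id, "nuclei")))
    }
    if (keep_images) {
      stacks[[i]] <- list(actin = sim$actin, nuclei = sim$nuclei)
    }
  }
  if (keep_images) names(stacks) <- layout$well_id

  wells <- mutate(layout, n_cysts = n_cysts)
  cysts <- bind_rows(cysts_all)
  if (!is.null(outdir)) {
    readr::write_csv(wells, file.path(outdir, "truth_wells.csv"))
    readr::write_csv(cysts, file.path(outdir, "truth_cysts.csv"))
  }
  structure(list(wells = wells, cysts = cysts, stacks = stacks,
                 config = config, outdir = outdir),
            class = "cyst_screen_sim")
}

#' @export
print.cyst_screen_sim <- function(x, ...) {
  cat(sprintf("<cyst_screen_sim> %d wells, %d cysts, seed %d%s\n",
              nrow(x$wells), nrow(x$cysts), x$config$seed,
              if (is.null(x$stacks)) " (images on disk)" else ""))
  invisible(x)
}

#' Simulate a two-compound combination experiment (well-level)
#'
#' Generates replicate well-level median cyst sizes for a dose x dose
#' grid under *exact Bliss independence*: the combined true effect of
#' doses `(a, b)` is `E_a + E_b - E_a * E_b` of the single-agent Hill
#' effects, and effects act linearly on median cyst area (see
#' [draw_well_cysts()]). Single-agent rows (dose 0 of the partner) and
#' unstimulated/stimulated control wells are included. This is the
#' well-level statistical layer of the generator: it samples per-well
#' median areas directly instead of rendering and re-segmenting images,
#' which is what a synergy analysis consumes.
#'
#' @param config A [screen_config()]; `swelling_factor`, the radius
#'   distribution, `cysts_per_well` and `seed` are used.
#' @param hill_a,hill_b Single-row compound tibbles ([compound_table()]).
#' @param doses_a_um,doses_b_um Dose vectors (uM), zero added
#'   automatically.
#' @param replicates Wells per dose pair.
#' @param n_controls Unstimulated and stimulated control wells.
#' @return A long tibble: `dose_a_um`, `dose_b_um`, `replicate`, `role`,
#'   `size` (median cyst area, px).
#' @export
simulate_combination <- function(config, hill_a, hill_b,
                                 doses_a_um, doses_b_um,
                                 replicates = 4L, n_controls = 8L) {
  set.seed(config$seed)
  grid <- crossing(dose_a_um = c(0, doses_a_um), dose_b_um = c(0, doses_b_um),
                   replicate = seq_len(replicates)) %>%
    filter(!(.data$dose_a_um == 0 & .data$dose_b_um == 0)) %>%
    mutate(role = "test")
  ctrls <- bind_rows(
    tibble(dose_a_um = 0, dose_b_um = 0, replicate = seq_len(n_controls),
           role = "unstimulated"),
    tibble(dose_a_um = 0, dose_b_um = 0, replicate = seq_len(n_controls),
           role = "stimulated")
  )
  wells <- bind_rows(ctrls, grid)

  e_a <- hill_effect(wells$dose_a_um, hill_a$ec50_um, hill_a$hill_slope,
                     hill_a$max_inhibition)
  e_b <- hill_effect(wells$dose_b_um, hill_b$ec50_um, hill_b$hill_slope,
                     hill_b$max_inhibition)
  eff <- e_a + e_b - e_a * e_b
  eff[wells$role == "unstimulated"] <- NA     # no forskolin: no swelling

  sizes <- vapply(seq_len(nrow(wells)), function(i) {
    n <- config$cysts_per_well[1] +
      sample.int(diff(config$cysts_per_well) + 1L, 1L) - 1L
    r <- pmax(rnorm(n, config$radius_mean_px, config$radius_sd_px),
              config$radius_min_px)
    growth <- if (is.na(eff[i])) 1 else {
      sqrt(pmax(1 + (config$swelling_factor^2 - 1) * (1 - eff[i]), 0.04))
    }
    median(pi * (r * growth)^2)
  }, numeric(1))

  mutate(wells, size = sizes)
}
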