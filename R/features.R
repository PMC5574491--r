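#' Per-object phenotypic descriptors
#'
#' Extends a [detect_cysts()] table with shape- and intensity-related
#' descriptors: circularity (`4 * pi * area / perimeter^2`, clamped to 1
#' for digital shapes and flagged missing when the perimeter is 0), the
#' wall-to-whole-cyst ratios, and intensity statistics of the object
#' mask evaluated on the actin maximum intensity projection.
#'
#' @param objects Tibble from [detect_cysts()].
#' @param projection Actin maximum intensity projection
#'   ([max_projection()]); intensity features are skipped when `NULL`.
#' @return The input tibble with added columns `circularity`,
#'   `wall_area_fraction`, `wall_to_size`, `intensity_mean`,
#'   `intensity_max` (the `pixels` list-column is dropped).
#' @export
compute_object_features <- function(objects, projection = NULL) {
  if (!nrow(objects)) {
    return(mutate(select(objects, -any_of("pixels")),
                  circularity = double(), wall_area_fraction = double(),
                  wall_to_size = double(), intensity_mean = double(),
                  intensity_max = double()))
  }
  circ <- ifelse(objects$perimeter_px > 0,
                 pmin(4 * pi * objects$area_px / objects$perimeter_px^2, 1),
                 NA_real_)
  wall_frac <- pmin(objects$wall_area_px / objects$area_px, 1)
  equiv_r <- sqrt(objects$area_px / pi)
  wall_to_size <- objects$wall_mean_thickness_px / equiv_r

  if (!is.null(projection)) {
    ints <- map(objects$pixels, ~ projection[.x])
    int_mean <- map_dbl(ints, mean)
    int_max <- map_dbl(ints, max)
  } else {
    int_mean <- int_max <- rep(NA_real_, nrow(objects))
  }

  objects %>%
    mutate(circularity = circ, wall_area_fraction = wall_frac,
           wall_to_size = wall_to_size,
           intensity_mean = int_mean, intensity_max = int_max) %>%
    select(-any_of("pixels"))
}

object_descriptors <- c("area_px", "perimeter_px", "circularity",
                        "wall_mean_thickness_px", "wall_area_fraction",
                        "wall_to_size", "intensity_mean", "intensity_max")

#' Aggregate per-object descriptors into one well record
#'
#' Per-well robust aggregates of every per-object descriptor: the median
#' and the MAD (scaled by 1.4826) of each, plus the mean cyst area
#' (retained alongside the median because per-well mean size is the
#' conventional reporting scale). Border-touching objects are excluded
#' by default since partial objects bias area. A well with zero objects
#' is retained — object and nuclei counts are phenotypes in their own
#' right (cytotoxicity) — with all aggregates missing.
#'
#' @param objects Feature tibble from [compute_object_features()].
#' @param nuclei_count Nuclei count of the well ([count_nuclei()]).
#' @param annotations Single-row tibble of well annotations (carried
#'   through unchanged), or `NULL`.
#' @param exclude_border Drop border-flagged objects before aggregating.
#' @return A single-row tibble: annotations, `object_count`,
#'   `nuclei_count`, then `<descriptor>_med`, `<descriptor>_mad` for each
#'   descriptor and `area_px_mean`.
#' @export
aggregate_well_features <- function(objects, nuclei_count = NA_integer_,
                                    annotations = NULL,
                                    exclude_border = TRUE) {
  if (exclude_border && nrow(objects)) {
    objects <- filter(objects, !.data$on_border)
  }
  descr <- intersect(object_descriptors, names(objects))
  aggs <- list(object_count = nrow(objects),
               nuclei_count = as.double(nuclei_count))
  for (d in descr) {
    v <- objects[[d]]
    v <- v[!is.na(v)]
    aggs[[paste0(d, "_med")]] <- if (length(v)) median(v) else NA_real_
    aggs[[paste0(d, "_mad")]] <- if (length(v)) mad(v) else NA_real_
  }
  v <- objects$area_px
  aggs$area_px_mean <- if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  rec <- as_tibble(aggs)
  if (!is.null(annotations)) rec <- bind_cols(annotations, rec)
  rec
}

#' Quantify every well of a simulated or on-disk screen
#'
#' Runs segmentation ([detect_cysts()]), nuclei counting
#' ([count_nuclei()]), per-object descriptors
#' ([compute_object_features()]) and well aggregation
#' ([aggregate_well_features()]) over all wells of a screen, producing
#' the wells x features table every downstream stage consumes.
#'
#' @param sim A `cyst_screen_sim` from [simulate_screen()] (with images
#'   in memory or on disk), or a directory containing
#'   `<plate>_<well>_<channel>.tif` stacks plus `truth_wells.csv`.
#' @param params A [seg_params()].
#' @param config A [screen_config()] (needed when `sim` is a directory).
#' @return A list: `features` (one row per well: annotations + counts +
#'   aggregates) and `objects` (all per-object descriptor rows).
#' @export
featurize_screen <- function(sim, params = seg_params(), config = NULL) {
  if (is.character(sim)) {
    dirpath <- sim
    wells_path <- file.path(dirpath, "truth_wells.csv")
    if (!file.exists(wells_path)) {
      abort(paste0("no truth_wells.csv in ", dirpath),
            class = "cystscreen_pipeline_error")
    }
    wells <- readr::read_csv(wells_path, show_col_types = FALSE)
    get_stacks <- function(i) {
      zint <- if (!is.null(config)) config$z_interval_um else 50
      a_path <- file.path(dirpath,
                          stack_filename(wells$plate[i], wells$well_id[i], "actin"))
      n_path <- file.path(dirpath,
                          stack_filename(wells$plate[i], wells$well_id[i], "nuclei"))
      for (p in c(a_path, n_path)) {
        if (!file.exists(p)) {
          abort(paste0("missing channel file: ", p),
                class = "cystscreen_pipeline_error")
        }
      }
      list(actin = read_image_stack(a_path, zint),
           nuclei = read_image_stack(n_path, zint))
    }
  } else {
    stopifnot(inherits(sim, "cyst_screen_sim"))
    wells <- sim$wells
    if (is.null(sim$stacks)) {
      return(featurize_screen(sim$outdir, params, config %||% sim$config))
    }
    get_stacks <- function(i) sim$stacks[[i]]
  }

  anno_cols <- intersect(
    c("well_index", "plate", "well_id", "row", "col", "role", "compound",
      "concentration_um", "stimulated", "replicate"), names(wells))

  feats <- vector("list", nrow(wells))
  objs <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    st <- get_stacks(i)
    objects <- detect_cysts(st$actin, params)
    objects$well_id <- wells$well_id[i]
    proj <- max_projection(st$actin)
    objects <- compute_object_features(objects, proj)
    nuc <- count_nuclei(st$nuclei, params)
    feats[[i]] <- aggregate_well_features(objects, nuc,
                                          wells[i, anno_cols, drop = FALSE])
    objs[[i]] <- mutate(objects, plate = wells$plate[i], .before = 1)
  }
  list(features = bind_rows(feats), objects = bind_rows(objs))
}

#' Names of the feature columns of a well table
#'
#' Every numeric column that is not a plate/layout annotation; includes
#' `object_count` and `nuclei_count`, which the screen uses as phenotypes.
#'
#' @param tbl A well-feature tibble.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(tbl) {
  anno <- c("well_index", "row", "col", "concentration_um", "replicate",
            "effect_raw", "true_effect", "n_cysts", "seed")
  num <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  setdiff(num, anno)
}
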