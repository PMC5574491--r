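pipeline_stages <- c("simulate", "featurize", "normalize", "hits", "profile")

#' Run the screening pipeline end to end
#'
#' Orchestrates simulate -> segment/featurize -> normalize (+ Z' QC) ->
#' hit calling -> phenotype profiling from one configuration, writing
#' every stage's tabular output as CSV under `outdir` and returning a
#' run manifest (config snapshot, seed, per-plate Z', stage timings,
#' output checksums). Stages can be selected individually; a stage whose
#' inputs are missing from `outdir` fails fast with the stage named, so
#' e.g. a `"normalize"`-only re-run on precomputed features reproduces
#' the downstream tables exactly.
#'
#' Two runs from the same configuration and seed produce byte-identical
#' tabular outputs.
#'
#' @param config A [screen_config()], or the path of a YAML file for
#'   [read_screen_config()].
#' @param compounds Compound tibble ([compound_table()]).
#' @param outdir Output directory (created if needed).
#' @param stages Subset of `simulate`, `featurize`, `normalize`,
#'   `hits`, `profile`, executed in pipeline order.
#' @param params Segmentation parameters ([seg_params()]).
#' @param size_feature Feature used for QC, hit calling and percent
#'   inhibition.
#' @return A `run_manifest` (invisibly written to
#'   `outdir/manifest.yaml`).
#' @export
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "demo-run")
#' mf <- run_pipeline(demo_screen_config(seed = 1), demo_compounds(), out)
#' mf$qc
#' }
run_pipeline <- function(config, compounds = demo_compounds(), outdir,
                         stages = pipeline_stages, params = seg_params(),
                         size_feature = "area_px_med") {
  if (is.character(config)) config <- read_screen_config(config)
  stopifnot(inherits(config, "screen_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "cystscreen_pipeline_error")
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(outdir, "images")

  paths <- list(
    wells = file.path(img_dir, "truth_wells.csv"),
    objects = file.path(outdir, "objects.csv"),
    features = file.path(outdir, "well_features.csv"),
    plate_z = file.path(outdir, "normalized_plate_z.csv"),
    control_z = file.path(outdir, "normalized_control_z.csv"),
    pct_inh = file.path(outdir, "normalized_percent_inhibition.csv"),
    qc = file.path(outdir, "qc.csv"),
    hits = file.path(outdir, "hits.csv"),
    selected = file.path(outdir, "selected_features.csv"),
    loadings = file.path(outdir, "loadings.csv"),
    scores = file.path(outdir, "scores.csv"),
    labels = file.path(outdir, "labels.csv")
  )
  need <- function(path, stage, what) {
    if (!file.exists(path)) {
      abort(paste0("stage '", stage, "': required input missing (", what,
                   " at ", path, ")"),
            class = "cystscreen_pipeline_error")
    }
    readr::read_csv(path, show_col_types = FALSE)
  }
  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      if (inherits(e, "cystscreen_pipeline_error")) stop(e)
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "cystscreen_pipeline_error", parent = e)
    })
    list(result = res,
         seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  timings <- list(); log <- list(); qc <- NULL

  if ("simulate" %in% stages) {
    st <- run_stage("simulate", function() {
      simulate_screen(config, compounds, outdir = img_dir,
                      keep_images = FALSE)
    })
    timings$simulate <- st$seconds
    log$wells_simulated <- nrow(st$result$wells)
  }

  if ("featurize" %in% stages) {
    st <- run_stage("featurize", function() {
      need(paths$wells, "featurize", "truth/layout table")
      fz <- featurize_screen(img_dir, params, config)
      readr::write_csv(select(fz$objects, -any_of("pixels")), paths$objects)
      readr::write_csv(fz$features, paths$features)
      fz
    })
    timings$featurize <- st$seconds
    log$objects_detected <- nrow(st$result$objects)
    log$wells_featurized <- nrow(st$result$features)
  }

  if ("normalize" %in% stages) {
    st <- run_stage("normalize", function() {
      feats <- need(paths$features, "normalize", "well features")
      for (role in c("unstimulated", "stimulated")) {
        if (sum(feats$role == role) < 2) {
          abort(paste0("stage 'normalize': fewer than 2 '", role,
                       "' control wells"),
                class = "cystscreen_pipeline_error")
        }
      }
      pz <- normalize_plate_median(feats)
      cz <- normalize_to_control(pz)
      pi_tbl <- normalize_percent_inhibition(feats, size_feature)
      qc_tbl <- zprime_controls(feats, feature = size_feature,
                                n = config$replicates)
      readr::write_csv(pz, paths$plate_z)
      readr::write_csv(cz, paths$control_z)
      readr::write_csv(pi_tbl, paths$pct_inh)
      readr::write_csv(qc_tbl, paths$qc)
      qc_tbl
    })
    timings$normalize <- st$seconds
    qc <- st$result
  }

  if ("hits" %in% stages) {
    st <- run_stage("hits", function() {
      cz <- need(paths$control_z, "hits", "control-z table")
      hits <- call_hits(cz, size_feature = size_feature)
      readr::write_csv(hits, paths$hits)
      hits
    })
    timings$hits <- st$seconds
    log$hits_called <- sum(st$result$hit[!duplicated(st$result$compound)])
  }

  if ("profile" %in% stages) {
    st <- run_stage("profile", function() {
      cz <- need(paths$control_z, "profile", "control-z table")
      group_b <- if (any(cz$role == "reference_inhibitor")) {
        "reference_inhibitor"
      } else {
        inform("no reference-inhibitor wells; gating features against unstimulated controls")
        "unstimulated"
      }
      sel <- rank_features_by_zprime(cz, group_a = "stimulated",
                                     group_b = group_b,
                                     n = config$replicates)
      if (nrow(sel) < 3) {
        abort("stage 'profile': fewer than 3 features pass the Z' gate",
              class = "cystscreen_pipeline_error")
      }
      space <- fit_phenotype_space(cz, sel$feature)
      scores <- project_phenotypes(space, cz)
      raw_feats <- need(paths$features, "profile", "raw well features")
      labels <- classify_phenotypes(scores, space,
                                    nuclei_counts = raw_feats)
      readr::write_csv(sel, paths$selected)
      readr::write_csv(tidy(space), paths$loadings)
      readr::write_csv(scores, paths$scores)
      readr::write_csv(labels, paths$labels)
      list(sel = sel, space = space, labels = labels)
    })
    timings$profile <- st$seconds
    log$features_selected <- nrow(st$result$sel)
  }

  outputs <- keep(paths, file.exists)
  manifest <- structure(list(
    config = unclass(config),
    compounds = compounds,
    seed = config$seed,
    version = as.character(packageVersion("cystscreen")),
    stages = stages,
    qc = qc,
    log = log,
    timings = timings,
    outputs = map(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  ), class = "run_manifest")

  yaml::write_yaml(manifest_to_yaml(manifest), file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

manifest_to_yaml <- function(m) {
  out <- unclass(m)
  out$compounds <- as.list(as.data.frame(m$compounds))
  if (!is.null(m$qc)) out$qc <- as.list(as.data.frame(m$qc))
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, stages: %s\n", x$seed,
              paste(x$stages, collapse = " -> ")))
  if (!is.null(x$qc)) {
    cat(sprintf("  Z' (%s): %s\n", x$qc$feature[1],
                paste(sprintf("%s = %.2f", x$qc$plate, x$qc$zprime),
                      collapse = ", ")))
  }
  for (nm in names(x$log)) cat(sprintf("  %s: %s\n", nm, x$log[[nm]]))
  invisible(x)
}
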