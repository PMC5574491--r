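#' Rank features by between-control Z'-factor
#'
#' Feature selection gate for phenotypic profiling: for every feature,
#' the replicate-adjusted [zprime()] between two control-well groups is
#' computed (max/min roles assigned by group means) and features
#' separating the groups better than the cutoff (`Z' > cutoff`, default
#' -1.0) are retained, ranked by descending Z' with alphabetical
#' tie-breaking. Features constant in both groups, or with equal group
#' means, carry no separation signal and are excluded (recorded in the
#' `excluded` attribute).
#'
#' @param tbl Normalized well-feature tibble.
#' @param group_a,group_b Control roles to separate; defaults compare
#'   the forskolin-stimulated controls against reference-inhibitor
#'   (fully rescued) wells.
#' @param cutoff Retain features with `Z' > cutoff`.
#' @param features Candidate feature columns ([feature_columns()] by
#'   default).
#' @param n Technical-replicate count used in the Z' adjustment: the
#'   screen's per-condition replicate number (e.g. 4 for quadruplicate
#'   test wells), which is usually smaller than the control group sizes.
#'   Defaults to the smaller group size.
#' @return A tibble `feature`, `zprime`, `rank` of the selected
#'   features, best separator first; attribute `excluded` names the
#'   degenerate ones.
#' @export
rank_features_by_zprime <- function(tbl, group_a = "stimulated",
                                    group_b = "reference_inhibitor",
                                    cutoff = -1, features = NULL,
                                    n = NULL) {
  features <- features %||% feature_columns(tbl)
  a <- filter(tbl, .data$role == group_a)
  b <- filter(tbl, .data$role == group_b)
  if (nrow(a) < 2 || nrow(b) < 2) {
    abort(paste0("need >= 2 wells in each control group ('", group_a,
                 "', '", group_b, "')"),
          class = "cystscreen_profile_error")
  }
  rows <- list(); excluded <- character()
  for (f in features) {
    va <- a[[f]][!is.na(a[[f]])]; vb <- b[[f]][!is.na(b[[f]])]
    if (length(va) < 2 || length(vb) < 2 || mean(va) == mean(vb)) {
      excluded <- c(excluded, f); next
    }
    hi <- if (mean(va) >= mean(vb)) va else vb
    lo <- if (mean(va) >= mean(vb)) vb else va
    z <- zprime(mean(hi), sd(hi), mean(lo), sd(lo),
                n = n %||% min(length(va), length(vb)))
    rows[[f]] <- tibble(feature = f, zprime = z)
  }
  out <- bind_rows(rows)
  if (nrow(out)) {
    out <- out %>%
      filter(.data$zprime > cutoff) %>%
      arrange(dplyr::desc(.data$zprime), .data$feature) %>%
      mutate(rank = row_number())
  } else {
    out <- tibble(feature = character(), zprime = double(), rank = integer())
  }
  if (length(excluded)) {
    inform(paste0("excluded degenerate feature(s): ",
                  paste(excluded, collapse = ", ")))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Fit the 3-component PCA phenotype space
#'
#' Standardizes the selected features (centre + unit scale; they mix
#' pixel areas, ratios and counts) and decomposes them into principal
#' components named PC0, PC1, PC2. Loadings are made sign-deterministic
#' by forcing the largest-magnitude loading of each component positive.
#' Reference centroids (and a pooled, lightly regularized covariance of
#' control scores, used for Mahalanobis classification) are stored for
#' the unstimulated and stimulated control wells.
#'
#' @param tbl Normalized well-feature tibble (the fit set; all wells of
#'   the run by default usage).
#' @param features Feature columns to use, e.g.
#'   `rank_features_by_zprime(...)$feature`.
#' @param n_components Number of components retained (default 3).
#' @return An object of class `phenotype_space`: selected features,
#'   centring/scaling constants, loadings, per-component explained
#'   variance fractions, control centroids and score covariance.
#' @export
fit_phenotype_space <- function(tbl, features, n_components = 3L) {
  features <- unique(features)
  if (length(features) < n_components) {
    abort("fewer features than requested components",
          class = "cystscreen_profile_error")
  }
  complete <- stats::complete.cases(tbl[, features])
  fit_tbl <- tbl[complete, ]
  if (nrow(fit_tbl) < n_components + 1L) {
    abort("need at least n_components + 1 complete wells",
          class = "cystscreen_profile_error")
  }
  x <- as.matrix(fit_tbl[, features])
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl <= 0 | !is.finite(scl))) {
    drop <- features[scl <= 0 | !is.finite(scl)]
    abort(paste0("constant feature(s) cannot be standardized: ",
                 paste(drop, collapse = ", ")),
          class = "cystscreen_profile_error")
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)

  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                    # sign convention
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  colnames(load) <- paste0("PC", seq_len(k) - 1L)
  ev <- pc$sdev^2
  ev_frac <- ev[seq_len(k)] / sum(ev)

  scores <- xs %*% load
  centroids <- list()
  ctrl_resid <- NULL
  for (role in c("unstimulated", "stimulated")) {
    sel <- fit_tbl$role == role
    if (any(sel)) {
      centroids[[role]] <- colMeans(scores[sel, , drop = FALSE])
      ctrl_resid <- rbind(ctrl_resid,
                          sweep(scores[sel, , drop = FALSE], 2,
                                centroids[[role]]))
    }
  }
  control_cov <- if (!is.null(ctrl_resid) && nrow(ctrl_resid) > k) {
    cov(ctrl_resid) + diag(1e-8, k)
  } else {
    diag(1, k)
  }

  structure(list(features = features, center = ctr, scale = scl,
                 loadings = load, explained_variance_fraction = ev_frac,
                 centroids = centroids, control_cov = control_cov,
                 n_components = k, n_wells = nrow(fit_tbl)),
            class = "phenotype_space")
}

#' @export
print.phenotype_space <- function(x, ...) {
  cat(sprintf("<phenotype_space> %d features -> %d components (%s of variance)\n",
              length(x$features), x$n_components,
              paste0(round(100 * x$explained_variance_fraction, 1), "%",
                     collapse = " + ")))
  invisible(x)
}

#' @describeIn fit_phenotype_space Loadings in long form (`component`,
#'   `feature`, `loading`).
#' @param x,object A `phenotype_space`.
#' @param ... Unused.
#' @export
tidy.phenotype_space <- function(x, ...) {
  as_tibble(x$loadings, rownames = "feature") %>%
    pivot_longer(-"feature", names_to = "component", values_to = "loading") %>%
    arrange(.data$component, .data$feature)
}

#' @describeIn fit_phenotype_space One-row model summary (feature and
#'   well counts, per-component and cumulative explained variance).
#' @export
glance.phenotype_space <- function(x, ...) {
  ev <- x$explained_variance_fraction
  out <- tibble(n_features = length(x$features), n_wells = x$n_wells)
  for (j in seq_along(ev)) out[[paste0("var_pc", j - 1L)]] <- ev[j]
  out$var_total <- sum(ev)
  out
}

#' Project wells into a phenotype space
#'
#' Standardizes the selected features with the constants stored at fit
#' time and applies the loadings. Wells missing any selected feature are
#' flagged (`projected = FALSE`) with `NA` scores rather than dropped.
#'
#' @param space A [fit_phenotype_space()] object.
#' @param tbl Well-feature tibble on the same normalization as the fit
#'   set.
#' @return The annotation columns of `tbl` plus `PC0`, `PC1`, `PC2`
#'   (... per component) and `projected`.
#' @export
project_phenotypes <- function(space, tbl) {
  miss <- setdiff(space$features, names(tbl))
  if (length(miss)) {
    abort(paste0("table lacks selected feature(s): ",
                 paste(miss, collapse = ", ")),
          class = "cystscreen_profile_error")
  }
  keep <- setdiff(names(tbl), setdiff(feature_columns(tbl),
                                      c("nuclei_count", "object_count")))
  out <- tbl[, keep, drop = FALSE]
  x <- as.matrix(tbl[, space$features])
  ok <- stats::complete.cases(x)
  scores <- matrix(NA_real_, nrow(tbl), space$n_components,
                   dimnames = list(NULL, colnames(space$loadings)))
  if (any(ok)) {
    xs <- sweep(sweep(x[ok, , drop = FALSE], 2, space$center), 2,
                space$scale, "/")
    scores[ok, ] <- xs %*% space$loadings
  }
  bind_cols(out, as_tibble(scores)) %>% mutate(projected = ok)
}

#' Classify compound phenotypes in PC space
#'
#' Labels every compound-dose by where its replicate-mean PC scores sit
#' relative to the control centroids: `restored` within a Mahalanobis
#' radius of the unstimulated centroid, `unchanged` within radius of the
#' stimulated centroid (the nearer centroid wins when inside both), and
#' `novel` outside both — or whenever the replicate-mean nuclei count
#' falls below a configured fraction of the unstimulated-control median,
#' the low-cell-count signature of cytotoxic "novel phenotype" wells
#' regardless of where their size features project.
#'
#' @param scores Projection tibble from [project_phenotypes()], carrying
#'   `role`, `compound`, `concentration_um` and `nuclei_count`.
#' @param space The [fit_phenotype_space()] used for the projection.
#' @param nuclei_counts Optional tibble of *raw* per-well nuclei counts
#'   (`well_id`, `nuclei_count`), used for the low-cell-count rule. When
#'   `scores` comes from a normalized table its `nuclei_count` column is
#'   on the z scale, where a fraction-of-median cutoff is meaningless —
#'   always pass the raw counts in that case.
#' @param mahalanobis_radius Radius (in pooled single-well control-score
#'   units) around each centroid. The default (8) absorbs the centroid
#'   and covariance estimation error of small control groups and the
#'   mild overshoot of strong actives, while cytotoxic novel phenotypes
#'   sit far outside it; tighten it on screens with many control wells.
#' @param nuclei_fraction Novel-phenotype cutoff on the nuclei count, as
#'   a fraction of the unstimulated-control median.
#' @return A tibble with one row per compound-dose: mean scores,
#'   distances to both centroids, mean nuclei count, `n_wells`, and
#'   `label` in `restored`/`unchanged`/`novel` (`NA` when unevaluable).
#' @export
classify_phenotypes <- function(scores, space, nuclei_counts = NULL,
                                mahalanobis_radius = 8,
                                nuclei_fraction = 0.5) {
  if (!is.null(nuclei_counts)) {
    scores <- scores %>%
      select(-any_of("nuclei_count")) %>%
      left_join(select(nuclei_counts, "well_id", "nuclei_count"),
                by = "well_id")
  }
  pc_cols <- colnames(space$loadings)
  if (!all(c("unstimulated", "stimulated") %in% names(space$centroids))) {
    abort("phenotype space lacks both control centroids",
          class = "cystscreen_profile_error")
  }
  unstim_nuc <- median(scores$nuclei_count[scores$role == "unstimulated"],
                       na.rm = TRUE)
  test <- filter(scores, .data$role == "test", .data$projected)
  if (!nrow(test)) {
    abort("no projected test wells to classify",
          class = "cystscreen_profile_error")
  }
  grp <- test %>%
    group_by(.data$compound, .data$concentration_um) %>%
    summarise(across(all_of(pc_cols), mean),
              mean_nuclei = mean(.data$nuclei_count, na.rm = TRUE),
              n_wells = n(), .groups = "drop")

  m <- as.matrix(grp[, pc_cols])
  d_u <- sqrt(stats::mahalanobis(m, space$centroids$unstimulated,
                                 space$control_cov))
  d_s <- sqrt(stats::mahalanobis(m, space$centroids$stimulated,
                                 space$control_cov))
  low_nuclei <- !is.na(grp$mean_nuclei) & is.finite(unstim_nuc) &
    grp$mean_nuclei < nuclei_fraction * unstim_nuc

  label <- case_when(
    low_nuclei ~ "novel",
    d_u <= mahalanobis_radius & d_u <= d_s ~ "restored",
    d_s <= mahalanobis_radius ~ "unchanged",
    d_u <= mahalanobis_radius ~ "restored",
    TRUE ~ "novel"
  )
  mutate(grp, dist_unstimulated = d_u, dist_stimulated = d_s,
         low_nuclei = low_nuclei, label = label)
}
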