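# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

no_nuclei <- function() matrix(numeric(0), ncol = 3)

# One fully specified cyst row, bypassing the random generator.
cyst_row <- function(id = 1L, cx = 64, cy = 64, cz = 1, r = 20, wall = 3,
                     wall_int = 20000, lumen_int = 3000, integrity = 1,
                     gap1 = 0, gap2 = pi, nuclei = no_nuclei()) {
  tibble::tibble(cyst = id, cx = cx, cy = cy, cz = cz, radius_px = r,
                 wall_thickness_px = wall, wall_intensity = wall_int,
                 lumen_intensity = lumen_int, n_nuclei = nrow(nuclei),
                 integrity = integrity, gap_start1 = gap1, gap_start2 = gap2,
                 true_area_px = pi * r^2, nuclei = list(nuclei))
}

# Minimal noise-free configuration for hand-built scenes.
scene_config <- function(n_planes = 5L, image_size = c(128L, 128L), ...) {
  screen_config(noise_sd = 0, n_planes = n_planes, image_size = image_size,
                cysts_per_well = c(1L, 1L), plate_shape = c(4L, 8L),
                controls = list(unstimulated = 4L, stimulated = 4L), ...)
}

# A layout row to hang hand-built scenes on.
scene_well <- function(config) plate_layout(config, demo_compounds())[1, ]

render_scene <- function(cysts, config = scene_config()) {
  render_well(scene_well(config), cysts, config)
}

# Well-feature table fixture at the statistical level (no images):
# unstimulated wells small, stimulated (and inert test) wells swollen.
feature_table_fixture <- function(seed = 1, n_ctrl = 8, n_test = 8,
                                  unstim_mean = 100, stim_mean = 256,
                                  sd = 10) {
  set.seed(seed)
  roles <- c(rep("unstimulated", n_ctrl), rep("stimulated", n_ctrl),
             rep("test", n_test))
  tibble::tibble(
    plate = "P1",
    well_id = sprintf("%s%02d", rep(LETTERS[1:4], length.out = length(roles)),
                      seq_along(roles)),
    role = roles,
    compound = ifelse(roles == "test", "cmpd-1", "ctrl"),
    concentration_um = ifelse(roles == "test", 1, 0),
    area_px_med = rnorm(length(roles),
                        ifelse(roles == "unstimulated", unstim_mean, stim_mean),
                        sd),
    wall_px = rnorm(length(roles), 5, 0.5),
    nuclei_count = round(rnorm(length(roles), 60, 5))
  )
}

# Control-group table for the feature-selection gate: 3 informative
# features (separated means) + 5 pure-noise features (shared
# distribution), 16 wells per control group, quadruplicate screen.
selection_fixture <- function(seed, n_per_group = 16) {
  set.seed(seed)
  roles <- rep(c("stimulated", "reference_inhibitor"), each = n_per_group)
  tbl <- tibble::tibble(plate = "P1",
                        well_id = sprintf("A%02d", seq_along(roles)),
                        role = roles)
  for (f in c("size_a", "size_b", "wall_c")) {
    tbl[[f]] <- ifelse(roles == "stimulated", 3, 0) +
      rnorm(length(roles), 0, 0.5)
  }
  for (f in paste0("noise_", 1:5)) tbl[[f]] <- rnorm(length(roles))
  tbl
}

informative_features <- c("size_a", "size_b", "wall_c")
candidate_features <- c(informative_features, paste0("noise_", 1:5))

# Run the demo screen end to end in memory; returns the pieces the
# screen-level tests look at.
run_mini_screen <- function(seed) {
  cfg <- demo_screen_config(seed = seed)
  sim <- simulate_screen(cfg, demo_compounds())
  fz <- featurize_screen(sim)
  cz <- normalize_to_control(normalize_plate_median(fz$features))
  hits <- call_hits(cz)
  sel <- suppressMessages(rank_features_by_zprime(cz, group_b = "unstimulated",
                                                  n = cfg$replicates))
  space <- fit_phenotype_space(cz, sel$feature)
  scores <- project_phenotypes(space, cz)
  labels <- classify_phenotypes(scores, space, nuclei_counts = fz$features)
  list(config = cfg, sim = sim, features = fz$features, cz = cz,
       hits = hits, selected = sel, space = space, labels = labels)
}

label_of <- function(labels, compound, dose) {
  labels$label[labels$compound == compound &
                 labels$concentration_um == dose]
}
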