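test_that("the Z' gate excludes degenerate features and ranks separators first", {
  tbl <- selection_fixture(seed = 1)
  tbl$same <- 1                       # identical in both groups
  tbl$perfect <- ifelse(tbl$role == "stimulated", 10, 0) +
    rnorm(nrow(tbl), 0, 0.01)         # near-perfect separator
  sel <- suppressMessages(rank_features_by_zprime(
    tbl, features = c(candidate_features, "same", "perfect"), n = 4))
  expect_false("same" %in% sel$feature)
  expect_true("same" %in% attr(sel, "excluded"))
  expect_equal(sel$feature[1], "perfect")
  expect_gt(sel$zprime[1], 0.9)
})

test_that("raising the cutoff never adds a feature", {
  tbl <- selection_fixture(seed = 7)
  sels <- lapply(c(-2, -1, 0, 0.5), function(ct) {
    suppressMessages(rank_features_by_zprime(tbl, cutoff = ct,
                                             features = candidate_features,
                                             n = 4))$feature
  })
  for (i in seq_len(length(sels) - 1)) {
    expect_true(all(sels[[i + 1]] %in% sels[[i]]))
  }
})

test_that("ties in Z' break alphabetically and errors name the groups", {
  tbl <- selection_fixture(seed = 2)
  tbl$zeta <- tbl$size_a              # exact duplicate, tie on Z'
  sel <- suppressMessages(rank_features_by_zprime(
    tbl, features = c("zeta", "size_a"), n = 4))
  expect_equal(sel$feature, c("size_a", "zeta"))
  expect_error(rank_features_by_zprime(tbl[tbl$role == "stimulated", ]),
               class = "cystscreen_profile_error")
})

test_that("PCA space is deterministic, sign-fixed and rank-aware", {
  set.seed(31)
  n <- 60
  base <- tibble::tibble(
    plate = "P1", well_id = sprintf("A%02d", 1:n),
    role = sample(c("unstimulated", "stimulated"), n, TRUE),
    u = rnorm(n), v = rnorm(n))
  # data confined to a 2-D affine subspace of 3 features
  tbl <- dplyr::mutate(base, f1 = u, f2 = v, f3 = u + v + 1)
  sp <- fit_phenotype_space(tbl, c("f1", "f2", "f3"))
  expect_equal(sum(sp$explained_variance_fraction[1:2]), 1, tolerance = 1e-10)
  expect_lt(sp$explained_variance_fraction[3], 1e-10)
  # orthonormal loadings
  expect_equal(crossprod(sp$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive
  for (j in 1:3) expect_gt(sp$loadings[which.max(abs(sp$loadings[, j])), j], 0)
  # duplicating every well changes nothing
  sp2 <- fit_phenotype_space(dplyr::bind_rows(tbl, tbl), c("f1", "f2", "f3"))
  expect_equal(sp$loadings, sp2$loadings, tolerance = 1e-8)
  expect_equal(sp$explained_variance_fraction,
               sp2$explained_variance_fraction, tolerance = 1e-8)
  expect_error(fit_phenotype_space(tbl, c("f1", "f2")),
               class = "cystscreen_profile_error")
})

test_that("isotropic data spreads variance evenly across components", {
  set.seed(55)
  n <- 3000
  tbl <- tibble::tibble(plate = "P1", well_id = as.character(1:n),
                        role = "test", a = rnorm(n), b = rnorm(n),
                        c = rnorm(n))
  sp <- fit_phenotype_space(tbl, c("a", "b", "c"))
  expect_equal(unname(sp$explained_variance_fraction), rep(1 / 3, 3),
               tolerance = 0.05)
})

test_that("projection centres the fit set and reproduces explained variance", {
  tbl <- selection_fixture(seed = 9)
  sp <- fit_phenotype_space(tbl, informative_features)
  sc <- project_phenotypes(sp, tbl)
  expect_equal(colMeans(as.matrix(sc[, c("PC0", "PC1", "PC2")])), c(0, 0, 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  # score variances recover the explained fractions
  v <- apply(as.matrix(sc[, c("PC0", "PC1", "PC2")]), 2, var)
  expect_equal(unname(v / (sum(v) / sum(sp$explained_variance_fraction))),
               unname(sp$explained_variance_fraction), tolerance = 1e-8)
  # affine rescaling of the inputs yields identical scores after refit
  tbl2 <- tbl
  for (f in informative_features) tbl2[[f]] <- 3 * tbl2[[f]] - 11
  sp2 <- fit_phenotype_space(tbl2, informative_features)
  sc2 <- project_phenotypes(sp2, tbl2)
  expect_equal(sc$PC0, sc2$PC0, tolerance = 1e-8)
  # wells missing a selected feature are flagged, not dropped
  tbl3 <- tbl; tbl3$size_a[1] <- NA
  sc3 <- project_phenotypes(sp, tbl3)
  expect_false(sc3$projected[1])
  expect_true(is.na(sc3$PC0[1]))
  expect_error(project_phenotypes(sp, dplyr::select(tbl, -size_a)),
               class = "cystscreen_profile_error")
})

test_that("phenotype classification recovers the three archetypes", {
  set.seed(77)
  n <- 12
  mk <- function(role, compound, dose, centre, nuc) {
    tibble::tibble(plate = "P1",
                   well_id = paste0(compound, dose, seq_len(n)),
                   role = role, compound = compound, concentration_um = dose,
                   f1 = rnorm(n, centre[1], 0.3),
                   f2 = rnorm(n, centre[2], 0.3),
                   f3 = rnorm(n, centre[3], 0.3),
                   nuclei_count = round(rnorm(n, nuc, 3)))
  }
  tbl <- dplyr::bind_rows(
    mk("unstimulated", "DMSO", 0, c(0, 0, 0), 60),
    mk("stimulated", "forskolin", 0, c(5, 0, 0), 60),
    mk("test", "rescuer", 1, c(0, 0, 0), 60),       # restored
    mk("test", "dud", 1, c(5, 0, 0), 60),           # unchanged
    mk("test", "weird", 1, c(2.5, 6, 0), 60),       # off-axis novel
    mk("test", "poison", 1, c(0.3, 0, 0), 12))      # low-nuclei novel
  sp <- fit_phenotype_space(tbl, c("f1", "f2", "f3"))
  sc <- project_phenotypes(sp, tbl)
  labs <- classify_phenotypes(sc, sp, nuclei_counts = tbl)
  expect_equal(label_of(labs, "rescuer", 1), "restored")
  expect_equal(label_of(labs, "dud", 1), "unchanged")
  expect_equal(label_of(labs, "weird", 1), "novel")
  expect_equal(label_of(labs, "poison", 1), "novel")
  expect_true(labs$low_nuclei[labs$compound == "poison"])
})

test_that("tidy and glance expose loadings and explained variance", {
  tbl <- selection_fixture(seed = 10)
  sp <- fit_phenotype_space(tbl, informative_features)
  td <- tidy(sp)
  expect_equal(nrow(td), 9)
  expect_setequal(unique(td$component), c("PC0", "PC1", "PC2"))
  gl <- glance(sp)
  expect_equal(gl$n_features, 3)
  expect_equal(gl$var_total,
               sum(sp$explained_variance_fraction), tolerance = 1e-12)
})
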