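test_that("plate-median z-scoring centres, scales and flags constants", {
  tbl <- tibble::tibble(plate = "P1", well_id = sprintf("A%02d", 1:5),
                        role = "test", f = c(1, 2, 3, 4, 5),
                        const = rep(7, 5))
  out <- normalize_plate_median(tbl, c("f", "const"))
  expect_equal(out$f[3], 0)                       # median maps to 0
  expect_true(all(is.na(out$const)))              # zero spread flagged
  expect_equal(attr(out, "normalization"), "plate_z")

  out_sd <- normalize_plate_median(tbl, "f", scale = "sd")
  expect_equal(sum(out_sd$f), 0, tolerance = 1e-12)
  expect_equal(sd(out_sd$f), 1, tolerance = 1e-12)

  single <- tibble::tibble(plate = "P9", well_id = "A01", f = 1)
  expect_error(normalize_plate_median(single, "f"),
               class = "cystscreen_normalize_error")
})

test_that("control z-scoring anchors the unstimulated median at zero", {
  tbl <- feature_table_fixture(seed = 2)
  cz <- normalize_to_control(tbl, c("area_px_med", "wall_px"))
  for (f in c("area_px_med", "wall_px")) {
    expect_equal(median(cz[[f]][cz$role == "unstimulated"]), 0,
                 tolerance = 1e-12)
  }
  # stimulated wells sit above zero for size on a swelling fixture
  expect_gt(median(cz$area_px_med[cz$role == "stimulated"]), 0)
  # a well exactly at the control median scores 0
  anchor <- median(tbl$area_px_med[tbl$role == "unstimulated"])
  tbl2 <- dplyr::bind_rows(tbl, tibble::tibble(
    plate = "P1", well_id = "Z99", role = "test", compound = "x",
    concentration_um = 1, area_px_med = anchor, wall_px = 5,
    nuclei_count = 60))
  cz2 <- normalize_to_control(tbl2, "area_px_med")
  expect_equal(cz2$area_px_med[cz2$well_id == "Z99"], 0, tolerance = 1e-12)
  # re-centering on the same controls leaves their median at 0
  cz3 <- normalize_to_control(cz, c("area_px_med", "wall_px"))
  expect_equal(median(cz3$area_px_med[cz3$role == "unstimulated"]), 0,
               tolerance = 1e-12)

  no_ctrl <- dplyr::filter(tbl, role != "unstimulated")
  expect_error(normalize_to_control(no_ctrl, "area_px_med"),
               class = "cystscreen_normalize_error")
})

test_that("percent inhibition is the anchored linear map, unclamped", {
  expect_equal(percent_inhibition(200, 100, 200), 0)
  expect_equal(percent_inhibition(100, 100, 200), 100)
  expect_equal(percent_inhibition(150, 100, 200), 50)
  expect_equal(percent_inhibition(50, 100, 200), 150)   # over-inhibition kept
  expect_error(percent_inhibition(1, 5, 5),
               class = "cystscreen_normalize_error")
  # inverse map is the identity on the anchor interval
  x <- seq(100, 200, by = 10)
  p <- percent_inhibition(x, 100, 200)
  expect_equal(200 + p / 100 * (100 - 200), x, tolerance = 1e-12)
})

test_that("table-level percent inhibition hits both anchors exactly", {
  tbl <- feature_table_fixture(seed = 3)
  out <- normalize_percent_inhibition(tbl, "area_px_med")
  expect_equal(median(out$area_px_med[out$role == "stimulated"]), 0,
               tolerance = 1e-12)
  expect_equal(median(out$area_px_med[out$role == "unstimulated"]), 100,
               tolerance = 1e-12)
})

test_that("the replicate-adjusted Z' evaluates eq-form cases exactly", {
  expect_equal(zprime(100, 10, 0, 10, n = 4), 0.70, tolerance = 1e-12)
  expect_equal(zprime(100, 10, 0, 10, n = 1), 0.40, tolerance = 1e-12)
  # perfect separation for any replicate count
  for (n in c(1, 2, 4, 16)) expect_equal(zprime(50, 0, 10, 0, n = n), 1)
  expect_error(zprime(5, 1, 5, 1), class = "cystscreen_zprime_error")
  expect_error(zprime(1, -1, 0, 1), class = "cystscreen_zprime_error")
  expect_error(zprime(1, 1, 0, 1, n = 0), class = "cystscreen_zprime_error")
})

test_that("Z' is monotone in noise and replicates, invariant to affine rescaling", {
  sds <- seq(0, 30, by = 5)
  z_sd <- vapply(sds, function(s) zprime(100, s, 0, 10, n = 4), numeric(1))
  expect_true(all(diff(z_sd) < 0))
  z_n <- vapply(c(1, 2, 4, 8, 16), function(n) zprime(100, 15, 0, 15, n = n),
                numeric(1))
  expect_true(all(diff(z_n) > 0))
  base <- zprime(100, 15, 20, 10, n = 4)
  for (a in c(-3, 0.5, 10)) {
    for (b in c(-50, 0, 7)) {
      # max/min roles follow the group means, as in zprime_controls()
      hi <- a * 100 + b; lo <- a * 20 + b
      s_hi <- abs(a) * 15; s_lo <- abs(a) * 10
      scaled <- if (hi >= lo) zprime(hi, s_hi, lo, s_lo, n = 4) else
        zprime(lo, s_lo, hi, s_hi, n = 4)
      expect_equal(scaled, base, tolerance = 1e-12)
    }
  }
})

test_that("per-plate control Z' assigns max/min by group means", {
  tbl <- feature_table_fixture(seed = 4)
  qc <- zprime_controls(tbl, "area_px_med", n = 4)
  # flipping which role swells leaves the statistic unchanged
  flipped <- tbl
  flipped$role[tbl$role == "stimulated"] <- "unstimulated"
  flipped$role[tbl$role == "unstimulated"] <- "stimulated"
  qc2 <- zprime_controls(flipped, "area_px_med", n = 4)
  expect_equal(qc$zprime, qc2$zprime, tolerance = 1e-12)
})

test_that("hit calling follows the either-dose rule on replicate means", {
  mk <- function(compound, dose, z) tibble::tibble(
    plate = "P1", role = "test", compound = compound,
    concentration_um = dose, area_px_med = z)
  tbl <- dplyr::bind_rows(
    mk("a", 0.1, c(-0.6, -0.5, -0.4, -0.5)),   # hit at low dose
    mk("a", 1, c(3.1, 2.9, 3.0, 3.2)),
    mk("b", 0.1, c(0.2, 0.1, 0.05, 0.05)),     # above threshold at both
    mk("b", 1, c(0.3, 0.2, 0.1, 0.2)),
    mk("c", 0.1, c(NA, NA, NA, NA)),           # unevaluable
    mk("c", 1, c(NA, -0.1, NA, NA))
  )
  hits <- call_hits(tbl, "area_px_med")
  expect_true(all(hits$hit[hits$compound == "a"]))
  expect_false(any(hits$hit[hits$compound == "b"]))
  expect_false(any(hits$hit[hits$compound == "c"]))
  expect_false(any(hits$evaluable[hits$compound == "c"]))

  # row order cannot change the result
  shuffled <- tbl[sample.int(nrow(tbl)), ]
  expect_equal(call_hits(tbl, "area_px_med"),
               call_hits(shuffled, "area_px_med"))
  expect_error(call_hits(dplyr::filter(tbl, compound == "none")),
               class = "cystscreen_hits_error")
})
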