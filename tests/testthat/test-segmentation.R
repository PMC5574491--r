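test_that("segment_plane finds disjoint cysts as filled, hole-free masks", {
  cfg <- scene_config(n_planes = 1L, image_size = c(256L, 256L))
  cysts <- dplyr::bind_rows(cyst_row(1L, cx = 60, cy = 60, cz = 1, r = 18),
                            cyst_row(2L, cx = 180, cy = 70, cz = 1, r = 12),
                            cyst_row(3L, cx = 110, cy = 190, cz = 1, r = 24))
  plane <- render_scene(cysts, cfg)$actin$planes[, , 1]
  obj <- segment_plane(plane, seg_params())
  expect_equal(nrow(obj), 3)
  # each mask is filled: area close to the full disc, not just the ring
  got <- obj$area_px[order(obj$area_px)]
  want <- sort(pi * c(12, 18, 24)^2)
  expect_true(all(abs(got - want) / want < 0.05))
})

test_that("constant planes yield no objects rather than an error", {
  expect_equal(nrow(segment_plane(matrix(400, 64, 64), seg_params())), 0)
  expect_equal(nrow(segment_plane(matrix(0, 64, 64), seg_params())), 0)
})

test_that("histogram thresholding is invariant to intensity rescaling", {
  cfg <- scene_config(n_planes = 1L)
  plane <- render_scene(cyst_row(cz = 1, r = 16), cfg)$actin$planes[, , 1]
  base <- segment_plane(plane, seg_params())
  for (k in c(0.5, 2)) {
    scaled <- segment_plane(plane * k, seg_params())
    expect_identical(scaled$pixels, base$pixels)
  }
})

test_that("size filtering and border flagging work", {
  cfg <- scene_config(n_planes = 1L, image_size = c(200L, 200L))
  cysts <- dplyr::bind_rows(cyst_row(1L, cx = 100, cy = 100, cz = 1, r = 20),
                            cyst_row(2L, cx = 197, cy = 100, cz = 1, r = 15))
  plane <- render_scene(cysts, cfg)$actin$planes[, , 1]
  obj <- segment_plane(plane, seg_params())
  expect_equal(sum(obj$on_border), 1)
  # min_area above the small object's size removes it
  obj2 <- segment_plane(plane, seg_params(min_area = 1000))
  expect_equal(nrow(obj2), 1)
})

test_that("vertically overlapping cysts resolve into distinct objects", {
  cfg <- scene_config(n_planes = 15L)
  cysts <- dplyr::bind_rows(cyst_row(1L, cz = 2, r = 18),
                            cyst_row(2L, cz = 12, r = 18))
  dc <- detect_cysts(render_scene(cysts, cfg)$actin, seg_params())
  expect_equal(nrow(dc), 2)
  expect_true(all(abs(dc$centroid_x - 64) < 3))
})

test_that("a sphere spanning adjacent planes yields one object at its equator", {
  cfg <- scene_config()
  dc <- detect_cysts(render_scene(cyst_row(cz = 3, r = 18), cfg)$actin,
                     seg_params())
  expect_equal(nrow(dc), 1)
  expect_equal(dc$plane_index, 3L)
  expect_equal(dc$n_planes_spanned, 3L)
  expect_lt(abs(dc$area_px - pi * 18^2) / (pi * 18^2), 0.05)
})

test_that("background-only stacks give an empty cyst table", {
  cfg <- scene_config()
  dc <- detect_cysts(render_scene(cyst_row()[0, ], cfg)$actin, seg_params())
  expect_equal(nrow(dc), 0)
})

test_that("detection is invariant to reversing plane order", {
  cfg <- demo_screen_config(seed = 12, noise_sd = 0)
  well <- plate_layout(cfg, demo_compounds())[2, ]
  stack <- simulate_well(well, cfg)$actin
  fwd <- detect_cysts(stack, seg_params())
  rev_stack <- image_stack(stack$planes[, , rev(seq_len(dim(stack$planes)[3]))],
                           stack$z_interval_um, stack$channel, stack$well_id)
  bwd <- detect_cysts(rev_stack, seg_params())
  expect_equal(sort(fwd$area_px), sort(bwd$area_px))
  expect_equal(nrow(fwd), nrow(bwd))
})

test_that("wall measurements recover thickness, absence and fragmentation", {
  cfg1 <- scene_config(n_planes = 1L)
  # intact ring, wall 3 px
  intact <- detect_cysts(render_scene(cyst_row(cz = 1, r = 20), cfg1)$actin,
                         seg_params())
  expect_gte(intact$wall_mean_thickness_px, 2.5)
  expect_lte(intact$wall_mean_thickness_px, 3.5)

  # uniform disc: no actin-dense band, thickness 0
  flat <- cyst_row(cz = 1, r = 20, wall_int = 12000, lumen_int = 12000)
  disc <- detect_cysts(render_scene(flat, cfg1)$actin, seg_params())
  expect_equal(disc$wall_mean_thickness_px, 0)
  expect_equal(disc$wall_area_px, 0)

  # half-integrity ring: total wall area about half the intact ring
  frag <- detect_cysts(render_scene(cyst_row(cz = 1, r = 20, integrity = 0.5),
                                    cfg1)$actin, seg_params())
  expect_equal(sum(frag$wall_area_px) / sum(intact$wall_area_px), 0.5,
               tolerance = 0.15)

  # degenerate mask is flagged with zero thickness
  plane <- matrix(400, 64, 64); plane[30:31, 30:31] <- 20000
  res <- measure_wall(plane > 1000, plane, seg_params())
  expect_true(res$flagged)
  expect_equal(res$wall_mean_thickness_px, 0)
})

test_that("maximum projection obeys its defining identities", {
  p <- matrix(runif(64), 8, 8)
  expect_identical(max_projection(image_stack(list(p))), p)
  s <- image_stack(list(matrix(1, 4, 4), matrix(2, 4, 4), matrix(3, 4, 4)))
  expect_true(all(max_projection(s) == 3))
  cfg <- demo_screen_config(seed = 5)
  stack <- simulate_well(plate_layout(cfg, demo_compounds())[1, ], cfg)$actin
  proj <- max_projection(stack)
  for (k in seq_len(dim(stack$planes)[3])) {
    expect_true(all(proj >= stack$planes[, , k]))
  }
})

test_that("nuclei counting is exact for separated spots and robust at density", {
  # 40 well-separated Gaussian spots, noise-free
  pl <- matrix(400, 200, 200)
  centers <- expand.grid(x = seq(20, 180, length.out = 7),
                         y = seq(20, 180, length.out = 6))[1:40, ]
  for (i in 1:40) {
    dx <- outer(rep(1, 200), 1:200) - centers$x[i]
    dy <- outer(1:200, rep(1, 200)) - centers$y[i]
    pl <- pmax(pl, 400 + 15000 * exp(-(dx^2 + dy^2) / 8))
  }
  stack <- image_stack(round(pl), channel = "nuclei")
  expect_equal(count_nuclei(stack, seg_params()), 40)

  # empty channel
  expect_equal(count_nuclei(image_stack(matrix(400, 64, 64)), seg_params()), 0)

  # ~100 nuclei at generator-default spacing and noise: within 10% across seeds
  errs <- vapply(1:4, function(s) {
    cfg <- screen_config(image_size = c(256L, 256L), n_planes = 5L,
                         cysts_per_well = c(12L, 12L), radius_mean_px = 14,
                         radius_sd_px = 2, plate_shape = c(4L, 8L),
                         controls = list(unstimulated = 4L, stimulated = 4L),
                         seed = s)
    w <- plate_layout(cfg, demo_compounds())[1, ]
    sim <- simulate_well(w, cfg)
    truth <- sum(sim$cysts$n_nuclei)
    (count_nuclei(sim$nuclei, seg_params()) - truth) / truth
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.10)
})
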