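test_that("scene validation rejects invalid descriptions", {
  expect_error(scene(c(64, 64),
                     boundaries = boundary_circle(32, 32, 40,
                                                  amplitude = 100)),
               "outside canvas")
  expect_error(scene(c(64, 64), puncta = punctum(70, 32, amplitude = 10)),
               "outside canvas")
  expect_error(scene(c(64, 64),
                     puncta = punctum(32, 32, amplitude = -5)),
               "amplitudes")
  expect_error(scene(c(64, 64),
                     puncta = punctum(32, 32, amplitude = 5, g = 1.5)),
               "anisotropy")
})

test_that("an isotropic punctum contributes equally to all four quadrants", {
  sc <- scene(c(48, 48), puncta = punctum(24, 24, amplitude = 1000,
                                          radius = 2), seed = 3)
  r <- render_quadrants(sc, quantize = FALSE)
  s <- r$stack
  expect_identical(s$tl, s$tr)
  expect_identical(s$tl, s$bl)
  expect_identical(s$tl, s$br)
  expect_equal(sum(s$tl), 250, tolerance = 1e-12)
})

test_that("a fully directional straight edge lands in the opposing quadrant only", {
  sc <- scene(c(64, 64),
              boundaries = boundary_segment(20, 30, 44, 30, ny = -1, nx = -1,
                                            amplitude = 500, g = 1))
  r <- render_quadrants(sc, quantize = FALSE)
  s <- r$stack
  expect_equal(sum(s$br), 500, tolerance = 1e-9)
  expect_equal(sum(s$tl) + sum(s$tr) + sum(s$bl), 0)
})

test_that("photon budget is conserved independent of anisotropy", {
  for (g in c(0, 0.3, 0.7, 1)) {
    sc <- scene(c(80, 80),
                boundaries = boundary_circle(40, 40, 18, amplitude = 2e4,
                                             g = g),
                puncta = punctum(40, 40, amplitude = 3000, radius = 1.5),
                background_level = 5)
    r <- render_quadrants(sc, quantize = FALSE)
    total <- sum(compute_darkfield(r$stack))
    expect_equal(total, 2e4 + 3000 + 4 * 5 * 80 * 80, tolerance = 1e-9)
  }
})

test_that("a g=1 bead shows one quarter-arc per quadrant at the analytic centroid", {
  R <- 20
  r <- render_quadrants(bead_scene(g = 1, radius = R), quantize = FALSE)
  s <- r$stack
  # analytic centroid of a quarter arc: center +/- 2R/pi on each axis.
  # BR illumination receives the arc whose normals point toward TL.
  d <- 2 * R / pi
  expected <- list(br = c(48 - d, 48 - d), bl = c(48 - d, 48 + d),
                   tr = c(48 + d, 48 - d), tl = c(48 + d, 48 + d))
  for (qn in names(expected)) {
    m <- s[[qn]]
    cy <- sum(row(m) * m) / sum(m)
    cx <- sum(col(m) * m) / sum(m)
    expect_equal(c(cy, cx), expected[[qn]], tolerance = 0.02)
    expect_equal(sum(m), 5e4 / 4, tolerance = 0.02)
  }
  # union of the four arcs covers the ring: every edge pixel lit somewhere
  lit <- s$tl + s$tr + s$bl + s$br
  expect_true(all(lit[r$truth$edge_mask] > 0))
})

test_that("rendering is deterministic under the scene seed", {
  sc <- cell_scene(seed = 11)
  r1 <- render_quadrants(sc)
  r2 <- render_quadrants(sc)
  expect_identical(r1$stack$tl, r2$stack$tl)
  expect_identical(r1$stack$br, r2$stack$br)
  sc2 <- sc; sc2$seed <- 12L
  expect_false(identical(render_quadrants(sc2)$stack$tl, r1$stack$tl))
})

test_that("ground-truth masks are disjoint and puncta sit inside one label", {
  r <- render_quadrants(cell_scene(seed = 2))
  expect_false(any(r$truth$edge_mask & r$truth$puncta_mask))
  sc <- cell_scene(seed = 2)
  for (i in seq_len(nrow(sc$puncta))) {
    lab <- r$truth$cell_labels[round(sc$puncta$cy[i]), round(sc$puncta$cx[i])]
    expect_gt(lab, 0)
  }
  expect_equal(sum(r$truth$per_cell$puncta_total), sum(sc$puncta$amplitude))
})

test_that("phase rendering conserves integrated phase per cell", {
  sc <- scene(c(128, 128),
              boundaries = dplyr::bind_rows(
                boundary_circle(40, 40, 18, amplitude = 1e4,
                                phase_total = 500),
                boundary_circle(88, 88, 22, amplitude = 1e4,
                                phase_total = 800)))
  ph <- render_phase(sc)
  expect_equal(sum(ph$phase), 1300, tolerance = 1e-9)
  # direct summation oracle over each truth label
  labs <- render_quadrants(sc, quantize = FALSE)$truth$cell_labels
  for (l in 1:2) {
    expect_equal(sum(ph$phase[labs == l]),
                 ph$per_cell_phase$phase_total[l], tolerance = 1e-6)
  }
  # rounding concentrates phase: same integral, higher peak, smaller support
  sc2 <- sc
  sc2$boundaries$radius <- sc$boundaries$radius * 0.7
  ph2 <- render_phase(sc2)
  expect_equal(sum(ph2$phase), sum(ph$phase), tolerance = 1e-9)
  expect_gt(max(ph2$phase), max(ph$phase))
  expect_lt(sum(ph2$phase > 0.05), sum(ph$phase > 0.05))
  expect_equal(sum(render_phase(scene(c(32, 32)))$phase), 0)
})

test_that("shape sequences conserve puncta while edge brightness grows", {
  base <- qdf:::shape_change_base(1)
  expect_error(make_shape_sequence(base, 3, c(0.2, 1.2)), "\\[0, 1\\]")
  sq <- make_shape_sequence(base, n_frames = 3, shape_range = c(0.1, 0.9))
  edge_amp <- vapply(sq$frames,
                     function(f) f$boundaries$amplitude[1], numeric(1))
  expect_true(all(diff(edge_amp) > 0))
  punc_tot <- vapply(sq$frames,
                     function(f) sum(f$puncta$amplitude), numeric(1))
  expect_true(all(punc_tot == sq$conserved_puncta_total))
  # rendered ground truth reproduces the conserved total exactly
  for (f in sq$frames) {
    r <- render_quadrants(f)
    expect_equal(sum(r$truth$per_cell$puncta_total),
                 sq$conserved_puncta_total)
  }
  # radii shrink and puncta contract toward the centroid
  radii <- vapply(sq$frames, function(f) f$boundaries$radius[1], numeric(1))
  expect_true(all(diff(radii) < 0))
  spread <- vapply(sq$frames, function(f) {
    mean(sqrt((f$puncta$cy - 64)^2 + (f$puncta$cx - 64)^2))
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
  # degenerate range: identical frames apart from the noise seed
  sq2 <- make_shape_sequence(base, n_frames = 3, shape_range = c(0.2, 0.2))
  f1 <- sq2$frames[[1]]; f3 <- sq2$frames[[3]]
  f3$seed <- f1$seed
  expect_equal(f1, f3)
})

test_that("population sampling follows the Poisson law and is reproducible", {
  pop1 <- make_population(20, 0.01, seed = 5)
  pop2 <- make_population(20, 0.01, seed = 5)
  expect_equal(pop1, pop2)
  expect_true(all(vapply(make_population(5, 0, seed = 1),
                         function(s) nrow(s$puncta) == 0, logical(1))))
  d <- 0.012
  pop <- make_population(500, d, seed = 42)
  counts <- vapply(pop, function(s) nrow(s$puncta), numeric(1))
  areas <- vapply(pop, function(s) pi * s$boundaries$radius[1]^2, numeric(1))
  diff_ <- counts - d * areas
  expect_lt(abs(mean(diff_)), 3 * sd(diff_) / sqrt(length(diff_)))
})

test_that("scene descriptions round-trip through JSON", {
  sc <- cell_scene(seed = 9)
  sc$poly_background <- matrix(c(10, 2, 0, 1), 2, 2)
  path <- withr::local_tempfile(fileext = ".json")
  scene_to_json(sc, path)
  back <- scene_from_json(path)
  expect_equal(back$boundaries, sc$boundaries)
  expect_equal(back$puncta, sc$puncta)
  expect_equal(back$poly_background, sc$poly_background)
  r1 <- render_quadrants(sc); r2 <- render_quadrants(back)
  expect_identical(r1$stack$tl, r2$stack$tl)
})
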