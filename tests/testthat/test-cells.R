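test_that("segmentation handles empty, single and touching cells", {
  expect_true(all(segment_cells(matrix(0, 64, 64)) == 0L))
  # one isolated blob above threshold -> one label on its support
  blob <- outer(1:80, 1:80, function(r, c) exp(-((r - 40)^2 + (c - 40)^2) /
                                                 (2 * 8^2)))
  lab <- segment_cells(blob)
  expect_equal(max(lab), 1L)
  expect_equal(lab[40, 40], 1L)
  # two touching cells -> two labels, each containing its punctum centers
  sc <- scene(c(128, 128),
              boundaries = dplyr::bind_rows(
                boundary_circle(64, 45, 20, amplitude = 1e4,
                                phase_total = 600),
                boundary_circle(64, 93, 20, amplitude = 1e4,
                                phase_total = 600)),
              puncta = dplyr::bind_rows(punctum(64, 45, 2000),
                                        punctum(64, 93, 2000)))
  r <- render_quadrants(sc)
  ph <- render_phase(sc)
  lab <- segment_cells(ph$phase)
  expect_equal(max(lab), 2L)
  expect_true(lab[64, 45] > 0 && lab[64, 93] > 0)
  expect_true(lab[64, 45] != lab[64, 93])
  # majority overlap with the ground-truth labels
  truth <- r$truth$cell_labels
  for (l in 1:2) {
    votes <- table(truth[lab == l & truth > 0])
    expect_gt(max(votes) / sum(votes), 0.9)
  }
  # labels partition the foreground contiguously from 1
  expect_setequal(unique(as.vector(lab[lab > 0])), 1:2)
})

test_that("stationary and moving cells keep one track id across frames", {
  recs <- tidyr::expand_grid(frame = 1:5, label = 1:3) |>
    dplyr::mutate(y = c(20, 60, 100)[label], x = 30)
  tr <- track_cells(recs)
  per_track <- tr |> dplyr::count(.data$track_id)
  expect_equal(nrow(per_track), 3)
  expect_true(all(per_track$n == 5))
  # single cell moving 3 px/frame
  mov <- tibble::tibble(frame = 1:6, label = 1, y = 10 + 3 * (0:5), x = 10)
  expect_equal(length(unique(track_cells(mov, max_disp_px = 10)$track_id)), 1)
  # displacement beyond max_disp starts a new track
  jump <- tibble::tibble(frame = 1:2, label = 1, y = c(10, 60), x = 10)
  expect_equal(length(unique(track_cells(jump, max_disp_px = 10)$track_id)), 2)
})

test_that("tracking survives a missed frame within memory", {
  recs <- tibble::tibble(frame = c(1, 3), label = 1, y = c(10, 12), x = 10)
  expect_equal(length(unique(track_cells(recs, memory = 1)$track_id)), 1)
  expect_equal(length(unique(track_cells(recs, memory = 0)$track_id)), 2)
})

test_that("frame-to-frame assignment matches brute-force enumeration", {
  oracle_assign <- function(cost) {
    n <- nrow(cost); m <- ncol(cost)
    choices <- rep(list(c(NA_integer_, seq_len(m))), n)
    grid <- do.call(expand.grid, choices)
    best <- NULL; best_links <- -1L; best_cost <- Inf
    for (k in seq_len(nrow(grid))) {
      a <- as.integer(unlist(grid[k, ]))
      used <- a[!is.na(a)]
      if (anyDuplicated(used)) next
      cc <- 0; ok <- TRUE
      for (i in seq_len(n)) {
        if (!is.na(a[i])) {
          if (!is.finite(cost[i, a[i]])) { ok <- FALSE; break }
          cc <- cc + cost[i, a[i]]
        }
      }
      if (!ok) next
      links <- sum(!is.na(a))
      if (links > best_links || (links == best_links && cc < best_cost)) {
        best <- a; best_links <- links; best_cost <- cc
      }
    }
    list(sol = best, links = best_links, cost = best_cost)
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    cost <- matrix(runif(n * m, 0, 100), n, m)
    cost[runif(n * m) < 0.3] <- Inf
    got <- qdf:::assign_exact(cost)
    want <- oracle_assign(cost)
    got_links <- sum(!is.na(got))
    got_cost <- sum(cost[cbind(which(!is.na(got)), got[!is.na(got)])])
    expect_equal(got_links, want$links)
    expect_equal(got_cost, want$cost, tolerance = 1e-12)
  }
})

test_that("two crossing cells link by minimum total squared displacement", {
  # cell A moves right-down, cell B right-up; nearest-neighbour would swap
  recs <- tibble::tibble(frame = c(1, 1, 2, 2), label = c(1, 2, 1, 2),
                         y = c(10, 16, 14, 12), x = c(10, 10, 12, 12))
  tr <- track_cells(recs, max_disp_px = 10)
  # optimal assignment keeps 1->1 (cost 16+4+16+4=40) over the swap (4+..)
  cost_keep <- (14 - 10)^2 + (12 - 16)^2
  cost_swap <- (12 - 10)^2 + (14 - 16)^2
  expect_lt(cost_swap, cost_keep)   # the swap IS optimal here
  expect_equal(tr$track_id[3], tr$track_id[2])
  expect_equal(tr$track_id[4], tr$track_id[1])
})

test_that("dry mass follows the unit-tracking closed form and is linear", {
  optics <- optical_config(wavelength_nm = 525, pixel_size_um = 0.5)
  phase <- matrix(0, 20, 20)
  lab <- matrix(0L, 20, 20)
  lab[1:10, 1:10] <- 1L
  expect_equal(compute_dry_mass(phase, lab, optics)$dry_mass_pg, 0)
  phase[1:10, 1:10] <- 1
  got <- compute_dry_mass(phase, lab, optics)
  # independent unit analysis: 100 px * 1 rad * (lambda/2pi) * A_px / alpha
  want_kg <- 100 * 1 * (525e-9 / (2 * pi)) * (0.5e-6)^2 / 1.8e-4
  expect_equal(got$dry_mass_pg, want_kg * 1e15, tolerance = 1e-12)
  expect_equal(got$mass_per_area_pg_per_um2,
               want_kg * 1e15 / (100 * 0.25), tolerance = 1e-12)
  # doubling the pixel area doubles the mass
  optics2 <- optical_config(pixel_size_um = 0.5 * sqrt(2))
  expect_equal(compute_dry_mass(phase, lab, optics2)$dry_mass_pg,
               2 * got$dry_mass_pg, tolerance = 1e-12)
})

test_that("per-cell totals are additive and match phantom ground truth", {
  lab <- matrix(0L, 10, 10)
  lab[1:5, 1:5] <- 1L; lab[6:10, 6:10] <- 2L
  df <- matrix(2, 10, 10); zeros <- matrix(0, 10, 10)
  t0 <- per_cell_signals(lab, df, zeros)
  expect_equal(t0$total_qdf, c(0, 0))
  qd <- matrix(runif(100, -1, 3), 10, 10)
  t1 <- per_cell_signals(lab, df, qd)
  merged <- lab; merged[merged == 2L] <- 1L
  t2 <- per_cell_signals(merged, df, qd)
  expect_equal(t2$total_qdf, sum(t1$total_qdf))   # additive over unions
  expect_equal(t2$total_df, sum(t1$total_df))
  expect_true(all(t1$total_qdf >= 0))             # clipped at zero
  # a single punctum's integrated QDF is recovered within quantization
  sc <- scene(c(96, 96),
              boundaries = boundary_circle(48, 48, 20, amplitude = 0,
                                           width = 1.5),
              puncta = punctum(48, 48, amplitude = 5000, radius = 1.5))
  r <- render_quadrants(sc)
  rec <- compute_qdf(r$stack, c = 1)
  t3 <- per_cell_signals(r$truth$cell_labels, rec$df, rec$qdf)
  expect_equal(t3$total_qdf, 5000, tolerance = 0.01)
})

test_that("debris flags match a rule-by-rule enumeration", {
  recs <- tibble::tibble(
    frame = 1L, label = 1:5, track_id = 1:5,
    area_px = c(10, 500, 500, 500, 500),
    total_df = c(500, 25000, 100, 25000, 25000),
    total_qdf = c(500, 25000, 25000, 50, 25000),
    mean_phase = c(0.5, 0.5, 0.5, 0.5, 0.01)
  )
  out <- suppressMessages(
    filter_debris(recs, min_area_px = 50, max_area_px = 1000,
                  min_track_len = 0, min_mean_phase = 0.1,
                  min_mean_df = 1, min_mean_qdf = 1)
  )
  expect_equal(out$debris, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_match(out$debris_reason[1], "area_small")
  expect_match(out$debris_reason[3], "low_df")
  expect_match(out$debris_reason[4], "low_qdf")
  expect_match(out$debris_reason[5], "low_phase")
  # no thresholds -> nothing flagged; records never deleted
  out0 <- suppressMessages(filter_debris(recs))
  expect_equal(nrow(out0), 5)
  expect_false(any(out0$debris))
  # track-length rule
  recs2 <- tibble::tibble(frame = c(1, 2, 1), label = c(1, 1, 2),
                          track_id = c(1, 1, 2),
                          area_px = 100, total_df = 1000, total_qdf = 1000)
  out2 <- suppressMessages(filter_debris(recs2, min_track_len = 2))
  expect_equal(out2$debris, c(FALSE, FALSE, TRUE))
})

test_that("SNR threshold follows the background quantile and flags degenerate noise", {
  set.seed(8)
  qd <- matrix(rnorm(200 * 200), 200, 200)
  s <- compute_snr(qd, matrix(0L, 200, 200))
  # 4 x the 99th percentile of a standard normal background
  expect_equal(s$threshold, 4 * qnorm(0.99), tolerance = 0.05)
  expect_equal(nrow(s$per_cell), 0)
  expect_error(compute_snr(matrix(5, 50, 50), matrix(0L, 50, 50)),
               "zero variance")
})

test_that("constructed puncta at 30 sigma yield per-cell SNR near 30", {
  set.seed(15)
  H <- 160
  qd <- matrix(rnorm(H * H, 0, 2), H, H)
  lab <- matrix(0L, H, H)
  Y <- row(qd); X <- col(qd)
  centers <- list(c(45, 45), c(45, 115), c(115, 45), c(115, 115))
  for (i in seq_along(centers)) {
    cc <- centers[[i]]
    lab[(Y - cc[1])^2 + (X - cc[2])^2 <= 18^2] <- i
    sel <- (Y - cc[1])^2 + (X - cc[2])^2 <= 3^2
    qd[sel] <- qd[sel] + 30 * 2
  }
  s <- compute_snr(qd, lab)
  expect_equal(nrow(s$per_cell), 4)
  expect_true(all(abs(s$per_cell$snr - 30) / 30 < 0.15))
})
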