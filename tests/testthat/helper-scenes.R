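# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

random_stack <- function(seed = 1, n = 16, maxval = 1000) {
  set.seed(seed)
  imgs <- replicate(4, matrix(as.numeric(sample.int(maxval, n * n,
                                                    replace = TRUE)),
                              n, n), simplify = FALSE)
  quadrant_stack(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]])
}

bead_scene <- function(g = 1, amplitude = 5e4, noise = 0, background = 0,
                       seed = 1, canvas = 96, radius = 20) {
  scene(c(canvas, canvas),
        boundaries = boundary_circle(canvas / 2, canvas / 2, radius,
                                     amplitude = amplitude, g = g,
                                     is_cell = FALSE),
        background_level = background, noise_sigma = noise, seed = seed)
}

# bead with an internal isotropic punctum ("imperfect bead")
imperfect_bead_scene <- function(g = 0.9, seed = 1) {
  scene(c(96, 96),
        boundaries = boundary_circle(48, 48, 20, amplitude = 5e4, g = g,
                                     is_cell = FALSE),
        puncta = punctum(44, 52, amplitude = 5e3, radius = 1.5, g = 0),
        seed = seed)
}

# single cell with edge + internal puncta, edge and puncta totals comparable
cell_scene <- function(seed = 1, n_puncta = 10, noise = 2, background = 20,
                       punctum_amplitude = 2000) {
  set.seed(seed)
  rr <- 14 * sqrt(runif(n_puncta))
  th <- runif(n_puncta, 0, 2 * pi)
  scene(c(128, 128),
        boundaries = boundary_circle(64, 64, 22, amplitude = 3e4, g = 0.9,
                                     phase_total = 900),
        puncta = punctum(64 + rr * sin(th), 64 + rr * cos(th),
                         amplitude = punctum_amplitude, radius = 1.2),
        background_level = background, noise_sigma = noise, seed = seed)
}

empty_reference_stack <- function(canvas = 128, background = 20, noise = 2,
                                  seed = 999) {
  render_quadrants(scene(c(canvas, canvas), background_level = background,
                         noise_sigma = noise, seed = seed))$stack
}

# per-pixel loop oracles for the reconstruction equations
oracle_df <- function(s) {
  out <- matrix(0, nrow(s$tl), ncol(s$tl))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- s$tl[i, j] + s$tr[i, j] + s$bl[i, j] + s$br[i, j]
  }
  out
}

oracle_edge <- function(s) {
  out <- matrix(0, nrow(s$tl), ncol(s$tl))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- abs(s$tl[i, j] - s$br[i, j]) + abs(s$bl[i, j] - s$tr[i, j])
  }
  out
}
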