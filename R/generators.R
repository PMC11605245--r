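#' Flat-to-round shape-change sequence with conserved puncta
#'
#' Builds a time series of scenes for one cell changing shape from flat and
#' spread to rounded, the situation where the darkfield signal rises sharply
#' (stronger lensing at the rounded edge) while the organelle content — and
#' hence the puncta signal — stays constant. Per frame, the shape parameter
#' `s` interpolates across `shape_range`:
#'
#' * boundary radius shrinks: `R(s) = R0 * (1 - 0.4 s)`,
#' * edge brightness grows: `A(s) = A0 * (1 + 1.5 s)` (monotone in `s`),
#' * puncta amplitudes are unchanged and positions contract toward the
#'   centroid with the radius, and
#' * the cell's integrated phase is constant, so its peak phase rises as
#'   the support shrinks (mass per area grows).
#'
#' @param base A single-cell [scene()] describing the flat state (first
#'   circular `is_cell` boundary is the cell; its puncta all inside).
#' @param n_frames Number of frames, >= 2.
#' @param shape_range Range `(s_min, s_max)` of the shape parameter, each in
#'   \[0, 1\].
#' @param seed Base RNG seed; frame `k` renders with `seed + k`.
#' @return A `shape_sequence`: list with `frames` (list of scenes),
#'   `shape_parameter` (per-frame), `conserved_puncta_total`.
#' @export
make_shape_sequence <- function(base, n_frames, shape_range, seed = 1L) {
  validate_scene(base)
  stopifnot(n_frames >= 2, length(shape_range) == 2)
  if (any(shape_range < 0 | shape_range > 1)) {
    stop("shape_range must lie in [0, 1]", call. = FALSE)
  }
  ci <- which(base$boundaries$type == "circle" & base$boundaries$is_cell)
  if (!length(ci)) stop("base scene needs a circular cell boundary",
                        call. = FALSE)
  ci <- ci[1]
  b0 <- base$boundaries[ci, ]
  s_vals <- seq(shape_range[1], shape_range[2], length.out = n_frames)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    s <- s_vals[k]
    sc <- base
    shrink <- 1 - 0.4 * s
    sc$boundaries$radius[ci] <- b0$radius * shrink
    sc$boundaries$amplitude[ci] <- b0$amplitude * (1 + 1.5 * s)
    if (nrow(sc$puncta)) {
      scale <- 0.85 * shrink
      sc$puncta$cy <- b0$cy + (base$puncta$cy - b0$cy) * scale
      sc$puncta$cx <- b0$cx + (base$puncta$cx - b0$cx) * scale
    }
    sc$seed <- as.integer(seed + k)
    frames[[k]] <- sc
  }
  structure(list(frames = frames, shape_parameter = s_vals,
                 conserved_puncta_total = sum(base$puncta$amplitude)),
            class = "shape_sequence")
}

#' @export
print.shape_sequence <- function(x, ...) {
  cat(sprintf("<shape_sequence> %d frames, shape %g..%g, puncta total %g\n",
              length(x$frames), min(x$shape_parameter),
              max(x$shape_parameter), x$conserved_puncta_total))
  invisible(x)
}

#' Simulate a cell population with a given puncta density
#'
#' One scene per cell. Cell radii follow a lognormal law; per-cell puncta
#' counts are Poisson with mean `puncta_density * area_px`; puncta are
#' placed uniformly inside the cell at a safe margin from the edge ring.
#' Per-cell edge brightness is lognormal with wide dispersion
#' (`edge_sdlog`): in real populations the darkfield edge signal varies far
#' more with shape and attachment state than the puncta content does, which
#' is exactly why total darkfield separates populations poorly.
#'
#' @param n_cells Number of cells (scenes), >= 1.
#' @param puncta_density Mean puncta per pixel of cell area, >= 0.
#' @param seed RNG seed; the whole population is reproducible.
#' @param canvas_px Square canvas side, pixels.
#' @param radius_meanlog,radius_sdlog Lognormal parameters of the cell
#'   radius (pixels).
#' @param edge_amplitude_mean Mean total edge brightness (counts).
#' @param edge_sdlog Lognormal sdlog of the edge brightness.
#' @param punctum_amplitude Total counts per punctum.
#' @param punctum_sigma_px Punctum spot sigma, pixels.
#' @param g_edge Edge anisotropy (effective directionality of the boundary).
#' @param background_level,noise_sigma Passed to each [scene()].
#' @return List of `qdf_scene`, one per cell, each with one `is_cell`
#'   boundary.
#' @export
make_population <- function(n_cells, puncta_density, seed = 1L,
                            canvas_px = 96,
                            radius_meanlog = log(15), radius_sdlog = 0.15,
                            edge_amplitude_mean = 4e4, edge_sdlog = 0.8,
                            punctum_amplitude = 300,
                            punctum_sigma_px = 1.2,
                            g_edge = 0.9,
                            background_level = 20, noise_sigma = 2) {
  stopifnot(n_cells >= 1, puncta_density >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ctr <- (canvas_px + 1) / 2
  scenes <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    radius <- min(stats::rlnorm(1, radius_meanlog, radius_sdlog),
                  (canvas_px - 12) / 2 - 4.5)
    amp <- stats::rlnorm(1, log(edge_amplitude_mean) - edge_sdlog^2 / 2,
                         edge_sdlog)
    area <- pi * radius^2
    n_p <- stats::rpois(1, puncta_density * area)
    pct <- NULL
    if (n_p > 0) {
      # uniform in the disk, margin 4 px inside the edge ring
      rmax <- max(radius - 6, 2)
      rr <- rmax * sqrt(stats::runif(n_p))
      th <- stats::runif(n_p, 0, 2 * pi)
      pct <- punctum(cy = ctr + rr * sin(th), cx = ctr + rr * cos(th),
                     amplitude = punctum_amplitude,
                     radius = punctum_sigma_px, g = 0)
    }
    scenes[[i]] <- scene(
      canvas_shape = c(canvas_px, canvas_px),
      boundaries = boundary_circle(ctr, ctr, radius = radius,
                                   amplitude = amp, g = g_edge),
      puncta = pct,
      background_level = background_level,
      noise_sigma = noise_sigma,
      seed = as.integer((seed + i) %% .Machine$integer.max)
    )
  }
  scenes
}
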