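#' Parametric phantom scenes
#'
#' A scene is the forward-model description used by the phantom simulator:
#' closed boundaries (cell or bead edges) that refract light directionally,
#' plus small puncta that scatter near-isotropically, over a flat or
#' polynomial background with Gaussian read noise.
#'
#' The scattering anisotropy `g` interpolates linearly between the two
#' physical regimes the method exploits: `g = 0` deposits light equally into
#' all four quadrant images (broad Mie-type scattering from sub-wavelength
#' puncta) and `g = 1` deposits light only into the image whose illumination
#' quadrant opposes the local outward normal (Snell-type refraction at a
#' large edge). The optional `leak` models the weak symmetric diffraction
#' from the far edge of an object: a fraction `leak` of the directional light
#' is redistributed isotropically, so the effective directionality is
#' `g * (1 - leak)`.
#'
#' Image coordinates follow raster convention: row 1 is the top of the image,
#' column 1 the left; "top-left quadrant" is low row, low column.
#'
#' @param canvas_shape Integer vector `c(H, W)`, canvas size in pixels.
#' @param boundaries Tibble of boundary contours, one row each, built with
#'   [boundary_circle()] / [boundary_segment()] and combined with
#'   `dplyr::bind_rows()`.
#' @param puncta Tibble of puncta, one row each, built with [punctum()].
#' @param background_level Flat background added to every quadrant image
#'   (counts).
#' @param noise_sigma Gaussian read-noise standard deviation (counts).
#' @param poly_background Optional coefficient matrix of a 2D polynomial
#'   background over coordinates normalized to \[-1, 1\]^2; entry `[i, j]`
#'   multiplies `x^(i-1) * y^(j-1)`, total degree at most 8. Added to every
#'   quadrant image.
#' @param seed Integer RNG seed used for the noise draw; rendering the same
#'   scene twice is bit-identical.
#'
#' @return An object of class `qdf_scene`.
#' @seealso [render_quadrants()], [render_phase()], [make_shape_sequence()],
#'   [make_population()]
#' @examples
#' sc <- scene(
#'   canvas_shape = c(96, 96),
#'   boundaries = boundary_circle(48, 48, radius = 25, amplitude = 8000),
#'   puncta = punctum(48, 48, amplitude = 500)
#' )
#' sc
#' @export
scene <- function(canvas_shape,
                  boundaries = NULL,
                  puncta = NULL,
                  background_level = 0,
                  noise_sigma = 0,
                  poly_background = NULL,
                  seed = 1L) {
  sc <- structure(
    list(
      canvas_shape = as.integer(canvas_shape),
      boundaries = if (is.null(boundaries)) empty_boundaries() else
        tibble::as_tibble(boundaries),
      puncta = if (is.null(puncta)) empty_puncta() else
        tibble::as_tibble(puncta),
      background_level = background_level,
      noise_sigma = noise_sigma,
      poly_background = poly_background,
      seed = as.integer(seed)
    ),
    class = "qdf_scene"
  )
  validate_scene(sc)
  sc
}

empty_boundaries <- function() {
  tibble::tibble(
    type = character(), cy = numeric(), cx = numeric(), radius = numeric(),
    y0 = numeric(), x0 = numeric(), y1 = numeric(), x1 = numeric(),
    ny = numeric(), nx = numeric(),
    amplitude = numeric(), width = numeric(), g = numeric(), leak = numeric(),
    is_cell = logical(), phase_total = numeric()
  )
}

empty_puncta <- function() {
  tibble::tibble(
    cy = numeric(), cx = numeric(), amplitude = numeric(), radius = numeric(),
    g = numeric(), dir_y = numeric(), dir_x = numeric()
  )
}

#' Boundary and puncta constructors
#'
#' Build the rows of a [scene()]'s `boundaries` and `puncta` tables.
#' `boundary_circle()` describes a closed circular edge (a bead or a rounded
#' cell outline); `boundary_segment()` a straight edge piece with an explicit
#' outward normal, mainly useful for directionality tests.
#'
#' @param cy,cx Centre, in pixels (row, column).
#' @param radius Circle radius in pixels; for [punctum()], the Gaussian sigma
#'   of the spot in pixels.
#' @param amplitude Total deposited signal of the object, in counts (the sum
#'   over all pixels and all four quadrant images).
#' @param width Gaussian cross-section sigma of the edge profile, pixels.
#' @param g Scattering anisotropy in \[0, 1\]; see [scene()].
#' @param leak Symmetric edge-leak fraction in \[0, 1); see [scene()].
#' @param is_cell Should this boundary define a cell label in the ground
#'   truth (filled disk)?
#' @param phase_total Integrated phase of the cell in radian-pixels, used by
#'   [render_phase()]. Default scales with the disk area.
#' @return A one-row tibble.
#' @export
boundary_circle <- function(cy, cx, radius, amplitude, width = 1.5,
                            g = 1, leak = 0, is_cell = TRUE,
                            phase_total = NULL) {
  if (is.null(phase_total)) phase_total <- 0.5 * pi * radius^2
  tibble::tibble(
    type = "circle", cy = cy, cx = cx, radius = radius,
    y0 = NA_real_, x0 = NA_real_, y1 = NA_real_, x1 = NA_real_,
    ny = NA_real_, nx = NA_real_,
    amplitude = amplitude, width = width, g = g, leak = leak,
    is_cell = is_cell, phase_total = phase_total
  )
}

#' @rdname boundary_circle
#' @param y0,x0,y1,x1 Segment endpoints, pixels.
#' @param ny,nx Outward normal direction of the segment (need not be unit
#'   length; only its quadrant sign pattern matters).
#' @export
boundary_segment <- function(y0, x0, y1, x1, ny, nx, amplitude,
                             width = 1.5, g = 1, leak = 0) {
  tibble::tibble(
    type = "segment", cy = NA_real_, cx = NA_real_, radius = NA_real_,
    y0 = y0, x0 = x0, y1 = y1, x1 = x1, ny = ny, nx = nx,
    amplitude = amplitude, width = width, g = g, leak = leak,
    is_cell = FALSE, phase_total = 0
  )
}

#' @rdname boundary_circle
#' @param dir_y,dir_x Optional directional axis for an anisotropic punctum
#'   (`g > 0`); ignored when `g = 0`. Defaults to the radial direction from
#'   the nearest boundary centre at render time.
#' @export
punctum <- function(cy, cx, amplitude, radius = 1.2, g = 0,
                    dir_y = NA_real_, dir_x = NA_real_) {
  tibble::tibble(cy = cy, cx = cx, amplitude = amplitude, radius = radius,
                 g = g, dir_y = dir_y, dir_x = dir_x)
}

#' Validate a scene
#'
#' Checks the scene invariants: non-negative amplitudes, anisotropies in
#' \[0, 1\], and every object (plus its edge width margin) contained in the
#' canvas. Called by [scene()] and by the renderers.
#'
#' @param sc A [scene()].
#' @return `sc`, invisibly; errors on violation.
#' @export
validate_scene <- function(sc) {
  stopifnot(inherits(sc, "qdf_scene"))
  H <- sc$canvas_shape[1]; W <- sc$canvas_shape[2]
  if (length(sc$canvas_shape) != 2 || H < 1 || W < 1) {
    stop("canvas_shape must be positive c(H, W)", call. = FALSE)
  }
  b <- sc$boundaries; p <- sc$puncta
  if (any(b$amplitude < 0) || any(p$amplitude < 0)) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (any(b$g < 0 | b$g > 1) || any(p$g < 0 | p$g > 1)) {
    stop("anisotropy g must lie in [0, 1]", call. = FALSE)
  }
  if (any(b$leak < 0 | b$leak >= 1)) {
    stop("leak must lie in [0, 1)", call. = FALSE)
  }
  if (nrow(b)) {
    circ <- b[b$type == "circle", ]
    if (nrow(circ)) {
      m <- circ$radius + 3 * circ$width
      inside <- circ$cy - m >= 1 & circ$cy + m <= H &
        circ$cx - m >= 1 & circ$cx + m <= W
      if (!all(inside)) stop("circle boundary outside canvas", call. = FALSE)
    }
    seg <- b[b$type == "segment", ]
    if (nrow(seg)) {
      inside <- pmin(seg$y0, seg$y1) >= 1 & pmax(seg$y0, seg$y1) <= H &
        pmin(seg$x0, seg$x1) >= 1 & pmax(seg$x0, seg$x1) <= W
      if (!all(inside)) stop("segment boundary outside canvas", call. = FALSE)
    }
  }
  if (nrow(p)) {
    inside <- p$cy >= 1 & p$cy <= H & p$cx >= 1 & p$cx <= W
    if (!all(inside)) stop("punctum outside canvas", call. = FALSE)
  }
  if (!is.null(sc$poly_background)) {
    pb <- sc$poly_background
    if (!is.matrix(pb) || (nrow(pb) - 1) + (ncol(pb) - 1) > 16) {
      stop("poly_background must be a small coefficient matrix", call. = FALSE)
    }
  }
  invisible(sc)
}

#' @export
print.qdf_scene <- function(x, ...) {
  cat(sprintf("<qdf_scene> %dx%d px, %d boundaries, %d puncta\n",
              x$canvas_shape[1], x$canvas_shape[2],
              nrow(x$boundaries), nrow(x$puncta)))
  cat(sprintf("  background %g, noise sigma %g, seed %d\n",
              x$background_level, x$noise_sigma, x$seed))
  invisible(x)
}

#' Scene JSON round trip
#'
#' Serializes a scene description (not rendered pixels) to JSON and back, so
#' phantom suites can be stored on disk alongside their ground truth.
#'
#' @param sc A [scene()].
#' @param path File path to write to / read from.
#' @return `scene_to_json()` returns `path` invisibly; `scene_from_json()`
#'   returns the reconstructed `qdf_scene`.
#' @export
scene_to_json <- function(sc, path) {
  validate_scene(sc)
  obj <- list(
    canvas_shape = sc$canvas_shape,
    boundaries = sc$boundaries,
    puncta = sc$puncta,
    background_level = sc$background_level,
    noise_sigma = sc$noise_sigma,
    poly_background = sc$poly_background,
    seed = sc$seed
  )
  jsonlite::write_json(obj, path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname scene_to_json
#' @export
scene_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pb <- obj$poly_background
  if (!is.null(pb)) pb <- as.matrix(pb)
  # all-NA columns come back logical from JSON; restore numeric types
  renum <- function(d, keep = character()) {
    if (is.null(d) || NROW(d) == 0) return(NULL)
    d <- tibble::as_tibble(d)
    for (cn in setdiff(names(d), keep)) d[[cn]] <- as.numeric(d[[cn]])
    d
  }
  bnd <- renum(obj$boundaries, keep = c("type", "is_cell"))
  if (!is.null(bnd)) bnd$is_cell <- as.logical(bnd$is_cell)
  pct <- renum(obj$puncta)
  scene(
    canvas_shape = obj$canvas_shape,
    boundaries = bnd,
    puncta = pct,
    background_level = obj$background_level,
    noise_sigma = obj$noise_sigma,
    poly_background = pb,
    seed = obj$seed
  )
}
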