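#' Render the four quadrant-illuminated darkfield images of a scene
#'
#' The forward model behind every phantom. Each object deposits its total
#' `amplitude` counts over a Gaussian profile (cross-section sigma = edge
#' `width` for boundaries, spot sigma = `radius` for puncta) and splits each
#' pixel's deposit across the four quadrant images according to its effective
#' anisotropy `g_eff = g * (1 - leak)`:
#'
#' * a fraction `g_eff` goes only into the image whose illumination quadrant
#'   opposes the local outward normal (a pixel whose normal points toward the
#'   top-left receives its directional light under bottom-right
#'   illumination), and
#' * the remaining `1 - g_eff` is split equally across all four images.
#'
#' The split redistributes but never creates or destroys signal: with noise
#' off and no clipping the four images sum to `4 * background + total object
#' amplitude` regardless of `g`. Background (flat plus optional polynomial),
#' seeded Gaussian read noise, clipping to `[0, 2^bit_depth - 1]` and integer
#' quantization are applied last, in that order.
#'
#' @param sc A [scene()].
#' @param optics An [optical_config()]; supplies the camera bit depth.
#' @param quantize Clip and round to integer counts (default) or return the
#'   unquantized floating-point images.
#' @return A list with `stack` (a [quadrant_stack()]) and `truth`, the ground
#'   truth: `edge_mask` and `puncta_mask` (disjoint logical matrices),
#'   `cell_labels` (integer matrix, 0 = background), and `per_cell`, a tibble
#'   with per-label puncta totals.
#' @examples
#' sc <- scene(c(64, 64),
#'             boundaries = boundary_circle(32, 32, 20, amplitude = 4000))
#' r <- render_quadrants(sc)
#' range(r$stack$tl)
#' @export
render_quadrants <- function(sc, optics = optical_config(), quantize = TRUE) {
  validate_scene(sc)
  H <- sc$canvas_shape[1]; W <- sc$canvas_shape[2]
  Y <- matrix(seq_len(H), H, W)
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  q <- list(tl = matrix(0, H, W), tr = matrix(0, H, W),
            bl = matrix(0, H, W), br = matrix(0, H, W))
  edge_w <- matrix(0, H, W)
  punc_w <- matrix(0, H, W)

  b <- sc$boundaries
  for (i in seq_len(nrow(b))) {
    bi <- b[i, ]
    if (bi$type == "circle") {
      D <- sqrt((Y - bi$cy)^2 + (X - bi$cx)^2)
      prof <- exp(-(D - bi$radius)^2 / (2 * bi$width^2))
      prof[abs(D - bi$radius) > 4 * bi$width] <- 0
      prof <- prof * (bi$amplitude / sum(prof))
      ny <- Y - bi$cy; nx <- X - bi$cx
    } else {
      v <- c(bi$y1 - bi$y0, bi$x1 - bi$x0)
      len2 <- sum(v^2)
      t <- ((Y - bi$y0) * v[1] + (X - bi$x0) * v[2]) / len2
      py <- bi$y0 + t * v[1]; px <- bi$x0 + t * v[2]
      dperp <- sqrt((Y - py)^2 + (X - px)^2)
      prof <- exp(-dperp^2 / (2 * bi$width^2))
      prof[t < 0 | t > 1 | dperp > 4 * bi$width] <- 0
      if (sum(prof) == 0) next
      prof <- prof * (bi$amplitude / sum(prof))
      ny <- matrix(bi$ny, H, W); nx <- matrix(bi$nx, H, W)
    }
    q <- deposit(q, prof, bi$g * (1 - bi$leak), ny, nx)
    edge_w <- edge_w + prof
  }

  p <- sc$puncta
  for (i in seq_len(nrow(p))) {
    pp <- p[i, ]
    D2 <- (Y - pp$cy)^2 + (X - pp$cx)^2
    prof <- exp(-D2 / (2 * pp$radius^2))
    prof[D2 > (4 * pp$radius)^2] <- 0
    prof <- prof * (pp$amplitude / sum(prof))
    if (pp$g > 0) {
      dir <- punctum_direction(pp, b)
      ny <- matrix(dir[1], H, W); nx <- matrix(dir[2], H, W)
    } else {
      ny <- nx <- matrix(0, H, W)
    }
    q <- deposit(q, prof, pp$g, ny, nx)
    punc_w <- punc_w + prof
  }

  bg <- matrix(sc$background_level, H, W)
  if (!is.null(sc$poly_background)) {
    bg <- bg + eval_poly2d(sc$poly_background, H, W)
  }
  q <- lapply(q, function(m) m + bg)

  if (sc$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(sc$seed)
    q <- lapply(q, function(m) {
      m + matrix(stats::rnorm(H * W, 0, sc$noise_sigma), H, W)
    })
  }

  maxval <- 2^optics$bit_depth - 1
  if (quantize) {
    q <- lapply(q, function(m) round(pmin(pmax(m, 0), maxval)))
  }

  stack <- quadrant_stack(q$tl, q$tr, q$bl, q$br,
                          bit_depth = optics$bit_depth)

  edge_mask <- edge_w > 1e-3 * max(edge_w, 0)
  puncta_mask <- punc_w > 1e-3 * max(punc_w, 0) & !edge_mask
  labels <- matrix(0L, H, W)
  circ <- b[b$type == "circle" & b$is_cell, ]
  for (i in seq_len(nrow(circ))) {
    D <- sqrt((Y - circ$cy[i])^2 + (X - circ$cx[i])^2)
    labels[D <= circ$radius[i] + 2 * circ$width[i]] <- i
  }
  per_cell <- per_cell_truth(circ, p)
  list(stack = stack,
       truth = list(edge_mask = edge_mask, puncta_mask = puncta_mask,
                    cell_labels = labels, per_cell = per_cell))
}

# Split a deposit map across quadrant images by anisotropy and normal signs.
# Normal toward TL (ny<0, nx<0) -> directional light under BR illumination.
deposit <- function(q, prof, g_eff, ny, nx) {
  iso <- (1 - g_eff) / 4 * prof
  q$tl <- q$tl + iso; q$tr <- q$tr + iso
  q$bl <- q$bl + iso; q$br <- q$br + iso
  if (g_eff > 0) {
    d <- g_eff * prof
    # pixels whose normal lies exactly on an axis split evenly between the
    # two adjacent quadrants; diagonal pairs stay balanced, so E and QDF
    # identities are unaffected
    f_top <- (ny < 0) + 0.5 * (ny == 0)
    f_left <- (nx < 0) + 0.5 * (nx == 0)
    q$br <- q$br + d * f_top * f_left              # normal -> TL
    q$bl <- q$bl + d * f_top * (1 - f_left)        # normal -> TR
    q$tr <- q$tr + d * (1 - f_top) * f_left        # normal -> BL
    q$tl <- q$tl + d * (1 - f_top) * (1 - f_left)  # normal -> BR
  }
  q
}

punctum_direction <- function(pp, boundaries) {
  if (!is.na(pp$dir_y) && !is.na(pp$dir_x)) return(c(pp$dir_y, pp$dir_x))
  circ <- boundaries[boundaries$type == "circle", ]
  if (!nrow(circ)) {
    stop("anisotropic punctum needs dir_y/dir_x or a circular boundary",
         call. = FALSE)
  }
  d2 <- (circ$cy - pp$cy)^2 + (circ$cx - pp$cx)^2
  k <- which.min(d2)
  dir <- c(pp$cy - circ$cy[k], pp$cx - circ$cx[k])
  if (all(dir == 0)) dir <- c(-1, -1)
  dir
}

# coefficient matrix C: C[i, j] multiplies u^(i-1) * v^(j-1) with u, v the
# column/row coordinates normalized to [-1, 1]
eval_poly2d <- function(coef, H, W) {
  u <- if (W > 1) seq(-1, 1, length.out = W) else 0
  v <- if (H > 1) seq(-1, 1, length.out = H) else 0
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(coef))) {
    for (j in seq_len(ncol(coef))) {
      if (coef[i, j] != 0) {
        out <- out + coef[i, j] * outer(v^(j - 1), u^(i - 1))
      }
    }
  }
  out
}

per_cell_truth <- function(circ, puncta) {
  if (!nrow(circ)) {
    return(tibble::tibble(label = integer(), puncta_total = numeric(),
                          phase_total = numeric()))
  }
  totals <- numeric(nrow(circ))
  if (nrow(puncta)) {
    for (i in seq_len(nrow(puncta))) {
      d <- sqrt((circ$cy - puncta$cy[i])^2 + (circ$cx - puncta$cx[i])^2)
      inside <- which(d <= circ$radius)
      if (length(inside)) totals[inside[1]] <- totals[inside[1]] +
          puncta$amplitude[i]
    }
  }
  tibble::tibble(label = seq_len(nrow(circ)), puncta_total = totals,
                 phase_total = circ$phase_total)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Render the quantitative phase image of a scene
#'
#' Produces the phase channel the segmentation and dry-mass steps consume.
#' Every cell boundary contributes a smooth compact blob whose integrated
#' phase equals its `phase_total` (radian-pixels); the blob's support shrinks
#' and its peak grows as the cell radius shrinks, so rounded cells show
#' higher peak phase at conserved integral. Puncta add small phase bumps
#' whose integral is booked to their containing cell.
#'
#' @param sc A [scene()].
#' @param optics An [optical_config()] (reserved; the phase image is in
#'   radians and needs no camera model).
#' @param noise_sigma Optional Gaussian noise (radians); default noiseless.
#' @param puncta_phase Integrated phase per unit punctum amplitude
#'   (radian-pixels per count); default 0 leaves puncta out of the phase
#'   channel.
#' @return A list with `phase` (matrix, radians) and `per_cell_phase`, a
#'   tibble of exact integrated phase per cell label.
#' @export
render_phase <- function(sc, optics = optical_config(), noise_sigma = 0,
                         puncta_phase = 0) {
  validate_scene(sc)
  H <- sc$canvas_shape[1]; W <- sc$canvas_shape[2]
  Y <- matrix(seq_len(H), H, W)
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  phase <- matrix(0, H, W)
  circ <- sc$boundaries[sc$boundaries$type == "circle" &
                          sc$boundaries$is_cell, ]
  integ <- numeric(nrow(circ))
  for (i in seq_len(nrow(circ))) {
    r_eff <- 0.7 * circ$radius[i]
    D <- sqrt((Y - circ$cy[i])^2 + (X - circ$cx[i])^2)
    prof <- exp(-(D / r_eff)^4)
    prof[D > circ$radius[i]] <- 0   # cell has finite extent
    prof <- prof * (circ$phase_total[i] / sum(prof))
    phase <- phase + prof
    integ[i] <- circ$phase_total[i]
  }
  p <- sc$puncta
  if (puncta_phase > 0 && nrow(p)) {
    for (i in seq_len(nrow(p))) {
      D2 <- (Y - p$cy[i])^2 + (X - p$cx[i])^2
      prof <- exp(-D2 / (2 * p$radius[i]^2))
      prof[D2 > (4 * p$radius[i])^2] <- 0
      tot <- puncta_phase * p$amplitude[i]
      prof <- prof * (tot / sum(prof))
      phase <- phase + prof
      if (nrow(circ)) {
        d <- sqrt((circ$cy - p$cy[i])^2 + (circ$cx - p$cx[i])^2)
        inside <- which(d <= circ$radius)
        if (length(inside)) integ[inside[1]] <- integ[inside[1]] + tot
      }
    }
  }
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(sc$seed + 1L)
    phase <- phase + matrix(stats::rnorm(H * W, 0, noise_sigma), H, W)
  }
  list(phase = phase,
       per_cell_phase = tibble::tibble(label = seq_len(nrow(circ)),
                                       phase_total = integ))
}
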