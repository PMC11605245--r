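#' Quadrant darkfield stack
#'
#' Container for the four co-registered darkfield images of one field of
#' view, captured under top-left, top-right, bottom-left and bottom-right
#' sector illumination.
#'
#' @param tl,tr,bl,br Numeric matrices of identical shape, counts >= 0.
#' @param bit_depth Camera bit depth.
#' @param exposure_ms,gain_db Optional acquisition metadata.
#' @return An object of class `quadrant_stack`.
#' @export
quadrant_stack <- function(tl, tr, bl, br, bit_depth = 16,
                           exposure_ms = NA_real_, gain_db = NA_real_) {
  imgs <- list(tl = tl, tr = tr, bl = bl, br = br)
  dims <- lapply(imgs, dim)
  if (any(!vapply(imgs, is.matrix, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("tl, tr, bl, br must be matrices of identical shape", call. = FALSE)
  }
  if (any(vapply(imgs, function(m) any(m < 0), logical(1)))) {
    stop("quadrant images must be non-negative", call. = FALSE)
  }
  structure(c(imgs, list(bit_depth = as.integer(bit_depth),
                         exposure_ms = exposure_ms, gain_db = gain_db)),
            class = "quadrant_stack")
}

#' @export
print.quadrant_stack <- function(x, ...) {
  cat(sprintf("<quadrant_stack> %dx%d px, %d-bit\n",
              nrow(x$tl), ncol(x$tl), x$bit_depth))
  invisible(x)
}

#' Darkfield, edge, and QDF reconstruction
#'
#' The core image arithmetic. All operations are pixel-wise in double
#' precision:
#' \deqn{DF = TL + TR + BL + BR}
#' \deqn{E = |TL - BR| + |BL - TR|}
#' \deqn{QDF = c \cdot DF - E}
#'
#' Light refracted by a large edge arrives predominantly under one of each
#' diagonally opposed illumination pair, so it survives in `E` and is
#' subtracted; light scattered broadly by small puncta arrives nearly equally
#' under all four and cancels in `E`, so it survives in `QDF`. The scaling
#' factor `c` matches the darkfield edge intensity to `E` before subtraction
#' and is typically between 0.8 and 1.0.
#'
#' `compute_qdf()` keeps signed values; where `E > c * DF` (noise, imperfect
#' calibration) the QDF image goes negative. Set `clip_negative = TRUE` to
#' clip at zero for display; per-cell totals always use the clipped sum (see
#' [per_cell_signals()]).
#'
#' @param stack A [quadrant_stack()].
#' @param c Scaling factor, > 0.
#' @param clip_negative Clip negative QDF values to zero?
#' @return `compute_darkfield()` and `compute_edge()` return a matrix;
#'   `compute_qdf()` returns a `qdf_reconstruction` with elements `df`,
#'   `edge`, `qdf`, `c`, `clip_negative`.
#' @examples
#' s <- quadrant_stack(matrix(4, 8, 8), matrix(4, 8, 8),
#'                     matrix(4, 8, 8), matrix(4, 8, 8))
#' r <- compute_qdf(s, c = 1)
#' all(r$edge == 0)
#' all(r$qdf == r$df)
#' @export
compute_darkfield <- function(stack) {
  stopifnot(inherits(stack, "quadrant_stack"))
  stack$tl + stack$tr + stack$bl + stack$br
}

#' @rdname compute_darkfield
#' @export
compute_edge <- function(stack) {
  stopifnot(inherits(stack, "quadrant_stack"))
  abs(stack$tl - stack$br) + abs(stack$bl - stack$tr)
}

#' @rdname compute_darkfield
#' @export
compute_qdf <- function(stack, c, clip_negative = FALSE) {
  stopifnot(inherits(stack, "quadrant_stack"))
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c <= 0) {
    stop("`c` must be a single positive number", call. = FALSE)
  }
  df <- compute_darkfield(stack)
  e <- compute_edge(stack)
  qdf <- c * df - e
  if (clip_negative) qdf <- pmax(qdf, 0)
  structure(list(df = df, edge = e, qdf = qdf, c = c,
                 clip_negative = clip_negative),
            class = "qdf_reconstruction")
}

#' @export
print.qdf_reconstruction <- function(x, ...) {
  cat(sprintf("<qdf_reconstruction> %dx%d px, c = %.4g%s\n",
              nrow(x$df), ncol(x$df), x$c,
              if (x$clip_negative) ", negatives clipped" else ""))
  cat(sprintf("  DF range [%.4g, %.4g], QDF range [%.4g, %.4g]\n",
              min(x$df), max(x$df), min(x$qdf), max(x$qdf)))
  invisible(x)
}

#' Calibrate the darkfield scaling factor c
#'
#' `c` is system-specific: it matches the darkfield signal at object edges to
#' the edge image before subtraction. This calibration minimizes the sum of
#' squared residuals of `c * DF - E` over a set of edge pixels, giving the
#' closed form `c = sum(DF * E) / sum(DF^2)` on the mask.
#'
#' When no mask is supplied, edge pixels are taken as those where `E` exceeds
#' its 95th percentile among positive-`E` pixels — a practical stand-in for
#' "the edges of segmented objects" when no segmentation is at hand. Supply
#' your own mask for anything quantitative.
#'
#' @param stack A [quadrant_stack()].
#' @param edge_mask Logical matrix selecting edge pixels, or `NULL` for the
#'   default percentile mask.
#' @return A number of class `qdf_calibration`: the fitted `c`, with
#'   attributes `residual_fraction` (edge energy left after subtraction, as a
#'   fraction of the masked edge energy) and `n_pixels`.
#' @examples
#' sc <- scene(c(64, 64),
#'             boundaries = boundary_circle(32, 32, 20, amplitude = 5e4))
#' r <- render_quadrants(sc)
#' calibrate_c(r$stack, r$truth$edge_mask)
#' @export
calibrate_c <- function(stack, edge_mask = NULL) {
  stopifnot(inherits(stack, "quadrant_stack"))
  df <- compute_darkfield(stack)
  e <- compute_edge(stack)
  if (is.null(edge_mask)) {
    pos <- e[e > 0]
    if (!length(pos)) stop("image has no edge signal to calibrate on",
                           call. = FALSE)
    edge_mask <- e > stats::quantile(pos, 0.95)
  }
  if (!is.logical(edge_mask) || !identical(dim(edge_mask), dim(df))) {
    stop("edge_mask must be a logical matrix matching the stack shape",
         call. = FALSE)
  }
  if (!any(edge_mask)) stop("edge_mask is empty", call. = FALSE)
  dfm <- df[edge_mask]; em <- e[edge_mask]
  if (all(dfm == 0)) stop("DF is zero on every masked pixel", call. = FALSE)
  c_hat <- sum(dfm * em) / sum(dfm^2)
  resid <- sum((c_hat * dfm - em)^2)
  structure(c_hat,
            residual_fraction = if (sum(em^2) > 0) resid / sum(em^2) else 0,
            n_pixels = sum(edge_mask),
            class = "qdf_calibration")
}

#' @export
print.qdf_calibration <- function(x, ...) {
  cat(sprintf("c = %.4f  (residual edge energy %.2g%%, %d px)\n",
              unclass(x)[1], 100 * attr(x, "residual_fraction"),
              attr(x, "n_pixels")))
  invisible(x)
}
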