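#' Camera bit rescaling
#'
#' Scales raw counts down by an integer divisor (16-bit to 12-bit by
#' dividing by 16) and rounds to the nearest integer. Ties (x.5) round away
#' from zero on these non-negative counts, matching common camera-pipeline
#' behaviour; base R's `round()` would round half to even.
#'
#' @param image Non-negative numeric matrix of integer counts.
#' @param divisor Integer divisor >= 1; default 16.
#' @return Integer-valued matrix.
#' @examples
#' rescale_bit_depth(matrix(65535, 1, 1))  # 4096
#' @export
rescale_bit_depth <- function(image, divisor = 16L) {
  stopifnot(is.numeric(image), divisor >= 1)
  if (any(image < 0)) stop("expected non-negative counts", call. = FALSE)
  floor(image / divisor + 0.5)
}

#' Empty-reference background subtraction
#'
#' Subtracts the darkfield image of an empty reference position, removing
#' stray-light background. The difference is kept in floating point and not
#' clipped: negative residuals carry information the later polynomial fit
#' needs.
#'
#' @param image,reference Numeric matrices of identical shape.
#' @return Matrix of differences.
#' @export
subtract_reference <- function(image, reference) {
  if (!identical(dim(image), dim(reference))) {
    stop("image and reference shapes differ", call. = FALSE)
  }
  image - reference
}

#' Masked polynomial background model
#'
#' Fits a bivariate polynomial of total degree `order` (default 8, 45 terms)
#' to the background — the pixels *outside* the object mask — by least
#' squares over image coordinates normalized to \[-1, 1\]^2 for
#' conditioning. Object pixels never enter the fit, so bright cells cannot
#' bias the background estimate. `remove_background()` evaluates the surface
#' everywhere (objects included) and subtracts it.
#'
#' When the background has more than `max_fit_pixels` pixels, a deterministic
#' uniform subsample is used: the fit is heavily over-determined and the
#' surface smooth, so subsampling changes nothing material.
#'
#' @param image Numeric matrix.
#' @param object_mask Logical matrix, `TRUE` on object (excluded) pixels, or
#'   `NULL` for no objects.
#' @param order Total polynomial degree, default 8.
#' @param max_fit_pixels Cap on background pixels entering the least squares.
#' @return A `background_model`: list with `coefficients`, `order`,
#'   `residual_rms` (on fit pixels), `fit_mask`, `dim`.
#' @examples
#' img <- outer(seq(-1, 1, length.out = 32), seq(-1, 1, length.out = 32),
#'              function(y, x) 100 + 20 * x + 10 * y^2)
#' m <- fit_background(img)
#' m$residual_rms < 1e-9
#' @export
fit_background <- function(image, object_mask = NULL, order = 8,
                           max_fit_pixels = 1e5) {
  stopifnot(is.matrix(image), order >= 0)
  H <- nrow(image); W <- ncol(image)
  if (is.null(object_mask)) object_mask <- matrix(FALSE, H, W)
  if (!identical(dim(object_mask), dim(image))) {
    stop("object_mask shape differs from image", call. = FALSE)
  }
  n_terms <- (order + 1) * (order + 2) / 2
  bg_idx <- which(!object_mask)
  if (length(bg_idx) < n_terms) {
    stop(sprintf("need at least %d background pixels for an order-%d fit, have %d",
                 n_terms, order, length(bg_idx)), call. = FALSE)
  }
  if (length(bg_idx) > max_fit_pixels) {
    # deterministic uniform thinning: fit is over-determined and smooth
    bg_idx <- bg_idx[seq(1L, length(bg_idx),
                         length.out = as.integer(max_fit_pixels))]
  }
  v <- if (H > 1) seq(-1, 1, length.out = H) else 0   # row coord
  u <- if (W > 1) seq(-1, 1, length.out = W) else 0   # col coord
  rows <- ((bg_idx - 1L) %% H) + 1L
  cols <- ((bg_idx - 1L) %/% H) + 1L
  A <- poly2d_design(v[rows], u[cols], order)
  fit <- stats::lsfit(A, image[bg_idx], intercept = FALSE)
  coef <- fit$coefficients
  rms <- sqrt(mean(fit$residuals^2))
  structure(list(coefficients = coef, order = order, residual_rms = rms,
                 fit_mask = !object_mask, dim = c(H, W)),
            class = "background_model")
}

# design matrix of all monomials y^i x^j with i + j <= order
poly2d_design <- function(y, x, order) {
  cols <- list()
  for (i in 0:order) {
    for (j in 0:(order - i)) {
      cols[[length(cols) + 1L]] <- y^i * x^j
    }
  }
  do.call(cbind, cols)
}

#' @rdname fit_background
#' @param model A `background_model` from `fit_background()`.
#' @export
remove_background <- function(image, model) {
  stopifnot(inherits(model, "background_model"))
  if (!identical(dim(image), as.integer(model$dim)) &&
      !identical(dim(image), model$dim)) {
    stop("model was fitted on a different image shape", call. = FALSE)
  }
  image - evaluate_background(model)
}

#' @rdname fit_background
#' @export
evaluate_background <- function(model) {
  H <- model$dim[1]; W <- model$dim[2]
  v <- if (H > 1) seq(-1, 1, length.out = H) else 0
  u <- if (W > 1) seq(-1, 1, length.out = W) else 0
  grid_y <- rep(v, times = W)
  grid_x <- rep(u, each = H)
  A <- poly2d_design(grid_y, grid_x, model$order)
  matrix(A %*% model$coefficients, H, W)
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> order %d, %d terms, residual RMS %.4g\n",
              x$order, length(x$coefficients), x$residual_rms))
  invisible(x)
}

#' Standard preprocessing chain for a quadrant stack
#'
#' Applies, in order: bit rescaling (optional), empty-reference subtraction
#' (optional), and masked polynomial background removal on each quadrant
#' image (optional). Each step can be toggled independently. Negative values
#' from the subtractions are preserved; downstream reconstruction operates in
#' floating point.
#'
#' @param stack A [quadrant_stack()].
#' @param reference Optional reference [quadrant_stack()] from an empty
#'   field of view.
#' @param object_mask Optional logical matrix of object pixels for the
#'   polynomial fit.
#' @param bit_divisor Divisor for [rescale_bit_depth()], or `NULL` to skip.
#' @param poly_order Polynomial order for background removal, or `NULL` to
#'   skip.
#' @return A new `quadrant_stack` (values may be negative after background
#'   removal; the container check is relaxed via an offset-free rebuild).
#' @export
preprocess_stack <- function(stack, reference = NULL, object_mask = NULL,
                             bit_divisor = NULL, poly_order = 8) {
  stopifnot(inherits(stack, "quadrant_stack"))
  imgs <- list(tl = stack$tl, tr = stack$tr, bl = stack$bl, br = stack$br)
  if (!is.null(bit_divisor)) {
    imgs <- lapply(imgs, rescale_bit_depth, divisor = bit_divisor)
  }
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "quadrant_stack"))
    ref <- list(tl = reference$tl, tr = reference$tr,
                bl = reference$bl, br = reference$br)
    if (!is.null(bit_divisor)) {
      ref <- lapply(ref, rescale_bit_depth, divisor = bit_divisor)
    }
    imgs <- purrr::map2(imgs, ref, subtract_reference)
  }
  if (!is.null(poly_order)) {
    imgs <- lapply(imgs, function(m) {
      remove_background(m, fit_background(m, object_mask, order = poly_order))
    })
  }
  out <- stack
  out$tl <- imgs$tl; out$tr <- imgs$tr; out$bl <- imgs$bl; out$br <- imgs$br
  out
}
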