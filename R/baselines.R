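#' Digital edge-detection baseline
#'
#' The digital counterpart the optical edge removal is compared against:
#' Gaussian blur (sigma 2 px by default), a Sobel or Canny gradient
#' detector, and morphological dilation of the binary mask with a disc.
#' Thresholds are expressed as fractions of the 99th percentile of the
#' gradient magnitude so parameters are comparable across images.
#'
#' @param gaussian_sigma_px Blur sigma, pixels (>= 0; 0 skips the blur).
#' @param detector `"sobel"` or `"canny"`.
#' @param threshold For Sobel a single fraction; for Canny a `(low, high)`
#'   pair of fractions of the gradient-magnitude 99th percentile.
#' @param dilation_radius_px Disc radius for mask dilation (0 = none).
#' @return An `edge_detect_config` list.
#' @export
edge_detect_config <- function(gaussian_sigma_px = 2,
                               detector = c("sobel", "canny"),
                               threshold = 0.5,
                               dilation_radius_px = 2L) {
  detector <- match.arg(detector)
  stopifnot(gaussian_sigma_px >= 0, dilation_radius_px >= 0)
  if (detector == "sobel") {
    if (length(threshold) != 1 || threshold < 0) {
      stop("sobel threshold must be a single non-negative fraction",
           call. = FALSE)
    }
  } else {
    if (length(threshold) != 2 || any(threshold < 0) ||
        threshold[1] > threshold[2]) {
      stop("canny threshold must be (low, high) with low <= high",
           call. = FALSE)
    }
  }
  structure(list(gaussian_sigma_px = gaussian_sigma_px, detector = detector,
                 threshold = threshold,
                 dilation_radius_px = as.integer(dilation_radius_px)),
            class = "edge_detect_config")
}

sobel_gradient <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- EBImage::filter2(image, kx)
  gy <- EBImage::filter2(image, ky)
  list(mag = sqrt(gx^2 + gy^2), gx = gx, gy = gy)
}

#' @rdname edge_detect_config
#' @param image Grayscale matrix (typically the darkfield image).
#' @param cfg An `edge_detect_config`.
#' @return `digital_edge_mask()` returns a logical matrix.
#' @export
digital_edge_mask <- function(image, cfg = edge_detect_config()) {
  stopifnot(is.matrix(image), inherits(cfg, "edge_detect_config"))
  sm <- if (cfg$gaussian_sigma_px > 0) {
    EBImage::gblur(image, sigma = cfg$gaussian_sigma_px)
  } else image
  g <- sobel_gradient(sm)
  ref <- stats::quantile(g$mag, 0.99, names = FALSE)
  if (ref == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  mask <- if (cfg$detector == "sobel") {
    g$mag > cfg$threshold * ref
  } else {
    canny_mask(g, low = cfg$threshold[1] * ref, high = cfg$threshold[2] * ref)
  }
  if (cfg$dilation_radius_px > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * cfg$dilation_radius_px + 1,
                                shape = "disc")
    mask <- EBImage::dilate(mask + 0, brush) > 0
  }
  mask
}

# Canny: non-maximum suppression along the quantized gradient direction,
# then hysteresis (strong pixels seed; weak pixels kept if connected).
canny_mask <- function(g, low, high) {
  mag <- g$mag
  H <- nrow(mag); W <- ncol(mag)
  ang <- atan2(g$gy, g$gx)                     # -pi..pi
  sector <- (round(ang / (pi / 4)) %% 4)       # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mag
  keep <- matrix(FALSE, H, W)
  for (s in 0:3) {
    d <- off[[s + 1]]
    n1 <- pad[2:(H + 1) + d[1], 2:(W + 1) + d[2]]
    n2 <- pad[2:(H + 1) - d[1], 2:(W + 1) - d[2]]
    sel <- sector == s
    keep[sel] <- mag[sel] >= n1[sel] & mag[sel] >= n2[sel]
  }
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(matrix(FALSE, H, W))
  # hysteresis via connected components of the weak mask
  cc <- EBImage::bwlabel(weak + 0)
  good <- unique(cc[strong])
  good <- good[good > 0]
  matrix(cc %in% good, H, W) & weak
}

#' Edge-suppression scoring against ground truth
#'
#' Quantifies how well a processed image removes edge signal while keeping
#' puncta signal, relative to the darkfield image:
#' `edge_residual_fraction` = sum of the signal over true edge pixels
#' divided by the darkfield sum there; `puncta_retention_fraction` = sum
#' over true puncta pixels divided by the `c`-scaled darkfield sum there.
#' An ideal separator scores (0, 1).
#'
#' @param signal Processed image to score (e.g. QDF, or DF with a digital
#'   edge mask zeroed).
#' @param df Darkfield image (reference).
#' @param edge_mask_truth,puncta_mask_truth Disjoint logical ground-truth
#'   masks.
#' @param c Scaling factor used for the puncta reference (`c * DF`).
#' @return Tibble with `edge_residual_fraction`, `puncta_retention_fraction`.
#' @export
edge_suppression_score <- function(signal, df, edge_mask_truth,
                                   puncta_mask_truth, c = 1) {
  stopifnot(identical(dim(signal), dim(df)))
  if (!any(edge_mask_truth) || !any(puncta_mask_truth)) {
    stop("ground-truth masks must be nonempty", call. = FALSE)
  }
  if (any(edge_mask_truth & puncta_mask_truth)) {
    stop("edge and puncta truth masks must be disjoint", call. = FALSE)
  }
  tibble::tibble(
    edge_residual_fraction = sum(signal[edge_mask_truth]) /
      sum(df[edge_mask_truth]),
    puncta_retention_fraction = sum(signal[puncta_mask_truth]) /
      (c * sum(df[puncta_mask_truth]))
  )
}

#' Parameter sweep of the digital baseline
#'
#' For every (threshold, dilation) combination, builds the digital edge mask
#' on the darkfield image, zeroes the masked pixels, and scores the result
#' with [edge_suppression_score()]. The best row maximizes puncta retention
#' subject to an edge residual no worse than `target_edge_residual` (QDF's,
#' when comparing).
#'
#' @param df Darkfield image.
#' @param edge_mask_truth,puncta_mask_truth Ground-truth masks.
#' @param threshold_grid For Sobel a numeric vector; for Canny a list of
#'   `(low, high)` pairs.
#' @param dilation_grid Integer vector of dilation radii.
#' @param detector `"sobel"` or `"canny"`.
#' @param gaussian_sigma_px Blur sigma.
#' @param c Scaling factor for the puncta reference.
#' @param target_edge_residual Constraint defining the "best" row.
#' @return Tibble, one row per grid point: threshold(s), dilation, mask
#'   area, both scores, and `best` flagging the winning row (all `FALSE` if
#'   no row satisfies the constraint).
#' @export
sweep_baseline <- function(df, edge_mask_truth, puncta_mask_truth,
                           threshold_grid, dilation_grid,
                           detector = c("sobel", "canny"),
                           gaussian_sigma_px = 2, c = 1,
                           target_edge_residual = 0.1) {
  detector <- match.arg(detector)
  stopifnot(length(threshold_grid) > 0, length(dilation_grid) > 0)
  if (detector == "sobel") threshold_grid <- as.list(threshold_grid)
  grid <- tidyr::expand_grid(ti = seq_along(threshold_grid),
                             dilation = as.integer(dilation_grid))
  rows <- purrr::pmap_dfr(grid, function(ti, dilation) {
    thr <- threshold_grid[[ti]]
    cfg <- edge_detect_config(gaussian_sigma_px = gaussian_sigma_px,
                              detector = detector, threshold = thr,
                              dilation_radius_px = dilation)
    mask <- digital_edge_mask(df, cfg)
    cleaned <- df
    cleaned[mask] <- 0
    sc <- edge_suppression_score(cleaned, df, edge_mask_truth,
                                 puncta_mask_truth, c = c)
    tibble::tibble(
      threshold_low = thr[1],
      threshold_high = thr[length(thr)],
      dilation = dilation,
      mask_area = sum(mask),
      edge_residual_fraction = sc$edge_residual_fraction,
      puncta_retention_fraction = sc$puncta_retention_fraction
    )
  })
  ok <- rows$edge_residual_fraction <= target_edge_residual
  rows$best <- FALSE
  if (any(ok)) {
    best_i <- which(ok)[which.max(rows$puncta_retention_fraction[ok])]
    rows$best[best_i] <- TRUE
  }
  rows
}
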