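#' Watershed segmentation of single cells from a phase image
#'
#' Segments a background-corrected quantitative phase image into single-cell
#' labels. The phase landscape is Gaussian-smoothed, thresholded into a
#' foreground mask, and split by an intensity watershed so that touching
#' cells separated by a phase valley get distinct labels. Objects smaller
#' than `min_area_px` are dropped and labels relabelled contiguously from 1.
#'
#' @param phase Numeric matrix, phase in radians, background-corrected.
#' @param smooth_sigma_px Gaussian smoothing sigma, pixels (default 2).
#' @param phase_threshold Foreground threshold on the smoothed phase,
#'   radians (default 0.2).
#' @param tolerance Watershed merge tolerance on the smoothed phase
#'   (minimum peak prominence, radians).
#' @param min_peak_sep_px Minimum separation of watershed seeds, pixels.
#' @param min_area_px Minimum object area kept, pixels.
#' @return Integer label matrix; 0 is background, labels contiguous from 1.
#'   An all-background image yields an all-zero matrix.
#' @export
segment_cells <- function(phase, smooth_sigma_px = 2, phase_threshold = 0.2,
                          tolerance = 0.05, min_peak_sep_px = 10,
                          min_area_px = 50) {
  stopifnot(is.matrix(phase))
  sm <- EBImage::gblur(phase, sigma = smooth_sigma_px)
  mask <- sm > phase_threshold
  if (!any(mask)) return(matrix(0L, nrow(phase), ncol(phase)))
  ws <- EBImage::watershed(ifelse(mask, sm, 0), tolerance = tolerance,
                           ext = max(1L, round(min_peak_sep_px / 2)))
  lab <- matrix(as.integer(ws), nrow(phase), ncol(phase))
  # drop small objects, relabel 1..n
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  lab
}

#' Centroids of a label image
#'
#' @param label_image Integer label matrix (0 = background).
#' @return Tibble with `label`, `y`, `x`, `area_px`.
#' @export
label_centroids <- function(label_image) {
  idx <- which(label_image > 0L)
  if (!length(idx)) {
    return(tibble::tibble(label = integer(), y = numeric(), x = numeric(),
                          area_px = integer()))
  }
  H <- nrow(label_image)
  lab <- label_image[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  tibble::tibble(label = lab, y = rows, x = cols) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(y = mean(.data$y), x = mean(.data$x),
                     area_px = dplyr::n(), .groups = "drop")
}

#' Link cells across frames (Crocker-Grier style)
#'
#' Frame-to-frame linking that minimizes the total squared centroid
#' displacement, subject to a maximum displacement per link, with short-gap
#' memory: a track that misses up to `memory` consecutive frames can be
#' resumed. For small per-frame candidate sets the assignment is solved
#' exactly by branch-and-bound enumeration; larger sets fall back to greedy
#' nearest-neighbour linking. Cells that cannot be linked start new tracks.
#'
#' @param records Tibble with at least `frame`, `label`, `y`, `x` (one row
#'   per cell per frame).
#' @param max_disp_px Maximum allowed centroid displacement per frame gap.
#' @param memory Number of consecutive missing frames a track may survive.
#' @param exact_max Largest candidate-set size solved by exact enumeration.
#' @return `records` with a `track_id` column (stable over a track).
#' @export
track_cells <- function(records, max_disp_px = 20, memory = 1L,
                        exact_max = 9L) {
  stopifnot(all(c("frame", "label", "y", "x") %in% names(records)))
  records <- dplyr::arrange(records, .data$frame, .data$label)
  records$track_id <- NA_integer_
  frames <- sort(unique(records$frame))
  next_id <- 1L
  # active tracks: id, last y/x, last frame
  act <- tibble::tibble(track_id = integer(), y = numeric(), x = numeric(),
                        frame = numeric())
  for (f in frames) {
    cur <- which(records$frame == f)
    n_cur <- length(cur)
    act <- act[f - act$frame <= memory + 1L, , drop = FALSE]
    assigned <- rep(NA_integer_, n_cur)   # index into act
    if (nrow(act) && n_cur) {
      cost <- outer(seq_len(n_cur), seq_len(nrow(act)),
                    function(i, j) (records$y[cur[i]] - act$y[j])^2 +
                      (records$x[cur[i]] - act$x[j])^2)
      cost[cost > max_disp_px^2] <- Inf
      assigned <- if (n_cur <= exact_max && nrow(act) <= exact_max) {
        assign_exact(cost)
      } else {
        assign_greedy(cost)
      }
    }
    for (i in seq_len(n_cur)) {
      if (!is.na(assigned[i])) {
        id <- act$track_id[assigned[i]]
      } else {
        id <- next_id; next_id <- next_id + 1L
      }
      records$track_id[cur[i]] <- id
    }
    if (n_cur) {
      upd <- tibble::tibble(track_id = records$track_id[cur],
                            y = records$y[cur], x = records$x[cur],
                            frame = f)
      act <- dplyr::bind_rows(act[!(act$track_id %in% upd$track_id), ], upd)
    }
  }
  records
}

# exact min-cost assignment allowing unassigned rows; Inf = forbidden link.
# maximizes number of links, then minimizes total cost; branch and bound.
assign_exact <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(links = -1L, cost = Inf, sol = rep(NA_integer_, n))
  sol <- rep(NA_integer_, n)
  used <- rep(FALSE, m)
  rec <- function(i, links, acc) {
    if (i > n) {
      if (links > best$links ||
          (links == best$links && acc < best$cost)) {
        best <<- list(links = links, cost = acc, sol = sol)
      }
      return(invisible())
    }
    # upper bound on achievable links from here
    if (links + (n - i + 1L) < best$links) return(invisible())
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j])) {
        used[j] <<- TRUE; sol[i] <<- j
        rec(i + 1L, links + 1L, acc + cost[i, j])
        used[j] <<- FALSE; sol[i] <<- NA_integer_
      }
    }
    rec(i + 1L, links, acc)   # leave row i unassigned
  }
  rec(1L, 0L, 0)
  best$sol
}

assign_greedy <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  sol <- rep(NA_integer_, n)
  repeat {
    k <- which.min(cost)
    if (!length(k) || !is.finite(cost[k])) break
    i <- ((k - 1L) %% n) + 1L
    j <- ((k - 1L) %/% n) + 1L
    sol[i] <- j
    cost[i, ] <- Inf
    cost[, j] <- Inf
  }
  sol
}

#' Per-cell dry mass from integrated phase
#'
#' Converts integrated phase to dry mass with the standard QPI relation
#' `m = sum(phi) * (lambda / 2 pi) * A_px / alpha`, where `phi` is the phase
#' in radians, `A_px` the pixel area, and `alpha` the specific refractive
#' increment (default 1.8e-4 m^3/kg). Mass is reported in picograms.
#'
#' @param phase Phase image, radians.
#' @param label_image Integer label matrix.
#' @param optics An [optical_config()] (wavelength, pixel size, alpha).
#' @return Tibble with `label`, `area_px`, `area_um2`, `phase_sum`,
#'   `dry_mass_pg`, `mass_per_area_pg_per_um2`.
#' @export
compute_dry_mass <- function(phase, label_image, optics = optical_config()) {
  stopifnot(is.matrix(phase), identical(dim(phase), dim(label_image)))
  if (is.null(optics$wavelength_nm) || is.null(optics$pixel_size_um)) {
    stop("optics must provide wavelength and pixel size", call. = FALSE)
  }
  idx <- which(label_image > 0L)
  if (!length(idx)) {
    return(tibble::tibble(label = integer(), area_px = integer(),
                          area_um2 = numeric(), phase_sum = numeric(),
                          dry_mass_pg = numeric(),
                          mass_per_area_pg_per_um2 = numeric()))
  }
  lambda_m <- optics$wavelength_nm * 1e-9
  px_area_m2 <- (optics$pixel_size_um * 1e-6)^2
  alpha <- optics$refractive_increment_m3_per_kg
  kg_to_pg <- 1e15
  tibble::tibble(label = label_image[idx], phi = phase[idx]) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(area_px = dplyr::n(), phase_sum = sum(.data$phi),
                     .groups = "drop") |>
    dplyr::mutate(
      area_um2 = .data$area_px * optics$pixel_size_um^2,
      dry_mass_pg = .data$phase_sum * (lambda_m / (2 * pi)) * px_area_m2 /
        alpha * kg_to_pg,
      mass_per_area_pg_per_um2 = .data$dry_mass_pg / .data$area_um2
    ) |>
    dplyr::select("label", "area_px", "area_um2", "phase_sum",
                  "dry_mass_pg", "mass_per_area_pg_per_um2")
}

#' Per-cell darkfield and QDF totals
#'
#' Sums the darkfield and QDF signal over each cell label. QDF totals clip
#' negative pixels at zero first (negative values are calibration/noise
#' residuals, not puncta signal). When a phase image and optics are given,
#' dry mass and the mass-normalized signals are added.
#'
#' @param label_image Integer label matrix.
#' @param df,qdf Darkfield and QDF images (matrices, same shape as labels).
#' @param phase Optional phase image for dry mass.
#' @param optics An [optical_config()], needed with `phase`.
#' @param frame Frame index stored in the output (default 1).
#' @return A tibble of cell records: `frame`, `label`, `area_px`,
#'   `total_df`, `total_qdf`, and with phase also `dry_mass_pg`,
#'   `mass_per_area_pg_per_um2`, `qdf_per_mass`, `df_per_mass`,
#'   `mean_phase`.
#' @export
per_cell_signals <- function(label_image, df, qdf, phase = NULL,
                             optics = optical_config(), frame = 1L) {
  stopifnot(identical(dim(label_image), dim(df)),
            identical(dim(label_image), dim(qdf)))
  cent <- label_centroids(label_image)
  idx <- which(label_image > 0L)
  base <- tibble::tibble(label = label_image[idx], df = df[idx],
                         qdf = pmax(qdf[idx], 0)) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(total_df = sum(.data$df), total_qdf = sum(.data$qdf),
                     .groups = "drop")
  out <- dplyr::left_join(cent, base, by = "label") |>
    dplyr::mutate(frame = as.integer(frame), .before = 1)
  if (!is.null(phase)) {
    stopifnot(identical(dim(phase), dim(label_image)))
    mass <- compute_dry_mass(phase, label_image, optics)
    mean_phase <- tibble::tibble(label = label_image[idx],
                                 phi = phase[idx]) |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(mean_phase = mean(.data$phi), .groups = "drop")
    out <- out |>
      dplyr::left_join(dplyr::select(mass, -"area_px"), by = "label") |>
      dplyr::left_join(mean_phase, by = "label") |>
      dplyr::mutate(
        qdf_per_mass = .data$total_qdf / .data$dry_mass_pg,
        df_per_mass = .data$total_df / .data$dry_mass_pg
      )
  }
  out
}

#' Debris filtering
#'
#' Flags records that fail any of the debris criteria: area bounds, minimum
#' track length, and minimum per-cell averages of phase, darkfield and QDF.
#' Records are flagged, never deleted; a summary of flag counts is messaged.
#'
#' @param records Cell-record tibble (from [per_cell_signals()], tracked).
#' @param min_area_px,max_area_px Area bounds, pixels.
#' @param min_track_len Minimum number of frames in the record's track.
#' @param min_mean_phase Minimum per-cell mean phase, radians.
#' @param min_mean_df,min_mean_qdf Minimum per-cell mean DF / QDF counts
#'   (total over area).
#' @return `records` with logical `debris` and character `debris_reason`.
#' @export
filter_debris <- function(records,
                          min_area_px = 0, max_area_px = Inf,
                          min_track_len = 0,
                          min_mean_phase = 0,
                          min_mean_df = 0, min_mean_qdf = 0) {
  r <- records
  if (!"track_id" %in% names(r)) r$track_id <- r$label
  track_len <- r |>
    dplyr::count(.data$track_id, name = "track_len")
  r <- dplyr::left_join(r, track_len, by = "track_id")
  mean_phase <- if ("mean_phase" %in% names(r)) r$mean_phase else Inf
  fails <- tibble::tibble(
    area_small = r$area_px < min_area_px,
    area_large = r$area_px > max_area_px,
    short_track = r$track_len < min_track_len,
    low_phase = mean_phase < min_mean_phase,
    low_df = r$total_df / r$area_px < min_mean_df,
    low_qdf = r$total_qdf / r$area_px < min_mean_qdf
  )
  reason <- apply(fails, 1, function(row) {
    paste(names(fails)[which(row)], collapse = ",")
  })
  r$debris <- rowSums(fails) > 0
  r$debris_reason <- ifelse(r$debris, reason, "")
  n_flag <- sum(r$debris)
  message(sprintf("filter_debris: flagged %d of %d records", n_flag, nrow(r)))
  r
}

#' Puncta signal-to-noise ratio of a QDF image
#'
#' The puncta signal in each cell is the mean QDF over the pixels of that
#' cell that exceed a threshold of 4x the 99th percentile of the background
#' QDF; the noise level is the standard deviation of the background outside
#' the (dilated) cell masks. Per-cell SNR = signal / noise, reported as
#' mean +/- sd over cells.
#'
#' The background region defaults to all pixels outside the cell labels
#' dilated by 3 px, excluding a 5-px image border.
#'
#' @param qdf QDF image (matrix).
#' @param label_image Integer cell label matrix.
#' @param background_region Optional logical matrix; `NULL` for the default.
#' @param dilate_px Dilation radius applied to labels before excluding them
#'   from the background.
#' @param border_px Image border excluded from the background.
#' @return An `snr_report`: list with `threshold`, `noise_sigma`,
#'   `per_cell`, a tibble (`label`, `n_pixels`, `signal`, `snr`), `mean`,
#'   `sd`.
#' @export
compute_snr <- function(qdf, label_image, background_region = NULL,
                        dilate_px = 3, border_px = 5) {
  stopifnot(identical(dim(qdf), dim(label_image)))
  H <- nrow(qdf); W <- ncol(qdf)
  if (is.null(background_region)) {
    fg <- label_image > 0L
    if (any(fg) && dilate_px > 0) {
      brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
      fg <- EBImage::dilate(fg, brush) > 0
    }
    background_region <- !fg
    if (border_px > 0 && H > 2 * border_px && W > 2 * border_px) {
      background_region[c(seq_len(border_px), (H - border_px + 1):H), ] <- FALSE
      background_region[, c(seq_len(border_px), (W - border_px + 1):W)] <- FALSE
    }
  }
  bg <- qdf[background_region]
  if (!length(bg)) stop("background region is empty", call. = FALSE)
  noise_sigma <- stats::sd(bg)
  if (!is.finite(noise_sigma) || noise_sigma == 0) {
    stop("background has zero variance; SNR undefined", call. = FALSE)
  }
  threshold <- 4 * stats::quantile(bg, 0.99, names = FALSE)
  labs <- sort(unique(label_image[label_image > 0L]))
  per_cell <- purrr::map_dfr(labs, function(l) {
    sel <- label_image == l & qdf > threshold
    n <- sum(sel)
    signal <- if (n > 0) mean(qdf[sel]) else 0
    tibble::tibble(label = l, n_pixels = n, signal = signal,
                   snr = signal / noise_sigma)
  })
  structure(list(threshold = threshold, noise_sigma = noise_sigma,
                 per_cell = per_cell,
                 mean = if (nrow(per_cell)) mean(per_cell$snr) else NA_real_,
                 sd = if (nrow(per_cell) > 1) stats::sd(per_cell$snr) else
                   NA_real_),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> threshold %.4g, noise sigma %.4g\n",
              x$threshold, x$noise_sigma))
  cat(sprintf("  %d cells, SNR %.3g +/- %.3g\n", nrow(x$per_cell),
              x$mean, x$sd))
  invisible(x)
}
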