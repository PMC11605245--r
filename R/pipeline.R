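#' Materialize a demo phantom dataset on disk
#'
#' Writes one of the built-in phantom suites in the on-disk layout
#' [run_pipeline()] consumes: `<pos>/<frame>/{TL,TR,BL,BR}.tif` plus
#' `phase.tif`, ground-truth label TIFFs and a JSON sidecar per frame.
#'
#' * `"beads"`: bead phantoms including a clean bead and an "imperfect"
#'   bead carrying an internal punctum.
#' * `"shape_change"`: one cell rounding up over several frames with
#'   conserved puncta content.
#' * `"two_populations"`: two cell populations differing 3x in puncta
#'   density (positions `pop1/`, `pop2/`).
#'
#' @param name One of `"beads"`, `"shape_change"`, `"two_populations"`.
#' @param out_dir Output directory (created).
#' @param seed RNG seed.
#' @param n_cells Cells per population (two_populations only).
#' @return The dataset directory, invisibly.
#' @export
demo_datasets <- function(name, out_dir, seed = 1L, n_cells = 50L) {
  choices <- c("beads", "shape_change", "two_populations")
  if (!name %in% choices) {
    stop("unknown dataset; options: ", paste(choices, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  optics <- optical_config()
  write_frame <- function(sc, pos, frame) {
    d <- file.path(out_dir, pos, sprintf("%03d", frame))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    r <- render_quadrants(sc, optics)
    for (qn in c("TL", "TR", "BL", "BR")) {
      img <- r$stack[[tolower(qn)]]
      tiff::writeTIFF(img / (2^16 - 1), file.path(d, paste0(qn, ".tif")),
                      bits.per.sample = 16)
    }
    ph <- render_phase(sc, optics)
    write_float_tiff(ph$phase, file.path(d, "phase.tif"))
    write_label_tiff(r$truth$cell_labels, file.path(d, "labels_truth.tif"))
    scene_to_json(sc, file.path(d, "scene.json"))
    jsonlite::write_json(
      list(per_cell = r$truth$per_cell, per_cell_phase = ph$per_cell_phase),
      file.path(d, "truth.json"), digits = NA)
    invisible(NULL)
  }
  if (name == "beads") {
    clean <- scene(c(96, 96),
                   boundaries = boundary_circle(48, 48, 20, amplitude = 4e4,
                                                g = 0.9, is_cell = FALSE),
                   background_level = 30, noise_sigma = 2, seed = seed)
    imperfect <- scene(c(96, 96),
                       boundaries = boundary_circle(48, 48, 20,
                                                    amplitude = 4e4,
                                                    g = 0.9,
                                                    is_cell = FALSE),
                       puncta = punctum(44, 52, amplitude = 4e3,
                                        radius = 1.5),
                       background_level = 30, noise_sigma = 2,
                       seed = seed + 1L)
    write_frame(clean, "bead_clean", 1L)
    write_frame(imperfect, "bead_imperfect", 1L)
  } else if (name == "shape_change") {
    base <- shape_change_base(seed)
    seq_ <- make_shape_sequence(base, n_frames = 5,
                                shape_range = c(0.1, 0.9), seed = seed)
    for (k in seq_along(seq_$frames)) write_frame(seq_$frames[[k]], "cell", k)
  } else {
    pops <- list(pop1 = make_population(n_cells, 0.01, seed = seed),
                 pop2 = make_population(n_cells, 0.03, seed = seed + 1000L))
    for (pn in names(pops)) {
      for (i in seq_along(pops[[pn]])) {
        write_frame(pops[[pn]][[i]], file.path(pn, sprintf("cell%03d", i)), 1L)
      }
    }
  }
  invisible(out_dir)
}

# default single-cell scene for the shape-change experiment: edge and
# puncta totals comparable, as in cells where edge and internal darkfield
# signal are of the same order
shape_change_base <- function(seed = 1L) {
  set.seed(seed)
  n_p <- 24
  rr <- 16 * sqrt(stats::runif(n_p))
  th <- stats::runif(n_p, 0, 2 * pi)
  scene(c(128, 128),
        boundaries = boundary_circle(64, 64, 26, amplitude = 12000,
                                     g = 0.9, phase_total = 1200),
        puncta = punctum(cy = 64 + rr * sin(th), cx = 64 + rr * cos(th),
                         amplitude = 15000 / n_p, radius = 1.2, g = 0),
        background_level = 0, noise_sigma = 0, seed = seed)
}

#' Run the end-to-end pipeline on a dataset directory
#'
#' For every position/frame under `input_dir` (layout
#' `<pos>/<frame>/{TL,TR,BL,BR}.tif` plus optional `phase.tif`): load the
#' quadrant stack, preprocess, reconstruct DF/E/QDF, segment (from phase, or
#' use `labels_truth.tif` when `labels = "truth"`), track cells across
#' frames within each position, quantify per-cell signals, and flag debris.
#' Writes per-frame float TIFFs (`DF.tif`, `E.tif`, `QDF.tif`), label
#' TIFFs, a combined `cells.csv`, an `snr.json` report for the last frame
#' of each position, and `manifest.json` (config echo, c used, seed).
#'
#' @param input_dir Dataset directory (see [demo_datasets()]).
#' @param out_dir Output directory.
#' @param optics An [optical_config()]; `c = "auto"` calibrates on the
#'   first frame encountered and reuses that c everywhere.
#' @param labels `"segment"` (watershed on phase) or `"truth"` (use
#'   `labels_truth.tif`).
#' @param preprocess Apply the polynomial background removal chain?
#' @param clip_negative Clip negative QDF pixels in the written images?
#' @param debris Named list of [filter_debris()] thresholds, or `NULL`.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given the inputs).
#' @return Tibble of cell records (also written as `cells.csv`), invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, optics = optical_config(),
                         labels = c("segment", "truth"),
                         preprocess = FALSE, clip_negative = FALSE,
                         debris = NULL, seed = 1L) {
  labels <- match.arg(labels)
  if (!dir.exists(input_dir)) stop("input_dir does not exist", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  frame_dirs <- sort(list.dirs(input_dir, recursive = TRUE))
  frame_dirs <- frame_dirs[file.exists(file.path(frame_dirs, "TL.tif"))]
  if (!length(frame_dirs)) stop("no quadrant frames found under input_dir",
                                call. = FALSE)
  for (qn in c("TR", "BL", "BR")) {
    miss <- frame_dirs[!file.exists(file.path(frame_dirs, paste0(qn, ".tif")))]
    if (length(miss)) {
      stop(sprintf("missing %s.tif in: %s", qn, miss[1]), call. = FALSE)
    }
  }
  pos_of <- dirname(frame_dirs)
  c_used <- if (identical(optics$c, "auto")) NA_real_ else optics$c
  records <- list()
  for (k in seq_along(frame_dirs)) {
    fd <- frame_dirs[k]
    imgs <- lapply(c("TL", "TR", "BL", "BR"), function(qn) {
      round(tiff::readTIFF(file.path(fd, paste0(qn, ".tif"))) * (2^16 - 1))
    })
    stack <- quadrant_stack(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]],
                            bit_depth = optics$bit_depth)
    phase_path <- file.path(fd, "phase.tif")
    phase <- if (file.exists(phase_path)) read_float_tiff(phase_path) else NULL
    lab <- if (labels == "truth" &&
               file.exists(file.path(fd, "labels_truth.tif"))) {
      read_label_tiff(file.path(fd, "labels_truth.tif"))
    } else if (!is.null(phase)) {
      segment_cells(phase)
    } else {
      stop("no phase image and no truth labels in ", fd, call. = FALSE)
    }
    if (preprocess) {
      obj <- lab > 0L
      stack <- preprocess_stack(stack, object_mask = obj)
    }
    if (is.na(c_used)) {
      c_used <- as.numeric(calibrate_c(stack))
    }
    rec <- compute_qdf(stack, c = c_used, clip_negative = clip_negative)
    od <- file.path(out_dir, sub(paste0("^", input_dir, "/?"), "", fd))
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    write_float_tiff(rec$df, file.path(od, "DF.tif"))
    write_float_tiff(rec$edge, file.path(od, "E.tif"))
    write_float_tiff(rec$qdf, file.path(od, "QDF.tif"))
    write_label_tiff(lab, file.path(od, "labels.tif"))
    frame_idx <- suppressWarnings(as.integer(basename(fd)))
    if (is.na(frame_idx)) frame_idx <- k
    tab <- per_cell_signals(lab, rec$df, rec$qdf, phase = phase,
                            optics = optics, frame = frame_idx)
    tab$position <- sub(paste0("^", input_dir, "/?"), "", pos_of[k])
    records[[k]] <- tab
    if (k == length(frame_dirs) || pos_of[k + 1] != pos_of[k]) {
      snr <- tryCatch(compute_snr(rec$qdf, lab), error = function(e) NULL)
      if (!is.null(snr)) {
        jsonlite::write_json(
          list(threshold = snr$threshold, noise_sigma = snr$noise_sigma,
               mean = snr$mean, sd = snr$sd, per_cell = snr$per_cell),
          file.path(od, "snr.json"), auto_unbox = TRUE, digits = NA)
      }
    }
  }
  cells <- dplyr::bind_rows(records)
  # track within each position
  cells <- cells |>
    dplyr::group_by(.data$position) |>
    dplyr::group_modify(~ track_cells(.x)) |>
    dplyr::ungroup()
  if (!is.null(debris)) {
    cells <- do.call(filter_debris, c(list(records = cells), debris))
  }
  utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(input_dir = input_dir, c = c_used, labels = labels,
         preprocess = preprocess, clip_negative = clip_negative,
         seed = seed, n_frames = length(frame_dirs),
         package_version = as.character(utils::packageVersion("qdf"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(cells)
}
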