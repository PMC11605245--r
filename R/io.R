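#' Read and write quadrant stacks as TIFF
#'
#' Stacks are stored either as a 4-page TIFF (page order TL, TR, BL, BR) or
#' as four single-page TIFFs with suffixes `_TL/_TR/_BL/_BR`. Integer counts
#' are stored as 16-bit samples scaled by `2^16 - 1`, which round-trips
#' integer counts exactly.
#'
#' @param stack A [quadrant_stack()].
#' @param path Output path: a `.tif` file for multi-page, or a path prefix
#'   for the suffixed layout.
#' @param layout `"pages"` (one 4-page TIFF) or `"suffix"` (four files).
#' @return `write_quadrant_tiff()` returns the written path(s) invisibly;
#'   `read_quadrant_tiff()` returns a `quadrant_stack`.
#' @export
write_quadrant_tiff <- function(stack, path, layout = c("pages", "suffix")) {
  layout <- match.arg(layout)
  stopifnot(inherits(stack, "quadrant_stack"))
  sc <- 2^16 - 1
  imgs <- list(TL = stack$tl, TR = stack$tr, BL = stack$bl, BR = stack$br)
  if (any(vapply(imgs, function(m) max(m) > sc || min(m) < 0, logical(1)))) {
    stop("stack values outside the 16-bit range", call. = FALSE)
  }
  if (layout == "pages") {
    tiff::writeTIFF(lapply(imgs, function(m) m / sc), path,
                    bits.per.sample = 16)
    invisible(path)
  } else {
    paths <- sprintf("%s_%s.tif", sub("\\.tif{1,2}$", "", path), names(imgs))
    for (i in seq_along(imgs)) {
      tiff::writeTIFF(imgs[[i]] / sc, paths[i], bits.per.sample = 16)
    }
    invisible(paths)
  }
}

#' @rdname write_quadrant_tiff
#' @param bit_depth Bit depth recorded in the returned stack.
#' @export
read_quadrant_tiff <- function(path, layout = c("pages", "suffix"),
                               bit_depth = 16) {
  layout <- match.arg(layout)
  sc <- 2^16 - 1
  if (layout == "pages") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 4) stop("expected a 4-page TIFF", call. = FALSE)
    imgs <- lapply(pages, function(m) round(m * sc))
  } else {
    prefix <- sub("\\.tif{1,2}$", "", path)
    paths <- sprintf("%s_%s.tif", prefix, c("TL", "TR", "BL", "BR"))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("missing quadrant file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    imgs <- lapply(paths, function(p) round(tiff::readTIFF(p) * sc))
  }
  quadrant_stack(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]],
                 bit_depth = bit_depth)
}

#' Float image TIFF round trip
#'
#' Reconstruction outputs (DF, E, QDF) are real-valued and may be negative.
#' They are stored as 32-bit TIFF scaled into \[0, 1\], with offset and
#' scale recorded in a JSON sidecar (`<path>.json`), and restored exactly on
#' read.
#'
#' @param image Numeric matrix.
#' @param path Output `.tif` path.
#' @return `write_float_tiff()` returns `path` invisibly;
#'   `read_float_tiff()` the restored matrix.
#' @export
write_float_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  lo <- min(image); hi <- max(image)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image - lo) / scale, path, bits.per.sample = 32)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            dim = dim(image)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_float_tiff
#' @export
read_float_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  m * meta$scale + meta$offset
}

#' Label image TIFF round trip
#'
#' Integer label images stored as 16-bit TIFF (labels up to 65535).
#'
#' @param label_image Integer matrix.
#' @param path Output `.tif` path.
#' @return Path / the label matrix.
#' @export
write_label_tiff <- function(label_image, path) {
  stopifnot(max(label_image) <= 2^16 - 1, min(label_image) >= 0)
  tiff::writeTIFF(label_image / (2^16 - 1), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- round(tiff::readTIFF(path) * (2^16 - 1))
  storage.mode(m) <- "integer"
  m
}
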