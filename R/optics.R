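#' Optical configuration
#'
#' Bundles the acquisition parameters needed to reconstruct quadrant-darkfield
#' images and to convert integrated phase to dry mass. The illumination
#' annulus is expressed in units of the objective NA; darkfield requires the
#' inner radius to exceed 1.
#'
#' @param wavelength_nm Illumination wavelength in nanometres.
#' @param pixel_size_um Object-space pixel size in micrometres.
#' @param objective_na Objective numerical aperture.
#' @param illumination_na_range Inner and outer radius of the illumination
#'   annulus, in units of `objective_na`.
#' @param c Darkfield scaling factor used in `QDF = c * DF - E`. Either a
#'   number in (0, 2] or `"auto"`, which means: calibrate with
#'   [calibrate_c()] on a designated field of view before reconstructing.
#' @param bit_depth Camera bit depth of the quadrant images.
#' @param refractive_increment_m3_per_kg Specific refractive increment
#'   relating refractive-index excess to dry-mass concentration; the
#'   cell-average value 1.8e-4 m^3/kg is the default.
#'
#' @return An object of class `optical_config` (a named list).
#' @examples
#' optical_config()
#' optical_config(c = 0.9, bit_depth = 12)
#' @export
optical_config <- function(wavelength_nm = 525,
                           pixel_size_um = 0.5,
                           objective_na = 0.25,
                           illumination_na_range = c(1.05, 1.33),
                           c = "auto",
                           bit_depth = 16,
                           refractive_increment_m3_per_kg = 1.8e-4) {
  stopifnot(wavelength_nm > 0, pixel_size_um > 0, objective_na > 0,
            length(illumination_na_range) == 2,
            illumination_na_range[1] > 1,
            illumination_na_range[2] >= illumination_na_range[1],
            bit_depth >= 1, refractive_increment_m3_per_kg > 0)
  if (is.numeric(c)) {
    if (length(c) != 1 || is.na(c) || c <= 0 || c > 2) {
      stop("numeric `c` must be a single value in (0, 2]", call. = FALSE)
    }
  } else if (!identical(c, "auto")) {
    stop('`c` must be a number in (0, 2] or "auto"', call. = FALSE)
  }
  structure(
    list(
      wavelength_nm = wavelength_nm,
      pixel_size_um = pixel_size_um,
      objective_na = objective_na,
      illumination_na_range = illumination_na_range,
      c = c,
      bit_depth = as.integer(bit_depth),
      refractive_increment_m3_per_kg = refractive_increment_m3_per_kg
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength: %g nm, pixel: %g um, NA: %g\n",
              x$wavelength_nm, x$pixel_size_um, x$objective_na))
  cat(sprintf("  illumination annulus: %.2f-%.2fx NA, bit depth: %d\n",
              x$illumination_na_range[1], x$illumination_na_range[2],
              x$bit_depth))
  cat(sprintf("  scaling factor c: %s\n",
              if (identical(x$c, "auto")) "auto" else format(x$c)))
  invisible(x)
}
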