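#' Ocular magnification factor from axial length
#'
#' Bennett's reduced-eye magnification factor \eqn{q = 0.01306 (AL - 1.82)},
#' with axial length AL in millimetres. The factor converts angular scan
#' extent into true retinal distance; it is strictly increasing in axial
#' length and vanishes at the (physically impossible) AL of 1.82 mm.
#'
#' @param axial_length_mm Axial length of the eye in mm. Must exceed 1.82.
#' @return Dimensionless magnification factor.
#' @examples
#' magnification_factor(24.46)  # ~0.29568, unit magnification at p = 3.382
#' @export
magnification_factor <- function(axial_length_mm) {
  if (!is.numeric(axial_length_mm) || any(!is.finite(axial_length_mm))) {
    stop("axial_length_mm must be finite numeric", call. = FALSE)
  }
  if (any(axial_length_mm <= 1.82)) {
    stop("axial_length_mm must exceed 1.82 mm (non-positive magnification factor)",
         call. = FALSE)
  }
  0.01306 * (axial_length_mm - 1.82)
}

#' True scan length after magnification correction
#'
#' Rescales the nominal scan length of the OCTA protocol to the actual
#' retinal distance covered, \eqn{s_{actual} = p \times q \times s}, where
#' p is the camera magnification factor of the imaging system, q the ocular
#' magnification factor from [magnification_factor()], and s the nominal
#' scan length.
#'
#' @param axial_length_mm Axial length in mm (> 1.82).
#' @param nominal_s_mm Nominal scan length in mm (e.g. 3.0).
#' @param camera_p Camera magnification factor; the default 3.382 gives unit
#'   magnification at the design axial length 24.46 mm.
#' @return Actual scan length in mm.
#' @export
actual_scan_length <- function(axial_length_mm, nominal_s_mm, camera_p = 3.382) {
  stopifnot(is.numeric(nominal_s_mm), nominal_s_mm >= 0, camera_p > 0)
  camera_p * magnification_factor(axial_length_mm) * nominal_s_mm
}

#' Pixel size from scan length
#'
#' @param actual_scan_length_mm Corrected scan length in mm.
#' @param n_pixels Pixels per side of the (square, isotropic) scan grid.
#' @return Pixel side length in micrometres.
#' @export
pixel_size_um <- function(actual_scan_length_mm, n_pixels) {
  if (!is.numeric(n_pixels) || any(n_pixels <= 0)) {
    stop("n_pixels must be a positive count", call. = FALSE)
  }
  1000 * actual_scan_length_mm / n_pixels
}

#' Scan geometry of an en-face acquisition
#'
#' Bundles the nominal field size, grid size, axial length and camera factor
#' of one eye's scan, and derives the magnification-corrected scan length and
#' pixel size. Magnification is carried as coordinate metadata (a corrected
#' pixel size); pixel data are never resampled, so binarized maps stay free
#' of interpolation artefacts.
#'
#' Pixel indices are 0-based; a pixel covers a square of side
#' `pixel_size_um` centred on its grid point, and the field origin is the
#' image centre.
#'
#' @param nominal_scan_length_mm Nominal field side, mm (default 3).
#' @param n_pixels_per_side Grid side in pixels (default 245).
#' @param axial_length_mm Axial length, mm (> 1.82).
#' @param camera_factor Camera magnification factor p (default 3.382).
#' @return A `scan_geometry` object (list with the input fields plus
#'   `actual_scan_length_mm` and `pixel_size_um`).
#' @examples
#' g <- scan_geometry(axial_length_mm = 24.46)
#' g$actual_scan_length_mm  # ~3.000 mm
#' @export
scan_geometry <- function(nominal_scan_length_mm = 3,
                          n_pixels_per_side = 245L,
                          axial_length_mm = 24.46,
                          camera_factor = 3.382) {
  stopifnot(nominal_scan_length_mm > 0, n_pixels_per_side > 0)
  s_actual <- actual_scan_length(axial_length_mm, nominal_scan_length_mm,
                                 camera_factor)
  structure(list(
    nominal_scan_length_mm = nominal_scan_length_mm,
    n_pixels_per_side = as.integer(n_pixels_per_side),
    axial_length_mm = axial_length_mm,
    camera_factor = camera_factor,
    actual_scan_length_mm = s_actual,
    pixel_size_um = pixel_size_um(s_actual, n_pixels_per_side)
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: %g mm nominal, %d px, AL %.2f mm -> %.4f mm actual (%.4f um/px)\n",
    x$nominal_scan_length_mm, x$n_pixels_per_side, x$axial_length_mm,
    x$actual_scan_length_mm, x$pixel_size_um))
  invisible(x)
}

#' Field-centred physical coordinates of pixel centres
#'
#' Returns the x (column) and y (row) coordinates, in magnification-corrected
#' millimetres, of every pixel centre. x increases rightwards with column
#' index, y downwards with row index; (0, 0) is the field centre.
#'
#' @param geometry A [scan_geometry()].
#' @return List with matrices `x_mm` and `y_mm`, each
#'   `n_pixels_per_side` square.
#' @export
pixel_centers_mm <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  n <- geometry$n_pixels_per_side
  step <- geometry$pixel_size_um / 1000
  coord <- (seq_len(n) - 1 - (n - 1) / 2) * step
  list(x_mm = matrix(coord, n, n, byrow = TRUE),
       y_mm = matrix(coord, n, n, byrow = FALSE))
}

#' Convert between physical mm and pixel units
#'
#' @param length_mm Length in corrected mm.
#' @param geometry A [scan_geometry()].
#' @return `mm_to_px`: length in pixels; `px_to_mm`: length in mm.
#' @export
mm_to_px <- function(length_mm, geometry) {
  length_mm * 1000 / geometry$pixel_size_um
}

#' @rdname mm_to_px
#' @param length_px Length in pixels.
#' @export
px_to_mm <- function(length_px, geometry) {
  length_px * geometry$pixel_size_um / 1000
}
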