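#' Polygon area of a FAZ annotation
#'
#' Absolute shoelace area in mm^2; independent of vertex orientation.
#' Computed on the polygon in physical coordinates, never on a rasterised
#' mask.
#'
#' @param faz A [faz_annotation()] or a two-column vertex matrix.
#' @return Area in mm^2.
#' @export
polygon_area <- function(faz) {
  v <- if (inherits(faz, "faz_annotation")) faz$vertices else as.matrix(faz)
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  a <- abs(sum(x * y[j] - x[j] * y)) / 2
  if (a <= 0) stop("degenerate polygon: zero area", call. = FALSE)
  a
}

#' Polygon perimeter of a FAZ annotation
#'
#' Sum of consecutive vertex distances including the closing edge, in mm.
#'
#' @inheritParams polygon_area
#' @return Perimeter in mm.
#' @export
polygon_perimeter <- function(faz) {
  v <- if (inherits(faz, "faz_annotation")) faz$vertices else as.matrix(faz)
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
}

#' FAZ circularity (perimeter-ratio convention)
#'
#' Ratio of the polygon perimeter to the perimeter of the circle of equal
#' area: \eqn{P / (2 \sqrt{\pi A})}. By the isoperimetric inequality the
#' value is >= 1 for every simple polygon, with 1 attained only in the
#' circular limit; larger values mean a more irregular FAZ. (This is the
#' convention under which typical healthy values run 1.0--1.3; it is the
#' reciprocal square root of the common 4*pi*A/P^2 roundness index.)
#'
#' @param area_mm2 Area in mm^2 (> 0).
#' @param perimeter_mm Perimeter in mm (> 0).
#' @return Dimensionless circularity >= 1.
#' @examples
#' circularity(pi * 0.3^2, 2 * pi * 0.3)  # exactly 1 for a circle
#' circularity(1, 4)                      # unit square: 1.12838
#' @export
circularity <- function(area_mm2, perimeter_mm) {
  if (any(area_mm2 <= 0) || any(perimeter_mm <= 0)) {
    stop("area and perimeter must be positive", call. = FALSE)
  }
  perimeter_mm / (2 * sqrt(pi * area_mm2))
}

#' All FAZ metrics for one annotation
#'
#' @param faz A [faz_annotation()].
#' @return List of class `faz_metrics` with `layer`, `area_mm2`,
#'   `perimeter_mm`, `circularity`.
#' @export
compute_faz_metrics <- function(faz) {
  stopifnot(inherits(faz, "faz_annotation"))
  a <- polygon_area(faz)
  p <- polygon_perimeter(faz)
  structure(list(layer = faz$layer, area_mm2 = a, perimeter_mm = p,
                 circularity = circularity(a, p)),
            class = "faz_metrics")
}

#' @export
print.faz_metrics <- function(x, ...) {
  cat(sprintf("FAZ (%s): area %.4f mm^2, perimeter %.4f mm, circularity %.4f\n",
              x$layer, x$area_mm2, x$perimeter_mm, x$circularity))
  invisible(x)
}
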