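#' En-face OCTA slab image
#'
#' Container for one 8-bit en-face slab (SCP, DCP or CC) of one eye, with
#' its scan geometry and instrument signal strength.
#'
#' @param pixels Square numeric matrix of intensities in 0--255
#'   (rows = y, columns = x).
#' @param slab One of `"SCP"`, `"DCP"`, `"CC"`.
#' @param geometry A [scan_geometry()]; its grid side must match `pixels`.
#' @param signal_strength Instrument quality index, integer 0--10.
#' @param eye_id Identifier string.
#' @param laterality `"OD"` or `"OS"`.
#' @return An `enface_image` object.
#' @export
enface_image <- function(pixels, slab, geometry, signal_strength = 10L,
                         eye_id = "eye", laterality = "OD") {
  slab <- match.arg(slab, c("SCP", "DCP", "CC"))
  laterality <- match.arg(laterality, c("OD", "OS"))
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels)) {
    stop("pixels must be a square matrix", call. = FALSE)
  }
  stopifnot(inherits(geometry, "scan_geometry"))
  if (nrow(pixels) != geometry$n_pixels_per_side) {
    stop("pixels side does not match geometry$n_pixels_per_side", call. = FALSE)
  }
  if (any(pixels < 0 | pixels > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (signal_strength < 0 || signal_strength > 10) {
    stop("signal_strength must lie in 0..10", call. = FALSE)
  }
  structure(list(pixels = pixels, slab = slab, geometry = geometry,
                 signal_strength = as.integer(signal_strength),
                 eye_id = eye_id, laterality = laterality),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("enface_image [%s] %s %s: %dx%d px, mean intensity %.1f, SS %d\n",
              x$slab, x$eye_id, x$laterality, nrow(x$pixels), ncol(x$pixels),
              mean(x$pixels), x$signal_strength))
  invisible(x)
}

#' Binary map over an en-face grid
#'
#' A labelled boolean mask (vessels, large vessels, flow deficits, FAZ,
#' artifact or annulus) with the same dimensions as its source slab.
#'
#' @param mask Logical matrix.
#' @param label One of `"vessels"`, `"large_vessels"`, `"flow_deficits"`,
#'   `"faz"`, `"artifact"`, `"annulus"`.
#' @param source_slab `"SCP"`, `"DCP"` or `"CC"` (may be `NA` for the
#'   geometry-derived annulus).
#' @return A `binary_map` object.
#' @export
binary_map <- function(mask, label, source_slab = NA_character_) {
  label <- match.arg(label, c("vessels", "large_vessels", "flow_deficits",
                              "faz", "artifact", "annulus"))
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, label = label, source_slab = source_slab),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("binary_map [%s] from %s: %d/%d pixels set (%.1f%%)\n",
              x$label, x$source_slab, sum(x$mask), length(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Foveal avascular zone annotation
#'
#' A closed simple polygon delineating the FAZ of one layer, in physical
#' (magnification-corrected) millimetre coordinates with the origin at the
#' field centre, x right, y down. A repeated final vertex is dropped;
#' closure is implicit.
#'
#' @param vertices Two-column numeric matrix (or data.frame) of
#'   `(x_mm, y_mm)` pairs, at least 3 after closure.
#' @param layer `"superficial"` or `"deep"`.
#' @return A `faz_annotation` object.
#' @export
faz_annotation <- function(vertices, layer) {
  layer <- match.arg(layer, c("superficial", "deep"))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("vertices must have two columns", call. = FALSE)
  storage.mode(vertices) <- "double"
  n <- nrow(vertices)
  if (n >= 2 && isTRUE(all(vertices[1, ] == vertices[n, ]))) {
    vertices <- vertices[-n, , drop = FALSE]
  }
  if (nrow(vertices) < 3) {
    stop("a FAZ polygon needs at least 3 distinct vertices", call. = FALSE)
  }
  if (!polygon_is_simple(vertices)) {
    stop("FAZ polygon is self-intersecting", call. = FALSE)
  }
  colnames(vertices) <- c("x_mm", "y_mm")
  structure(list(vertices = vertices, layer = layer), class = "faz_annotation")
}

# Simplicity test: no two non-adjacent edges may intersect. O(n^2) segment
# intersection; annotation polygons are small (<= a few hundred vertices).
polygon_is_simple <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      # skip edges sharing a vertex (adjacent, incl. the closing edge)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (seg_int(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

#' Read an en-face slab image
#'
#' Reads an 8-bit grayscale PNG or TIFF and attaches per-eye metadata.
#' Intensities are preserved bit-exactly (stored as 0--255).
#'
#' @param path Path to a single-channel PNG or TIFF.
#' @param metadata A list (or one-row data.frame) with at least
#'   `axial_length_mm` and `slab`; optional `nominal_scan_length_mm`,
#'   `camera_factor`, `signal_strength`, `eye_id`, `laterality`.
#' @return An [enface_image()].
#' @export
read_enface <- function(path, metadata) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  metadata <- as.list(metadata)
  if (is.null(metadata$axial_length_mm) || is.na(metadata$axial_length_mm)) {
    stop("metadata error: axial_length_mm is required", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] > 1) {
      stop("format error: expected single-channel grayscale, got ",
           dim(raw)[3], " channels", call. = FALSE)
    }
    raw <- raw[, , 1]
  }
  if (nrow(raw) != ncol(raw)) {
    stop("format error: image is not square", call. = FALSE)
  }
  geom <- scan_geometry(
    nominal_scan_length_mm = metadata$nominal_scan_length_mm %||% 3,
    n_pixels_per_side = nrow(raw),
    axial_length_mm = metadata$axial_length_mm,
    camera_factor = metadata$camera_factor %||% 3.382)
  enface_image(round(raw * 255), slab = metadata$slab %||% "SCP",
               geometry = geom,
               signal_strength = metadata$signal_strength %||% 10L,
               eye_id = metadata$eye_id %||% basename(path),
               laterality = metadata$laterality %||% "OD")
}

#' Write an en-face slab or mask as an 8-bit image
#'
#' Slabs are written with their 0--255 intensities; masks with 0/255
#' semantics. PNG only (lossless 8-bit).
#'
#' @param x An [enface_image()] or [binary_map()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_enface_png <- function(x, path) {
  m <- if (inherits(x, "binary_map")) x$mask * 255 else x$pixels
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Read a 0/255 mask PNG back into a binary map
#'
#' @param path PNG path.
#' @inheritParams binary_map
#' @export
read_mask_png <- function(path, label, source_slab = NA_character_) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  binary_map(raw >= 0.5, label = label, source_slab = source_slab)
}

#' Read a FAZ annotation
#'
#' JSON dialect: object with fields `layer` and `vertices` (list of
#' `[x_mm, y_mm]`). CSV fallback: columns `x_mm,y_mm` (layer passed
#' explicitly). Coordinates are physical millimetres, origin at the field
#' centre, x right, y down; decoupling the annotation from the pixel grid
#' lets magnification correction apply uniformly.
#'
#' @param path `.json` or `.csv` annotation file.
#' @param layer Layer tag required for CSV input; overrides the file for JSON.
#' @return A [faz_annotation()].
#' @export
read_faz_annotation <- function(path, layer = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    rec <- jsonlite::fromJSON(path)
    if (is.null(rec$vertices)) stop("format error: no vertices field", call. = FALSE)
    v <- rec$vertices
    if (is.list(v) && !is.matrix(v)) v <- do.call(rbind, v)
    if (is.null(dim(v)) || nrow(v) < 3) {
      stop("format error: fewer than 3 vertices", call. = FALSE)
    }
    faz_annotation(v, layer = layer %||% rec$layer)
  } else if (ext == "csv") {
    if (is.null(layer)) stop("layer tag required for CSV annotations", call. = FALSE)
    v <- utils::read.csv(path)
    if (!all(c("x_mm", "y_mm") %in% names(v)) || nrow(v) < 3) {
      stop("format error: CSV needs >= 3 rows of x_mm,y_mm", call. = FALSE)
    }
    faz_annotation(as.matrix(v[, c("x_mm", "y_mm")]), layer = layer)
  } else {
    stop("unsupported annotation format: .", ext, call. = FALSE)
  }
}

#' Write a FAZ annotation as JSON
#'
#' @param faz A [faz_annotation()].
#' @param path Output `.json` path.
#' @export
write_faz_annotation <- function(faz, path) {
  jsonlite::write_json(
    list(layer = faz$layer,
         vertices = unname(split(faz$vertices, row(faz$vertices)[, 1]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Column order of the per-eye metrics table
#'
#' The 13 per-eye outputs: four perfusion densities, three FAZ metrics for
#' each of the superficial and deep layers, and three choriocapillaris
#' flow-deficit metrics.
#' @export
metrics_columns <- function() {
  c("pd_lv_pct", "pd_scp_pct", "pd_scp_wo_lv_pct", "pd_dcp_pct",
    "faz_sup_area_mm2", "faz_sup_perimeter_mm", "faz_sup_circularity",
    "faz_deep_area_mm2", "faz_deep_perimeter_mm", "faz_deep_circularity",
    "fd_density_pct", "fd_size_um2", "fd_number")
}

#' Write per-eye metrics to CSV
#'
#' One row per eye; columns are `eye_id` plus the 13 metrics in the fixed
#' order of [metrics_columns()]. Round-trips losslessly via
#' [read_metrics_table()].
#'
#' @param records A data.frame with an `eye_id` column and the metric
#'   columns (as returned by [compute_all_metrics()] rows), or a list of
#'   such one-row data.frames.
#' @param path Output CSV path.
#' @export
write_metrics_table <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- if (length(records)) do.call(rbind, records) else NULL
  }
  cols <- c("eye_id", metrics_columns())
  if (!is.null(records) && nrow(records) > 0) {
    missing <- setdiff(cols, names(records))
    if (length(missing)) {
      stop("missing metric columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(records$eye_id)) {
      stop("duplicate eye_id in metrics records", call. = FALSE)
    }
    records <- records[, cols, drop = FALSE]
  } else {
    records <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default run configuration
#'
#' Flat key-value configuration covering the camera factor, annulus
#' diameters, filter parameters, thresholds and the seed. Values can be
#' overridden individually; unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
octa_config <- function(...) {
  cfg <- list(
    camera_factor = 3.382,
    annulus_inner_diameter_mm = 1.0,
    annulus_outer_diameter_mm = 2.5,
    gabor_wavelength_px = 8,
    gabor_n_orientations = 12L,
    gabor_bandwidth_octaves = 1,
    hessian_scales_px = c(2, 3, 4),
    lv_quantile = 0.92,
    lv_min_size_px = 50L,
    lv_close_radius_px = 1L,
    cc_artifact_dilate_px = 1L,
    scp_wo_lv_dilate_px = 3L,
    welch = FALSE,
    adjust_spherical_equivalent = TRUE,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Read / write configuration JSON
#'
#' @param path JSON path.
#' @export
read_config <- function(path) {
  do.call(octa_config, jsonlite::fromJSON(path))
}

#' @rdname read_config
#' @param config A configuration list from [octa_config()].
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
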