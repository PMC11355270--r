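# Regional quantification over the fovea-centred annulus: perfusion density
# in the retinal layers, flow-deficit density / size / count in the CC, and
# the whole-eye pipeline driver.

#' Fovea-centred annulus of measurement
#'
#' @param center_mm Annulus centre `(x, y)` in field coordinates (default
#'   the field centre).
#' @param inner_diameter_mm Inner diameter, mm (default 1.0).
#' @param outer_diameter_mm Outer diameter, mm (default 2.5).
#' @return An `annulus_spec` list.
#' @export
annulus_spec <- function(center_mm = c(0, 0), inner_diameter_mm = 1.0,
                         outer_diameter_mm = 2.5) {
  if (!(inner_diameter_mm > 0 && inner_diameter_mm < outer_diameter_mm)) {
    stop("config error: need 0 < inner diameter < outer diameter", call. = FALSE)
  }
  structure(list(center_mm = center_mm,
                 inner_diameter_mm = inner_diameter_mm,
                 outer_diameter_mm = outer_diameter_mm),
            class = "annulus_spec")
}

#' Rasterise the annulus onto the pixel grid
#'
#' A pixel belongs to the annulus iff its centre lies at distance
#' `[inner radius, outer radius)` from the annulus centre, distances in
#' magnification-corrected mm. Warns if the outer ring is clipped by the
#' field.
#'
#' @param spec An [annulus_spec()].
#' @param geometry A [scan_geometry()].
#' @return A [binary_map()] labelled `annulus`.
#' @export
make_annulus_mask <- function(spec = annulus_spec(), geometry) {
  stopifnot(inherits(spec, "annulus_spec"), inherits(geometry, "scan_geometry"))
  half_field <- geometry$actual_scan_length_mm / 2
  r_out <- spec$outer_diameter_mm / 2
  if (max(abs(spec$center_mm)) + r_out > half_field + 1e-12) {
    warning("annulus outer ring extends beyond the imaged field; clipped")
  }
  ctr <- pixel_centers_mm(geometry)
  d <- sqrt((ctr$x_mm - spec$center_mm[1])^2 + (ctr$y_mm - spec$center_mm[2])^2)
  binary_map(d >= spec$inner_diameter_mm / 2 & d < r_out, label = "annulus")
}

as_mask <- function(x) if (inherits(x, "binary_map")) x$mask else x

#' Perfusion density within the annulus
#'
#' Percentage of vessel area per total imaged area in the annulus region of
#' measurement: `100 * |vessel & annulus & !exclude| / |annulus & !exclude|`.
#' Without an exclusion mask the denominator is the full annulus.
#'
#' @param vessels A vessel [binary_map()] (or logical matrix).
#' @param annulus The annulus [binary_map()].
#' @param exclude Optional exclusion [binary_map()] removed from both
#'   numerator and denominator.
#' @return Percentage in [0, 100].
#' @export
perfusion_density <- function(vessels, annulus, exclude = NULL) {
  v <- as_mask(vessels); a <- as_mask(annulus)
  if (!all(dim(v) == dim(a))) stop("shape mismatch", call. = FALSE)
  keep <- a
  if (!is.null(exclude)) {
    e <- as_mask(exclude)
    if (!all(dim(e) == dim(a))) stop("shape mismatch", call. = FALSE)
    keep <- keep & !e
  }
  denom <- sum(keep)
  if (denom == 0) stop("degenerate input: empty measurement region", call. = FALSE)
  100 * sum(v & keep) / denom
}

#' Choriocapillaris flow-deficit density within the annulus
#'
#' `100 * |fd & annulus & !artifact| / |annulus & !artifact|`.
#'
#' @param fd The flow-deficit [binary_map()].
#' @param annulus The annulus [binary_map()].
#' @param artifact The large-vessel artefact [binary_map()] (may be `NULL`).
#' @return Percentage in [0, 100].
#' @export
fd_density <- function(fd, annulus, artifact = NULL) {
  perfusion_density(fd, annulus, exclude = artifact)
}

#' Flow-deficit count and mean size
#'
#' Connected components (8-connectivity) of the flow-deficit mask restricted
#' to the annulus; the mean size is the mean component pixel count scaled by
#' the squared corrected pixel size. With no components the size is `NA`.
#'
#' @param fd The flow-deficit [binary_map()].
#' @param annulus The annulus [binary_map()].
#' @param geometry A [scan_geometry()].
#' @return List with `fd_count` and `fd_mean_size_um2`.
#' @export
fd_components <- function(fd, annulus, geometry) {
  m <- as_mask(fd) & as_mask(annulus)
  if (!any(m)) return(list(fd_count = 0L, fd_mean_size_um2 = NA_real_))
  lab <- label_components_8(m)
  sizes <- tabulate(lab[m])
  list(fd_count = length(sizes),
       fd_mean_size_um2 = mean(sizes) * geometry$pixel_size_um^2)
}

#' Run the full per-eye quantification pipeline
#'
#' Orchestrates the stages in acquisition-processing order: large-vessel
#' enhancement and segmentation on the SCP; mean-threshold vessel
#' binarization of SCP and DCP; FAZ masking of the retinal vessel maps;
#' large-vessel artefact exclusion on the CC; flow-deficit binarization;
#' and regional quantification over the magnification-corrected
#' fovea-centred annulus. Returns the 13 per-eye metrics.
#'
#' The capillary-only density `pd_scp_wo_lv_pct` excludes the large-vessel
#' mask dilated by `scp_wo_lv_dilate_px` from the numerator while keeping
#' the full annulus as denominator, so that the peri-vascular capillary-free
#' zone around arterioles/venules is not counted as capillary signal.
#'
#' @param scp,dcp,cc [enface_image()] slabs of one eye, sharing geometry.
#' @param faz_sup,faz_deep [faz_annotation()]s for the superficial and deep
#'   layers.
#' @param config Configuration from [octa_config()].
#' @return One-row data.frame with `eye_id` and the columns of
#'   [metrics_columns()], plus an attribute `"masks"` holding the
#'   intermediate binary maps for audit.
#' @export
compute_all_metrics <- function(scp, dcp, cc, faz_sup, faz_deep,
                                config = octa_config()) {
  stopifnot(inherits(scp, "enface_image"), inherits(dcp, "enface_image"),
            inherits(cc, "enface_image"))
  g <- scp$geometry
  if (dcp$geometry$n_pixels_per_side != g$n_pixels_per_side ||
      cc$geometry$n_pixels_per_side != g$n_pixels_per_side) {
    stop("stage[geometry]: the three slabs must share one scan geometry",
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage[%s]: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  resp <- stage("enhance_large_vessels", enhance_large_vessels(scp, config))
  lv <- stage("segment_large_vessels",
              segment_large_vessels(resp, quantile = config$lv_quantile,
                                    min_size_px = config$lv_min_size_px,
                                    close_radius_px = config$lv_close_radius_px))
  v_scp <- stage("binarize_vessels", binarize_vessels(scp))
  v_dcp <- stage("binarize_vessels", binarize_vessels(dcp))
  v_scp <- stage("mask_faz", mask_faz(v_scp, faz_sup, g))
  v_dcp <- stage("mask_faz", mask_faz(v_dcp, faz_deep, g))
  art <- stage("remove_cc_artifacts",
               remove_cc_artifacts(cc, lv, dilate_px = config$cc_artifact_dilate_px))
  fd <- stage("binarize_flow_deficits",
              binarize_flow_deficits(cc, art$artifact))
  ann <- stage("make_annulus_mask", make_annulus_mask(
    annulus_spec(inner_diameter_mm = config$annulus_inner_diameter_mm,
                 outer_diameter_mm = config$annulus_outer_diameter_mm), g))

  lv_excl <- lv$mask
  if (config$scp_wo_lv_dilate_px > 0 && any(lv_excl)) {
    brush <- EBImage::makeBrush(2 * config$scp_wo_lv_dilate_px + 1, "disc")
    lv_excl <- EBImage::dilate(lv_excl * 1, brush) > 0.5
  }

  fm_sup <- stage("faz_metrics", compute_faz_metrics(faz_sup))
  fm_deep <- stage("faz_metrics", compute_faz_metrics(faz_deep))
  comp <- stage("fd_components", fd_components(fd, ann, g))

  out <- data.frame(
    eye_id = scp$eye_id,
    pd_lv_pct = perfusion_density(lv, ann),
    pd_scp_pct = perfusion_density(v_scp, ann),
    pd_scp_wo_lv_pct = perfusion_density(v_scp$mask & !lv_excl, ann),
    pd_dcp_pct = perfusion_density(v_dcp, ann),
    faz_sup_area_mm2 = fm_sup$area_mm2,
    faz_sup_perimeter_mm = fm_sup$perimeter_mm,
    faz_sup_circularity = fm_sup$circularity,
    faz_deep_area_mm2 = fm_deep$area_mm2,
    faz_deep_perimeter_mm = fm_deep$perimeter_mm,
    faz_deep_circularity = fm_deep$circularity,
    fd_density_pct = fd_density(fd, ann, art$artifact),
    fd_size_um2 = comp$fd_mean_size_um2,
    fd_number = comp$fd_count,
    stringsAsFactors = FALSE)
  attr(out, "masks") <- list(large_vessels = lv, vessels_scp = v_scp,
                             vessels_dcp = v_dcp, artifact = art$artifact,
                             flow_deficits = fd, annulus = ann)
  out
}
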