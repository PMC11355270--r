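# Stage (2)-(7) image operations: large-vessel enhancement and segmentation
# on the SCP, mean-threshold vessel binarization, FAZ masking, large-vessel
# artefact exclusion on the CC, and flow-deficit binarization.

#' Quadrature Gabor kernel pair
#'
#' Even (cosine) and odd (sine) Gabor kernels at one orientation. The
#' envelope sigma follows the standard half-response bandwidth relation, and
#' the even kernel is made DC-free so a constant image yields zero response.
#'
#' @param wavelength_px Carrier wavelength in pixels.
#' @param theta Orientation in radians (0 = along x).
#' @param bandwidth_octaves Half-response spatial-frequency bandwidth.
#' @param gamma Spatial aspect ratio of the envelope (ellipticity).
#' @return List with matrices `even` and `odd`.
#' @keywords internal
gabor_kernel <- function(wavelength_px, theta, bandwidth_octaves = 1,
                         gamma = 0.5) {
  b <- 2^bandwidth_octaves
  sigma <- wavelength_px / pi * sqrt(log(2) / 2) * (b + 1) / (b - 1)
  half <- ceiling(3 * sigma)
  g <- seq(-half, half)
  x <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  y <- matrix(g, 2 * half + 1, 2 * half + 1)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xr^2 + (gamma * yr)^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / wavelength_px)
  list(even = even - mean(even), odd = env * sin(2 * pi * xr / wavelength_px))
}

min_max_norm <- function(m, guard = 1e-8) {
  rng <- range(m)
  if (!is.finite(rng[2] - rng[1]) || (rng[2] - rng[1]) < guard) {
    return(m * 0)
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

# shift a matrix by (dr, dc) with replicated borders
shift_mat <- function(m, dr, dc) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- pmin(pmax(seq_len(n1) - dr, 1L), n1)
  ci <- pmin(pmax(seq_len(n2) - dc, 1L), n2)
  m[ri, ci, drop = FALSE]
}

#' Orientation-bank Gabor magnitude
#'
#' Pixelwise maximum over orientations of the quadrature (even/odd)
#' magnitude response.
#'
#' @param pixels Numeric matrix.
#' @param wavelength_px Carrier wavelength in pixels.
#' @param n_orientations Number of evenly spaced orientations over pi.
#' @param bandwidth_octaves Envelope bandwidth.
#' @return Non-negative matrix of the same shape.
#' @keywords internal
gabor_bank_response <- function(pixels, wavelength_px = 8,
                                n_orientations = 12L,
                                bandwidth_octaves = 1) {
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  out <- matrix(0, nrow(pixels), ncol(pixels))
  for (th in thetas) {
    k <- gabor_kernel(wavelength_px, th, bandwidth_octaves)
    ce <- EBImage::filter2(pixels, k$even, boundary = "replicate")
    co <- EBImage::filter2(pixels, k$odd, boundary = "replicate")
    out <- pmax(out, sqrt(ce^2 + co^2))
  }
  out
}

#' Multiscale Hessian tubularity (Frangi-style, bright ridges)
#'
#' For each Gaussian scale, scale-normalised second derivatives give the
#' Hessian eigenvalues; bright tubular structure is flagged where the
#' dominant eigenvalue is negative, weighted by the blobness ratio and the
#' second-order structure energy. The pixelwise maximum over scales is
#' returned.
#'
#' @param pixels Numeric matrix.
#' @param scales_px Gaussian sigmas in pixels.
#' @param beta Blobness sensitivity (default 0.5, the usual choice).
#' @return Non-negative matrix of the same shape.
#' @keywords internal
hessian_tubularity <- function(pixels, scales_px = c(2, 3, 4), beta = 0.5) {
  out <- matrix(0, nrow(pixels), ncol(pixels))
  for (s in scales_px) {
    sm <- EBImage::gblur(pixels, sigma = s, boundary = "replicate")
    lxx <- (shift_mat(sm, 0, 1) + shift_mat(sm, 0, -1) - 2 * sm) * s^2
    lyy <- (shift_mat(sm, 1, 0) + shift_mat(sm, -1, 0) - 2 * sm) * s^2
    lxy <- (shift_mat(sm, 1, 1) + shift_mat(sm, -1, -1) -
              shift_mat(sm, 1, -1) - shift_mat(sm, -1, 1)) / 4 * s^2
    mean_l <- (lxx + lyy) / 2
    disc <- sqrt(pmax(((lxx - lyy) / 2)^2 + lxy^2, 0))
    e_hi <- mean_l + disc   # algebraically larger
    e_lo <- mean_l - disc
    # order by magnitude: l2 has the larger |.|
    swap <- abs(e_hi) > abs(e_lo)
    l1 <- ifelse(swap, e_lo, e_hi)
    l2 <- ifelse(swap, e_hi, e_lo)
    rb2 <- (l1 / ifelse(l2 == 0, .Machine$double.eps, l2))^2
    s2 <- l1^2 + l2^2
    cpar <- max(sqrt(s2)) / 2
    if (cpar <= 0) next
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cpar^2)))
    v[l2 >= 0] <- 0   # bright-on-dark tubes only
    out <- pmax(out, v)
  }
  out
}

#' Enhance large vessels in the SCP slab
#'
#' Combines an orientation bank of quadrature Gabor filters (tuned to
#' large-vessel calibre) with multiscale Hessian tubularity: each response
#' is min-max normalised to [0, 1] and the pixelwise maximum is taken.
#' A structureless (constant) image maps to an all-zero response.
#'
#' @param img An [enface_image()] with `slab == "SCP"`.
#' @param config Configuration from [octa_config()]; uses
#'   `gabor_wavelength_px`, `gabor_n_orientations`,
#'   `gabor_bandwidth_octaves`, `hessian_scales_px`.
#' @return A `vesselness_response` (list with `response`, `gabor_params`,
#'   `hessian_scales`).
#' @export
enhance_large_vessels <- function(img, config = octa_config()) {
  stopifnot(inherits(img, "enface_image"))
  if (img$slab != "SCP") {
    stop("large-vessel enhancement applies to the SCP slab", call. = FALSE)
  }
  if (length(config$hessian_scales_px) == 0 ||
      config$gabor_n_orientations < 1) {
    stop("config error: empty filter parameter lists", call. = FALSE)
  }
  if (diff(range(img$pixels)) < 1e-9) {
    # structureless image: the filter outputs are pure numerical noise, so
    # the normalization guard pins the response to zero
    zero <- matrix(0, nrow(img$pixels), ncol(img$pixels))
    return(structure(list(
      response = zero,
      gabor_params = list(wavelength_px = config$gabor_wavelength_px,
                          n_orientations = config$gabor_n_orientations,
                          bandwidth_octaves = config$gabor_bandwidth_octaves),
      hessian_scales = config$hessian_scales_px),
      class = "vesselness_response"))
  }
  gb <- gabor_bank_response(img$pixels,
                            wavelength_px = config$gabor_wavelength_px,
                            n_orientations = config$gabor_n_orientations,
                            bandwidth_octaves = config$gabor_bandwidth_octaves)
  he <- hessian_tubularity(img$pixels, scales_px = config$hessian_scales_px)
  structure(list(
    response = pmax(min_max_norm(gb), min_max_norm(he)),
    gabor_params = list(wavelength_px = config$gabor_wavelength_px,
                        n_orientations = config$gabor_n_orientations,
                        bandwidth_octaves = config$gabor_bandwidth_octaves),
    hessian_scales = config$hessian_scales_px),
    class = "vesselness_response")
}

#' 8-connected component labelling
#'
#' Labels connected foreground components using 8-connectivity (diagonal
#' neighbours connect), by iterated minimum-label propagation until a fixed
#' point. Labels are consecutive integers from 1; background is 0.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels.
#' @export
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- matrix(0, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  big <- sum(mask) + 1
  off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    cur <- lab
    work <- lab
    work[!mask] <- big
    mn <- work
    for (k in seq_len(8)) {
      sh <- shift_mat(work, off[k, 1], off[k, 2])
      mn <- pmin(mn, sh)
    }
    lab[mask] <- mn[mask]
    if (identical(lab, cur)) break
  }
  u <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], u)
  lab
}

#' Segment large vessels from a vesselness response
#'
#' Thresholds the response at a configurable quantile, removes connected
#' components below a minimum size, then closes with a radius-1 disk.
#'
#' @param resp A `vesselness_response` from [enhance_large_vessels()].
#' @param quantile Response quantile for the threshold (default 0.92).
#' @param min_size_px Minimum component size kept (default 50).
#' @param close_radius_px Morphological closing radius (default 1; 0 skips).
#' @return A [binary_map()] labelled `large_vessels`.
#' @export
segment_large_vessels <- function(resp, quantile = 0.92, min_size_px = 50L,
                                  close_radius_px = 1L) {
  r <- if (inherits(resp, "vesselness_response")) resp$response else resp
  thr <- stats::quantile(r, probs = quantile, names = FALSE)
  mask <- r >= thr & r > 0
  if (min_size_px > 1 && any(mask)) {
    lab <- label_components_8(mask)
    sizes <- tabulate(lab[mask])
    keep <- which(sizes >= min_size_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (close_radius_px > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * close_radius_px + 1, "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  binary_map(mask, label = "large_vessels", source_slab = "SCP")
}

#' Binarize retinal vessels at the mean intensity
#'
#' A pixel is vessel iff its intensity is greater than or equal to the mean
#' intensity of the full image (computed before any masking). The inclusive
#' `>=` convention means a constant image classifies every pixel as vessel;
#' the rule is invariant under positive affine intensity transforms.
#'
#' @param img An [enface_image()] with slab SCP or DCP.
#' @return A [binary_map()] labelled `vessels`.
#' @export
binarize_vessels <- function(img) {
  stopifnot(inherits(img, "enface_image"))
  if (!img$slab %in% c("SCP", "DCP")) {
    stop("mean-threshold vessel binarization applies to SCP/DCP slabs",
         call. = FALSE)
  }
  binary_map(img$pixels >= mean(img$pixels), label = "vessels",
             source_slab = img$slab)
}

#' Rasterise a physical-coordinate polygon onto the pixel grid
#'
#' Pixel-centre membership by the even-odd rule; coordinates in
#' magnification-corrected mm, origin at the field centre.
#'
#' @param vertices Two-column matrix of `(x_mm, y_mm)`.
#' @param geometry A [scan_geometry()].
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(vertices, geometry) {
  v <- if (inherits(vertices, "faz_annotation")) vertices$vertices else as.matrix(vertices)
  ctr <- pixel_centers_mm(geometry)
  px <- as.vector(ctr$x_mm); py <- as.vector(ctr$y_mm)
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  matrix(inside, geometry$n_pixels_per_side, geometry$n_pixels_per_side)
}

#' Mask the FAZ out of a vessel map
#'
#' Vessel pixels whose centres fall inside the annotated FAZ polygon are set
#' to non-vessel; all other pixels are unchanged. The annotation layer must
#' match the slab (superficial <-> SCP, deep <-> DCP). A polygon entirely
#' outside the field triggers a warning and returns the map unchanged.
#'
#' @param vessels A [binary_map()] labelled `vessels`.
#' @param faz A [faz_annotation()].
#' @param geometry A [scan_geometry()].
#' @return A [binary_map()] labelled `vessels`.
#' @export
mask_faz <- function(vessels, faz, geometry) {
  stopifnot(inherits(vessels, "binary_map"), inherits(faz, "faz_annotation"))
  expected <- c(superficial = "SCP", deep = "DCP")[[faz$layer]]
  if (!is.na(vessels$source_slab) && vessels$source_slab != expected) {
    stop(sprintf("annotation layer '%s' does not match slab '%s'",
                 faz$layer, vessels$source_slab), call. = FALSE)
  }
  inside <- rasterize_polygon(faz$vertices, geometry)
  if (!any(inside)) {
    warning("FAZ polygon lies entirely outside the field; mask unchanged")
    return(vessels)
  }
  binary_map(vessels$mask & !inside, label = vessels$label,
             source_slab = vessels$source_slab)
}

#' Exclude large-vessel artefacts from the CC slab
#'
#' Superficial large vessels cast decorrelation shadows onto the
#' choriocapillaris; the SCP large-vessel mask, dilated by a configurable
#' radius, defines an artefact region excluded from all downstream CC
#' statistics and metrics. Pixels are not inpainted.
#'
#' @param cc An [enface_image()] with `slab == "CC"`.
#' @param lv_mask A [binary_map()] labelled `large_vessels` from the same
#'   eye's SCP.
#' @param dilate_px Dilation radius in pixels (default 1; 0 = identity).
#' @return List with `image` (the unchanged CC slab) and `artifact`
#'   (a [binary_map()] labelled `artifact`).
#' @export
remove_cc_artifacts <- function(cc, lv_mask, dilate_px = 1L) {
  stopifnot(inherits(cc, "enface_image"), inherits(lv_mask, "binary_map"))
  if (cc$slab != "CC") stop("expected a CC slab", call. = FALSE)
  if (!all(dim(cc$pixels) == dim(lv_mask$mask))) {
    stop("shape mismatch between CC slab and large-vessel mask", call. = FALSE)
  }
  art <- lv_mask$mask
  if (dilate_px > 0 && any(art)) {
    brush <- EBImage::makeBrush(2 * dilate_px + 1, "disc")
    art <- EBImage::dilate(art * 1, brush) > 0.5
  }
  list(image = cc, artifact = binary_map(art, "artifact", source_slab = "CC"))
}

#' Binarize choriocapillaris flow deficits
#'
#' Over non-artefact pixels, computes the mean mu and population standard
#' deviation sigma (divisor N) of the CC intensities; a pixel is a flow
#' deficit iff it is non-artefact and its intensity is strictly below
#' mu - sigma. On a constant image sigma = 0 and no pixel is flagged. The
#' rule is equivariant under positive affine intensity transforms.
#'
#' @param cc An [enface_image()] with `slab == "CC"`.
#' @param artifact A [binary_map()] labelled `artifact` (may be empty).
#' @return A [binary_map()] labelled `flow_deficits`.
#' @export
binarize_flow_deficits <- function(cc, artifact = NULL) {
  stopifnot(inherits(cc, "enface_image"))
  if (cc$slab != "CC") {
    stop("flow-deficit binarization applies to the CC slab", call. = FALSE)
  }
  keep <- if (is.null(artifact)) {
    matrix(TRUE, nrow(cc$pixels), ncol(cc$pixels))
  } else {
    if (!all(dim(artifact$mask) == dim(cc$pixels))) {
      stop("shape mismatch between CC slab and artifact mask", call. = FALSE)
    }
    !artifact$mask
  }
  if (!any(keep)) {
    stop("degenerate input: every pixel is flagged as artefact", call. = FALSE)
  }
  x <- cc$pixels[keep]
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  binary_map(keep & (cc$pixels < mu - sigma), label = "flow_deficits",
             source_slab = "CC")
}
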