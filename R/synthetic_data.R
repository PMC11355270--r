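# Synthetic en-face slabs with known ground truth, and synthetic cohorts
# with prescribed group structure. Every generator is a pure function of
# (recipe, seed): the global RNG state is saved and restored.

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Synthetic FAZ polygon of prescribed area
#'
#' A radially perturbed star polygon: vertex radii are modulated by a
#' smooth random harmonic profile scaled by `irregularity` (0 gives a
#' regular n-gon, whose circularity tends to 1 as n grows), then the whole
#' polygon is rescaled so its shoelace area matches the target to machine
#' precision. Radial polygons are always simple.
#'
#' @param area_mm2_target Target area, mm^2 (> 0).
#' @param irregularity 0 = circle limit; larger values give lobed outlines.
#' @param n_vertices Number of vertices (>= 8).
#' @param seed Integer seed.
#' @param layer `"superficial"` or `"deep"`.
#' @param center_mm Polygon centre in field coordinates.
#' @return A [faz_annotation()].
#' @export
generate_faz_polygon <- function(area_mm2_target, irregularity = 0,
                                 n_vertices = 64L, seed = 1L,
                                 layer = "superficial", center_mm = c(0, 0)) {
  stopifnot(area_mm2_target > 0, n_vertices >= 8, irregularity >= 0)
  with_seed(seed, {
    th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
    r <- rep(1, n_vertices)
    if (irregularity > 0) {
      prof <- rep(0, n_vertices)
      for (k in 2:6) {
        prof <- prof + stats::rnorm(1) / k * cos(k * th + stats::runif(1, 0, 2 * pi))
      }
      prof <- prof / max(abs(prof), 1e-12)
      r <- pmax(1 + irregularity * 0.6 * prof, 0.15)
    }
    v <- cbind(r * cos(th), r * sin(th))
    k <- sqrt(area_mm2_target / polygon_area(v))
    v <- v * k
    v[, 1] <- v[, 1] + center_mm[1]
    v[, 2] <- v[, 2] + center_mm[2]
    faz_annotation(v, layer = layer)
  })
}

#' Recipe for one synthetic en-face slab
#'
#' Targets are fractions of the measurement annulus; the two intensity
#' levels make every binarization stage provably recoverable (the
#' mean-threshold and mean-minus-SD rules separate the levels exactly when
#' `noise_sd = 0`).
#'
#' @param slab `"SCP"`, `"DCP"` or `"CC"`.
#' @param vessel_fraction_target Vessel (capillary + large vessel) area
#'   fraction in the annulus (SCP/DCP).
#' @param lv_fraction_target Approximate large-vessel fraction in the
#'   annulus (SCP only).
#' @param faz_area_mm2_target FAZ area, mm^2 (SCP/DCP).
#' @param faz_irregularity FAZ outline irregularity (0 = circular).
#' @param fd_fraction_target Flow-deficit fraction in the annulus (CC).
#' @param fd_blob_count Number of flow-deficit blobs planted in the annulus
#'   (CC).
#' @param foreground_level,background_level 8-bit intensity levels.
#' @param lv_level Intensity of large-vessel tracks (SCP): arterioles and
#'   venules carry a stronger decorrelation signal than the capillary mesh,
#'   so they render brighter. Must be >= `foreground_level`; vessel
#'   binarization stays exactly recoverable because both vessel levels lie
#'   above the image mean.
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param seed Integer seed.
#' @return A `slab_recipe` list.
#' @export
slab_recipe <- function(slab,
                        vessel_fraction_target = if (slab == "SCP") 0.42 else 0.39,
                        lv_fraction_target = 0.067,
                        faz_area_mm2_target = if (slab == "SCP") 0.34 else 1.14,
                        faz_irregularity = 0.3,
                        fd_fraction_target = 0.17,
                        fd_blob_count = 1379L,
                        foreground_level = 170,
                        background_level = 60,
                        lv_level = 230,
                        noise_sd = 0,
                        seed = 1L) {
  slab <- match.arg(slab, c("SCP", "DCP", "CC"))
  stopifnot(foreground_level > background_level, lv_level >= foreground_level,
            vessel_fraction_target > 0, vessel_fraction_target < 1,
            fd_fraction_target > 0, fd_fraction_target < 0.5,
            noise_sd >= 0)
  structure(list(slab = slab,
                 lv_level = lv_level,
                 vessel_fraction_target = vessel_fraction_target,
                 lv_fraction_target = lv_fraction_target,
                 faz_area_mm2_target = faz_area_mm2_target,
                 faz_irregularity = faz_irregularity,
                 fd_fraction_target = fd_fraction_target,
                 fd_blob_count = as.integer(fd_blob_count),
                 foreground_level = foreground_level,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "slab_recipe")
}

# --- internal geometry helpers -------------------------------------------

default_annulus_mask <- function(geometry) {
  make_annulus_mask(annulus_spec(), geometry)$mask
}

dilate_mask <- function(mask, radius_px) {
  if (radius_px <= 0 || !any(mask)) return(mask)
  EBImage::dilate(mask * 1, EBImage::makeBrush(2 * radius_px + 1, "disc")) > 0.5
}

# Draw random-walk capillary strokes until the mesh reaches the requested
# pixel budget. Strokes are single-pixel calibre: at ~12 um/px a capillary
# (~10 um) is about one pixel wide, so the mesh reads as fine texture to
# filters tuned to large-vessel calibre.
draw_capillary_mesh <- function(n, budget_px, step_sd = 0.35, stroke_len = 60L) {
  mesh <- matrix(FALSE, n, n)
  guard <- 0L
  while (sum(mesh) < budget_px && guard < 4000L) {
    for (b in seq_len(40L)) {
      guard <- guard + 1L
      h <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(stroke_len, 0, step_sd))
      rr <- stats::runif(1, 2, n - 1) + cumsum(sin(h))
      cc <- stats::runif(1, 2, n - 1) + cumsum(cos(h))
      out <- which(rr < 1 | rr > n | cc < 1 | cc > n)
      if (length(out)) {
        if (out[1] == 1) next
        rr <- rr[seq_len(out[1] - 1)]; cc <- cc[seq_len(out[1] - 1)]
      }
      mesh[cbind(round(rr), round(cc))] <- TRUE
    }
  }
  mesh
}

# One smooth vessel track: a gently curved crossing at perpendicular offset
# d_mm from the field centre, dilated to the requested calibre.
draw_one_track <- function(geometry, d_range_mm, width_px) {
  n <- geometry$n_pixels_per_side
  px_mm <- geometry$pixel_size_um / 1000
  phi <- stats::runif(1, 0, 2 * pi)          # crossing direction
  d_mm <- sample(c(-1, 1), 1) * stats::runif(1, d_range_mm[1], d_range_mm[2])
  amp <- stats::runif(1, 0.05, 0.18)         # mm, gentle curvature
  wl <- stats::runif(1, 2.2, 4.5)            # mm
  ph <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(phi), sin(phi)); nv <- c(-sin(phi), cos(phi))
  t_mm <- seq(-2.6, 2.6, by = px_mm / 2)
  off <- d_mm + amp * sin(2 * pi * t_mm / wl + ph)
  x <- t_mm * u[1] + off * nv[1]
  y <- t_mm * u[2] + off * nv[2]
  half <- (n - 1) / 2
  ci <- round(x / px_mm + half) + 1L
  ri <- round(y / px_mm + half) + 1L
  ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
  path <- matrix(FALSE, n, n)
  path[cbind(ri[ok], ci[ok])] <- TRUE
  dilate_mask(path, (width_px - 1L) %/% 2L)
}

# Large-vessel geometry of a macular 3x3 field: arteriole/venule tracks
# (~60 um calibre) crossing the parafovea plus further vessels at the field
# periphery, as in real SCP en-face scans where large vessels are denser
# away from the fovea. Parafoveal tracks are added until the annulus
# fraction reaches the target (approximately; the capillary adjustment
# absorbs the remainder); peripheral vessels are added until large vessels
# occupy ~10% of the whole field, their share in normal macular scans.
draw_lv_tracks <- function(geometry, target_fraction, width_px = 5L,
                           center_avoid_mm = 0.62,
                           field_fraction = 0.10, arcade_width_px = 5L) {
  ann <- default_annulus_mask(geometry)
  lv <- matrix(FALSE, geometry$n_pixels_per_side, geometry$n_pixels_per_side)
  guard <- 0L
  # each full parafoveal crossing adds ~2% of the annulus; stopping half a
  # track early centres the achieved fraction on the target
  while (sum(lv & ann) / sum(ann) < target_fraction - 0.010 && guard < 40L) {
    guard <- guard + 1L
    lv <- lv | draw_one_track(geometry, c(center_avoid_mm, 1.15), width_px)
  }
  guard <- 0L
  while (mean(lv) < field_fraction - 0.015 && guard < 40L) {
    guard <- guard + 1L
    arc <- draw_one_track(geometry, c(1.45, 1.95), arcade_width_px)
    lv <- lv | (arc & !ann)   # arcades stay clear of the measurement annulus
  }
  lv
}

# Exact-count adjustment: add or delete `delta` adjustable pixels inside
# `region` (positive delta adds from `addable`, negative removes from
# `removable`).
adjust_count <- function(mask, region, delta, removable, addable) {
  if (delta > 0) {
    cand <- which(region & addable & !mask)
    if (length(cand) < delta) stop("generation error: cannot reach target fraction", call. = FALSE)
    mask[cand[sample.int(length(cand), delta)]] <- TRUE
  } else if (delta < 0) {
    cand <- which(region & removable & mask)
    if (length(cand) < -delta) stop("generation error: cannot reach target fraction", call. = FALSE)
    mask[cand[sample.int(length(cand), -delta)]] <- FALSE
  }
  mask
}

# Place `count` blobs, mutually separated by at least 2 px (so 8-connected
# counting is unambiguous), totalling exactly `total_px` pixels inside
# `region`. Centres come from a jittered hexagonal lattice; blobs then grow
# one at a time by nearest-first breadth-first search, never stepping onto
# another blob's single-pixel moat.
place_fd_blobs <- function(region, count, total_px) {
  n1 <- nrow(region); n2 <- ncol(region)
  if (total_px < count) stop("generation error: fewer pixels than blobs", call. = FALSE)
  area <- sum(region)
  if (area < total_px) stop("generation error: region too small for target", call. = FALSE)

  pitch <- max(2.6, sqrt(2 * area / (sqrt(3) * count)))
  centers <- NULL
  for (try in seq_len(40L)) {
    dy <- pitch * sqrt(3) / 2
    rows <- seq(1 + dy / 2, n1, by = dy)
    pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
      xs <- seq(1 + (i %% 2) * pitch / 2, n2, by = pitch)
      cbind(rows[i] + stats::runif(length(xs), -0.3, 0.3),
            xs + stats::runif(length(xs), -0.3, 0.3))
    }))
    ri <- pmin(pmax(round(pts[, 1]), 1L), n1)
    ci <- pmin(pmax(round(pts[, 2]), 1L), n2)
    keep <- region[cbind(ri, ci)]
    cand <- unique(cbind(ri[keep], ci[keep]))
    if (nrow(cand) >= count) { centers <- cand; break }
    pitch <- pitch * 0.93
    if (pitch < 2.2) break
  }
  if (is.null(centers)) {
    stop("generation error: could not place the requested blob count", call. = FALSE)
  }
  centers <- centers[sample.int(nrow(centers), count), , drop = FALSE]

  alloc <- rep(total_px %/% count, count)
  extra <- total_px - sum(alloc)
  if (extra > 0) {
    idx <- sample.int(count, extra)
    alloc[idx] <- alloc[idx] + 1L
  }

  owner <- matrix(0L, n1, n2)   # 0 free, i claimed by blob i
  # frontier state per blob, kept so stalled blobs can be re-grown later
  frontier_r <- vector("list", count)
  frontier_c <- vector("list", count)
  grown <- integer(count)

  eligible <- function(r, c, i) {
    if (r < 1 || r > n1 || c < 1 || c > n2) return(FALSE)
    if (!region[r, c] || owner[r, c] != 0L) return(FALSE)
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= n1 && cc >= 1 && cc <= n2) {
        o <- owner[rr, cc]
        if (o != 0L && o != i) return(FALSE)
      }
    }
    TRUE
  }

  grow_blob <- function(i, want) {
    fr <- frontier_r[[i]]; fc <- frontier_c[[i]]
    got <- 0L
    while (got < want && length(fr)) {
      d2 <- (fr - centers[i, 1])^2 + (fc - centers[i, 2])^2
      k <- which.min(d2)
      r <- fr[k]; c <- fc[k]
      fr <- fr[-k]; fc <- fc[-k]
      if (!eligible(r, c, i)) next
      owner[r, c] <<- i
      got <- got + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        fr <- c(fr, r + dr); fc <- c(fc, c + dc)
      }
    }
    frontier_r[[i]] <<- fr; frontier_c[[i]] <<- fc
    got
  }

  ord <- sample.int(count)
  for (i in ord) {
    frontier_r[[i]] <- centers[i, 1]
    frontier_c[[i]] <- centers[i, 2]
    grown[i] <- grow_blob(i, alloc[i])
  }
  shortfall <- total_px - sum(grown)
  pass <- 0L
  while (shortfall > 0 && pass < 8L) {
    pass <- pass + 1L
    for (i in sample.int(count)) {
      if (shortfall == 0L) break
      add <- grow_blob(i, shortfall)
      grown[i] <- grown[i] + add
      shortfall <- shortfall - add
    }
  }
  if (shortfall > 0 || any(grown == 0L)) {
    stop("generation error: cannot reach target fraction with requested blob count",
         call. = FALSE)
  }
  owner > 0L
}

#' Generate one synthetic en-face slab with ground truth
#'
#' Retinal slabs (SCP/DCP) are a seeded random curvilinear capillary mesh
#' at capillary calibre, with the FAZ carved out as a radially perturbed
#' polygon of the target area; the SCP additionally carries thick smooth
#' large-vessel tracks. The vessel fraction inside the default measurement
#' annulus is adjusted to the exact pixel count nearest the target, and the
#' whole-field (non-FAZ) fraction is held within 0.01 of the target. The CC
#' slab is a background texture with `fd_blob_count` dark flow-deficit
#' blobs, mutually separated by at least 2 px, totalling the exact in-region
#' pixel count nearest `fd_fraction_target`.
#'
#' Intensities are two-level (foreground/background) plus optional clipped
#' Gaussian noise; truth masks are returned before noise, so with
#' `noise_sd = 0` the mean-threshold and mean-minus-SD binarization rules
#' recover them exactly.
#'
#' @param recipe A [slab_recipe()].
#' @param geometry A [scan_geometry()].
#' @param lv_shadow Optional logical matrix (or [binary_map()]) of SCP
#'   large-vessel positions; for CC slabs these are painted as dark shadow
#'   artefacts and flow-deficit blobs avoid their 2 px neighbourhood.
#' @return List with `image` (an [enface_image()]) and `truth`: the
#'   pre-noise `vessel_mask`, `lv_mask`, `faz_polygon`, `fd_mask`, plus the
#'   achieved in-annulus fractions `vessel_fraction`, `lv_fraction`,
#'   `fd_fraction`.
#' @export
generate_enface <- function(recipe, geometry = scan_geometry(),
                            lv_shadow = NULL) {
  stopifnot(inherits(recipe, "slab_recipe"))
  with_seed(recipe$seed, {
    n <- geometry$n_pixels_per_side
    ann <- default_annulus_mask(geometry)
    fg <- recipe$foreground_level; bg <- recipe$background_level
    truth <- list(vessel_mask = NULL, lv_mask = matrix(FALSE, n, n),
                  faz_polygon = NULL, fd_mask = matrix(FALSE, n, n))

    if (recipe$slab %in% c("SCP", "DCP")) {
      layer <- if (recipe$slab == "SCP") "superficial" else "deep"
      faz <- generate_faz_polygon(recipe$faz_area_mm2_target,
                                  recipe$faz_irregularity,
                                  n_vertices = 64L,
                                  seed = recipe$seed + 101L, layer = layer)
      faz_px <- rasterize_polygon(faz$vertices, geometry)
      lv <- matrix(FALSE, n, n)
      if (recipe$slab == "SCP" && recipe$lv_fraction_target > 0) {
        lv <- draw_lv_tracks(geometry, recipe$lv_fraction_target)
        lv <- lv & !faz_px
      }
      f <- recipe$vessel_fraction_target
      nonfaz <- !faz_px
      mesh <- draw_capillary_mesh(n, budget_px = ceiling(f * sum(nonfaz) * 1.1))
      vessels <- (mesh | lv) & nonfaz
      # exact pixel count inside the annulus, capillary pixels adjustable
      target_ann <- round(f * sum(ann))
      vessels <- adjust_count(vessels, ann, target_ann - sum(vessels & ann),
                              removable = !lv, addable = nonfaz)
      # outside the annulus the mesh is thinned to the same non-FAZ density
      # as inside it, so the field is spatially uniform (the annulus target
      # counts FAZ-overlap pixels in its denominator, as the perfusion
      # density measurement does)
      outside <- nonfaz & !ann
      f_uniform <- target_ann / sum(ann & nonfaz)
      target_out <- round(f_uniform * sum(outside))
      vessels <- adjust_count(vessels, outside,
                              target_out - sum(vessels & outside),
                              removable = !lv, addable = nonfaz)
      img <- matrix(bg, n, n)
      img[vessels] <- fg
      img[lv & vessels] <- recipe$lv_level
      truth$vessel_mask <- vessels
      truth$lv_mask <- lv
      truth$faz_polygon <- faz
      truth$vessel_fraction <- sum(vessels & ann) / sum(ann)
      truth$lv_fraction <- sum(lv & ann) / sum(ann)
    } else {
      # CC: dark blobs on bright background; levels swap roles
      hi <- max(fg, bg); lo <- min(fg, bg)
      avoid <- matrix(FALSE, n, n)
      shadow <- matrix(FALSE, n, n)
      if (!is.null(lv_shadow)) {
        shadow <- if (inherits(lv_shadow, "binary_map")) lv_shadow$mask else lv_shadow
        avoid <- dilate_mask(shadow, 2L)
      }
      region <- ann & !avoid
      total <- round(recipe$fd_fraction_target * sum(region))
      fd <- place_fd_blobs(region, recipe$fd_blob_count, total)
      img <- matrix(hi, n, n)
      img[fd] <- lo
      img[shadow] <- round((hi + lo) / 2)   # dark decorrelation shadow
      truth$fd_mask <- fd
      truth$fd_fraction <- sum(fd & region) / sum(region)
    }

    if (recipe$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, recipe$noise_sd)
    }
    img <- round(pmin(pmax(img, 0), 255))
    list(image = enface_image(img, slab = recipe$slab, geometry = geometry,
                              eye_id = sprintf("synthetic_%s_seed%d",
                                               recipe$slab, recipe$seed)),
         truth = truth)
  })
}

#' Generate a complete synthetic eye (SCP + DCP + CC + FAZ annotations)
#'
#' Convenience wrapper composing [generate_enface()] for the three slabs of
#' one eye on a shared geometry. The CC slab carries shadow artefacts at the
#' SCP large-vessel positions, and its flow-deficit blobs avoid them.
#'
#' @param geometry A [scan_geometry()].
#' @param seed Integer seed.
#' @param scp_recipe,dcp_recipe,cc_recipe Optional [slab_recipe()]
#'   overrides (their `seed` fields are derived from `seed` if left NULL).
#' @return List with `scp`, `dcp`, `cc` ([enface_image()]s), `faz_sup`,
#'   `faz_deep` ([faz_annotation()]s) and `truth` (per-slab truth lists).
#' @export
generate_synthetic_eye <- function(geometry = scan_geometry(), seed = 1L,
                                   scp_recipe = NULL, dcp_recipe = NULL,
                                   cc_recipe = NULL) {
  scp_recipe <- scp_recipe %||% slab_recipe("SCP", seed = seed)
  dcp_recipe <- dcp_recipe %||% slab_recipe("DCP", seed = seed + 1000L)
  cc_recipe <- cc_recipe %||% slab_recipe("CC", seed = seed + 2000L)
  scp <- generate_enface(scp_recipe, geometry)
  dcp <- generate_enface(dcp_recipe, geometry)
  cc <- generate_enface(cc_recipe, geometry, lv_shadow = scp$truth$lv_mask)
  list(scp = scp$image, dcp = dcp$image, cc = cc$image,
       faz_sup = scp$truth$faz_polygon, faz_deep = dcp$truth$faz_polygon,
       truth = list(scp = scp$truth, dcp = dcp$truth, cc = cc$truth))
}

#' Recipe for a synthetic two-group cohort
#'
#' Continuous variables are drawn from per-group normals, binary variables
#' from per-group Bernoullis. The default parameters are the published
#' normative group summaries for healthy Chinese (n = 92) and Caucasian
#' (n = 99) adults: demographics/biometry (age, axial length, spherical
#' equivalent, IOP, signal strength) and the 13 annulus OCTA metrics.
#'
#' @param n Per-group sizes (length 2).
#' @param groups Group labels.
#' @param continuous Named list; each element `c(mean1, sd1, mean2, sd2)`.
#' @param binary Named list; each element `c(p1, p2)`.
#' @param null_effect If TRUE, group 2 parameters are replaced by group 1's
#'   (a zero-effect cohort for type-I-error checks).
#' @param seed Integer seed.
#' @return A `cohort_recipe` list.
#' @export
cohort_recipe <- function(n = c(92L, 99L),
                          groups = c("Chinese", "Caucasian"),
                          continuous = list(
                            age = c(44, 13, 42, 14),
                            axial_length_mm = c(24.7, 1.5, 23.2, 0.9),
                            spherical_equivalent = c(-2.4, 3.3, -0.1, 1.9),
                            iop_mmHg = c(16.8, 3.3, 15.1, 2.4),
                            signal_strength = c(9.3, 0.9, 9.4, 1.0),
                            pd_lv_pct = c(6.7, 0.8, 6.6, 0.8),
                            pd_scp_pct = c(42.4, 2.6, 40.9, 2.5),
                            pd_scp_wo_lv_pct = c(29.6, 2.6, 28.6, 2.4),
                            pd_dcp_pct = c(39.1, 3.6, 40.1, 3.4),
                            faz_sup_area_mm2 = c(0.34, 0.1, 0.28, 0.1),
                            faz_sup_perimeter_mm = c(2.41, 0.6, 2.14, 0.5),
                            faz_sup_circularity = c(1.19, 0.2, 1.18, 0.1),
                            faz_deep_area_mm2 = c(1.14, 0.3, 1.11, 0.3),
                            faz_deep_perimeter_mm = c(4.04, 0.6, 4.12, 0.6),
                            faz_deep_circularity = c(1.08, 0.1, 1.11, 0.1),
                            fd_density_pct = c(17.2, 1.7, 16.7, 1.6),
                            fd_size_um2 = c(508, 96, 496, 91),
                            fd_number = c(1379, 129, 1407, 121)),
                          binary = list(
                            sex_female = c(63 / 92, 63 / 99),
                            diabetes = c(0 / 92, 2 / 99),
                            hypertension = c(17 / 92, 11 / 99)),
                          null_effect = FALSE,
                          seed = 1L) {
  stopifnot(length(n) == 2, all(n >= 2))
  stopifnot(all(vapply(continuous, function(v) length(v) == 4 && v[2] >= 0 && v[4] >= 0, TRUE)))
  stopifnot(all(vapply(binary, function(p) length(p) == 2 && all(p >= 0 & p <= 1), TRUE)))
  if (null_effect) {
    continuous <- lapply(continuous, function(v) c(v[1], v[2], v[1], v[2]))
    binary <- lapply(binary, function(p) c(p[1], p[1]))
  }
  structure(list(n = as.integer(n), groups = groups, continuous = continuous,
                 binary = binary, seed = as.integer(seed)),
            class = "cohort_recipe")
}

#' Generate a synthetic participant table
#'
#' @param recipe A [cohort_recipe()].
#' @return Data.frame with `participant_id`, `ethnicity`, `sex`, the binary
#'   and continuous variables of the recipe; reproducible by seed.
#' @export
generate_cohort <- function(recipe = cohort_recipe()) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  with_seed(recipe$seed, {
    out <- lapply(1:2, function(g) {
      ng <- recipe$n[g]
      df <- data.frame(
        participant_id = sprintf("%s_%03d", substr(recipe$groups[g], 1, 3), seq_len(ng)),
        ethnicity = recipe$groups[g], stringsAsFactors = FALSE)
      for (nm in names(recipe$binary)) {
        p <- recipe$binary[[nm]][g]
        df[[nm]] <- stats::rbinom(ng, 1, p)
      }
      for (nm in names(recipe$continuous)) {
        v <- recipe$continuous[[nm]]
        df[[nm]] <- stats::rnorm(ng, v[2 * g - 1], v[2 * g])
      }
      df
    })
    out <- rbind(out[[1]], out[[2]])
    if ("sex_female" %in% names(out)) {
      out$sex <- ifelse(out$sex_female == 1, "F", "M")
    }
    out
  })
}
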