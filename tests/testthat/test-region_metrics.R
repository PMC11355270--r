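test_that("annulus rasterisation matches the analytic area fraction", {
  g <- design_geometry()
  ann <- make_annulus_mask(annulus_spec(), g)
  analytic <- pi * (1.25^2 - 0.5^2) / 9
  expect_equal(mean(ann$mask), analytic, tolerance = 0.01)
  # coarser sampling of the same physical annulus keeps the area ratio
  g2 <- scan_geometry(n_pixels_per_side = 123L, axial_length_mm = 24.46)
  ann2 <- make_annulus_mask(annulus_spec(), g2)
  expect_equal(mean(ann2$mask), analytic, tolerance = 0.02)
  # tiny inner ring, outer ring covering the field: nearly every pixel
  expect_warning(
    big <- make_annulus_mask(
      annulus_spec(inner_diameter_mm = 0.02, outer_diameter_mm = 6), g),
    "beyond")
  expect_gt(mean(big$mask), 0.999)
  expect_error(annulus_spec(inner_diameter_mm = 2, outer_diameter_mm = 1),
               "config error")
})

test_that("perfusion density counts pixels exactly", {
  g <- design_geometry()
  ann <- make_annulus_mask(annulus_spec(), g)
  n <- g$n_pixels_per_side
  expect_equal(perfusion_density(matrix(TRUE, n, n), ann), 100.0)
  checker <- matrix((row(matrix(0, n, n)) + col(matrix(0, n, n))) %% 2 == 0, n, n)
  expect_equal(perfusion_density(checker, ann), 50.0, tolerance = 0.1)
  # planted exact fraction
  idx <- which(ann$mask)
  planted <- matrix(FALSE, n, n)
  planted[idx[seq_len(round(0.3 * length(idx)))]] <- TRUE
  expect_equal(perfusion_density(planted, ann),
               100 * round(0.3 * length(idx)) / length(idx))
  expect_error(perfusion_density(planted, binary_map(matrix(FALSE, n, n), "annulus")),
               "degenerate")
})

test_that("flow-deficit density and components count planted structure", {
  g <- design_geometry()
  ann <- make_annulus_mask(annulus_spec(), g)
  n <- g$n_pixels_per_side
  none <- matrix(FALSE, n, n)
  expect_equal(fd_density(none, ann), 0.0)
  expect_equal(fd_density(ann$mask, ann), 100.0)
  comp0 <- fd_components(none, ann, g)
  expect_equal(comp0$fd_count, 0L)
  expect_true(is.na(comp0$fd_mean_size_um2))
  # 5 disjoint planted disks inside the annulus
  ctr <- pixel_centers_mm(g)
  disks <- none
  centers <- cbind(c(0.8, -0.8, 0, 0, 0.6), c(0, 0, 0.8, -0.8, -0.6))
  for (i in 1:5) {
    d <- sqrt((ctr$x_mm - centers[i, 1])^2 + (ctr$y_mm - centers[i, 2])^2)
    disks <- disks | (d < 0.05)
  }
  comp5 <- fd_components(disks, ann, g)
  expect_equal(comp5$fd_count, 5L)
  # one planted component of exactly 100 px
  one <- none
  one[110:119, 61:70] <- TRUE
  comp1 <- fd_components(one, ann, g)
  expect_equal(comp1$fd_count, 1L)
  expect_equal(comp1$fd_mean_size_um2, 100 * g$pixel_size_um^2)
  expect_equal(comp1$fd_mean_size_um2, 14993.8, tolerance = 1)
})

test_that("adding vessel pixels never decreases perfusion density", {
  g <- design_geometry()
  ann <- make_annulus_mask(annulus_spec(), g)
  n <- g$n_pixels_per_side
  set.seed(9)
  m <- matrix(runif(n * n) < 0.3, n, n)
  pd0 <- perfusion_density(m, ann)
  extra <- m
  extra[which(!extra)[sample.int(sum(!extra), 500)]] <- TRUE
  expect_gte(perfusion_density(extra, ann), pd0)
})

test_that("the pipeline recovers planted densities on a synthetic eye", {
  eye <- fixture_eye()
  m <- fixture_metrics()
  tr <- eye$truth
  expect_equal(m$pd_scp_pct, 100 * tr$scp$vessel_fraction, tolerance = 0.01)
  expect_equal(m$pd_scp_pct, 42.0, tolerance = 0.01)
  expect_equal(m$pd_dcp_pct, 100 * tr$dcp$vessel_fraction, tolerance = 0.01)
  expect_equal(m$pd_dcp_pct, 39.0, tolerance = 0.01)
  # CC: artefact exclusion uses the measured (not planted) LV mask, so the
  # recovered density can drift from the planted fraction by a fraction of
  # a percentage point
  expect_equal(m$fd_density_pct, 100 * tr$cc$fd_fraction, tolerance = 1.0)
  # large-vessel PD carries the threshold-spill bias of quantile
  # segmentation (see the methods vignette); tolerance is wider
  expect_equal(m$pd_lv_pct, 100 * tr$scp$lv_fraction, tolerance = 1.5)
  expect_lte(m$pd_scp_wo_lv_pct, m$pd_scp_pct)
  # FAZ metrics flow through from the annotation polygons exactly
  expect_equal(m$faz_sup_area_mm2, 0.34, tolerance = 1e-9)
  expect_equal(m$faz_deep_area_mm2, 1.14, tolerance = 1e-9)
  expect_gte(m$faz_sup_circularity, 1)
})

test_that("metrics are invariant to a left-right flip of the field", {
  eye <- fixture_eye()
  g <- eye$scp$geometry
  flip <- function(img) {
    enface_image(img$pixels[, ncol(img$pixels):1], img$slab, img$geometry,
                 img$signal_strength, img$eye_id, img$laterality)
  }
  flip_poly <- function(f) {
    v <- f$vertices; v[, 1] <- -v[, 1]
    faz_annotation(v[nrow(v):1, ], f$layer)
  }
  m0 <- fixture_metrics()
  m1 <- compute_all_metrics(flip(eye$scp), flip(eye$dcp), flip(eye$cc),
                            flip_poly(eye$faz_sup), flip_poly(eye$faz_deep))
  for (col in c("pd_scp_pct", "pd_dcp_pct", "fd_density_pct",
                "faz_sup_area_mm2", "faz_deep_perimeter_mm")) {
    expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("the pipeline is deterministic and aborts with stage-labelled errors", {
  eye <- fixture_eye()
  m1 <- compute_all_metrics(eye$scp, eye$dcp, eye$cc, eye$faz_sup, eye$faz_deep)
  m2 <- compute_all_metrics(eye$scp, eye$dcp, eye$cc, eye$faz_sup, eye$faz_deep)
  attr(m1, "masks") <- NULL; attr(m2, "masks") <- NULL
  expect_identical(m1, m2)
  expect_error(
    compute_all_metrics(eye$scp, eye$dcp, eye$cc, eye$faz_deep, eye$faz_sup),
    "stage\\[mask_faz\\]")
  g_small <- small_geometry()
  tiny <- enface_image(matrix(0, 101, 101), "CC", g_small)
  expect_error(compute_all_metrics(eye$scp, eye$dcp, tiny, eye$faz_sup,
                                   eye$faz_deep), "share one scan geometry")
})
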