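test_that("vessel enhancement responds to a bar and not to flat images", {
  bar <- bar_image(width = 6)
  truth <- bar$pixels > 100
  resp <- enhance_large_vessels(bar)
  center <- matrix(FALSE, 101, 101)
  center[51, ] <- TRUE   # bar centreline (bar rows 48..53)
  center <- center & truth
  bg <- !EBImage::dilate(truth * 1, EBImage::makeBrush(15, "disc")) > 0.5
  expect_gt(mean(resp$response[center]), 3 * mean(resp$response[bg]))

  flat <- enface_image(matrix(120, 101, 101), "SCP", small_geometry())
  expect_lt(max(enhance_large_vessels(flat)$response), 1e-6)

  expect_error(enhance_large_vessels(
    bar, octa_config(hessian_scales_px = numeric(0))), "config error")
  dcp <- bar_image(slab = "DCP")
  expect_error(enhance_large_vessels(dcp), "SCP")
})

test_that("the orientation bank is isotropic across bar rotations", {
  h <- bar_image(width = 6, vertical = FALSE)
  v <- bar_image(width = 6, vertical = TRUE)
  rh <- enhance_large_vessels(h)$response
  rv <- enhance_large_vessels(v)$response
  on_h <- mean(rh[h$pixels > 100])
  on_v <- mean(rv[v$pixels > 100])
  expect_lt(abs(on_h - on_v) / on_h, 0.05)
})

test_that("large-vessel segmentation covers a planted bar and little else", {
  bar <- bar_image(width = 6)
  truth <- bar$pixels > 100
  resp <- enhance_large_vessels(bar)
  # quantile matched to the planted coverage of this phantom (6/101 of pixels)
  lv <- segment_large_vessels(resp, quantile = 1 - mean(truth))
  expect_gte(sum(lv$mask & truth) / sum(truth), 0.80)
  expect_lte(sum(lv$mask & !truth) / sum(!truth), 0.02)

  empty <- segment_large_vessels(matrix(0, 64, 64))
  expect_false(any(empty$mask))
})

test_that("two parallel bars segment into two components", {
  two <- bar_image(width = 6, row0 = 20L)
  two$pixels[70:75, ] <- 200
  truth <- two$pixels > 100
  resp <- enhance_large_vessels(two)
  lv <- segment_large_vessels(resp, quantile = 1 - mean(truth))
  lab <- label_components_8(lv$mask)
  expect_equal(max(lab), 2L)
})

test_that("segmentation threshold is monotone in the quantile", {
  resp <- enhance_large_vessels(fixture_eye()$scp)
  prev <- NULL
  for (q in c(0.85, 0.90, 0.95)) {
    m <- segment_large_vessels(resp, quantile = q, min_size_px = 0,
                               close_radius_px = 0)$mask
    if (!is.null(prev)) expect_true(all(prev | !m))  # m subset of prev
    prev <- m
  }
})

test_that("mean-intensity vessel binarization is exact and affine-invariant", {
  g <- scan_geometry(n_pixels_per_side = 10, axial_length_mm = 24)
  px <- matrix(0, 10, 10); px[1:5, ] <- 200
  img <- enface_image(px, "SCP", g)
  v <- binarize_vessels(img)
  expect_identical(v$mask, px == 200)

  const <- binarize_vessels(enface_image(matrix(37, 10, 10), "DCP", g))
  expect_true(all(const$mask))

  set.seed(2)
  px2 <- matrix(sample(0:100, 100, replace = TRUE), 10, 10)
  v1 <- binarize_vessels(enface_image(px2, "SCP", g))
  v2 <- binarize_vessels(enface_image(2 * px2 + 10, "SCP", g))
  expect_identical(v1$mask, v2$mask)

  cc <- enface_image(px2, "CC", g)
  expect_error(binarize_vessels(cc), "SCP/DCP")
})

test_that("FAZ masking clears exactly the rasterized polygon and is idempotent", {
  g <- small_geometry()
  full <- binary_map(matrix(TRUE, 101, 101), "vessels", "SCP")
  sq <- faz_annotation(0.5 * rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)),
                       "superficial")
  inside <- rasterize_polygon(sq$vertices, g)
  masked <- mask_faz(full, sq, g)
  expect_equal(sum(full$mask) - sum(masked$mask), sum(inside))
  expect_identical(mask_faz(masked, sq, g)$mask, masked$mask)
  # rasterized square of side 1 mm covers ~ (1/pixel_mm)^2 pixels
  expect_equal(sum(inside), (1000 / g$pixel_size_um)^2, tolerance = 0.05)

  empty <- binary_map(matrix(FALSE, 101, 101), "vessels", "SCP")
  expect_false(any(mask_faz(empty, sq, g)$mask))

  far <- faz_annotation(sq$vertices + 10, "superficial")
  expect_warning(same <- mask_faz(full, far, g), "outside")
  expect_identical(same$mask, full$mask)

  deep_sq <- faz_annotation(sq$vertices, "deep")
  expect_error(mask_faz(full, deep_sq, g), "does not match")
})

test_that("masking with two disjoint polygons commutes", {
  g <- small_geometry()
  full <- binary_map(matrix(TRUE, 101, 101), "vessels", "SCP")
  a <- faz_annotation(0.2 * rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)) - 0.4,
                      "superficial")
  b <- faz_annotation(0.2 * rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)) + 0.4,
                      "superficial")
  ab <- mask_faz(mask_faz(full, a, g), b, g)
  ba <- mask_faz(mask_faz(full, b, g), a, g)
  expect_identical(ab$mask, ba$mask)
})

test_that("CC artefact exclusion dilates the LV mask and lifts the clean mean", {
  g <- scan_geometry(n_pixels_per_side = 20, axial_length_mm = 24)
  px <- matrix(160, 20, 20)
  lv <- matrix(FALSE, 20, 20); lv[8:12, ] <- TRUE
  px[lv] <- 70   # dark shadow under the large vessels
  cc <- enface_image(px, "CC", g)
  res0 <- remove_cc_artifacts(cc, binary_map(lv, "large_vessels", "SCP"),
                              dilate_px = 0)
  expect_identical(res0$artifact$mask, lv)
  res1 <- remove_cc_artifacts(cc, binary_map(lv, "large_vessels", "SCP"),
                              dilate_px = 1)
  expect_true(all(res1$artifact$mask[lv]))
  expect_gt(sum(res1$artifact$mask), sum(lv))
  expect_gt(mean(px[!res1$artifact$mask]), mean(px))

  none <- remove_cc_artifacts(cc, binary_map(matrix(FALSE, 20, 20),
                                             "large_vessels", "SCP"))
  expect_false(any(none$artifact$mask))
  bad <- binary_map(matrix(FALSE, 10, 10), "large_vessels", "SCP")
  expect_error(remove_cc_artifacts(cc, bad), "shape mismatch")
})

test_that("flow-deficit threshold sits one SD below the mean", {
  g <- scan_geometry(n_pixels_per_side = 20, axial_length_mm = 24)
  # two-point distribution: 95% at 180, 5% at 20 -> mu - sigma ~ 137.2
  px <- matrix(180, 20, 20)
  px[seq_len(20)] <- 20
  cc <- enface_image(px, "CC", g)
  fd <- binarize_flow_deficits(cc)
  expect_identical(fd$mask, px == 20)
  mu <- mean(px); sig <- sqrt(mean((px - mu)^2))
  expect_equal(mu - sig, 137.2, tolerance = 0.1)

  const <- binarize_flow_deficits(enface_image(matrix(90, 20, 20), "CC", g))
  expect_false(any(const$mask))

  fd2 <- binarize_flow_deficits(enface_image(px / 2 + 10, "CC", g))
  expect_identical(fd2$mask, fd$mask)

  all_art <- binary_map(matrix(TRUE, 20, 20), "artifact", "CC")
  expect_error(binarize_flow_deficits(cc, all_art), "degenerate")
})

test_that("8-connected labelling joins diagonals and separates gaps", {
  m <- matrix(FALSE, 7, 7)
  m[cbind(1:5, 1:5)] <- TRUE          # diagonal chain: one component
  m[7, 7] <- TRUE                      # separated by > 1 px
  lab <- label_components_8(m)
  expect_equal(max(lab), 2L)
  expect_equal(length(unique(lab[cbind(1:5, 1:5)])), 1L)
  expect_equal(max(label_components_8(matrix(FALSE, 4, 4))), 0)
})
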