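# Shared fixtures, built in code. The synthetic eye and the vesselness
# response are comparatively expensive, so they are generated once per test
# run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

design_geometry <- function(n = 245L) {
  scan_geometry(n_pixels_per_side = n, axial_length_mm = 24.46)
}

fixture_eye <- function(seed = 42L) {
  key <- paste0("eye", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_synthetic_eye(design_geometry(), seed = seed)
  }
  .fixtures[[key]]
}

fixture_metrics <- function(seed = 42L) {
  key <- paste0("metrics", seed)
  if (is.null(.fixtures[[key]])) {
    eye <- fixture_eye(seed)
    .fixtures[[key]] <- compute_all_metrics(eye$scp, eye$dcp, eye$cc,
                                            eye$faz_sup, eye$faz_deep)
  }
  .fixtures[[key]]
}

# a small geometry for cheap image-op tests (101 px so filter kernels fit)
small_geometry <- function() scan_geometry(n_pixels_per_side = 101L,
                                           axial_length_mm = 24.46)

# bright horizontal bar of given width on a flat background
bar_image <- function(n = 101L, width = 6L, fg = 200, bg = 50,
                      row0 = NULL, slab = "SCP", vertical = FALSE) {
  px <- matrix(bg, n, n)
  row0 <- row0 %||% ((n - width) %/% 2L)
  rows <- row0 + seq_len(width)
  if (vertical) px[, rows] <- fg else px[rows, ] <- fg
  enface_image(px, slab = slab,
               geometry = scan_geometry(n_pixels_per_side = n,
                                        axial_length_mm = 24.46))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
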