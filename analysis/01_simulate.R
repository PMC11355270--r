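#!/usr/bin/env Rscript
# Step 1 — simulate one synthetic study eye and a synthetic two-group cohort.
#
# Writes, under results/simulated/:
#   scp.png, dcp.png, cc.png        en-face slabs (8-bit grayscale)
#   truth_*.png                     ground-truth masks (0/255)
#   faz_superficial.json, faz_deep.json
#   participants.csv                synthetic cohort drawn from the
#                                   published normative group parameters
#   recipe.json                     provenance (geometry, seeds)

suppressMessages(library(octaquant))

seed <- 20260925L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
t0 <- Sys.time()
log_stage <- function(...) message(sprintf("[%5.1fs] ",
  as.numeric(Sys.time() - t0, units = "secs")), sprintf(...))

geom <- scan_geometry(axial_length_mm = 24.46)
log_stage("geometry: %d px, %.4f um/px", geom$n_pixels_per_side,
          geom$pixel_size_um)

eye <- generate_synthetic_eye(geom, seed = seed)
log_stage("generated SCP/DCP/CC slabs (planted: vessels %.1f%%/%.1f%%, LV %.1f%%, FD %.1f%%)",
          100 * eye$truth$scp$vessel_fraction,
          100 * eye$truth$dcp$vessel_fraction,
          100 * eye$truth$scp$lv_fraction,
          100 * eye$truth$cc$fd_fraction)

write_enface_png(eye$scp, file.path(out, "scp.png"))
write_enface_png(eye$dcp, file.path(out, "dcp.png"))
write_enface_png(eye$cc, file.path(out, "cc.png"))
write_enface_png(binary_map(eye$truth$scp$vessel_mask, "vessels", "SCP"),
                 file.path(out, "truth_vessels_scp.png"))
write_enface_png(binary_map(eye$truth$scp$lv_mask, "large_vessels", "SCP"),
                 file.path(out, "truth_large_vessels.png"))
write_enface_png(binary_map(eye$truth$dcp$vessel_mask, "vessels", "DCP"),
                 file.path(out, "truth_vessels_dcp.png"))
write_enface_png(binary_map(eye$truth$cc$fd_mask, "flow_deficits", "CC"),
                 file.path(out, "truth_flow_deficits.png"))
write_faz_annotation(eye$faz_sup, file.path(out, "faz_superficial.json"))
write_faz_annotation(eye$faz_deep, file.path(out, "faz_deep.json"))
log_stage("wrote slabs, truth masks and FAZ annotations")

cohort <- generate_cohort(cohort_recipe(seed = seed))
utils::write.csv(cohort, file.path(out, "participants.csv"), row.names = FALSE)
log_stage("wrote synthetic cohort: %d participants (%d Chinese / %d Caucasian)",
          nrow(cohort), sum(cohort$ethnicity == "Chinese"),
          sum(cohort$ethnicity == "Caucasian"))

jsonlite::write_json(
  list(seed = seed, axial_length_mm = 24.46, n_pixels = 245,
       generated = format(Sys.time(), "%Y-%m-%d")),
  file.path(out, "recipe.json"), auto_unbox = TRUE)
log_stage("done; outputs under %s", out)
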