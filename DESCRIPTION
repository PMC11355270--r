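Package: octaquant
Title: Quantification of En-Face OCT Angiography Slabs and Cohort Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 3 x 3 mm en-face optical coherence tomography
    angiography (OCTA) slabs of the superficial and deep retinal capillary
    plexus and the choriocapillaris: ocular magnification correction from
    axial length (Bennett's formula), large-vessel enhancement with Gabor and
    Hessian vesselness filters, mean-intensity vessel binarization, foveal
    avascular zone (FAZ) morphometry (area, perimeter, circularity),
    choriocapillaris flow-deficit detection one standard deviation below the
    mean, and regional quantification over a fovea-centered annulus. Includes
    cohort statistics (eligibility filtering, random eye selection, pooled
    t-tests from summary statistics, 2x2 chi-square tests, covariate-adjusted
    linear regression) and a synthetic-data generator producing en-face slabs
    with known ground-truth masks and cohort tables with prescribed group
    structure, so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
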