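Package: trabflow
Title: Fluid Mechanics of Trabeculated Embryonic Ventricles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Moving-boundary low-Reynolds-number flow analysis of the
    trabeculated embryonic zebrafish ventricle at desk scale. Provides a
    seeded parametric generator for beating ventricular cross-sections with
    intra-trabecular grooves and trapped hemogenic cells, a quasi-steady
    Stokes finite-element solver (Taylor-Hood P2/P1 triangles) driven by
    prescribed wall motion with phase-switched zero-reference-pressure
    openings, wall shear stress, time-averaged wall shear stress, oscillatory
    shear index, mixed-viscosity, endocardial area-strain and exact Wilcoxon
    signed-rank analyses, and orchestration of the named computational
    experiments (motion decomposition, trapped-cell effect, trabeculated
    versus smooth comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    interp,
    sp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
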