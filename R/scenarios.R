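#' Specify a named simulation scenario
#'
#' Bundles everything needed to reproduce one computational experiment:
#' geometry source, motion variant, trapped cells, viscosity mode and seed.
#' Motion variants other than `baseline` apply only to isolated grooves:
#' `no_ventricle` is the isolated groove with its full motion (the chamber
#' replaced by the zero-reference-pressure opening), `no_ventricle_no_deformation`
#' keeps only the rigid translation, `no_ventricle_no_translation` keeps
#' only the deformational (squeeze) motion.
#'
#' @param geometry `"groove"`, `"ventricle"` or `"smooth_ventricle"`.
#' @param motion_variant One of `baseline`, `no_ventricle`,
#'   `no_ventricle_no_deformation`, `no_ventricle_no_translation`.
#' @param cells Logical: add trapped cells (groove geometry only), or a
#'   list of [trapped_cell_spec()] objects.
#' @param viscosity `"plasma"`, `"blood"` or `"mixed"`.
#' @param seed Integer seed.
#' @param params,motion Generator parameter objects.
#' @param resolution Mesh edge length (um).
#' @param dims Optional explicit groove dimensions (groove geometry).
#' @return An object of class `tf_scenario_spec`.
#' @export
scenario_spec <- function(geometry = c("groove", "ventricle", "smooth_ventricle"),
                          motion_variant = c("baseline", "no_ventricle",
                                             "no_ventricle_no_deformation",
                                             "no_ventricle_no_translation"),
                          cells = FALSE,
                          viscosity = c("plasma", "blood", "mixed"),
                          seed = 1L,
                          params = geometry_params(),
                          motion = motion_model(),
                          resolution = NULL,
                          dims = NULL) {
  geometry <- match.arg(geometry)
  motion_variant <- match.arg(motion_variant)
  viscosity <- match.arg(viscosity)
  if (motion_variant != "baseline" && geometry != "groove") {
    stop("motion variants other than `baseline` apply only to isolated ",
         "grooves", call. = FALSE)
  }
  if (!isFALSE(cells) && !geometry %in% "groove") {
    stop("trapped cells are only supported in groove scenarios", call. = FALSE)
  }
  structure(list(geometry = geometry, motion_variant = motion_variant,
                 cells = cells, viscosity = viscosity, seed = as.integer(seed),
                 params = params, motion = motion, resolution = resolution,
                 dims = dims),
            class = "tf_scenario_spec")
}

#' Run one simulation scenario end to end
#'
#' Generates the geometry, applies the motion variant through
#' [decompose_motion()], solves the cardiac cycle, and computes the summary
#' metrics: the spatio-temporally averaged endocardial WSS (area-weighted
#' mean over wall nodes of the per-node time-averaged |WSS|, opening nodes
#' excluded), per-region TAWSS/OSI, stroke volume, cell-surface WSS when
#' cells are present, and the Reynolds/Womersley audit.
#'
#' @param spec A [scenario_spec()].
#' @return A `tf_scenario_result`.
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "tf_scenario_spec"))
  mb <- scenario_geometry(spec)
  res <- spec$resolution %||% switch(spec$geometry,
                                     groove = 0.7,
                                     ventricle = 1.0,
                                     smooth_ventricle = 1.0)
  series <- withCallingHandlers(
    solve_cycle(mb, fluid_properties("plasma"), resolution = res),
    error = function(e) {
      stop("scenario (", spec$geometry, ", ", spec$motion_variant,
           ", seed ", spec$seed, ") failed: ", conditionMessage(e),
           call. = FALSE)
    })

  mask <- if (spec$geometry %in% c("ventricle", "smooth_ventricle")) {
    classify_ridge_groove(mb)
  } else {
    ifelse(mb$labels == "opening", "excluded",
           ifelse(mb$labels == "cell", "cell",
                  ifelse(mb$labels == "ridge", "ridge", "groove")))
  }
  w <- switch(spec$viscosity,
              plasma = wss(series, 1.5e-3),
              blood = wss(series, 7.35e-3),
              mixed = mixed_viscosity_wss(series, mask))

  tw <- tawss(w)
  ov <- osi(w)
  wgt <- rowMeans(series$weights)
  endo <- mask %in% c("ridge", "groove") & !is.na(tw)
  mean_wss <- sum(wgt[endo] * tw[endo]) / sum(wgt[endo])
  sd_wss <- sqrt(sum(wgt[endo] * (tw[endo] - mean_wss)^2) / sum(wgt[endo]))

  regions <- intersect(c("ridge", "groove", "cell"), unique(mask[!is.na(tw)]))
  metrics <- purrr::map_dfr(regions, function(rg) {
    ta <- region_average(tw, mask, rg, wgt)
    os <- region_average(ov, mask, rg, wgt)
    tibble::tibble(region = rg, tawss_mean = ta[["mean"]],
                   tawss_sd = ta[["sd"]], osi_mean = os[["mean"]],
                   osi_sd = os[["sd"]], n_nodes = as.integer(ta[["n"]]))
  })
  cell_wss <- if (any(mask == "cell" & !is.na(tw))) {
    unname(region_average(tw, mask, "cell", wgt)[["mean"]])
  } else {
    NA_real_
  }

  structure(list(
    spec = spec, mb = mb, series = series, wss = w, mask = mask,
    mean_wss = mean_wss, sd_wss = sd_wss,
    metrics = metrics, cell_wss = cell_wss,
    stroke_volume = stroke_volume(mb),
    audit = dplyr::summarise(
      series$audit,
      reynolds_max = max(.data$reynolds),
      womersley = max(.data$womersley),
      mass_residual_max = max(.data$mass_residual),
      quasi_steady_valid = all(.data$quasi_steady_valid))
  ), class = "tf_scenario_result")
}

scenario_geometry <- function(spec) {
  if (spec$geometry %in% c("ventricle", "smooth_ventricle")) {
    mb <- generate_ventricle(spec$params, spec$motion, spec$seed)
    if (spec$geometry == "smooth_ventricle") mb <- smooth_counterpart(mb)
    return(mb)
  }
  mb <- generate_groove(spec$params, spec$motion, spec$seed, dims = spec$dims)
  if (!isFALSE(spec$cells)) {
    cells <- if (isTRUE(spec$cells)) {
      list(default_cell(mb, spec$params))
    } else {
      spec$cells
    }
    mb <- add_trapped_cells(mb, cells, seed = spec$seed)
  }
  switch(spec$motion_variant,
         baseline = ,
         no_ventricle = mb,
         no_ventricle_no_deformation = decompose_motion(mb)$translation_only,
         no_ventricle_no_translation = decompose_motion(mb)$deformation_only)
}

# Groove dimensions guaranteed to host a trapped cell throughout the cycle:
# redraw from the measured distributions (deterministically from `seed`)
# until the cell clears the pocket at its shallowest/narrowest phase.
host_groove_dims <- function(seed, params, motion, clearance = 0.65) {
  dia <- params$cell_diameter
  wmax <- 1  # waveform maximum
  for (k in 0:49) {
    set.seed(as.integer(seed) * 1000L + k)
    dims <- tibble::tibble(
      groove = 1L,
      long = sample_truncnorm(1, params$groove_long[["mean"]],
                              params$groove_long[["sd"]]),
      radial = sample_truncnorm(1, params$groove_radial[["mean"]],
                                params$groove_radial[["sd"]]),
      circ = sample_truncnorm(1, params$groove_circ[["mean"]],
                              params$groove_circ[["sd"]])
    )
    d_min <- dims$radial * (1 - motion$squeeze_amplitude * wmax)
    if (d_min >= dia + 2 * clearance && dims$circ / 2 >= dia + 2 * clearance) {
      return(dims)
    }
  }
  stop("no feasible host groove found for a ", dia, " um cell", call. = FALSE)
}

# a cell seated mid-depth in the groove at end diastole
default_cell <- function(mb, params) {
  d_ed <- mb$meta$D * (1 - mb$meta$motion$squeeze_amplitude * mb$meta$w[1])
  trapped_cell_spec(
    center_phase0 = c(0, -0.5 * d_ed) + mb$meta$translation[1, ],
    diameter = params$cell_diameter,
    wobble_amplitude = 0.25
  )
}

#' @method print tf_scenario_result
#' @export
print.tf_scenario_result <- function(x, ...) {
  cat(sprintf("Scenario: %s / %s / %s viscosity, seed %d\n",
              x$spec$geometry, x$spec$motion_variant, x$spec$viscosity,
              x$spec$seed))
  cat(sprintf("  endocardial WSS %.4g +/- %.4g Pa; stroke area %.1f um^2\n",
              x$mean_wss, x$sd_wss, x$stroke_volume))
  if (!is.na(x$cell_wss)) cat(sprintf("  cell-surface WSS %.4g Pa\n", x$cell_wss))
  print(x$metrics)
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `tf_scenario_result`.
#' @param ... Unused.
#' @method tidy tf_scenario_result
#' @export
tidy.tf_scenario_result <- function(x, ...) x$metrics

#' @rdname run_scenario
#' @method glance tf_scenario_result
#' @export
glance.tf_scenario_result <- function(x, ...) {
  tibble::tibble(
    geometry = x$spec$geometry, motion_variant = x$spec$motion_variant,
    viscosity = x$spec$viscosity, seed = x$spec$seed,
    mean_wss = x$mean_wss, sd_wss = x$sd_wss,
    cell_wss = x$cell_wss, stroke_volume = x$stroke_volume,
    reynolds_max = x$audit$reynolds_max,
    womersley = x$audit$womersley,
    mass_residual_max = x$audit$mass_residual_max
  )
}

#' Motion-decomposition experiment on replicate synthetic grooves
#'
#' For each replicate groove: the isolated groove with full motion
#' (`no_ventricle`), translation only (`no_deformation`) and squeeze only
#' (`no_translation`). Reports the spatio-temporally averaged endocardial
#' WSS per scenario, fold changes against `no_ventricle`, and exact paired
#' one-sided Wilcoxon signed-rank p-values for the removal of deformation
#' (expected to collapse WSS) and of translation (expected to change
#' little).
#'
#' @param seeds Integer seeds, one per replicate groove (>= 2).
#' @param params,motion Generator parameters.
#' @param resolution Mesh edge length (um).
#' @return A `tf_comparison` tibble (one row per seed x scenario) with the
#'   test summary in `attr(, "tests")`.
#' @export
motion_decomposition_experiment <- function(seeds = 0:5,
                                            params = geometry_params(),
                                            motion = motion_model(),
                                            resolution = 0.7) {
  if (length(seeds) < 2) stop("need >= 2 replicate grooves", call. = FALSE)
  variants <- c(no_ventricle = "no_ventricle",
                no_deformation = "no_ventricle_no_deformation",
                no_translation = "no_ventricle_no_translation")
  rows <- purrr::map_dfr(seeds, function(s) {
    purrr::map_dfr(names(variants), function(v) {
      r <- run_scenario(scenario_spec("groove", variants[[v]], seed = s,
                                      params = params, motion = motion,
                                      resolution = resolution))
      tibble::tibble(seed = s, scenario = v, mean_wss = r$mean_wss,
                     sd_wss = r$sd_wss)
    })
  })
  wide <- tidyr::pivot_wider(rows[, c("seed", "scenario", "mean_wss")],
                             names_from = "scenario", values_from = "mean_wss")
  tests <- tibble::tibble(
    comparison = c("no_deformation < no_ventricle",
                   "no_translation < no_ventricle"),
    p_value = c(
      wilcoxon_exact(wide$no_ventricle - wide$no_deformation, "greater")$p.value,
      wilcoxon_exact(wide$no_ventricle - wide$no_translation, "greater")$p.value
    ),
    sidedness = "one-sided"
  )
  wide$fold_no_deformation <- wide$no_deformation / wide$no_ventricle
  wide$fold_no_translation <- wide$no_translation / wide$no_ventricle
  structure(rows, class = c("tf_comparison", class(rows)),
            tests = tests, wide = wide,
            experiment = "motion_decomposition")
}

#' Trapped-cell effect experiment
#'
#' Paired runs of identical isolated grooves with and without a trapped
#' hemogenic cell. The groove squeeze amplitude is reduced so that the cell
#' fits the pocket at every phase (in vivo the cells occupy most of the
#' groove section; the residual squeeze stands in for the out-of-plane
#' motion a 2D section cannot represent). Reports endocardial and
#' cell-surface WSS per replicate.
#'
#' @param seeds Integer seeds, one per replicate pair.
#' @param params,motion Generator parameters; `motion` defaults to a gentle
#'   squeeze (`squeeze_amplitude = 0.1`).
#' @param resolution Mesh edge length (um).
#' @return A `tf_comparison` tibble, one row per seed, with columns for the
#'   with/without-cell endocardial WSS and the cell-surface WSS.
#' @export
cell_effect_experiment <- function(seeds = 0:1,
                                   params = geometry_params(),
                                   motion = motion_model(squeeze_amplitude = 0.1),
                                   resolution = 0.45) {
  rows <- purrr::map_dfr(seeds, function(s) {
    # trapped cells are observed in grooves large enough to host them:
    # draw replicate grooves conditional on hosting feasibility
    dims <- host_groove_dims(s, params, motion)
    without <- run_scenario(scenario_spec("groove", "no_ventricle", seed = s,
                                          params = params, motion = motion,
                                          resolution = resolution,
                                          dims = dims))
    with <- run_scenario(scenario_spec("groove", "no_ventricle", cells = TRUE,
                                       seed = s, params = params,
                                       motion = motion,
                                       resolution = resolution,
                                       dims = dims))
    tibble::tibble(seed = s,
                   wss_without_cell = without$mean_wss,
                   wss_with_cell = with$mean_wss,
                   cell_surface_wss = with$cell_wss,
                   fold_change = with$mean_wss / without$mean_wss)
  })
  structure(rows, class = c("tf_comparison", class(rows)),
            experiment = "cell_effect")
}

#' Trabeculated-versus-smooth ventricle experiment
#'
#' Paired synthetic ventricles: each trabeculated geometry and its smooth
#' counterpart share the volume waveform (stroke volumes matched by
#' construction). Reports endocardial area strain (end diastole to end
#' systole, extruded-surface elements), stroke volumes, plasma-viscosity
#' mean WSS for both models, and ridge/groove TAWSS (mixed viscosity) and
#' OSI for the trabeculated model.
#'
#' @param seeds Integer seeds, one per replicate pair.
#' @param params,motion Generator parameters.
#' @param resolution Mesh edge length (um).
#' @param solve_flow Solve the flow (else only strain/stroke columns).
#' @return A `tf_comparison` tibble, one row per seed.
#' @export
trabeculation_effect_experiment <- function(seeds = 1:4,
                                            params = geometry_params(),
                                            motion = motion_model(),
                                            resolution = 1.2,
                                            solve_flow = TRUE) {
  if (!length(seeds)) stop("need >= 1 seed", call. = FALSE)
  rows <- purrr::map_dfr(seeds, function(s) {
    mbT <- generate_ventricle(params, motion, s)
    mbS <- smooth_counterpart(mbT)
    ph <- phase_frames(mbT)
    strainT <- area_strain(extrude_boundary(mbT, ph["ED"]),
                           extrude_boundary(mbT, ph["ES"]))
    strainS <- area_strain(extrude_boundary(mbS, ph["ED"]),
                           extrude_boundary(mbS, ph["ES"]))
    out <- tibble::tibble(
      seed = s,
      strain_trabeculated = strainT$mean_abs_strain,
      strain_smooth = strainS$mean_abs_strain,
      stroke_trabeculated = stroke_volume(mbT),
      stroke_smooth = stroke_volume(mbS)
    )
    if (solve_flow) {
      sT <- solve_cycle(mbT, fluid_properties("plasma"),
                        resolution = resolution)
      sS <- solve_cycle(mbS, fluid_properties("plasma"),
                        resolution = resolution)
      mask <- classify_ridge_groove(mbT)
      wp <- wss(sT, 1.5e-3)
      wm <- mixed_viscosity_wss(sT, mask)
      twp <- tawss(wp); twm <- tawss(wm); ovp <- osi(wp)
      wgt <- rowMeans(sT$weights)
      endo <- mask %in% c("ridge", "groove") & !is.na(twp)
      wpS <- wss(sS, 1.5e-3)
      twS <- tawss(wpS)
      maskS <- rep("ridge", length(twS))
      maskS[sS$labels %in% c("inlet", "outlet")] <- "excluded"
      wgtS <- rowMeans(sS$weights)
      endoS <- maskS == "ridge" & !is.na(twS)
      out$mean_wss_trabeculated <- sum(wgt[endo] * twp[endo]) / sum(wgt[endo])
      out$mean_wss_smooth <- sum(wgtS[endoS] * twS[endoS]) / sum(wgtS[endoS])
      out$tawss_ridge_mixed <- region_average(twm, mask, "ridge", wgt)[["mean"]]
      out$tawss_groove_mixed <- region_average(twm, mask, "groove", wgt)[["mean"]]
      out$osi_ridge <- region_average(ovp, mask, "ridge", wgt)[["mean"]]
      out$osi_groove <- region_average(ovp, mask, "groove", wgt)[["mean"]]
    }
    out
  })
  structure(rows, class = c("tf_comparison", class(rows)),
            experiment = "trabeculation_effect")
}

#' @method print tf_comparison
#' @export
print.tf_comparison <- function(x, ...) {
  cat("Comparison table (", attr(x, "experiment"), ")\n", sep = "")
  NextMethod()
  tests <- attr(x, "tests")
  if (!is.null(tests)) {
    cat("\nPaired exact Wilcoxon signed-rank tests:\n")
    print(as.data.frame(tests))
  }
  invisible(x)
}

#' @method glance tf_comparison
#' @export
glance.tf_comparison <- function(x, ...) {
  tests <- attr(x, "tests")
  out <- tibble::tibble(experiment = attr(x, "experiment"),
                        n = length(unique(x$seed)))
  if (!is.null(tests)) {
    for (i in seq_len(nrow(tests))) {
      out[[paste0("p_", gsub("[^a-z_]+", "_", tests$comparison[i]))]] <-
        tests$p_value[i]
    }
  }
  out
}
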