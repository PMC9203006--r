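#' Geometric parameters of the synthetic trabeculated ventricle
#'
#' Bundles the measured dimensions that the generator reproduces: the
#' ventricular inner diameter, the distributions of the intra-trabecular
#' groove dimensions (longitudinal, radial and circumferential; all at end
#' systole), the number of grooves cut by the optical section, and the
#' inlet/outlet opening widths. All lengths are in micrometres.
#'
#' Groove dimensions are drawn per groove from independent Gaussians with the
#' given means and standard deviations, truncated at +/- 2 sd so that no
#' non-physical (negative or degenerate) dimension can be realized.
#'
#' @param inner_diameter Lumen diameter through the chamber centre (um),
#'   valid range 30-50.
#' @param groove_long Mean/sd of the longitudinal groove dimension (um);
#'   used as the extrusion depth of exported 3D surfaces.
#' @param groove_radial Mean/sd of the radial groove depth (um).
#' @param groove_circ Mean/sd of the circumferential groove width (um).
#' @param n_grooves Number of grooves on the outer-curvature arc.
#' @param endocardial_thickness Endocardial layer thickness (um);
#'   informational only, the boundary is the endocardial surface itself.
#' @param cell_diameter Diameter of trapped hemogenic cells (um), valid 6-8.
#' @param inlet_width,outlet_width Arc widths of the inlet and outlet
#'   openings (um).
#' @param curvature_ratio Ratio of inner- to outer-curvature radius of the
#'   looped chamber section; controls the eccentricity of the base envelope.
#' @param node_spacing Target boundary node spacing at end systole (um).
#' @return An object of class `tf_geometry_params`.
#' @export
geometry_params <- function(inner_diameter = 40,
                            groove_long = c(mean = 12.5, sd = 3.1),
                            groove_radial = c(mean = 8.7, sd = 0.8),
                            groove_circ = c(mean = 21.7, sd = 10.7),
                            n_grooves = 2,
                            endocardial_thickness = 5,
                            cell_diameter = 6.5,
                            inlet_width = 10,
                            outlet_width = 10,
                            curvature_ratio = 0.5,
                            node_spacing = 0.9) {
  as_ms <- function(x, what) {
    if (length(x) == 1L) x <- c(mean = unname(x), sd = 0)
    if (length(x) != 2L || any(!is.finite(x))) {
      stop("`", what, "` must be a (mean, sd) pair", call. = FALSE)
    }
    x <- stats::setNames(as.numeric(x), c("mean", "sd"))
    if (x[["mean"]] <= 0 || x[["sd"]] < 0) {
      stop("`", what, "` mean must be > 0 and sd >= 0", call. = FALSE)
    }
    x
  }
  p <- list(
    inner_diameter = inner_diameter,
    groove_long = as_ms(groove_long, "groove_long"),
    groove_radial = as_ms(groove_radial, "groove_radial"),
    groove_circ = as_ms(groove_circ, "groove_circ"),
    n_grooves = as.integer(n_grooves),
    endocardial_thickness = endocardial_thickness,
    cell_diameter = cell_diameter,
    inlet_width = inlet_width,
    outlet_width = outlet_width,
    curvature_ratio = curvature_ratio,
    node_spacing = node_spacing
  )
  if (!is.finite(inner_diameter) || inner_diameter < 30 || inner_diameter > 50) {
    stop("`inner_diameter` must lie in [30, 50] um", call. = FALSE)
  }
  if (p$groove_radial[["mean"]] >= inner_diameter / 2) {
    stop("groove radial depth must be smaller than the chamber radius",
         call. = FALSE)
  }
  if (p$n_grooves < 0L) stop("`n_grooves` must be >= 0", call. = FALSE)
  if (cell_diameter <= 0) stop("`cell_diameter` must be > 0", call. = FALSE)
  gmin <- min(p$groove_long[["mean"]], p$groove_radial[["mean"]],
              p$groove_circ[["mean"]])
  if (cell_diameter > gmin) {
    stop("`cell_diameter` (", cell_diameter, " um) exceeds the smallest mean ",
         "groove dimension (", gmin, " um); cells must fit in grooves",
         call. = FALSE)
  }
  if (any(c(endocardial_thickness, inlet_width, outlet_width,
            curvature_ratio, node_spacing) <= 0)) {
    stop("all lengths and ratios must be > 0", call. = FALSE)
  }
  structure(p, class = "tf_geometry_params")
}

#' Cardiac motion model
#'
#' Describes one cardiac cycle of the moving endocardial boundary: the cycle
#' duration, the temporal sampling, the normalized volume waveform, the rigid
#' translation loop and the squeeze amplitude of the intra-trabecular grooves.
#'
#' The default cycle duration of 0.25 s corresponds to image acquisition at
#' 100 frames per second with about 25 frames per cardiac cycle. The volume
#' waveform is a piecewise-smooth two-phase curve: an early-systolic ejection,
#' an early-diastolic filling wave, a diastasis plateau and a late-diastolic
#' A-wave; phase 0 is end-diastole. Rigid rotation is never prescribed (and is
#' measured to be far below the 0.07 rad bound under which rotations are
#' neglected).
#'
#' @param cycle_duration Cardiac cycle duration T (s).
#' @param n_frames Frames per cycle (>= 8).
#' @param ejection_fraction Fraction of end-diastolic area ejected per beat.
#' @param phase_split Fraction of the cycle occupied by diastole.
#' @param translation_amplitude Two-vector (um): semi-axes of the elliptical
#'   rigid translation loop of the chamber.
#' @param squeeze_amplitude Fractional reduction of groove depth from end
#'   systole (where nominal dimensions are realized) to end diastole.
#'   Grooves are deepest at end systole, when the contracted myocardium
#'   protrudes the trabecular ridges furthest into the lumen.
#' @param groove_width_gain Fractional widening of isolated grooves at end
#'   diastole (mimics the envelope dilation a groove embedded in the
#'   ventricle experiences).
#' @param max_rotation Upper bound (rad) tolerated when auditing generated
#'   motion for rigid rotation; must be < 0.07.
#' @return An object of class `tf_motion_model`. Its `volume_waveform`
#'   element is a function of phase in [0, 1) returning the normalized
#'   waveform w with w = 0 at end systole and w = 1 at end diastole;
#'   `translation_waveform` maps phase to a rigid displacement vector (um).
#' @export
motion_model <- function(cycle_duration = 0.25,
                         n_frames = 25,
                         ejection_fraction = 0.4,
                         phase_split = 0.6,
                         translation_amplitude = c(3, 1.5),
                         squeeze_amplitude = 0.5,
                         groove_width_gain = 0.25,
                         max_rotation = 0.05) {
  if (n_frames < 8) stop("`n_frames` must be >= 8", call. = FALSE)
  if (cycle_duration <= 0) stop("`cycle_duration` must be > 0", call. = FALSE)
  if (ejection_fraction <= 0 || ejection_fraction >= 1) {
    stop("`ejection_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (phase_split <= 0 || phase_split >= 1) {
    stop("`phase_split` must lie in (0, 1)", call. = FALSE)
  }
  if (squeeze_amplitude < 0 || squeeze_amplitude >= 1) {
    stop("`squeeze_amplitude` must lie in [0, 1)", call. = FALSE)
  }
  if (max_rotation >= 0.07) {
    stop("`max_rotation` must be < 0.07 rad", call. = FALSE)
  }
  systole <- 1 - phase_split
  m <- list(
    cycle_duration = cycle_duration,
    n_frames = as.integer(n_frames),
    ejection_fraction = ejection_fraction,
    phase_split = phase_split,
    translation_amplitude = translation_amplitude,
    squeeze_amplitude = squeeze_amplitude,
    groove_width_gain = groove_width_gain,
    max_rotation = max_rotation,
    volume_waveform = make_volume_waveform(systole),
    translation_waveform = make_translation_waveform(translation_amplitude)
  )
  structure(m, class = "tf_motion_model")
}

# Normalized chamber-area waveform w(phase): 1 at end diastole (phase 0),
# 0 at end systole (phase = 1 - phase_split). Cosine smoothsteps give a
# C1-periodic curve with an early-diastolic filling wave, a diastasis
# plateau and a late-diastolic A-wave, mirroring the two filling transients
# seen in ridge shear waveforms.
make_volume_waveform <- function(systole) {
  force(systole)
  # diastolic sub-phases as fractions of the diastolic interval
  function(phase) {
    phase <- phase %% 1
    step <- function(x) 0.5 - 0.5 * cos(pi * pmin(pmax(x, 0), 1))
    dia <- 1 - systole
    e_end <- systole + 0.5 * dia     # end of early filling
    a_start <- systole + 0.7 * dia   # start of atrial kick
    w <- numeric(length(phase))
    sys_idx <- phase < systole
    w[sys_idx] <- 1 - step(phase[sys_idx] / systole)
    e_idx <- !sys_idx & phase < e_end
    w[e_idx] <- 0.6 * step((phase[e_idx] - systole) / (e_end - systole))
    d_idx <- phase >= e_end & phase < a_start
    w[d_idx] <- 0.6
    a_idx <- phase >= a_start
    w[a_idx] <- 0.6 + 0.4 * step((phase[a_idx] - a_start) / (1 - a_start))
    w
  }
}

make_translation_waveform <- function(amplitude) {
  force(amplitude)
  function(phase) {
    phase <- phase %% 1
    cbind(amplitude[1] * sin(2 * pi * phase),
          amplitude[2] * sin(2 * pi * phase + pi / 2) - amplitude[2])
  }
}

#' @method print tf_geometry_params
#' @export
print.tf_geometry_params <- function(x, ...) {
  cat("Trabeculated-ventricle geometry parameters (um)\n")
  cat(sprintf("  inner diameter : %.1f\n", x$inner_diameter))
  cat(sprintf("  grooves        : %d on the outer-curvature arc\n", x$n_grooves))
  cat(sprintf("  groove dims    : long %.1f+/-%.1f, radial %.1f+/-%.1f, circ %.1f+/-%.1f\n",
              x$groove_long[["mean"]], x$groove_long[["sd"]],
              x$groove_radial[["mean"]], x$groove_radial[["sd"]],
              x$groove_circ[["mean"]], x$groove_circ[["sd"]]))
  cat(sprintf("  cell diameter  : %.1f\n", x$cell_diameter))
  invisible(x)
}

#' @method print tf_motion_model
#' @export
print.tf_motion_model <- function(x, ...) {
  cat("Cardiac motion model\n")
  cat(sprintf("  cycle duration   : %.3f s (%d frames)\n",
              x$cycle_duration, x$n_frames))
  cat(sprintf("  ejection fraction: %.2f, diastole fraction %.2f\n",
              x$ejection_fraction, x$phase_split))
  cat(sprintf("  groove squeeze   : %.2f of end-systolic depth\n",
              x$squeeze_amplitude))
  invisible(x)
}

# Truncated-Gaussian sampler for groove dimensions (+/- 2 sd).
sample_truncnorm <- function(n, mean, sd, k = 2) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- abs(draw - mean) <= k * sd
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}
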