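#' Solve one full cardiac cycle of quasi-steady Stokes flow
#'
#' Remeshes the fluid domain at every cardiac frame (the persistent object
#' is the boundary node identity, not the volume mesh), solves the
#' quasi-steady Stokes problem with the moving-wall velocities from
#' [wall_velocities()], and maps the wall shear rate back onto the boundary
#' nodes so that per-node time series are well defined.
#'
#' The phase schedule realizes the valve switching: during diastole (the
#' enclosed area is growing) the inlet is the zero-reference-pressure open
#' segment and the outlet an impervious moving wall; during systole the
#' roles swap. Isolated grooves keep their single opening open throughout.
#' Phase-switch frames are the extrema of the enclosed-area waveform.
#'
#' @param mb A [tf_moving_boundary].
#' @param fluid A [fluid_properties()].
#' @param resolution Target mesh edge length (um); defaults to the
#'   generator's node spacing.
#' @param bc_schedule Optional `function(frame, dadt, mb)` returning the
#'   names of the open segments for that frame; `NULL` uses the default
#'   schedule described above.
#' @param store_frames Keep the solved [tf_flow_frame] objects (memory!).
#' @return An object of class `tf_wss_series` with elements `gamma`
#'   (n_nodes x n_frames signed wall shear rate, s^-1; `NA` on open
#'   segments while they are open), `labels`, `times`, `weights` (per-node
#'   boundary lengths per frame), `audit` (per-frame tibble with Reynolds,
#'   Womersley and mass-balance numbers) and `fluid`.
#' @export
solve_cycle <- function(mb, fluid = fluid_properties(),
                        resolution = NULL, bc_schedule = NULL,
                        store_frames = FALSE) {
  stopifnot(inherits(mb, "tf_moving_boundary"))
  if (is.null(resolution)) {
    resolution <- mb$meta$params$node_spacing %||% 1
  }
  nf <- n_frames(mb)
  nn <- n_nodes(mb)
  vel <- wall_velocities(mb)
  dadt <- area_rate(mb)
  node_order <- unlist(mb$rings, use.names = FALSE)

  gamma <- matrix(NA_real_, nn, nf)
  weights <- matrix(0, nn, nf)
  audit <- vector("list", nf)
  frames_out <- if (store_frames) vector("list", nf) else NULL

  for (f in seq_len(nf)) {
    fr <- mb$frames[[f]]
    open_names <- if (is.null(bc_schedule)) {
      default_open_segments(mb, dadt[f])
    } else {
      bc_schedule(f, dadt[f], mb)
    }
    open_nodes <- unlist(mb$openings[open_names], use.names = FALSE)
    outer <- fr[mb$rings[[1]], , drop = FALSE]
    holes <- lapply(mb$rings[-1], function(r) fr[r, , drop = FALSE])
    mesh <- tryCatch(
      mesh_domain(outer, resolution, holes = holes),
      error = function(e) {
        stop("remeshing failed at frame ", f, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    # boundary rows of the mesh follow ring order; map to mb node ids
    open_rows <- match(open_nodes, node_order)
    bc <- boundary_spec(vel[[f]][node_order, , drop = FALSE],
                        open = open_rows[!is.na(open_rows)])
    ff <- solve_frame(mesh, bc, fluid)
    g_rows <- wall_shear_rate(ff)
    gamma[node_order, f] <- g_rows
    weights[, f] <- node_weights(mb, f)
    audit[[f]] <- frame_audit(ff, mb, f, dadt[f],
                              scale = 1e-3 * max(abs(dadt)))
    if (store_frames) frames_out[[f]] <- ff
  }

  structure(list(
    gamma = gamma, labels = mb$labels, times = mb$times,
    cycle_duration = mb$cycle_duration, weights = weights,
    openings = mb$openings, rings = mb$rings, fluid = fluid,
    resolution = resolution,
    audit = dplyr::bind_rows(audit),
    frames = frames_out, mb = mb
  ), class = "tf_wss_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_open_segments <- function(mb, dadt) {
  nms <- names(mb$openings)
  if (length(nms) == 1L) return(nms)
  if (all(c("inlet", "outlet") %in% nms)) {
    return(if (dadt >= 0) "inlet" else "outlet")
  }
  nms
}

frame_audit <- function(ff, mb, f, dadt, scale = 1e-10) {
  umax <- max(sqrt(rowSums(ff$u2^2)))           # um/s
  L <- diff(range(ff$mesh$xy[, 1]))             # um
  mu <- ff$fluid$viscosity
  rho <- ff$fluid$density
  re <- rho * (umax * 1e-6) * (L * 1e-6) / mu
  omega <- 2 * pi / mb$cycle_duration
  wo <- (L * 1e-6 / 2) * sqrt(omega * rho / mu)
  tibble::tibble(
    frame = f, dadt = dadt,
    u_max = umax, reynolds = re, womersley = wo,
    mass_residual = mass_balance(ff, eps = scale),
    quasi_steady_valid = re < 1 & wo < 1
  )
}

#' @method print tf_wss_series
#' @export
print.tf_wss_series <- function(x, ...) {
  cat(sprintf("Wall shear rate series: %d nodes x %d frames, mu = %g Pa s\n",
              nrow(x$gamma), ncol(x$gamma), x$fluid$viscosity))
  cat(sprintf("  |gamma| max %.3g 1/s; Re max %.3g, Wo %.3g, mass residual max %.3g\n",
              max(abs(x$gamma), na.rm = TRUE), max(x$audit$reynolds),
              max(x$audit$womersley), max(x$audit$mass_residual)))
  invisible(x)
}

#' Tidy a wall shear rate / WSS series
#'
#' @param x A `tf_wss_series` or `tf_wss` object.
#' @param ... Unused.
#' @return Tibble with node, frame, time, label, value columns (`gamma`
#'   in s^-1 or `tau` in Pa).
#' @method tidy tf_wss_series
#' @export
tidy.tf_wss_series <- function(x, ...) {
  nf <- ncol(x$gamma)
  tibble::tibble(
    node = rep(seq_len(nrow(x$gamma)), nf),
    frame = rep(seq_len(nf), each = nrow(x$gamma)),
    time = rep(x$times, each = nrow(x$gamma)),
    label = rep(x$labels, nf),
    gamma = as.vector(x$gamma)
  )
}

#' @method autoplot tf_wss_series
#' @export
autoplot.tf_wss_series <- function(object, ...) {
  df <- tidy.tf_wss_series(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$node,
                                   fill = abs(.data$gamma))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|shear rate| (1/s)", na.value = "grey90") +
    ggplot2::labs(x = "time (s)", y = "boundary node") +
    ggplot2::theme_minimal()
}
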