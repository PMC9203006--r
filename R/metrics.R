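#' Wall shear stress from a shear-rate series
#'
#' Converts the signed wall shear rate gamma (s^-1) into wall shear stress
#' tau = mu * gamma (Pa). In the Stokes limit the velocity field driven by
#' prescribed wall motion is independent of viscosity, so the shear-rate
#' field is common to all viscosities and WSS scales linearly with mu: blood
#' at 7.35 cP carries 4.9-fold the WSS of plasma at 1.5 cP for identical
#' kinematics.
#'
#' @param series A `tf_wss_series` from [solve_cycle()].
#' @param mu Viscosity in Pa s, or a [fluid_properties()] object.
#' @return A `tf_wss` object: `tau` (n_nodes x n_frames, Pa, signed along
#'   the local wall tangent), plus labels, weights and times.
#' @export
wss <- function(series, mu = series$fluid) {
  stopifnot(inherits(series, "tf_wss_series"))
  if (inherits(mu, "tf_fluid")) mu <- mu$viscosity
  if (!all(is.finite(mu)) || any(mu <= 0)) {
    stop("viscosity must be > 0", call. = FALSE)
  }
  mu_node <- rep(mu, length.out = nrow(series$gamma))
  structure(list(
    tau = series$gamma * mu_node, mu = mu_node,
    labels = series$labels, times = series$times,
    cycle_duration = series$cycle_duration, weights = series$weights
  ), class = "tf_wss")
}

#' Mixed-viscosity wall shear stress
#'
#' Blood cells (6-8 um) are excluded from the intra-trabecular spaces by
#' their size, so the fluid there is plasma while the main chamber carries
#' whole blood: groove (and cell-surface) nodes are converted with the
#' plasma viscosity and every other wall node with the blood viscosity. By
#' Stokes linearity this equals combining two single-viscosity solves
#' node-wise.
#'
#' @param series A `tf_wss_series`.
#' @param mask Per-node region labels (`ridge`, `groove`, `excluded`,
#'   `cell`), e.g. from [classify_ridge_groove()].
#' @param mu_plasma,mu_blood Viscosities (Pa s).
#' @return A `tf_wss` object.
#' @export
mixed_viscosity_wss <- function(series, mask,
                                mu_plasma = 1.5e-3, mu_blood = 7.35e-3) {
  stopifnot(inherits(series, "tf_wss_series"))
  n <- nrow(series$gamma)
  if (length(mask) != n) {
    stop("mask must label all ", n, " wall nodes", call. = FALSE)
  }
  known <- mask %in% c("ridge", "groove", "excluded", "cell")
  if (!all(known)) {
    stop("unlabelled node(s): ", paste(utils::head(which(!known)), collapse = ", "),
         call. = FALSE)
  }
  mu_node <- ifelse(mask %in% c("groove", "cell"), mu_plasma, mu_blood)
  out <- wss(series, mu = mu_node)
  out$mask <- mask
  out
}

#' Time-averaged wall shear stress
#'
#' Per-node `TAWSS = (1/T) int_0^T |tau| dt` by the trapezoidal rule with
#' periodic closure (frame `n+1` identified with frame 1).
#'
#' @param w A `tf_wss` object (or a `tf_wss_series`, then the result is a
#'   time-averaged shear rate in s^-1).
#' @return Numeric per-node vector (Pa); `NA` for nodes that are open for
#'   part of the cycle.
#' @export
tawss <- function(w) {
  vals <- series_values(w)
  if (ncol(vals) < 2) stop("need >= 2 frames for a time average", call. = FALSE)
  rowMeans(abs(vals))
}

#' Oscillatory shear index
#'
#' `OSI = 1/2 (1 - |int tau dt| / int |tau| dt)`, in `[0, 0.5]`: 0 for
#' unidirectional shear, 0.5 for zero-mean oscillation. Nodes with
#' identically zero shear get OSI 0 by convention. OSI is invariant under
#' positive rescaling of tau and therefore viscosity-independent.
#'
#' @param w A `tf_wss` or `tf_wss_series` object.
#' @return Numeric per-node vector in `[0, 0.5]`.
#' @export
osi <- function(w) {
  vals <- series_values(w)
  num <- abs(rowSums(vals))
  den <- rowSums(abs(vals))
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

series_values <- function(w) {
  if (inherits(w, "tf_wss")) w$tau
  else if (inherits(w, "tf_wss_series")) w$gamma
  else if (is.matrix(w)) w
  else stop("expected a tf_wss, tf_wss_series or matrix", call. = FALSE)
}

#' Classify boundary nodes into trabecular ridges and grooves
#'
#' Automated surrogate for manual delineation of the indented regions:
#' nodes lying deeper than `threshold` beyond the smooth envelope through
#' the ridge crests are labelled `groove`, the rest `ridge`. Opening nodes
#' are labelled `excluded` and internal cell rings `cell`. A manual mask, if
#' supplied, is honoured verbatim.
#'
#' @param mb A [tf_moving_boundary].
#' @param frame Frame at which to classify; default end systole.
#' @param method `"envelope"` (automatic) or `"manual"`.
#' @param threshold Depth threshold (um); must be > 0.
#' @param mask Manual per-node labels for `method = "manual"`.
#' @return Character vector of per-node labels.
#' @export
classify_ridge_groove <- function(mb, frame = NULL,
                                  method = c("envelope", "manual"),
                                  threshold = 1, mask = NULL) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(mask)) stop("manual method requires `mask`", call. = FALSE)
    if (length(mask) != n_nodes(mb)) {
      stop("mask length must equal the node count", call. = FALSE)
    }
    return(mask)
  }
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (is.null(frame)) frame <- unname(phase_frames(mb)["ES"])
  out <- rep("ridge", n_nodes(mb))
  ring1 <- mb$rings[[1]]
  fr <- mb$frames[[frame]][ring1, , drop = FALSE]
  meta <- mb$meta
  if (!is.null(meta$R0)) {
    trans <- meta$translation[frame, ]
    d <- sweep(fr, 2, trans)
    th <- atan2(d[, 2], d[, 1])
    r <- sqrt(rowSums(d^2))
    depth <- r - meta$lambda[frame] * meta$R0 * (1 + meta$ecc * cos(th))
  } else {
    cent <- ring_centroid(fr)
    d <- sweep(fr, 2, cent)
    th <- atan2(d[, 2], d[, 1])
    r <- sqrt(rowSums(d^2))
    o <- order(th)
    env <- numeric(length(r))
    env[o] <- radial_envelope(r[o], th[o])
    depth <- r - env
  }
  out[ring1[depth > threshold]] <- "groove"
  out[mb$labels %in% c("inlet", "outlet", "opening")] <- "excluded"
  out[mb$labels == "cell"] <- "cell"
  out
}

#' Area-weighted regional mean and sd of a per-node field
#'
#' Weights are the boundary lengths incident to each node (triangle areas
#' for 3D surface fields supplied explicitly via `weights`).
#'
#' @param field Per-node numeric vector (e.g. TAWSS).
#' @param mask Per-node region labels.
#' @param region Region name to average over (e.g. `"groove"`).
#' @param weights Per-node weights; defaults to equal weights.
#' @return Named numeric vector `c(mean, sd, n)`.
#' @export
region_average <- function(field, mask, region, weights = NULL) {
  idx <- which(mask == region & !is.na(field))
  if (!length(idx)) stop("region `", region, "` is empty", call. = FALSE)
  w <- if (is.null(weights)) rep(1, length(idx)) else weights[idx]
  x <- field[idx]
  m <- sum(w * x) / sum(w)
  s <- sqrt(sum(w * (x - m)^2) / sum(w))
  c(mean = m, sd = s, n = length(idx))
}

#' Extrude a boundary frame into a 3D triangulated surface
#'
#' Builds the endocardial sheet as a straight extrusion of the 2D boundary
#' polyline along z, triangulated as a quad strip. Element connectivity is
#' frame-independent, so surfaces extruded from two frames of the same
#' boundary are in exact element correspondence -- as required for area
#' strain between end diastole and end systole.
#'
#' @param mb A [tf_moving_boundary].
#' @param frame Frame index.
#' @param depth Extrusion depth (um); defaults to the mean longitudinal
#'   groove dimension of the generator parameters, else 12.5.
#' @param n_layers Number of element layers along z.
#' @return A `tf_surface`: list with `vertices` (V x 3) and `faces` (F x 3).
#' @export
extrude_boundary <- function(mb, frame, depth = NULL, n_layers = 4) {
  if (is.null(depth)) {
    depth <- mb$meta$params$groove_long[["mean"]] %||% 12.5
  }
  ring1 <- mb$rings[[1]]
  xy <- mb$frames[[frame]][ring1, , drop = FALSE]
  n <- nrow(xy)
  z <- seq(0, depth, length.out = n_layers + 1)
  verts <- do.call(rbind, lapply(z, function(zz) cbind(xy, zz)))
  faces <- NULL
  for (l in seq_len(n_layers)) {
    a <- (l - 1) * n + seq_len(n)
    b <- (l - 1) * n + c(seq_len(n)[-1], 1L)
    a2 <- a + n
    b2 <- b + n
    faces <- rbind(faces, cbind(a, b, b2), cbind(a, b2, a2))
  }
  structure(list(vertices = verts, faces = unname(faces)),
            class = "tf_surface")
}

surface_face_areas <- function(s) {
  v1 <- s$vertices[s$faces[, 1], , drop = FALSE]
  v2 <- s$vertices[s$faces[, 2], , drop = FALSE]
  v3 <- s$vertices[s$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Endocardial area strain between two surfaces
#'
#' Per-element relative area change `(A_ES - A_ED) / A_ED` between two
#' triangulated surfaces in element correspondence (conventionally end
#' diastole to end systole). The summary statistic is the area-weighted mean
#' of |strain| (weighted by the end-diastolic element areas); a histogram of
#' the per-element strains is included. The result is invariant under rigid
#' motion of either surface.
#'
#' @param surface_ed,surface_es `tf_surface` objects with identical
#'   connectivity.
#' @param breaks Histogram breaks passed to [graphics::hist()] semantics
#'   (number of bins).
#' @return A `tf_strain_field`: list with `strain` (per element),
#'   `mean_abs_strain`, `area_ed`, `area_es` and `histogram` (tibble).
#' @export
area_strain <- function(surface_ed, surface_es, breaks = 30) {
  if (!identical(dim(surface_ed$faces), dim(surface_es$faces))) {
    stop("surfaces have different element counts", call. = FALSE)
  }
  a_ed <- surface_face_areas(surface_ed)
  a_es <- surface_face_areas(surface_es)
  strain <- (a_es - a_ed) / a_ed
  if (any(strain <= -1 + 1e-12)) {
    stop("element area collapses to zero or below; surfaces do not ",
         "correspond", call. = FALSE)
  }
  h <- graphics::hist(strain, breaks = breaks, plot = FALSE)
  structure(list(
    strain = strain,
    area_ed = a_ed, area_es = a_es,
    mean_abs_strain = sum(a_ed * abs(strain)) / sum(a_ed),
    mean_strain = sum(a_ed * strain) / sum(a_ed),
    histogram = tibble::tibble(mid = h$mids, count = h$counts,
                               density = h$density),
    summary_definition = "area-weighted mean of |per-element strain|, ED weights"
  ), class = "tf_strain_field")
}

#' @method print tf_strain_field
#' @export
print.tf_strain_field <- function(x, ...) {
  cat(sprintf("Area strain field: %d elements, mean |strain| = %.3f (%.1f%%)\n",
              length(x$strain), x$mean_abs_strain, 100 * x$mean_abs_strain))
  invisible(x)
}

#' @method autoplot tf_strain_field
#' @export
autoplot.tf_strain_field <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(strain = object$strain),
                  ggplot2::aes(x = .data$strain)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "element area strain (ED to ES)", y = "elements") +
    ggplot2::theme_minimal()
}

#' Percentage relative difference between two scalars
#'
#' `100 |a - b| / d` where `d` is `a`, `b` or their mean.
#'
#' @param a,b Scalars.
#' @param denominator Which value normalizes the difference.
#' @param digits Rounding of the returned percentage.
#' @return Percentage (rounded).
#' @export
relative_difference <- function(a, b,
                                denominator = c("first", "second", "mean"),
                                digits = 0) {
  denominator <- match.arg(denominator)
  d <- switch(denominator, first = a, second = b, mean = (a + b) / 2)
  if (d == 0) stop("zero denominator", call. = FALSE)
  round(100 * abs(a - b) / abs(d), digits)
}
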