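#' Generate a beating trabeculated ventricular cross-section
#'
#' Builds one cardiac cycle of a closed 2D endocardial boundary: a looped
#' chamber whose smooth base envelope is an eccentric oval (outer curvature
#' bulged, inner curvature flatter), with `n_grooves` intra-trabecular
#' pockets on the outer-curvature arc only. Groove dimensions are drawn from
#' the measured distributions and are realized exactly at the end-systolic
#' frame, when the contracted trabecular ridges protrude furthest and the
#' grooves are deepest. The enclosed area tracks the prescribed volume
#' waveform to solver precision at every frame: at each frame the envelope
#' scale is solved so that the shoelace area of the generated polygon equals
#' the target area.
#'
#' Inlet and outlet openings are labelled arcs on the inner-curvature side,
#' flanking the atrioventricular pole; grooves never overlap them.
#'
#' @param params A [geometry_params()] object.
#' @param motion A [motion_model()] object.
#' @param seed Integer seed; identical `(params, motion, seed)` give
#'   bit-identical geometry.
#' @return A [tf_moving_boundary] of kind `"ventricle"` with ground-truth
#'   ridge/groove/inlet/outlet node labels and generator metadata (realized
#'   groove dimensions, envelope parameters, per-frame envelope scale).
#' @export
generate_ventricle <- function(params = geometry_params(),
                               motion = motion_model(),
                               seed = 1L) {
  stopifnot(inherits(params, "tf_geometry_params"),
            inherits(motion, "tf_motion_model"))
  set.seed(as.integer(seed))

  R0 <- params$inner_diameter / 2
  ecc <- (1 - params$curvature_ratio) / (1 + params$curvature_ratio)
  r_env <- function(theta) R0 * (1 + ecc * cos(theta))

  ng <- params$n_grooves
  dims <- tibble::tibble(
    groove = seq_len(ng),
    long   = sample_truncnorm(ng, params$groove_long[["mean"]],
                              params$groove_long[["sd"]]),
    radial = sample_truncnorm(ng, params$groove_radial[["mean"]],
                              params$groove_radial[["sd"]]),
    circ   = sample_truncnorm(ng, params$groove_circ[["mean"]],
                              params$groove_circ[["sd"]])
  )

  # --- groove packing on the outer-curvature arc ---------------------------
  span <- c(-1.75, 1.75)           # rad; grooves only on the outer curvature
  min_gap <- 2.5                   # um of ridge between adjacent grooves
  g <- place_grooves(dims$circ, r_env, span, min_gap)
  if (ng > 0 && is.character(g)) stop(g, call. = FALSE)

  # --- opening arcs on the inner-curvature side ----------------------------
  th_in <- pi - 0.9
  th_out <- -(pi - 0.9)
  half_in <- params$inlet_width / (2 * r_env(th_in))
  half_out <- params$outlet_width / (2 * r_env(th_out))

  depth_at <- function(theta, depths) {
    d <- numeric(length(theta))
    for (k in seq_len(ng)) {
      s <- (wrap_angle(theta - g$center[k])) / g$halfwidth[k]
      inb <- abs(s) < 1
      d[inb] <- d[inb] + depths[k] * 0.5 * (1 + cos(pi * s[inb]))
    }
    d
  }

  # --- node parameterization: equal arc length at end systole --------------
  fine <- seq(-pi, pi, length.out = 8193L)[-8193L]
  r_es <- r_env(fine) + depth_at(fine, dims$radial)
  xy_f <- cbind(r_es * cos(fine), r_es * sin(fine))
  seg <- sqrt(rowSums((rbind(xy_f[-1, ], xy_f[1, ]) - xy_f)^2))
  arc <- cumsum(c(0, seg[-length(seg)]))
  per <- sum(seg)
  n_nodes <- max(32L, round(per / params$node_spacing))
  target <- (seq_len(n_nodes) - 1) / n_nodes * per
  theta <- stats::approx(arc, fine, xout = target, rule = 2)$y

  # ground-truth labels; a node belongs to groove k over the central 60% of
  # the pocket support (the obviously indented region)
  labels <- rep("ridge", n_nodes)
  groove_id <- rep(NA_integer_, n_nodes)
  for (k in seq_len(ng)) {
    s <- wrap_angle(theta - g$center[k]) / g$halfwidth[k]
    labels[abs(s) <= 0.6] <- "groove"
    groove_id[abs(s) <= 0.6] <- k
  }
  labels[abs(wrap_angle(theta - th_in)) <= half_in] <- "inlet"
  labels[abs(wrap_angle(theta - th_out)) <= half_out] <- "outlet"

  # --- frames: solve the envelope scale for the target area per frame ------
  nf <- motion$n_frames
  phase <- (seq_len(nf) - 1) / nf
  w <- motion$volume_waveform(phase)
  # reference end-systolic area (scale 1, nominal depths)
  area_of <- function(lambda, depths) {
    r <- lambda * r_env(theta) + depth_at(theta, depths)
    ring_area(cbind(r * cos(theta), r * sin(theta)))
  }
  a_es <- area_of(1, dims$radial)
  ef <- motion$ejection_fraction
  sv <- a_es * ef / (1 - ef)
  a_target <- a_es + sv * w
  trans <- motion$translation_waveform(phase)

  lambda <- numeric(nf)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    depths_f <- dims$radial * (1 - motion$squeeze_amplitude * w[f])
    lambda[f] <- stats::uniroot(function(l) area_of(l, depths_f) - a_target[f],
                                interval = c(0.5, 2.5), tol = 1e-12)$root
    r <- lambda[f] * r_env(theta) + depth_at(theta, depths_f)
    frames[[f]] <- cbind(r * cos(theta) + trans[f, 1],
                         r * sin(theta) + trans[f, 2])
  }
  es_frame <- which.min(a_target)
  for (f in unique(c(1L, es_frame))) {
    if (!ring_simple(frames[[f]])) {
      stop("generated boundary self-intersects at frame ", f,
           "; reduce groove depth or increase chamber size", call. = FALSE)
    }
  }

  openings <- list(inlet = which(labels == "inlet"),
                   outlet = which(labels == "outlet"))
  new_moving_boundary(
    frames = frames, labels = labels,
    rings = list(wall = seq_len(n_nodes)),
    openings = openings,
    times = phase * motion$cycle_duration,
    cycle_duration = motion$cycle_duration,
    kind = "ventricle",
    meta = list(
      seed = as.integer(seed), params = params, motion = motion,
      R0 = R0, ecc = ecc, theta = theta, dims = dims,
      groove_center = g$center, groove_halfwidth = g$halfwidth,
      groove_id = groove_id,
      opening_arcs = list(inlet = c(th_in - half_in, th_in + half_in),
                          outlet = c(th_out - half_out, th_out + half_out)),
      lambda = lambda, w = w, a_target = a_target,
      translation = trans
    )
  )
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# Place groove centers on the arc `span`, given circumferential widths (um).
# Returns list(center, halfwidth[rad]) or an error message string.
place_grooves <- function(circ, r_env, span, min_gap) {
  ng <- length(circ)
  if (ng == 0L) return(list(center = numeric(0), halfwidth = numeric(0)))
  # two passes: widths depend on local radius through the groove centres
  center <- seq(span[1], span[2], length.out = ng + 2)[2:(ng + 1)]
  for (pass in 1:2) {
    halfw <- circ / (2 * r_env(center))
    gap_ang <- min_gap / r_env(center[1])
    need <- 2 * sum(halfw) + (ng + 1) * gap_ang
    avail <- span[2] - span[1]
    if (need > avail) {
      return(sprintf(paste0(
        "infeasible groove packing: %d grooves of total angular width %.2f rad ",
        "plus ridge gaps need %.2f rad but only %.2f rad of outer-curvature ",
        "arc is available"), ng, 2 * sum(halfw), need, avail))
    }
    slack <- avail - need
    shares <- stats::runif(ng + 1)
    gaps <- gap_ang + slack * shares / sum(shares)
    left <- span[1] + cumsum(gaps[seq_len(ng)]) +
      2 * c(0, cumsum(halfw))[seq_len(ng)]
    center <- left + halfw
  }
  list(center = center, halfwidth = halfw)
}

#' Generate a beating isolated intra-trabecular groove
#'
#' Emulates cropping a single intra-trabecular space off the ventricle along
#' a plane near its mouth: a pocket-shaped cavity whose mouth is a named
#' opening segment. The pocket depth and width follow the cardiac waveform
#' (deepest/narrowest configuration prescribed by [motion_model()]); nominal
#' sampled dimensions are realized at end systole. Deformational (squeeze)
#' and translational motion components are prescribed separately and are
#' recoverable with [decompose_motion()].
#'
#' @param params A [geometry_params()] object; one groove-dimension triple is
#'   drawn from its distributions.
#' @param motion A [motion_model()] object.
#' @param seed Integer seed.
#' @param opening_fraction Fraction of the cavity mouth that is open
#'   (remainder is wall); must be in (0, 1].
#' @return A [tf_moving_boundary] of kind `"groove"` with one opening.
#' @export
generate_groove <- function(params = geometry_params(),
                            motion = motion_model(),
                            seed = 1L,
                            opening_fraction = 1,
                            dims = NULL) {
  stopifnot(inherits(params, "tf_geometry_params"),
            inherits(motion, "tf_motion_model"))
  if (opening_fraction > 1) {
    stop("opening wider than the cavity mouth: `opening_fraction` must be <= 1",
         call. = FALSE)
  }
  if (opening_fraction <= 0) {
    stop("`opening_fraction` must be in (0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (is.null(dims)) {
    dims <- tibble::tibble(
      groove = 1L,
      long = sample_truncnorm(1, params$groove_long[["mean"]],
                              params$groove_long[["sd"]]),
      radial = sample_truncnorm(1, params$groove_radial[["mean"]],
                                params$groove_radial[["sd"]]),
      circ = sample_truncnorm(1, params$groove_circ[["mean"]],
                              params$groove_circ[["sd"]])
    )
  }
  W <- dims$circ[1]; D <- dims$radial[1]

  # wall: xi from -1 to +1 along y = -D * bump(xi) (counter-clockwise ring);
  # equal arc at end systole
  fine <- seq(-1, 1, length.out = 2049L)
  wall_y <- function(xi, d) -d * 0.5 * (1 + cos(pi * xi))
  xy_f <- cbind(fine * W / 2, wall_y(fine, D))
  seg <- sqrt(rowSums(diff(xy_f)^2))
  arc <- cumsum(c(0, seg))
  n_wall <- max(24L, round(arc[length(arc)] / params$node_spacing))
  xi <- stats::approx(arc, fine, xout = seq(0, arc[length(arc)],
                                            length.out = n_wall + 1))$y
  # drop the final endpoint; mouth corners belong to the wall ring once
  xi <- xi[-(n_wall + 1)]

  n_mouth <- max(4L, round(W / params$node_spacing))
  mouth_x <- seq(W / 2, -W / 2, length.out = n_mouth + 1)[-(n_mouth + 1)]
  open_idx <- abs(mouth_x) <= W / 2 * opening_fraction + 1e-9

  nf <- motion$n_frames
  phase <- (seq_len(nf) - 1) / nf
  w <- motion$volume_waveform(phase)
  trans <- motion$translation_waveform(phase)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    Wf <- W * (1 + motion$groove_width_gain * w[f])
    Df <- D * (1 - motion$squeeze_amplitude * w[f])
    wall <- cbind(xi * Wf / 2, wall_y(xi, Df))
    mouth <- cbind(mouth_x * (Wf / W), 0)
    frames[[f]] <- sweep(rbind(wall, mouth), 2, trans[f, ], `+`)
  }
  labels <- c(rep("groove", length(xi)),
              ifelse(open_idx, "opening", "ridge"))
  n_tot <- length(labels)
  new_moving_boundary(
    frames = frames, labels = labels,
    rings = list(wall = seq_len(n_tot)),
    openings = list(opening = which(labels == "opening")),
    times = phase * motion$cycle_duration,
    cycle_duration = motion$cycle_duration,
    kind = "groove",
    meta = list(seed = as.integer(seed), params = params, motion = motion,
                dims = dims, W = W, D = D, w = w,
                xi = xi, translation = trans)
  )
}

#' Smooth (non-trabeculated) counterpart of a ventricle
#'
#' Removes the intra-trabecular pockets by replacing the boundary with the
#' smooth envelope through the trabecular ridge crests, then rescales the
#' envelope at every frame so that the enclosed area matches the trabeculated
#' model's frame by frame. Stroke volume is therefore matched by
#' construction, emulating aggressive surface smoothing driven by the same
#' motion field. The node count is preserved by equal-arc resampling, and
#' inlet/outlet opening labels are carried over by angular position.
#'
#' @param mb A whole-ventricle [tf_moving_boundary].
#' @return A [tf_moving_boundary] of kind `"smooth_ventricle"`. If `mb` has
#'   no grooves it is returned unchanged.
#' @export
smooth_counterpart <- function(mb) {
  stopifnot(inherits(mb, "tf_moving_boundary"))
  if (!mb$kind %in% c("ventricle", "smooth_ventricle")) {
    stop("smooth_counterpart() expects a whole-ventricle boundary", call. = FALSE)
  }
  meta <- mb$meta
  generated <- !is.null(meta$R0)
  if (generated && nrow(meta$dims) == 0L) return(mb)

  nf <- n_frames(mb)
  n <- n_nodes(mb)
  areas <- enclosed_area(mb)

  if (generated) {
    r_env <- function(theta) meta$R0 * (1 + meta$ecc * cos(theta))
    # node set: equal arc length on the end-systolic envelope
    fine <- seq(-pi, pi, length.out = 4097L)[-4097L]
    lam_es <- meta$lambda[which.min(areas)]
    xy_f <- cbind(lam_es * r_env(fine) * cos(fine),
                  lam_es * r_env(fine) * sin(fine))
    seg <- sqrt(rowSums((rbind(xy_f[-1, ], xy_f[1, ]) - xy_f)^2))
    arc <- cumsum(c(0, seg[-length(seg)]))
    target <- (seq_len(n) - 1) / n * sum(seg)
    theta <- stats::approx(arc, fine, xout = target, rule = 2)$y
    base_r <- r_env(theta)
    frames <- vector("list", nf)
    lambda_out <- numeric(nf)
    for (f in seq_len(nf)) {
      poly_a <- ring_area(cbind(meta$lambda[f] * base_r * cos(theta),
                                meta$lambda[f] * base_r * sin(theta)))
      s <- sqrt(areas[f] / poly_a)
      lambda_out[f] <- s * meta$lambda[f]
      r <- lambda_out[f] * base_r
      frames[[f]] <- cbind(r * cos(theta) + meta$translation[f, 1],
                           r * sin(theta) + meta$translation[f, 2])
    }
    meta$lambda <- lambda_out   # the envelope scale of this smooth boundary
    labels <- rep("ridge", n)
    for (nm in names(meta$opening_arcs)) {
      a <- meta$opening_arcs[[nm]]
      mid <- mean(a); half <- diff(a) / 2
      labels[abs(wrap_angle(theta - mid)) <= half] <- nm
    }
  } else {
    # generic path: morphological opening of the radial profile removes
    # outward pockets; the result is smoothed and area-matched per frame
    es <- which.min(areas)
    cent <- ring_centroid(mb$frames[[es]][mb$rings[[1]], , drop = FALSE])
    prof <- radial_profile(mb$frames[[es]], cent)
    env <- radial_envelope(prof$r, prof$theta)
    if (max(prof$r - env) < 1) return(mb)  # nothing to smooth away
    frames <- vector("list", nf)
    theta <- prof$theta
    for (f in seq_len(nf)) {
      cf <- ring_centroid(mb$frames[[f]][mb$rings[[1]], , drop = FALSE])
      pf <- radial_profile(mb$frames[[f]], cf)
      rf <- stats::approx(c(pf$theta - 2 * pi, pf$theta, pf$theta + 2 * pi),
                          rep(radial_envelope(pf$r, pf$theta), 3),
                          xout = theta)$y
      poly_a <- ring_area(cbind(rf * cos(theta), rf * sin(theta)))
      s <- sqrt(areas[f] / poly_a)
      frames[[f]] <- cbind(s * rf * cos(theta) + cf[1],
                           s * rf * sin(theta) + cf[2])
    }
    labels <- rep("ridge", n)
  }

  new_moving_boundary(
    frames = frames, labels = labels,
    rings = list(wall = seq_len(n)),
    openings = lapply(stats::setNames(nm = names(mb$openings)),
                      function(nm) which(labels == nm)),
    times = mb$times, cycle_duration = mb$cycle_duration,
    kind = "smooth_ventricle",
    meta = c(meta[setdiff(names(meta), c("dims", "groove_center",
                                         "groove_halfwidth"))],
             list(dims = meta$dims[0, ], smooth_of = meta$seed))
  )
}

# radius/angle profile of the outer ring about a centre, sorted by angle
radial_profile <- function(frame, centre) {
  d <- sweep(frame, 2, centre)
  th <- atan2(d[, 2], d[, 1])
  o <- order(th)
  list(theta = th[o], r = sqrt(rowSums(d^2))[o], order = o)
}

# circular morphological opening (erosion then dilation) with an angular
# window, followed by a light circular moving-average
radial_envelope <- function(r, theta, window = 0.9) {
  n <- length(r)
  k <- max(3L, round(window / (2 * pi / n)))
  roll <- function(x, fun) {
    xx <- c(x[(n - k + 1):n], x, x[1:k])
    vapply(seq_len(n), function(i) fun(xx[i:(i + 2 * k)]), 0)
  }
  opened <- roll(roll(r, min), max)
  sm <- max(3L, ceiling(k / 3))
  xx <- c(opened[(n - sm + 1):n], opened, opened[1:sm])
  vapply(seq_len(n), function(i) mean(xx[i:(i + 2 * sm)]), 0)
}

#' Specify a trapped hemogenic cell
#'
#' @param center_phase0 Cell centre (x, y) in frame-1 (end-diastolic)
#'   coordinates of the host boundary (um).
#' @param diameter Cell diameter (um); measured cells span 6-8 um.
#' @param wobble_amplitude Amplitude of the seeded periodic wobble about the
#'   wall-synchronous trajectory (um).
#' @param host_groove Index of the host groove.
#' @return An object of class `tf_cell_spec`.
#' @export
trapped_cell_spec <- function(center_phase0, diameter = 6.5,
                              wobble_amplitude = 0.3, host_groove = 1L) {
  stopifnot(length(center_phase0) == 2, diameter > 0, wobble_amplitude >= 0)
  structure(list(center_phase0 = as.numeric(center_phase0),
                 diameter = diameter,
                 wobble_amplitude = wobble_amplitude,
                 host_groove = as.integer(host_groove)),
            class = "tf_cell_spec")
}

#' Add trapped cells to an isolated groove
#'
#' Appends spherical (circular in section) cells as internal moving walls.
#' Each cell moves in synchrony with the deforming groove wall -- its centre
#' follows the material deformation map of the pocket -- plus a small seeded
#' periodic wobble, and returns exactly to its initial position after one
#' cycle. Cell boundaries must never touch the endocardial boundary; a
#' violation is rejected with the offending frame index.
#'
#' @param mb A groove-kind [tf_moving_boundary] from [generate_groove()].
#' @param cells A list of [trapped_cell_spec()] objects (or a single one).
#' @param seed Integer seed for the wobble phases.
#' @param margin Minimum clearance between cell and wall (um).
#' @return A [tf_moving_boundary] with additional `cell` rings.
#' @export
add_trapped_cells <- function(mb, cells, seed = 1L, margin = 0.25) {
  stopifnot(inherits(mb, "tf_moving_boundary"))
  if (mb$kind != "groove") {
    stop("trapped cells are supported for isolated intra-trabecular ",
         "geometries (kind = \"groove\")", call. = FALSE)
  }
  if (inherits(cells, "tf_cell_spec")) cells <- list(cells)
  set.seed(as.integer(seed))
  meta <- mb$meta
  nf <- n_frames(mb)
  w <- meta$w
  spacing <- meta$params$node_spacing
  out <- mb
  for (ci in seq_along(cells)) {
    cs <- cells[[ci]]
    radius <- cs$diameter / 2
    # material map of the pocket: scale x with width, y with depth
    W1 <- meta$W * (1 + meta$motion$groove_width_gain * w[1])
    D1 <- meta$D * (1 - meta$motion$squeeze_amplitude * w[1])
    anchor <- cs$center_phase0 - meta$translation[1, ]
    xi0 <- anchor[1] / (W1 / 2)
    eta0 <- anchor[2] / D1
    ph <- stats::runif(2, 0, 2 * pi)
    dir1 <- stats::runif(1, 0, 2 * pi)
    wob <- function(phase) {
      cs$wobble_amplitude * cbind(
        sin(2 * pi * phase + ph[1]) * cos(dir1) +
          0.5 * sin(4 * pi * phase + ph[2]) * sin(dir1),
        sin(2 * pi * phase + ph[1]) * sin(dir1) +
          0.5 * sin(4 * pi * phase + ph[2]) * cos(dir1))
    }
    nc <- max(24L, round(pi * cs$diameter / (0.6 * spacing)))
    ang <- seq(0, 2 * pi, length.out = nc + 1)[-(nc + 1)]
    # clockwise ring for an internal wall
    circ <- cbind(cos(-ang), sin(-ang)) * radius
    phase <- (seq_len(nf) - 1) / nf
    wobble <- wob(phase)
    new_frames <- out$frames
    for (f in seq_len(nf)) {
      Wf <- meta$W * (1 + meta$motion$groove_width_gain * w[f])
      Df <- meta$D * (1 - meta$motion$squeeze_amplitude * w[f])
      centre <- c(xi0 * Wf / 2, eta0 * Df) + meta$translation[f, ] +
        wobble[f, ]
      ring <- sweep(circ, 2, centre, `+`)
      # clearance against every wall ring of the host boundary
      wall_xy <- out$frames[[f]][out$rings[[1]], , drop = FALSE]
      dmin <- min(dist_point_segments(ring, wall_xy, closed = TRUE))
      inside <- sp::point.in.polygon(centre[1], centre[2],
                                     wall_xy[, 1], wall_xy[, 2]) > 0
      if (!inside || dmin < margin) {
        stop("cell ", ci, " (diameter ", cs$diameter,
             " um) intersects or escapes the groove wall at frame ", f,
             call. = FALSE)
      }
      if (length(out$rings) > 1) {
        for (r in out$rings[-1]) {
          other <- out$frames[[f]][r, , drop = FALSE]
          if (min(dist_point_segments(ring, other, closed = TRUE)) < margin) {
            stop("cell ", ci, " collides with another cell at frame ", f,
                 call. = FALSE)
          }
        }
      }
      new_frames[[f]] <- rbind(out$frames[[f]], ring)
    }
    idx <- nrow(out$frames[[1]]) + seq_len(nc)
    out$frames <- new_frames
    out$labels <- c(out$labels, rep("cell", nc))
    out$rings[[paste0("cell", length(out$rings))]] <- idx
    out$meta$cells <- c(out$meta$cells, list(cs))
  }
  validate_moving_boundary(out)
}

# Minimum distances from points to the segments of a polyline
# (closed = TRUE treats the polyline as a ring).
dist_point_segments <- function(pts, poly, closed = FALSE) {
  a <- poly
  b <- if (closed) rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
       else poly[-1, , drop = FALSE]
  if (!closed) a <- poly[-nrow(poly), , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-300)
  np <- nrow(pts)
  out <- numeric(np)
  chunk <- max(1L, floor(2e6 / nrow(a)))
  for (s in seq(1L, np, by = chunk)) {
    i <- s:min(s + chunk - 1L, np)
    apx <- outer(pts[i, 1], a[, 1], `-`)   # |i| x nseg
    apy <- outer(pts[i, 2], a[, 2], `-`)
    tt <- sweep(sweep(apx, 2, ab[, 1], `*`) + sweep(apy, 2, ab[, 2], `*`),
                2, len2, `/`)
    tt <- pmin(pmax(tt, 0), 1)
    dx <- apx - sweep(tt, 2, ab[, 1], `*`)
    dy <- apy - sweep(tt, 2, ab[, 2], `*`)
    out[i] <- sqrt(apply(dx^2 + dy^2, 1, min))
  }
  out
}
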