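#' Moving endocardial boundary
#'
#' A `tf_moving_boundary` holds one cardiac cycle of a closed endocardial
#' boundary as an ordered list of frames with persistent node identity: every
#' frame contains the same nodes (rows), so node trajectories and a
#' displacement field are well defined. The boundary may consist of several
#' rings: ring 1 is the outer endocardial wall; additional rings are internal
#' moving walls (trapped cells). Units are micrometres and seconds.
#'
#' Components:
#' \describe{
#'   \item{frames}{list of n_frames numeric matrices (n_nodes x 2).}
#'   \item{labels}{character vector of per-node ground-truth region labels
#'     (`ridge`, `groove`, `inlet`, `outlet`, `opening`, `cell`).}
#'   \item{rings}{named list of node-index vectors, one per closed ring.}
#'   \item{openings}{named list of node-index vectors usable as
#'     zero-reference-pressure openings.}
#'   \item{times}{frame times (s); frames sample one period uniformly and
#'     frame `n_frames + 1` is identified with frame 1.}
#' }
#'
#' @name tf_moving_boundary
NULL

new_moving_boundary <- function(frames, labels, rings, openings, times,
                                cycle_duration, kind, meta = list()) {
  mb <- structure(
    list(frames = frames, labels = labels, rings = rings,
         openings = openings, times = times,
         cycle_duration = cycle_duration, kind = kind,
         units = c(length = "um", time = "s"), meta = meta),
    class = "tf_moving_boundary"
  )
  validate_moving_boundary(mb)
}

validate_moving_boundary <- function(mb) {
  n <- nrow(mb$frames[[1]])
  stopifnot(length(mb$labels) == n,
            all(vapply(mb$frames, nrow, 0L) == n),
            length(mb$times) == length(mb$frames))
  for (f in seq_along(mb$frames)) {
    a <- ring_area(mb$frames[[f]][mb$rings[[1]], , drop = FALSE])
    if (!is.finite(a) || a <= 0) {
      stop("frame ", f, " has non-positive enclosed area", call. = FALSE)
    }
  }
  mb
}

#' @method print tf_moving_boundary
#' @export
print.tf_moving_boundary <- function(x, ...) {
  cat(sprintf("Moving boundary (%s): %d nodes, %d rings, %d frames, T = %.3f s\n",
              x$kind, nrow(x$frames[[1]]), length(x$rings),
              length(x$frames), x$cycle_duration))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  enclosed area: %.1f (ED) -> %.1f (ES) um^2\n",
              max(enclosed_area(x)), min(enclosed_area(x))))
  invisible(x)
}

n_frames <- function(mb) length(mb$frames)
n_nodes <- function(mb) nrow(mb$frames[[1]])

# Shoelace area of one closed ring given as an n x 2 matrix (no repeated
# first point). Positive for counter-clockwise orientation.
ring_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Enclosed area of each frame
#'
#' Net fluid area of the domain: the shoelace area of the outer ring minus
#' the area occupied by internal walls (cells).
#'
#' @param mb A [tf_moving_boundary].
#' @return Numeric vector of length `n_frames` (um^2).
#' @export
enclosed_area <- function(mb) {
  vapply(mb$frames, function(fr) {
    a <- abs(ring_area(fr[mb$rings[[1]], , drop = FALSE]))
    if (length(mb$rings) > 1) {
      for (r in mb$rings[-1]) a <- a - abs(ring_area(fr[r, , drop = FALSE]))
    }
    a
  }, 0)
}

#' Stroke area of a moving boundary
#'
#' Difference between the end-diastolic (maximum) and end-systolic (minimum)
#' enclosed area; the 2D analogue of stroke volume.
#'
#' @param mb A [tf_moving_boundary].
#' @return Scalar (um^2).
#' @export
stroke_volume <- function(mb) {
  a <- enclosed_area(mb)
  max(a) - min(a)
}

#' Wall node velocities at a frame
#'
#' Central finite difference of the node trajectories over time with periodic
#' wrap: `v(f) = (x(f+1) - x(f-1)) / (2 dt)` with `dt = T / n_frames`.
#'
#' @param mb A [tf_moving_boundary].
#' @param frame Frame index (1-based). If missing, a list of all frames'
#'   velocity matrices is returned.
#' @return An `n_nodes x 2` matrix of velocities (um/s), or a list of such
#'   matrices.
#' @export
wall_velocities <- function(mb, frame) {
  nf <- n_frames(mb)
  dt <- mb$cycle_duration / nf
  one <- function(f) {
    fp <- if (f == nf) 1L else f + 1L
    fm <- if (f == 1L) nf else f - 1L
    (mb$frames[[fp]] - mb$frames[[fm]]) / (2 * dt)
  }
  if (missing(frame)) lapply(seq_len(nf), one) else one(frame)
}

# Rate of change of enclosed area by central difference (um^2/s).
area_rate <- function(mb) {
  a <- enclosed_area(mb)
  nf <- length(a)
  dt <- mb$cycle_duration / nf
  (a[c(2:nf, 1)] - a[c(nf, 1:(nf - 1))]) / (2 * dt)
}

#' End-systolic and end-diastolic frame indices
#'
#' Phase-switch frames are defined as the extrema of the enclosed-area
#' waveform: end systole at the minimum, end diastole at the maximum.
#'
#' @param mb A [tf_moving_boundary].
#' @return Named integer vector with elements `ED` and `ES`.
#' @export
phase_frames <- function(mb) {
  a <- enclosed_area(mb)
  c(ED = which.max(a), ES = which.min(a))
}

#' Best-fit rigid rotation of each frame relative to frame 1
#'
#' Kabsch-style best-fit 2D rotation of the centroid-removed outer ring of
#' each frame against frame 1. The rotation is measured for auditing only,
#' never removed: generated motion must stay below the 0.07 rad bound under
#' which rigid rotations are neglected.
#'
#' @param mb A [tf_moving_boundary].
#' @return Numeric vector of signed rotation angles (rad), one per frame.
#' @export
rigid_rotation <- function(mb) {
  ref <- mb$frames[[1]][mb$rings[[1]], , drop = FALSE]
  ref <- sweep(ref, 2, colMeans(ref))
  vapply(mb$frames, function(fr) {
    cur <- fr[mb$rings[[1]], , drop = FALSE]
    cur <- sweep(cur, 2, colMeans(cur))
    h <- crossprod(ref, cur)  # 2x2
    atan2(h[1, 2] - h[2, 1], h[1, 1] + h[2, 2])
  }, 0)
}

#' Decompose wall motion into translation and deformation
#'
#' Splits the motion of a moving boundary into the rigid translation of its
#' outer-ring area centroid and the residual (deformational) motion. The
#' translation-only boundary rigidly translates the frame-1 shape along the
#' centroid path; the deformation-only boundary pins the centroid to its
#' frame-1 position. By construction the two components recompose exactly:
#' `translation_only + (deformation_only - frame1) = original`.
#'
#' Rigid rotation is deliberately not extracted; it is measured (Kabsch
#' best-fit) and reported, and an error is raised if it reaches 0.07 rad.
#'
#' @param mb A [tf_moving_boundary] with at least 2 frames.
#' @return A list with elements `translation` (tibble: frame, phase, tx, ty),
#'   `deformation_only` and `translation_only` (both [tf_moving_boundary]),
#'   and `max_rotation` (rad).
#' @export
decompose_motion <- function(mb) {
  if (n_frames(mb) < 2) stop("need >= 2 frames to decompose", call. = FALSE)
  cent <- t(vapply(mb$frames, function(fr)
    ring_centroid(fr[mb$rings[[1]], , drop = FALSE]), c(0, 0)))
  tr <- sweep(cent, 2, cent[1, ])
  rot <- rigid_rotation(mb)
  if (max(abs(rot)) >= 0.07) {
    stop("rigid rotation reaches ", signif(max(abs(rot)), 3),
         " rad (>= 0.07); decomposition into translation + deformation ",
         "is not meaningful", call. = FALSE)
  }
  def <- mb
  def$frames <- lapply(seq_len(n_frames(mb)), function(f)
    sweep(mb$frames[[f]], 2, tr[f, ]))
  def$meta$motion_variant <- "deformation_only"
  tro <- mb
  tro$frames <- lapply(seq_len(n_frames(mb)), function(f)
    sweep(mb$frames[[1]], 2, tr[f, ], `+`))
  tro$meta$motion_variant <- "translation_only"
  list(
    translation = tibble::tibble(
      frame = seq_len(n_frames(mb)),
      phase = (seq_len(n_frames(mb)) - 1) / n_frames(mb),
      tx = tr[, 1], ty = tr[, 2]
    ),
    deformation_only = def,
    translation_only = tro,
    max_rotation = max(abs(rot))
  )
}

# Per-node boundary weights: half the length of the two segments incident to
# each node of each ring, at one frame. Used for area-weighted wall averages.
node_weights <- function(mb, frame = 1L) {
  fr <- mb$frames[[frame]]
  w <- numeric(nrow(fr))
  for (r in mb$rings) {
    xy <- fr[r, , drop = FALSE]
    nxt <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
    seg <- sqrt(rowSums((nxt - xy)^2))
    prev <- c(seg[length(seg)], seg[-length(seg)])
    w[r] <- (seg + prev) / 2
  }
  w
}

# Simple polyline self-intersection check on a ring (O(n^2) on segment
# bounding boxes, exact orientation tests on candidates).
ring_simple <- function(xy) {
  n <- nrow(xy)
  p1 <- xy
  p2 <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- setdiff((i + 2):n, if (i == 1) n else integer())
    if (!length(j)) next
    d1 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[j, 1], p1[j, 2])
    d2 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[j, 1], p2[j, 2])
    d3 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], p1[i, 1], p1[i, 2])
    d4 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], p2[i, 1], p2[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Tidy node trajectories of a moving boundary
#'
#' @param x A [tf_moving_boundary].
#' @param ... Unused.
#' @return A tibble with one row per node and frame: node, frame, phase,
#'   time, x, y, label, ring.
#' @method tidy tf_moving_boundary
#' @export
tidy.tf_moving_boundary <- function(x, ...) {
  nf <- n_frames(x); nn <- n_nodes(x)
  ring_id <- integer(nn)
  for (k in seq_along(x$rings)) ring_id[x$rings[[k]]] <- k
  labels <- x$labels
  ring_names <- names(x$rings)[ring_id]
  times <- x$times
  purrr::map_dfr(seq_len(nf), function(f) {
    fr <- x$frames[[f]]
    tibble::tibble(
      node = seq_len(nn), frame = f, phase = (f - 1) / nf,
      time = times[f], x = fr[, 1], y = fr[, 2],
      label = labels, ring = ring_names
    )
  })
}

#' @method autoplot tf_moving_boundary
#' @export
autoplot.tf_moving_boundary <- function(object, frames = NULL, ...) {
  df <- tidy.tf_moving_boundary(object)
  if (!is.null(frames)) df <- df[df$frame %in% frames, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = interaction(.data$frame, .data$ring),
                                   colour = .data$phase)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "phase") +
    ggplot2::theme_minimal()
}
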