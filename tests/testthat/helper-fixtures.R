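# Shared geometric fixtures: rectangle and annular-sector channels with
# uniformly resampled boundaries, plus cached expensive solves.

# closed polygon resampled at spacing h (counter-clockwise corners)
resample_ring <- function(poly, h) {
  out <- NULL
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[i %% n + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, round(len / h))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2])))
  }
  out
}

# axis-aligned rectangle [0,L] x [0,H], boundary spacing h
rect_boundary <- function(L, H, h) {
  resample_ring(cbind(c(0, L, L, 0), c(0, 0, H, H)), h)
}

# rectangle channel fixture: returns mesh plus node index helpers
channel_fixture <- function(L, H, h) {
  m <- mesh_domain(rect_boundary(L, H, h), h)
  nb <- m$n_boundary
  bxy <- m$xy[seq_len(nb), , drop = FALSE]
  tol <- 1e-9
  list(
    mesh = m, nb = nb, bxy = bxy,
    bottom = which(abs(bxy[, 2]) < tol),
    top = which(abs(bxy[, 2] - H) < tol),
    sides_open = which((abs(bxy[, 1]) < tol | abs(bxy[, 1] - L) < tol) &
                         bxy[, 2] > tol & bxy[, 2] < H - tol),
    left = which(abs(bxy[, 1]) < tol)
  )
}

# annular sector r in [R1, R2], theta in [0, Theta]; open radial ends
annulus_fixture <- function(R1, R2, Theta, h) {
  n_in <- max(8L, round(R1 * Theta / h))
  n_out <- max(8L, round(R2 * Theta / h))
  n_rad <- max(4L, round((R2 - R1) / h))
  th_out <- seq(0, Theta, length.out = n_out + 1)
  th_in <- seq(Theta, 0, length.out = n_in + 1)
  r_end <- seq(R2, R1, length.out = n_rad + 1)
  r_start <- seq(R1, R2, length.out = n_rad + 1)
  poly <- rbind(
    cbind(r_start * cos(0), r_start * sin(0))[-(n_rad + 1), , drop = FALSE],
    cbind(R2 * cos(th_out), R2 * sin(th_out))[-(n_out + 1), , drop = FALSE],
    cbind(r_end * cos(Theta), r_end * sin(Theta))[-(n_rad + 1), , drop = FALSE],
    cbind(R1 * cos(th_in), R1 * sin(th_in))[-(n_in + 1), , drop = FALSE]
  )
  m <- mesh_domain(poly, h)
  nb <- m$n_boundary
  bxy <- m$xy[seq_len(nb), , drop = FALSE]
  r <- sqrt(rowSums(bxy^2))
  th <- atan2(bxy[, 2], bxy[, 1])
  tol <- 1e-6
  list(
    mesh = m, nb = nb, bxy = bxy, r = r, theta = th,
    inner = which(abs(r - R1) < tol & th > 0.15 * Theta & th < 0.85 * Theta),
    outer = which(abs(r - R2) < tol & th > 0.15 * Theta & th < 0.85 * Theta),
    end0 = which(abs(th) < tol & r > R1 + tol & r < R2 - tol),
    end1 = which(abs(th - Theta) < tol & r > R1 + tol & r < R2 - tol)
  )
}

# analytic azimuthal Stokes flow in an annulus under pressure gradient
# G = dp/dtheta: u(r) = A r + B / r + (G / (2 mu)) r log(r), no slip at
# R1 and R2. Returns the wall shear rate magnitudes |du/dr| at both walls.
annulus_exact_shear <- function(R1, R2, G, mu) {
  C <- G / (2 * mu)
  M <- rbind(c(R1, 1 / R1), c(R2, 1 / R2))
  rhs <- -C * c(R1 * log(R1), R2 * log(R2))
  ab <- solve(M, rhs)
  du <- function(r) ab[1] - ab[2] / r^2 + C * (log(r) + 1)
  c(inner = abs(du(R1)), outer = abs(du(R2)))
}

# cache for expensive cycle solves shared between test files
.tf_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .tf_cache)) {
    assign(key, force(expr), envir = .tf_cache)
  }
  get(key, envir = .tf_cache)
}
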