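#' Fluid properties
#'
#' Newtonian incompressible fluid. Presets follow the study fluids: blood
#' plasma at 1.5 cP and whole embryonic blood at 7.35 cP, both at a density
#' of 1.025 kg/L. In the Stokes limit the density only enters the
#' Reynolds/Womersley audit, never the solve.
#'
#' @param viscosity `"plasma"`, `"blood"`, or a numeric viscosity in Pa s.
#' @param density Density in kg/m^3.
#' @return An object of class `tf_fluid`.
#' @export
fluid_properties <- function(viscosity = "plasma", density = 1025) {
  mu <- if (is.character(viscosity)) {
    switch(match.arg(viscosity, c("plasma", "blood")),
           plasma = 1.5e-3, blood = 7.35e-3)
  } else {
    as.numeric(viscosity)
  }
  if (!is.finite(mu) || mu <= 0) stop("viscosity must be > 0", call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  structure(list(viscosity = mu, density = density,
                 preset = if (is.character(viscosity)) viscosity else "custom"),
            class = "tf_fluid")
}

#' @method print tf_fluid
#' @export
print.tf_fluid <- function(x, ...) {
  cat(sprintf("Fluid: mu = %g Pa s (%s), rho = %g kg/m^3\n",
              x$viscosity, x$preset, x$density))
  invisible(x)
}

# --- Taylor-Hood P2/P1 spaces ---------------------------------------------

# 7-point degree-5 triangle quadrature (barycentric, weights sum to 1)
.tri_quad <- local({
  a1 <- 0.797426985353087; b1 <- 0.101286507323456
  a2 <- 0.059715871789770; b2 <- 0.470142064105115
  list(
    lambda = rbind(c(1, 1, 1) / 3,
                   c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
                   c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2)),
    w = c(0.225,
          rep(0.125939180544827, 3),
          rep(0.132394152788506, 3))
  )
})

# Edge table and P2 connectivity for a triangle mesh.
fem_spaces <- function(mesh) {
  tri <- mesh$tri
  nv <- nrow(mesh$xy)
  pair_key <- function(i, j) pmin(i, j) * (nv + 1) + pmax(i, j)
  e_all <- cbind(c(tri[, 2], tri[, 3], tri[, 1]),
                 c(tri[, 3], tri[, 1], tri[, 2]))
  keys <- pair_key(e_all[, 1], e_all[, 2])
  ukeys <- unique(keys)
  eidx <- match(keys, ukeys)
  ne <- nrow(tri)
  edge_of_tri <- cbind(eidx[1:ne], eidx[ne + 1:ne], eidx[2 * ne + 1:ne])
  edge_v <- cbind(ukeys %/% (nv + 1), ukeys %% (nv + 1))
  mid <- (mesh$xy[edge_v[, 1], , drop = FALSE] +
            mesh$xy[edge_v[, 2], , drop = FALSE]) / 2
  list(nv = nv, n_edge = length(ukeys),
       edge_v = edge_v, edge_of_tri = edge_of_tri,
       elem_dof = cbind(tri, nv + edge_of_tri),
       p2_xy = rbind(mesh$xy, mid),
       pair_key = pair_key, edge_keys = ukeys)
}

# P2 basis gradients at one barycentric point for all elements.
# b, cc: ne x 3 matrices of d(lambda_i)/dx, d(lambda_i)/dy.
p2_grads <- function(lam, b, cc) {
  gx <- cbind((4 * lam[1] - 1) * b[, 1],
              (4 * lam[2] - 1) * b[, 2],
              (4 * lam[3] - 1) * b[, 3],
              4 * (lam[2] * b[, 3] + lam[3] * b[, 2]),
              4 * (lam[3] * b[, 1] + lam[1] * b[, 3]),
              4 * (lam[1] * b[, 2] + lam[2] * b[, 1]))
  gy <- cbind((4 * lam[1] - 1) * cc[, 1],
              (4 * lam[2] - 1) * cc[, 2],
              (4 * lam[3] - 1) * cc[, 3],
              4 * (lam[2] * cc[, 3] + lam[3] * cc[, 2]),
              4 * (lam[3] * cc[, 1] + lam[1] * cc[, 3]),
              4 * (lam[1] * cc[, 2] + lam[2] * cc[, 1]))
  list(gx = gx, gy = gy)
}

# Assemble the scalar P2 stiffness matrix K and the P1-P2 divergence
# matrices Bx, By (rows: pressure vertices, cols: P2 velocity dofs).
assemble_stokes <- function(mesh, sp) {
  tri <- mesh$tri
  xy <- mesh$xy
  ne <- nrow(tri)
  x1 <- xy[tri[, 1], 1]; y1 <- xy[tri[, 1], 2]
  x2 <- xy[tri[, 2], 1]; y2 <- xy[tri[, 2], 2]
  x3 <- xy[tri[, 3], 1]; y3 <- xy[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det / 2
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / det

  q <- .tri_quad
  nq <- length(q$w)
  G <- lapply(seq_len(nq), function(k) p2_grads(q$lambda[k, ], b, cc))

  K_val <- matrix(0, ne, 36)
  Bx_val <- matrix(0, ne, 18)
  By_val <- matrix(0, ne, 18)
  for (k in seq_len(nq)) {
    wq <- q$w[k]
    gx <- G[[k]]$gx; gy <- G[[k]]$gy
    lam <- q$lambda[k, ]
    for (i in 1:6) {
      for (j in 1:6) {
        col <- (i - 1) * 6 + j
        K_val[, col] <- K_val[, col] + wq * (gx[, i] * gx[, j] +
                                               gy[, i] * gy[, j])
      }
    }
    for (l in 1:3) {
      for (j in 1:6) {
        col <- (l - 1) * 6 + j
        Bx_val[, col] <- Bx_val[, col] + wq * lam[l] * gx[, j]
        By_val[, col] <- By_val[, col] + wq * lam[l] * gy[, j]
      }
    }
  }
  ed <- sp$elem_dof
  N2 <- sp$nv + sp$n_edge
  ii <- jj <- matrix(0L, ne, 36)
  for (i in 1:6) for (j in 1:6) {
    col <- (i - 1) * 6 + j
    ii[, col] <- ed[, i]
    jj[, col] <- ed[, j]
  }
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(K_val * area),
                            dims = c(N2, N2))
  pi_ <- pj_ <- matrix(0L, ne, 18)
  for (l in 1:3) for (j in 1:6) {
    col <- (l - 1) * 6 + j
    pi_[, col] <- tri[, l]
    pj_[, col] <- ed[, j]
  }
  Bx <- Matrix::sparseMatrix(i = as.vector(pi_), j = as.vector(pj_),
                             x = as.vector(Bx_val * area),
                             dims = c(sp$nv, N2))
  By <- Matrix::sparseMatrix(i = as.vector(pi_), j = as.vector(pj_),
                             x = as.vector(By_val * area),
                             dims = c(sp$nv, N2))
  list(K = K, Bx = Bx, By = By, area = area)
}

#' Boundary conditions for one cardiac frame
#'
#' Every boundary node carries exactly one condition: a prescribed wall
#' velocity (moving no-slip wall) or membership in an open segment, the
#' discrete realization of the zero-reference-pressure boundary: zero
#' pseudo-traction `mu du/dn - p n = -p_ref n`, with `p_ref = 0` by default.
#'
#' @param velocity `n_boundary x 2` matrix of boundary-node velocities
#'   (um/s); used on wall nodes and for the motion of open segments in the
#'   mass audit.
#' @param open Integer indices of boundary nodes belonging to open segments
#'   (may be empty for a sealed cavity).
#' @param p_ref Reference pressure (Pa): scalar or per-boundary-node vector;
#'   only values on open segments are used.
#' @return An object of class `tf_bc`.
#' @export
boundary_spec <- function(velocity, open = integer(0), p_ref = 0) {
  stopifnot(is.matrix(velocity), ncol(velocity) == 2)
  n <- nrow(velocity)
  if (length(p_ref) == 1) p_ref <- rep(p_ref, n)
  stopifnot(length(p_ref) == n)
  open <- as.integer(open)
  if (length(open) && (min(open) < 1 || max(open) > n)) {
    stop("`open` indices out of range", call. = FALSE)
  }
  structure(list(velocity = velocity, open = open, p_ref = p_ref),
            class = "tf_bc")
}

# boundary edges of the mesh: consecutive ring pairs, with open flag and
# the adjacent element (needed for shear extraction and Neumann terms)
boundary_edges <- function(mesh, sp, bc) {
  out <- NULL
  for (r in mesh$rings) {
    a <- r
    b <- c(r[-1], r[1])
    out <- rbind(out, cbind(a, b))
  }
  keys <- sp$pair_key(out[, 1], out[, 2])
  eid <- match(keys, sp$edge_keys)
  if (anyNA(eid)) stop("internal error: boundary edge missing from mesh")
  # adjacent element: triangle that contains this edge
  tri_of_edge <- rep(NA_integer_, sp$n_edge)
  eot <- sp$edge_of_tri
  for (loc in 1:3) tri_of_edge[eot[, loc]] <- seq_len(nrow(eot))
  # an edge is traction-free as soon as one endpoint is open: wall vertices
  # at the junction stay Dirichlet, but the junction edge is never clamped
  open_set <- bc$open
  is_open <- out[, 1] %in% open_set | out[, 2] %in% open_set
  list(v1 = out[, 1], v2 = out[, 2], edge = eid,
       elem = tri_of_edge[eid], open = is_open)
}

#' Solve quasi-steady Stokes flow on one frame
#'
#' Solves the stationary Stokes system `mu lap(u) = grad p`, `div u = 0` on
#' the meshed fluid domain with Taylor-Hood P2/P1 elements: prescribed
#' velocity on wall nodes (P2 midpoints interpolate linearly), zero
#' pseudo-traction with gauge pressure `p_ref` on open segments, and a
#' direct sparse solve of the saddle-point system. With no open segment the
#' prescribed wall flux must vanish (compatibility) and the pressure is
#' gauged at one vertex.
#'
#' @param mesh A [tf_mesh].
#' @param bc A [boundary_spec()].
#' @param fluid A [fluid_properties()].
#' @param method `"schur"` (pressure Schur complement by preconditioned
#'   conjugate gradients over a Cholesky factorization of the velocity
#'   block; fast) or `"lu"` (direct sparse LU of the full saddle system).
#'   The Schur path falls back to `"lu"` automatically if CG stalls.
#' @return An object of class `tf_flow_frame`: vertex velocities `u`
#'   (nv x 2), full P2 coefficients `u2`, pressure `p` (Pa), plus the mesh
#'   and space tables needed by [wall_shear_rate()] and [mass_balance()].
#' @export
solve_frame <- function(mesh, bc, fluid = fluid_properties(),
                        method = c("schur", "lu")) {
  method <- match.arg(method)
  stopifnot(inherits(mesh, "tf_mesh"), inherits(bc, "tf_bc"))
  if (nrow(bc$velocity) != mesh$n_boundary) {
    stop("bc velocity rows (", nrow(bc$velocity), ") must match boundary ",
         "nodes (", mesh$n_boundary, ")", call. = FALSE)
  }
  sp <- fem_spaces(mesh)
  asm <- assemble_stokes(mesh, sp)
  be <- boundary_edges(mesh, sp, bc)
  mu <- fluid$viscosity
  N2 <- sp$nv + sp$n_edge
  np <- sp$nv

  # --- Dirichlet data ------------------------------------------------------
  # vertex dofs: all boundary vertices not in an open segment
  wall_v <- setdiff(seq_len(mesh$n_boundary), bc$open)
  vx <- rep(NA_real_, N2); vy <- rep(NA_real_, N2)
  vx[wall_v] <- bc$velocity[wall_v, 1]
  vy[wall_v] <- bc$velocity[wall_v, 2]
  # midpoint dofs of non-open boundary edges
  wall_e <- !be$open
  me <- sp$nv + be$edge[wall_e]
  vx[me] <- (bc$velocity[be$v1[wall_e], 1] + bc$velocity[be$v2[wall_e], 1]) / 2
  vy[me] <- (bc$velocity[be$v1[wall_e], 2] + bc$velocity[be$v2[wall_e], 2]) / 2
  known <- which(!is.na(vx))

  has_open <- any(be$open)
  if (!has_open) {
    # compatibility of the prescribed wall flux with incompressibility
    flux <- prescribed_flux(mesh, bc, be, which(!be$open))
    scale <- sum(abs(bc$velocity)) + 1e-12
    if (abs(flux) > 1e-8 * max(scale, 1)) {
      stop("sealed cavity with incompatible wall flux: net inflow ",
           signif(flux, 4), " um^2/s cannot be absorbed by an ",
           "incompressible fluid; open a segment or fix the motion",
           call. = FALSE)
    }
  }

  # Neumann term for nonzero reference pressure on open edges
  neu_x <- numeric(N2); neu_y <- numeric(N2)
  if (has_open && any(bc$p_ref != 0)) {
    for (k in which(be$open)) {
      a <- be$v1[k]; b <- be$v2[k]
      pbar <- (bc$p_ref[a] + bc$p_ref[b]) / 2
      if (pbar == 0) next
      tv <- mesh$xy[b, ] - mesh$xy[a, ]
      len <- sqrt(sum(tv^2))
      nrm <- c(tv[2], -tv[1]) / len
      wphi <- c(len / 6, len / 6, 2 * len / 3)   # v1, v2, midpoint
      dofs <- c(a, b, sp$nv + be$edge[k])
      neu_x[dofs] <- neu_x[dofs] - pbar * nrm[1] * wphi
      neu_y[dofs] <- neu_y[dofs] - pbar * nrm[2] * wphi
    }
  }

  vx[is.na(vx)] <- 0; vy[is.na(vy)] <- 0
  free_v <- setdiff(seq_len(N2), known)
  sol <- NULL
  if (method == "schur") {
    sol <- solve_stokes_schur(asm, sp, mu, known, free_v, vx, vy,
                              neu_x, neu_y, has_open)
  }
  if (is.null(sol)) {
    sol <- solve_stokes_lu(asm, sp, mu, known, free_v, vx, vy,
                           neu_x, neu_y, has_open)
  }

  structure(list(
    mesh = mesh, sp = sp, be = be, bc = bc, fluid = fluid,
    u2 = sol$u2,
    u = sol$u2[1:sp$nv, , drop = FALSE],
    p = sol$p
  ), class = "tf_flow_frame")
}

# Pressure Schur-complement solve: S p = r with S = B_f (mu K_ff)^-1 B_f^T,
# by conjugate gradients preconditioned with the lumped P1 pressure mass
# matrix scaled by 1/mu (spectrally equivalent to S for Taylor-Hood).
# Returns NULL if CG fails to converge (caller falls back to direct LU).
solve_stokes_schur <- function(asm, sp, mu, known, free_v, vx, vy,
                               neu_x, neu_y, has_open,
                               tol = 1e-12, maxit = 600) {
  N2 <- sp$nv + sp$n_edge
  Kff <- Matrix::forceSymmetric(mu * asm$K[free_v, free_v])
  ch <- try(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE), silent = TRUE)
  if (inherits(ch, "try-error")) return(NULL)
  Kfk <- mu * asm$K[free_v, known, drop = FALSE]
  BxF <- asm$Bx[, free_v, drop = FALSE]
  ByF <- asm$By[, free_v, drop = FALSE]
  bx <- neu_x[free_v] - as.vector(Kfk %*% vx[known])
  by <- neu_y[free_v] - as.vector(Kfk %*% vy[known])
  g <- -as.vector(asm$Bx[, known, drop = FALSE] %*% vx[known] +
                    asm$By[, known, drop = FALSE] %*% vy[known])

  ksolve <- function(b) as.vector(Matrix::solve(ch, b))
  apply_S <- function(p) {
    as.vector(BxF %*% ksolve(as.vector(Matrix::crossprod(BxF, p)))) +
      as.vector(ByF %*% ksolve(as.vector(Matrix::crossprod(ByF, p))))
  }
  # lumped pressure mass (P1): one third of the incident element areas
  mp <- numeric(sp$nv)
  tri_all <- rbind(cbind(sp$elem_dof[, 1], asm$area),
                   cbind(sp$elem_dof[, 2], asm$area),
                   cbind(sp$elem_dof[, 3], asm$area))
  agg <- rowsum(tri_all[, 2], tri_all[, 1])
  mp[as.integer(rownames(agg))] <- agg[, 1] / 3
  mp[mp <= 0] <- min(mp[mp > 0])
  prec <- function(r) {
    z <- mu * r / mp
    if (!has_open) z <- z - sum(mp * z) / sum(mp)
    z
  }

  # solve S p = g - B_f K^-1 b, starting from p = 0
  r <- g - (as.vector(BxF %*% ksolve(bx)) + as.vector(ByF %*% ksolve(by)))
  p <- numeric(sp$nv)
  z <- prec(r)
  d <- z
  rz <- sum(r * z)
  r0 <- sqrt(sum(r * r))
  scale0 <- max(r0, sqrt(sum(g * g)), 1e-300)
  converged <- r0 <= 1e-300
  if (!converged) {
    for (it in seq_len(maxit)) {
      Sd <- apply_S(d)
      dSd <- sum(d * Sd)
      if (!is.finite(dSd) || dSd <= 0) break
      alpha <- rz / dSd
      p <- p + alpha * d
      r <- r - alpha * Sd
      if (sqrt(sum(r * r)) <= tol * scale0) { converged <- TRUE; break }
      z <- prec(r)
      rz_new <- sum(r * z)
      beta <- rz_new / rz
      rz <- rz_new
      d <- z + beta * d
    }
  }
  if (!converged) return(NULL)
  ux <- numeric(N2); uy <- numeric(N2)
  ux[known] <- vx[known]; uy[known] <- vy[known]
  ux[free_v] <- ksolve(bx + as.vector(Matrix::crossprod(BxF, p)))
  uy[free_v] <- ksolve(by + as.vector(Matrix::crossprod(ByF, p)))
  list(u2 = cbind(ux, uy), p = p)
}

# Direct sparse LU of the reduced saddle-point system.
solve_stokes_lu <- function(asm, sp, mu, known, free_v, vx, vy,
                            neu_x, neu_y, has_open) {
  N2 <- sp$nv + sp$n_edge
  np <- sp$nv
  Kt <- Matrix::mat2triplet(asm$K)
  Bxt <- Matrix::mat2triplet(asm$Bx)
  Byt <- Matrix::mat2triplet(asm$By)
  ti <- c(Kt$i, N2 + Kt$i,
          Bxt$j, N2 + Byt$j,
          2L * N2 + Bxt$i, 2L * N2 + Byt$i)
  tj <- c(Kt$j, N2 + Kt$j,
          2L * N2 + Bxt$i, 2L * N2 + Byt$i,
          Bxt$j, N2 + Byt$j)
  tx <- c(mu * Kt$x, mu * Kt$x,
          -Bxt$x, -Byt$x,
          Bxt$x, Byt$x)
  rhs <- numeric(2 * N2 + np)
  rhs[1:N2] <- neu_x
  rhs[N2 + 1:N2] <- neu_y
  known_dofs <- c(known, N2 + known)
  known_vals <- c(vx[known], vy[known])
  if (!has_open) {
    known_dofs <- c(known_dofs, 2L * N2 + 1L)  # pressure gauge
    known_vals <- c(known_vals, 0)
  }
  ndof <- 2 * N2 + np
  is_known <- logical(ndof)
  is_known[known_dofs] <- TRUE
  valvec <- numeric(ndof)
  valvec[known_dofs] <- known_vals
  keep <- !is_known[ti] & is_known[tj]
  if (any(keep)) {
    contrib <- rowsum(tx[keep] * valvec[tj[keep]], ti[keep])
    rows <- as.integer(rownames(contrib))
    rhs[rows] <- rhs[rows] - contrib[, 1]
  }
  newid <- cumsum(!is_known)
  mask <- !is_known[ti] & !is_known[tj]
  A_ff <- Matrix::sparseMatrix(i = newid[ti[mask]], j = newid[tj[mask]],
                               x = tx[mask],
                               dims = rep(ndof - length(known_dofs), 2))
  sol <- valvec
  sol[!is_known] <- as.vector(Matrix::solve(A_ff, rhs[!is_known]))
  list(u2 = cbind(sol[1:N2], sol[N2 + 1:N2]), p = sol[2 * N2 + 1:np])
}

#' @method print tf_flow_frame
#' @export
print.tf_flow_frame <- function(x, ...) {
  cat(sprintf("Stokes flow frame: %d velocity nodes, |u| max %.3g um/s, p range [%.3g, %.3g] Pa\n",
              nrow(x$u2), max(sqrt(rowSums(x$u2^2))), min(x$p), max(x$p)))
  invisible(x)
}

# outward (away from fluid) unit normal of a boundary edge with direction tv,
# oriented using the adjacent element centroid
outward_normal <- function(tv, mesh, elem) {
  nrm <- c(tv[2], -tv[1])
  nrm / sqrt(sum(nrm^2))
}

# net outward flux of the prescribed boundary velocity over given edges
prescribed_flux <- function(mesh, bc, be, edge_idx) {
  tot <- 0
  for (k in edge_idx) {
    a <- be$v1[k]; b <- be$v2[k]
    tv <- mesh$xy[b, ] - mesh$xy[a, ]
    len <- sqrt(sum(tv^2))
    nrm <- c(tv[2], -tv[1]) / max(len, 1e-300)
    vmid <- (bc$velocity[a, ] + bc$velocity[b, ]) / 2
    tot <- tot + sum(vmid * nrm) * len
  }
  tot
}

#' Wall shear rate of a solved frame
#'
#' Signed tangential shear rate at every wall boundary node, from the
#' rate-of-deformation tensor of the finite-element velocity field:
#' `gamma = t . (grad u + grad u^T) . n` with `n` the outward wall normal
#' and `t` the ring-traversal tangent. The rate-of-deformation form is
#' invariant under rigid wall motion, i.e. it measures shear in the
#' wall-relative frame. Contributions from the two boundary edges incident
#' to a node are averaged. Open-segment nodes get `NA`.
#'
#' @param ff A [tf_flow_frame].
#' @param nodes Optional subset of boundary node indices.
#' @return Numeric vector over boundary nodes (s^-1).
#' @export
wall_shear_rate <- function(ff, nodes = NULL) {
  mesh <- ff$mesh; sp <- ff$sp; be <- ff$be
  nb <- mesh$n_boundary
  if (is.null(nodes)) nodes <- seq_len(nb)
  if (any(nodes > nb)) stop("node not on the mesh boundary", call. = FALSE)
  acc <- numeric(nb); cnt <- numeric(nb)
  tri <- mesh$tri; xy <- mesh$xy
  for (k in seq_along(be$edge)) {
    if (be$open[k]) next
    el <- be$elem[k]
    vids <- tri[el, ]
    # element geometry
    x <- xy[vids, 1]; y <- xy[vids, 2]
    det <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
    b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2]) / det
    cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / det
    tv <- xy[be$v2[k], ] - xy[be$v1[k], ]
    len <- sqrt(sum(tv^2))
    tv <- tv / len
    nrm <- c(tv[2], -tv[1])
    ue <- ff$u2[sp$elem_dof[el, ], , drop = FALSE]
    for (vtx in c(be$v1[k], be$v2[k])) {
      lam <- c(0, 0, 0)
      lam[match(vtx, vids)] <- 1
      g <- p2_grads(lam, rbind(b), rbind(cc))
      # G = grad u (2x2): G[i,j] = du_i/dx_j
      G11 <- sum(g$gx * ue[, 1]); G12 <- sum(g$gy * ue[, 1])
      G21 <- sum(g$gx * ue[, 2]); G22 <- sum(g$gy * ue[, 2])
      # gamma = t . (G + G^T) . n
      gam <- tv[1] * ((2 * G11) * nrm[1] + (G12 + G21) * nrm[2]) +
        tv[2] * ((G12 + G21) * nrm[1] + (2 * G22) * nrm[2])
      acc[vtx] <- acc[vtx] + gam
      cnt[vtx] <- cnt[vtx] + 1
    }
  }
  out <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  out[nodes]
}

#' Discrete mass-balance residual of a solved frame
#'
#' Audits incompressibility against the moving boundary: the fluid flux
#' through the open segments, measured relative to the moving boundary,
#' must balance the rate of change of the domain area implied by the
#' prescribed boundary motion. Returns
#' `|flux_open_rel + dA/dt| / max(|dA/dt|, eps)`.
#'
#' @param ff A [tf_flow_frame].
#' @param eps Floor for the normalization (um^2/s).
#' @return Dimensionless residual fraction.
#' @export
mass_balance <- function(ff, eps = 1e-10) {
  mesh <- ff$mesh; sp <- ff$sp; be <- ff$be; bc <- ff$bc
  dadt <- prescribed_flux(mesh, bc, be, seq_along(be$edge))
  flux <- 0
  for (k in which(be$open)) {
    a <- be$v1[k]; b <- be$v2[k]
    tv <- mesh$xy[b, ] - mesh$xy[a, ]
    len <- sqrt(sum(tv^2))
    nrm <- c(tv[2], -tv[1]) / max(len, 1e-300)
    mdof <- sp$nv + be$edge[k]
    urel <- rbind(ff$u2[a, ] - bc$velocity[a, ],
                  ff$u2[b, ] - bc$velocity[b, ],
                  ff$u2[mdof, ] - (bc$velocity[a, ] + bc$velocity[b, ]) / 2)
    wphi <- c(len / 6, len / 6, 2 * len / 3)
    flux <- flux + sum((urel %*% nrm) * wphi)
  }
  abs(flux + dadt) / max(abs(dadt), eps)
}
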