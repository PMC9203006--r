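# Closed-form oracles for the quasi-steady Stokes solver. The rectangle
# fixtures admit exact Taylor-Hood representations (linear/quadratic
# velocity), so Couette and Poiseuille must be reproduced to solver
# precision, not just discretization accuracy.

test_that("static sealed cavity gives identically zero flow", {
  cf <- channel_fixture(2, 1, 0.1)
  ff <- solve_frame(cf$mesh, boundary_spec(matrix(0, cf$nb, 2)))
  expect_equal(max(abs(ff$u2)), 0)
  expect_equal(max(abs(ff$p)), 0)
  expect_equal(mass_balance(ff), 0)
})

test_that("Couette flow: wall shear rate equals U/h on both plates", {
  cf <- channel_fixture(2, 1, 0.1)
  U <- 10
  vel <- matrix(0, cf$nb, 2)
  vel[cf$top, 1] <- U
  ff <- solve_frame(cf$mesh, boundary_spec(vel, cf$sides_open))
  g <- wall_shear_rate(ff)
  expect_equal(abs(g[cf$bottom]), rep(U / 1, length(cf$bottom)),
               tolerance = 1e-8)
  expect_equal(abs(g[cf$top]), rep(U / 1, length(cf$top)), tolerance = 1e-8)
})

test_that("Poiseuille flow: wall shear stress equals h dp / (2 L)", {
  cf <- channel_fixture(2, 1, 0.1)
  mu <- 1.5e-3; dp <- 1e-3; L <- 2; H <- 1
  pref <- rep(0, cf$nb)
  pref[cf$left] <- dp
  ff <- solve_frame(cf$mesh,
                    boundary_spec(matrix(0, cf$nb, 2), cf$sides_open,
                                  p_ref = pref),
                    fluid_properties(mu))
  g <- wall_shear_rate(ff)
  tau_exact <- H * dp / (2 * L)
  expect_equal(mu * abs(g[cf$bottom]), rep(tau_exact, length(cf$bottom)),
               tolerance = 1e-8)
  umax_exact <- dp * H^2 / (8 * mu * L)
  expect_equal(max(sqrt(rowSums(ff$u2^2))), umax_exact, tolerance = 1e-6)
})

test_that("squeeze film matches lubrication theory within 10%", {
  L <- 10; H <- 1; hdot <- 1; mu <- 1.5e-3
  cf <- channel_fixture(L, H, 0.12)
  vel <- matrix(0, cf$nb, 2)
  vel[cf$top, 2] <- -hdot
  ff <- solve_frame(cf$mesh, boundary_spec(vel, cf$sides_open),
                    fluid_properties(mu))
  g <- wall_shear_rate(ff)
  x <- cf$bxy[cf$bottom, 1] - L / 2
  sel <- abs(x) > 0.05 * L & abs(x) < 0.4 * L  # away from centre and ends
  lub <- 6 * hdot * abs(x[sel]) / H^2           # shear rate, tau / mu
  expect_lt(max(abs(abs(g[cf$bottom][sel]) - lub) / lub), 0.10)
  expect_lt(mass_balance(ff), 0.02)
})

test_that("rigid translation of a sealed cavity has co-moving fluid", {
  cf <- channel_fixture(2, 1, 0.1)
  vel <- matrix(rep(c(5, 3), each = cf$nb), cf$nb, 2)
  ff <- solve_frame(cf$mesh, boundary_spec(vel))
  expect_lt(max(abs(wall_shear_rate(ff)), na.rm = TRUE), 1e-9)
})

test_that("sealed cavities with incompatible wall flux are rejected", {
  cf <- channel_fixture(2, 1, 0.1)
  vel <- matrix(0, cf$nb, 2)
  vel[cf$top, 2] <- -1   # compressing with no outlet
  expect_error(solve_frame(cf$mesh, boundary_spec(vel)), "flux")
})

test_that("pressure-driven annular flow shears the inner wall harder", {
  R1 <- 10; R2 <- 20; Theta <- pi / 2; mu <- 1.5e-3; P0 <- 1e-3
  ax <- annulus_fixture(R1, R2, Theta, 0.5)
  pref <- rep(0, ax$nb)
  pref[ax$end0] <- P0
  ff <- solve_frame(ax$mesh,
                    boundary_spec(matrix(0, ax$nb, 2), c(ax$end0, ax$end1),
                                  p_ref = pref),
                    fluid_properties(mu))
  g <- wall_shear_rate(ff)
  fem <- c(inner = mean(abs(g[ax$inner])), outer = mean(abs(g[ax$outer])))
  exact <- annulus_exact_shear(R1, R2, -P0 / Theta, mu)
  expect_gt(fem["inner"], fem["outer"])
  expect_equal(unname(fem), unname(exact), tolerance = 0.03)
})

test_that("Stokes linearity: doubled wall velocities double the shear", {
  mb <- cached("mb1", generate_ventricle(seed = 1))
  f <- 5
  m <- cached("mesh_f5", mesh_domain(mb$frames[[f]], 1.2))
  vel <- wall_velocities(mb, f)
  bc1 <- boundary_spec(vel, open = mb$openings$inlet)
  bc2 <- boundary_spec(2 * vel, open = mb$openings$inlet)
  g1 <- wall_shear_rate(solve_frame(m, bc1))
  g2 <- wall_shear_rate(solve_frame(m, bc2))
  scale <- max(abs(g1), na.rm = TRUE)
  expect_lt(max(abs(g2 - 2 * g1) / scale, na.rm = TRUE), 1e-9)
})

test_that("superposition: translation + deformation shear adds up", {
  mb <- cached("mb1", generate_ventricle(seed = 1))
  f <- 5
  m <- cached("mesh_f5", mesh_domain(mb$frames[[f]], 1.2))
  vel <- wall_velocities(mb, f)
  vmean <- colMeans(vel)
  vel_t <- matrix(rep(vmean, each = nrow(vel)), ncol = 2)
  vel_d <- vel - vel_t
  op <- mb$openings$inlet
  g_full <- wall_shear_rate(solve_frame(m, boundary_spec(vel, op)))
  g_t <- wall_shear_rate(solve_frame(m, boundary_spec(vel_t, op)))
  g_d <- wall_shear_rate(solve_frame(m, boundary_spec(vel_d, op)))
  scale <- max(abs(g_full), na.rm = TRUE)
  expect_lt(max(abs(g_full - (g_t + g_d)) / scale, na.rm = TRUE), 1e-9)
})

test_that("viscosity does not change the shear-rate field of a frame", {
  mb <- cached("mb1", generate_ventricle(seed = 1))
  f <- 5
  m <- cached("mesh_f5", mesh_domain(mb$frames[[f]], 1.2))
  bc <- boundary_spec(wall_velocities(mb, f), open = mb$openings$inlet)
  g_p <- wall_shear_rate(solve_frame(m, bc, fluid_properties("plasma")))
  g_b <- wall_shear_rate(solve_frame(m, bc, fluid_properties("blood")))
  expect_lt(max(abs(g_p - g_b), na.rm = TRUE) / max(abs(g_p), na.rm = TRUE),
            1e-9)
})

test_that("Schur and direct LU solves agree", {
  cf <- channel_fixture(2, 1, 0.15)
  vel <- matrix(0, cf$nb, 2)
  vel[cf$top, 1] <- 3
  vel[cf$top, 2] <- -0.5
  bc <- boundary_spec(vel, cf$sides_open)
  f1 <- solve_frame(cf$mesh, bc, method = "schur")
  f2 <- solve_frame(cf$mesh, bc, method = "lu")
  expect_lt(max(abs(f1$u2 - f2$u2)) / max(abs(f2$u2)), 1e-8)
  expect_lt(max(abs(f1$p - f2$p)) / max(abs(f2$p)), 1e-6)
})

test_that("wall shear extraction rejects off-boundary nodes", {
  cf <- channel_fixture(1, 1, 0.2)
  ff <- solve_frame(cf$mesh, boundary_spec(matrix(0, cf$nb, 2)))
  expect_error(wall_shear_rate(ff, nodes = nrow(cf$mesh$xy)), "boundary")
})
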