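test_that("generated ventricle area tracks the volume waveform", {
  mb <- generate_ventricle(seed = 3)
  a <- enclosed_area(mb)                       # shoelace oracle
  expect_lt(max(abs(a - mb$meta$a_target) / mb$meta$a_target), 0.01)
  # waveform shape carries through: max at phase 0, min at end systole
  expect_equal(which.max(a), 1L)
  expect_equal(unname(phase_frames(mb)["ES"]),
               which.min(mb$meta$w))
})

test_that("nominal groove dimensions are realized at end systole", {
  p <- geometry_params(inner_diameter = 50,
                       groove_long = c(12.5, 0),
                       groove_radial = c(8.7, 0),
                       groove_circ = c(21.7, 0),
                       n_grooves = 4)
  mb <- generate_ventricle(p, motion_model(), seed = 1)
  expect_equal(nrow(mb$meta$dims), 4L)
  expect_equal(mb$meta$dims$radial, rep(8.7, 4))
  expect_equal(mb$meta$dims$circ, rep(21.7, 4))
  es <- unname(phase_frames(mb)["ES"])
  # measure realized depth of each groove at the end-systolic frame:
  # radius at pocket centre minus envelope radius there
  fr <- sweep(mb$frames[[es]], 2, mb$meta$translation[es, ])
  th <- atan2(fr[, 2], fr[, 1])
  r <- sqrt(rowSums(fr^2))
  env <- mb$meta$lambda[es] * mb$meta$R0 * (1 + mb$meta$ecc * cos(th))
  for (k in 1:4) {
    sel <- abs(trabflow:::wrap_angle(th - mb$meta$groove_center[k])) <
      0.1 * mb$meta$groove_halfwidth[k]
    expect_lt(abs(max(r[sel] - env[sel]) - 8.7), 0.15)
  }
  # realized mouth width ~ circumferential dimension
  for (k in 1:4) {
    wk <- 2 * mb$meta$groove_halfwidth[k] *
      mb$meta$R0 * (1 + mb$meta$ecc * cos(mb$meta$groove_center[k]))
    expect_lt(abs(wk - 21.7) / 21.7, 0.05)
  }
})

test_that("infeasible groove packing is rejected with a diagnostic", {
  p <- geometry_params(inner_diameter = 30, n_grooves = 8,
                       groove_circ = c(21.7, 0))
  expect_error(generate_ventricle(p, seed = 1), "infeasible groove packing")
})

test_that("generation is seed-deterministic, bit for bit", {
  a <- generate_ventricle(seed = 7)
  b <- generate_ventricle(seed = 7)
  expect_identical(a$frames, b$frames)
  expect_identical(a$labels, b$labels)
  d <- generate_ventricle(seed = 8)
  expect_false(identical(a$frames[[1]], d$frames[[1]]))
})

test_that("groove sampling reproduces the measured distributions", {
  dims <- do.call(rbind, lapply(1:150, function(s) {
    generate_groove(seed = s)$meta$dims
  }))
  means <- c(12.5, 8.7, 21.7)
  sds <- c(3.1, 0.8, 10.7)
  for (j in 1:3) {
    col <- dims[[c("long", "radial", "circ")[j]]]
    sem <- sds[j] / sqrt(length(col))
    # truncation at 2 sd shrinks the realized spread slightly (~12%)
    expect_lt(abs(mean(col) - means[j]), 2 * sem + 0.05 * sds[j])
    expect_lt(abs(sd(col) - sds[j]) / sds[j], 0.30)
  }
})

test_that("grooves lie on the outer curvature only, beyond the ridge envelope", {
  mb <- generate_ventricle(seed = 5)
  es <- unname(phase_frames(mb)["ES"])
  fr <- sweep(mb$frames[[es]], 2, mb$meta$translation[es, ])
  th <- atan2(fr[, 2], fr[, 1])
  r <- sqrt(rowSums(fr^2))
  env <- mb$meta$lambda[es] * mb$meta$R0 * (1 + mb$meta$ecc * cos(th))
  gro <- mb$labels == "groove"
  expect_true(any(gro))
  expect_true(all(r[gro] > env[gro]))           # strictly beyond ridge crests
  expect_true(all(abs(th[gro]) < 1.8))          # outer-curvature arc only
  expect_true(all(abs(th[mb$labels %in% c("inlet", "outlet")]) > 1.9))
})

test_that("generated rigid rotation stays below the 0.07 rad bound", {
  expect_lt(max(abs(rigid_rotation(generate_ventricle(seed = 2)))), 0.07)
  expect_lt(max(abs(rigid_rotation(generate_groove(seed = 2)))), 0.07)
})

test_that("motion decomposition recomposes exactly and handles edge cases", {
  g <- generate_groove(seed = 4)
  dm <- decompose_motion(g)
  for (f in c(2, 9, 17)) {
    recomp <- dm$translation_only$frames[[f]] +
      (dm$deformation_only$frames[[f]] - g$frames[[1]])
    expect_lt(max(abs(recomp - g$frames[[f]])) / max(abs(g$frames[[f]])), 1e-9)
  }
  expect_lt(dm$max_rotation, 0.07)
  # pure rigid translation: deformation-only frames are all identical
  rigid <- generate_groove(motion = motion_model(squeeze_amplitude = 0,
                                                 groove_width_gain = 0),
                           seed = 1)
  dmr <- decompose_motion(rigid)
  for (f in seq_along(rigid$frames)) {
    expect_lt(max(abs(dmr$deformation_only$frames[[f]] -
                        dmr$deformation_only$frames[[1]])), 1e-9)
  }
  # centroid-stationary squeezing (pulsating circle): translation all zero
  nf <- 16
  ang <- seq(0, 2 * pi, length.out = 41)[-41]
  frames <- lapply(seq_len(nf) - 1, function(f) {
    r <- 10 + 2 * sin(2 * pi * f / nf)
    cbind(r * cos(ang), r * sin(ang))
  })
  circ <- trabflow:::new_moving_boundary(
    frames, labels = rep("ridge", 40), rings = list(wall = 1:40),
    openings = list(), times = (seq_len(nf) - 1) / nf * 0.25,
    cycle_duration = 0.25, kind = "groove")
  dms <- decompose_motion(circ)
  expect_lt(max(abs(c(dms$translation$tx, dms$translation$ty))), 1e-10)
})

test_that("wall velocities follow the central-difference definition", {
  g <- generate_groove(motion = motion_model(squeeze_amplitude = 0,
                                             translation_amplitude = c(0, 0),
                                             groove_width_gain = 0),
                       seed = 1)
  expect_equal(max(abs(wall_velocities(g, 3))), 0)
  # node on x(t) = A sin(2 pi t / T): central difference equals the
  # discrete derivative (A / dt) sin(2 pi dt / T)
  nf <- 25; T <- 0.25; A <- 2
  frames <- lapply(seq_len(nf) - 1, function(f) {
    cbind(c(0, 1, 1, 0) + A * sin(2 * pi * f / nf), c(0, 0, 1, 1))
  })
  mb <- trabflow:::new_moving_boundary(
    frames, labels = rep("ridge", 4), rings = list(wall = 1:4),
    openings = list(), times = (seq_len(nf) - 1) / nf * T,
    cycle_duration = T, kind = "groove")
  v <- wall_velocities(mb, 1)
  dt <- T / nf
  expect_equal(v[1, 1], A * sin(2 * pi / nf) / dt, tolerance = 1e-12)
  expect_equal(v[1, 1], 2 * pi * A / T, tolerance = 0.05)
})

test_that("boundary normal velocities satisfy the transport identity", {
  mb <- generate_ventricle(seed = 1)
  dadt_geom <- trabflow:::area_rate(mb)
  for (f in c(3, 8, 14, 21)) {
    xy <- mb$frames[[f]]
    v <- wall_velocities(mb, f)
    nxt <- rbind(xy[-1, ], xy[1, ])
    vn <- rbind(v[-1, ], v[1, ])
    ds <- nxt - xy
    # outward normal x edge length for a CCW ring: (dy, -dx)
    flux <- sum(((v + vn) / 2)[, 1] * ds[, 2] - ((v + vn) / 2)[, 2] * ds[, 1])
    expect_lt(abs(flux - dadt_geom[f]) / max(abs(dadt_geom)), 0.02)
  }
})

test_that("smooth counterpart removes pockets and preserves pumping", {
  mb <- generate_ventricle(seed = 6)
  sm <- smooth_counterpart(mb)
  expect_equal(n_nodes(sm), n_nodes(mb))
  expect_lt(max(abs(enclosed_area(sm) - enclosed_area(mb)) /
                  enclosed_area(mb)), 0.02)
  expect_lt(abs(stroke_volume(sm) - stroke_volume(mb)) / stroke_volume(mb),
            0.02)
  # no curvature sign alternation on the outer arc: radial profile about the
  # centroid is smooth, its second circular difference has no pocket-scale
  # oscillation
  es <- unname(phase_frames(sm)["ES"])
  fr <- sweep(sm$frames[[es]], 2, trabflow:::ring_centroid(sm$frames[[es]]))
  th <- atan2(fr[, 2], fr[, 1])
  r <- sqrt(rowSums(fr^2))
  o <- order(th)
  outer <- which(abs(th[o]) < 1.7)
  d2 <- diff(diff(r[o][outer]))
  expect_lt(max(abs(d2)), 0.02)   # um; pockets would give ~0.5
  # idempotence: a grooveless ventricle is returned unchanged
  mb0 <- generate_ventricle(geometry_params(n_grooves = 0), seed = 1)
  expect_identical(smooth_counterpart(mb0), mb0)
  # degenerate case: zero grooves equals its own smooth counterpart
  expect_equal(mb0$frames, smooth_counterpart(mb0)$frames)
})

test_that("trapped cells ride the groove and are validated", {
  p <- geometry_params(groove_radial = c(8.7, 0), groove_circ = c(21.7, 0),
                       groove_long = c(12.5, 0))
  m <- motion_model(squeeze_amplitude = 0.05)
  g <- generate_groove(p, m, seed = 1)
  cell <- trapped_cell_spec(c(0, -4.3) + g$meta$translation[1, ], diameter = 7,
                            wobble_amplitude = 0.15)
  gc <- add_trapped_cells(g, cell, seed = 1)
  expect_equal(length(gc$rings), 2L)
  expect_true(all(gc$labels[gc$rings[[2]]] == "cell"))
  # an oversized cell cannot fit
  big <- trapped_cell_spec(c(0, -4.3), diameter = 20)
  expect_error(add_trapped_cells(g, big, seed = 1), "intersects|escapes")
  # zero wobble + rigid motion: cell displacement equals the rigid component
  rigid <- generate_groove(p, motion_model(squeeze_amplitude = 0,
                                           groove_width_gain = 0), seed = 1)
  c0 <- trapped_cell_spec(c(0, -4.3) + rigid$meta$translation[1, ],
                          diameter = 7, wobble_amplitude = 0)
  gr <- add_trapped_cells(rigid, c0, seed = 1)
  disp_cell <- gr$frames[[10]][gr$rings[[2]], ] - gr$frames[[1]][gr$rings[[2]], ]
  disp_wall <- rigid$meta$translation[10, ] - rigid$meta$translation[1, ]
  expect_equal(disp_cell[, 1], rep(disp_wall[1], nrow(disp_cell)),
               tolerance = 1e-12)
  expect_equal(disp_cell[, 2], rep(disp_wall[2], nrow(disp_cell)),
               tolerance = 1e-12)
})

test_that("isolated groove realizes its sampled depth at end systole", {
  p <- geometry_params(groove_radial = c(8.7, 0))
  g <- generate_groove(p, seed = 1)
  # the pocket is deepest at end systole of the cycle, i.e. at the minimum
  # of the chamber volume waveform (the pocket area itself is anti-phase)
  es <- which.min(g$meta$w)
  fr <- sweep(g$frames[[es]], 2, g$meta$translation[es, ])
  expect_lt(abs(-min(fr[, 2]) - 8.7), 0.05)
  # zero-amplitude motion: all frames identical
  g0 <- generate_groove(p, motion_model(squeeze_amplitude = 0,
                                        translation_amplitude = c(0, 0),
                                        groove_width_gain = 0), seed = 1)
  for (f in seq_along(g0$frames)) {
    expect_identical(g0$frames[[f]], g0$frames[[1]])
  }
  expect_error(generate_groove(p, opening_fraction = 1.5), "opening wider")
})

test_that("moving boundaries tidy and plot", {
  mb <- cached("mb1", generate_ventricle(seed = 1))
  df <- tidy(mb)
  expect_equal(nrow(df), n_nodes(mb) * length(mb$frames))
  expect_true(all(c("node", "frame", "phase", "x", "y", "label") %in% names(df)))
  expect_s3_class(autoplot(mb, frames = c(1, 11)), "ggplot")
})
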