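test_that("boundary nodes are kept verbatim and conform to the mesh", {
  b <- rect_boundary(1, 1, 0.1)
  m <- mesh_domain(b, 0.1)
  expect_equal(m$xy[seq_len(nrow(b)), ], b, ignore_attr = TRUE)
  on_edge <- abs(m$xy[seq_len(m$n_boundary), 1]) < 1e-12 |
    abs(m$xy[seq_len(m$n_boundary), 1] - 1) < 1e-12 |
    abs(m$xy[seq_len(m$n_boundary), 2]) < 1e-12 |
    abs(m$xy[seq_len(m$n_boundary), 2] - 1) < 1e-12
  expect_true(all(on_edge))
})

test_that("halving the resolution roughly quadruples the element count", {
  m1 <- mesh_domain(rect_boundary(1, 1, 0.1), 0.1)
  m2 <- mesh_domain(rect_boundary(1, 1, 0.05), 0.05)
  ratio <- nrow(m2$tri) / nrow(m1$tri)
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 5)
})

test_that("the default ventricle frames mesh with good element quality", {
  mb <- cached("mb1", generate_ventricle(seed = 1))
  for (f in c(1, unname(phase_frames(mb)["ES"]))) {
    q <- mesh_quality(mesh_domain(mb$frames[[f]], 1.0))
    expect_gt(q$min_angle_deg, 20)
    expect_gt(q$min_area, 0)
  }
})

test_that("meshing is deterministic and independent of the caller RNG", {
  b <- rect_boundary(1, 1, 0.1)
  set.seed(1); m1 <- mesh_domain(b, 0.1)
  set.seed(999); m2 <- mesh_domain(b, 0.1)
  expect_identical(m1$xy, m2$xy)
  expect_identical(m1$tri, m2$tri)
  # and the caller RNG stream is left untouched
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(mesh_domain(b, 0.1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("self-intersecting boundaries are rejected", {
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(mesh_domain(bowtie, 0.1), "self-intersecting")
})

test_that("holes (internal walls) are carved out of the triangulation", {
  b <- rect_boundary(4, 4, 0.25)
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  hole <- cbind(2 + 0.8 * cos(-ang), 2 + 0.8 * sin(-ang))
  m <- mesh_domain(b, 0.25, holes = list(hole))
  cx <- rowMeans(matrix(m$xy[m$tri, 1], ncol = 3))
  cy <- rowMeans(matrix(m$xy[m$tri, 2], ncol = 3))
  expect_true(all((cx - 2)^2 + (cy - 2)^2 > 0.8^2 * 0.95))
  expect_equal(length(m$rings), 2L)
})
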