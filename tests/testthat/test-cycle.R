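test_that("a motionless boundary yields an all-zero shear series", {
  g0 <- generate_groove(motion = motion_model(squeeze_amplitude = 0,
                                              translation_amplitude = c(0, 0),
                                              groove_width_gain = 0,
                                              n_frames = 8),
                        seed = 1)
  s <- solve_cycle(g0, resolution = 0.8)
  expect_lt(max(abs(s$gamma), na.rm = TRUE), 1e-10)
  expect_equal(dim(s$gamma), c(n_nodes(g0), 8L))
})

test_that("cycle solves audit quasi-steadiness and conserve mass", {
  s <- cached("groove_series_s0",
              solve_cycle(generate_groove(seed = 0), resolution = 0.7))
  expect_true(all(s$audit$quasi_steady_valid))
  expect_lt(max(s$audit$reynolds), 1)
  expect_lt(max(s$audit$womersley), 1)
  expect_lt(max(s$audit$mass_residual), 0.02)
  # opening nodes carry NA while open; wall nodes are complete series
  open_nodes <- s$openings$opening
  expect_true(all(is.na(s$gamma[open_nodes, ])))
  wall_nodes <- setdiff(seq_len(nrow(s$gamma)), open_nodes)
  expect_false(anyNA(s$gamma[wall_nodes, ]))
})

test_that("the ventricle schedule opens the inlet in diastole only", {
  mb <- cached("mb1", generate_ventricle(seed = 1))
  dadt <- trabflow:::area_rate(mb)
  expect_equal(trabflow:::default_open_segments(mb, dadt[3]),
               if (dadt[3] >= 0) "inlet" else "outlet")
  expect_equal(trabflow:::default_open_segments(mb, 5), "inlet")
  expect_equal(trabflow:::default_open_segments(mb, -5), "outlet")
})

test_that("tidy and autoplot work on shear series", {
  s <- cached("groove_series_s0",
              solve_cycle(generate_groove(seed = 0), resolution = 0.7))
  df <- tidy(s)
  expect_s3_class(df, "tbl_df")
  expect_equal(nrow(df), nrow(s$gamma) * ncol(s$gamma))
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
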