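test_that("geometry parameter invariants are enforced", {
  expect_s3_class(geometry_params(), "tf_geometry_params")
  expect_error(geometry_params(inner_diameter = 20), "30, 50")
  expect_error(geometry_params(groove_radial = c(25, 0)), "chamber radius")
  expect_error(geometry_params(n_grooves = -1), "n_grooves")
  expect_error(geometry_params(cell_diameter = 20), "cells must fit")
  expect_error(geometry_params(node_spacing = 0), "> 0")
})

test_that("motion model invariants are enforced", {
  expect_error(motion_model(n_frames = 4), "n_frames")
  expect_error(motion_model(max_rotation = 0.07), "0.07")
  expect_error(motion_model(squeeze_amplitude = 1), "squeeze_amplitude")
  expect_error(motion_model(ejection_fraction = 0), "ejection_fraction")
})

test_that("volume and translation waveforms are periodic and span [0, 1]", {
  m <- motion_model()
  w <- m$volume_waveform
  expect_equal(w(0), w(1))
  expect_equal(w(0), 1)                      # end diastole
  expect_equal(w(1 - m$phase_split), 0)      # end systole
  phases <- seq(0, 1, by = 1 / 400)
  expect_true(all(w(phases) >= 0 & w(phases) <= 1))
  expect_equal(m$translation_waveform(0), m$translation_waveform(1))
  # two filling transients: early filling then a distinct late-diastolic bump
  dia <- w(seq(1 - m$phase_split, 1, length.out = 200))
  rate <- diff(dia)
  expect_gt(max(rate[1:80]), 0)    # early filling
  expect_gt(max(rate[145:199]), 0) # atrial kick after the diastasis plateau
  expect_lt(max(abs(rate[105:135])), max(rate[145:199]) / 10)  # plateau
})

test_that("truncated Gaussian sampling stays within two sd", {
  set.seed(42)
  x <- trabflow:::sample_truncnorm(2000, 21.7, 10.7)
  expect_true(all(abs(x - 21.7) <= 2 * 10.7))
  expect_equal(trabflow:::sample_truncnorm(5, 3, 0), rep(3, 5))
})
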