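# small helper: wrap a plain matrix of signed stress values as a WSS object
as_wss <- function(m) structure(list(tau = m), class = "tf_wss")

test_that("WSS is viscosity times shear rate, with the 4.9 blood/plasma ratio", {
  series <- structure(list(gamma = matrix(c(0, 100, -40), 1),
                           fluid = fluid_properties("plasma"),
                           labels = "ridge", times = c(0, 0.1, 0.2),
                           cycle_duration = 0.3,
                           weights = matrix(1, 1, 3)),
                      class = "tf_wss_series")
  wp <- wss(series, 1.5e-3)
  expect_equal(wp$tau[1, ], c(0, 0.15, -0.06))
  wb <- wss(series, 7.35e-3)
  expect_equal(wb$tau[1, 2] / wp$tau[1, 2], 4.9)
  expect_error(wss(series, -1), "> 0")
})

test_that("mixed-viscosity WSS equals node-wise selection of two solves", {
  set.seed(3)
  gamma <- matrix(rnorm(40), 8, 5)
  series <- structure(list(gamma = gamma,
                           fluid = fluid_properties("plasma"),
                           labels = rep("ridge", 8), times = 1:5,
                           cycle_duration = 5, weights = matrix(1, 8, 5)),
                      class = "tf_wss_series")
  mask <- c("groove", "groove", "ridge", "ridge", "excluded", "cell",
            "ridge", "groove")
  mixed <- mixed_viscosity_wss(series, mask)
  plasma <- wss(series, 1.5e-3)
  blood <- wss(series, 7.35e-3)
  pick_plasma <- mask %in% c("groove", "cell")
  expect_equal(mixed$tau[pick_plasma, ], plasma$tau[pick_plasma, ])
  expect_equal(mixed$tau[!pick_plasma, ], blood$tau[!pick_plasma, ])
  # degenerate masks: all plasma / all blood
  expect_equal(mixed_viscosity_wss(series, rep("groove", 8))$tau, plasma$tau)
  expect_equal(mixed_viscosity_wss(series, rep("ridge", 8))$tau, blood$tau)
  expect_error(mixed_viscosity_wss(series, rep("what", 8)), "unlabelled")
  # equal shear rate on a ridge and a groove node: WSS ratio 4.9
  series$gamma[3, ] <- series$gamma[1, ]
  m2 <- mixed_viscosity_wss(series, mask)
  expect_equal(m2$tau[3, ] / m2$tau[1, ], rep(4.9, 5))
})

test_that("TAWSS closed forms and quadrature", {
  expect_equal(tawss(as_wss(matrix(3, 2, 10))), c(3, 3))
  n <- 2000
  s <- matrix(sin(2 * pi * (0:(n - 1)) / n), 1)
  expect_equal(tawss(as_wss(s)), 2 / pi, tolerance = 1e-5)
  # equals an independent quadrature oracle at identical sampling
  set.seed(1)
  y <- rnorm(64)
  oracle <- mean(abs(y))  # periodic uniform trapezoid == plain mean
  expect_equal(tawss(as_wss(matrix(y, 1))), oracle, tolerance = 1e-12)
  expect_error(tawss(as_wss(matrix(1, 2, 1))), "frames")
})

test_that("OSI closed forms, range and scale invariance", {
  n <- 400
  t <- (0:(n - 1)) / n
  expect_equal(osi(as_wss(matrix(1 + 0 * t, 1))), 0)          # unidirectional
  expect_equal(osi(as_wss(matrix(sin(2 * pi * t), 1))), 0.5)  # zero mean
  sq <- matrix(c(rep(1, 300), rep(-1, 100)), 1)               # 3:1 square
  expect_equal(osi(as_wss(sq)), 0.25)
  expect_equal(osi(as_wss(matrix(0, 3, 8))), rep(0, 3))       # degenerate
  set.seed(2)
  m <- matrix(rnorm(50), 5)
  expect_true(all(osi(as_wss(m)) >= 0 & osi(as_wss(m)) <= 0.5))
  expect_equal(osi(as_wss(m)), osi(as_wss(4.9 * m)))          # scale invariant
})

test_that("ridge/groove classification recovers the ground truth", {
  mb <- cached("mb1", generate_ventricle(seed = 1))
  mask <- classify_ridge_groove(mb)
  truth <- mb$labels
  recovered <- mean(mask[truth == "groove"] == "groove")
  expect_gte(recovered, 0.9)
  # the automated surrogate dilates slightly onto the pocket shoulders,
  # but never labels more than a sliver of true ridge as groove
  expect_lt(mean(mask[truth == "ridge"] == "groove"), 0.15)
  expect_true(all(mask[truth %in% c("inlet", "outlet")] == "excluded"))
  # smooth convex boundary: no groove nodes
  sm <- smooth_counterpart(mb)
  expect_false(any(classify_ridge_groove(sm) == "groove"))
  # manual masks pass through verbatim; bad threshold rejected
  manual <- sample(c("ridge", "groove"), n_nodes(mb), replace = TRUE)
  expect_identical(classify_ridge_groove(mb, method = "manual",
                                         mask = manual), manual)
  expect_error(classify_ridge_groove(mb, threshold = 0), "threshold")
})

test_that("region averages are boundary-length weighted", {
  expect_equal(unname(region_average(c(2, 2, 9), rep("a", 3), "a")[1:2]),
               c(13 / 3, sd(c(2, 2, 9)) * sqrt(2 / 3)))
  # two equal segments with values 1 and 3 average to 2
  expect_equal(unname(region_average(c(1, 3), c("a", "a"), "a",
                                     weights = c(1, 1))[["mean"]]), 2)
  # agreement with an explicit weighted-sum oracle
  set.seed(4)
  x <- rnorm(30); w <- runif(30); mask <- rep(c("r", "g"), 15)
  got <- region_average(x, mask, "g", w)
  sel <- mask == "g"
  m0 <- sum(w[sel] * x[sel]) / sum(w[sel])
  expect_equal(got[["mean"]], m0, tolerance = 1e-12)
  expect_equal(got[["sd"]],
               sqrt(sum(w[sel] * (x[sel] - m0)^2) / sum(w[sel])),
               tolerance = 1e-12)
  expect_error(region_average(x, mask, "absent"), "empty")
})

test_that("area strain identities hold on extruded surfaces", {
  g <- generate_groove(seed = 2)
  s_ed <- extrude_boundary(g, 1)
  s_es <- extrude_boundary(g, which.min(g$meta$w))
  # identical surfaces: zero strain
  zero <- area_strain(s_ed, s_ed)
  expect_equal(max(abs(zero$strain)), 0)
  # uniform scaling by s: strain = s^2 - 1 on every element
  scaled <- s_ed
  scaled$vertices <- 1.1 * s_ed$vertices
  st <- area_strain(s_ed, scaled)
  expect_equal(st$strain, rep(1.1^2 - 1, length(st$strain)), tolerance = 1e-12)
  # rigid motion of either surface leaves the strain untouched
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  moved <- s_es
  moved$vertices <- s_es$vertices %*% t(R) +
    matrix(c(5, -3, 2), nrow(s_es$vertices), 3, byrow = TRUE)
  expect_equal(area_strain(s_ed, moved)$mean_abs_strain,
               area_strain(s_ed, s_es)$mean_abs_strain, tolerance = 1e-12)
  # mismatched connectivity is rejected
  bad <- s_es
  bad$faces <- bad$faces[-1, ]
  expect_error(area_strain(s_ed, bad), "element counts")
})

test_that("relative difference reproduces the printed comparisons", {
  expect_equal(relative_difference(0.124, 0.147, "second"), 16)
  expect_equal(relative_difference(0.124, 0.147, "second", digits = 1), 15.6)
  expect_equal(relative_difference(5, 5, "first"), 0)
  expect_equal(relative_difference(1, 3, "mean"), 100)
  expect_error(relative_difference(1, 0, "second"), "zero denominator")
})
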