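test_that("reference model grid reproduces the study geometries", {
  models <- make_reference_models()
  expect_length(models, 8)
  expect_identical(names(models), c("Normal", "A", "B", "C", "D", "E", "F", "G"))
  expect_false(any(duplicated(names(models))))

  ops <- vapply(models, function(m) m$va$width_operculum, numeric(1))
  mid <- vapply(models, function(m) m$va$width_midpoint, numeric(1))
  expect_equal(unname(ops), c(1.2, 3.6, 3.4, 3.2, 3.7, 3.6, 4.6, 4.3))
  expect_equal(unname(mid), c(0.8, 2.2, 2.2, 2.25, 2.3, 2.4, 2.8, 3.3))
  expect_equal(models$G$va$width_midpoint, 3.3)
  expect_equal(models$G$va$width_operculum, 4.3)
  expect_equal(models$Normal$va$width_midpoint, 0.8)

  # midpoint never wider than the operculum on this grid
  expect_true(all(mid <= ops))
  # only the VA differs between models
  for (m in models) {
    expect_identical(m$membrane, models$Normal$membrane)
    expect_identical(m$cavity_volume, models$Normal$cavity_volume)
    expect_equal(m$va$length, 8.7)
  }
})

test_that("ellipse derivation from area and perimeter round-trips", {
  # unit circle
  expect_equal(unname(derive_membrane_ellipse(pi, 2 * pi)), c(1, 1),
               tolerance = 1e-10)
  # equal-area circle of the membrane: perimeter 2*pi*sqrt(A/pi) = 5.0516...
  r_eq <- sqrt(2.031 / pi)
  ax <- derive_membrane_ellipse(2.031, 2 * pi * r_eq)
  expect_equal(unname(ax), c(r_eq, r_eq), tolerance = 1e-3)

  # the printed (area, perimeter) pair demands an eccentric ellipse
  ax <- derive_membrane_ellipse(2.031, 5.131)
  expect_gt(ax[["a"]], r_eq)
  expect_lt(ax[["b"]], r_eq)
  expect_equal(pi * ax[["a"]] * ax[["b"]], 2.031, tolerance = 1e-3 * 2.031)
  per <- pi * (3 * (ax[["a"]] + ax[["b"]]) -
                 sqrt((3 * ax[["a"]] + ax[["b"]]) * (ax[["a"]] + 3 * ax[["b"]])))
  expect_equal(per, 5.131, tolerance = 1e-5 * 5.131)

  # a perimeter below the equal-area circle circumference is infeasible
  expect_error(derive_membrane_ellipse(2.031, 4.5), "infeasible")
})

test_that("membrane spec holds its invariants", {
  ms <- membrane_spec()
  expect_equal(pi * ms$semi_axes[["a"]] * ms$semi_axes[["b"]], ms$area,
               tolerance = 1e-3 * ms$area)
  per <- pi * (3 * sum(ms$semi_axes) -
                 sqrt((3 * ms$semi_axes[["a"]] + ms$semi_axes[["b"]]) *
                        (ms$semi_axes[["a"]] + 3 * ms$semi_axes[["b"]])))
  expect_equal(per, ms$perimeter, tolerance = 5e-3 * ms$perimeter)
  expect_gt(ms$thickness, 0)
  expect_true(ms$poisson_ratio > 0 && ms$poisson_ratio < 0.5)

  # circle mode misses the printed perimeter slightly (that is the point of
  # the ellipse mode)
  mc <- membrane_spec(shape = "circle")
  expect_equal(mc$semi_axes[["a"]], mc$semi_axes[["b"]])

  expect_error(membrane_spec(area = -1), "positive")
  expect_error(membrane_spec(poisson_ratio = 0.7), "poisson")
  expect_warning(membrane_spec(thickness = 60e-9), "unit slip")
})

test_that("va_channel validates its inputs and tapers piecewise-linearly", {
  expect_error(va_channel(4.3, 3.3, length = -1), "length")
  expect_error(va_channel(-1, 3.3), "widths")
  va <- va_channel(width_operculum = 4.3, width_midpoint = 3.3, length = 8.7)
  expect_equal(va_width_at(va, 0), 3.3)            # inner opening = midpoint
  expect_equal(va_width_at(va, 8.7 / 2), 3.3)      # midpoint
  expect_equal(va_width_at(va, 8.7), 4.3)          # operculum
  expect_equal(va_width_at(va, 8.7 * 0.75), 3.8)   # halfway up the taper
})

test_that("Cincinnati classification uses strict thresholds", {
  expect_equal(classify_lva(2.2, 3.6), "LVA")
  expect_equal(classify_lva(0.8, 1.2), "not-LVA")
  expect_equal(classify_lva(0.9, 1.9), "not-LVA")    # boundary is strict
  expect_equal(classify_lva(0.91, 1.0), "LVA")       # midpoint alone suffices
  expect_equal(classify_lva(0.5, 1.91), "LVA")       # operculum alone suffices
  expect_error(classify_lva(0, 1), "positive")
  expect_error(classify_lva(1, -2), "positive")

  # study composition: A-G enlarged, Normal not
  models <- make_reference_models()
  verdicts <- vapply(models, function(m)
    classify_lva(m$va$width_midpoint, m$va$width_operculum), character(1))
  expect_identical(unname(verdicts),
                   c("not-LVA", rep("LVA", 7)))
})
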