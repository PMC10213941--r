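test_that("Reynolds number matches the worked aqueduct example", {
  re <- reynolds_number(1000, 0.00547, 0.00086, 1e-3)
  expect_equal(re$value, 1000 * 0.00547 * 0.00086 / 1e-3)
  expect_equal(round(re$value), 5)
  expect_identical(re$regime, "laminar")
  # linear in velocity
  expect_equal(reynolds_number(1000, 2 * 0.00547, 0.00086, 1e-3)$value,
               2 * re$value)
  expect_identical(reynolds_number(1000, 3, 0.001, 1e-3)$regime, "turbulent")
  expect_error(reynolds_number(1000, 0, 0.001, 1e-3), "velocity")
  expect_equal(reynolds_number(1000, 0, 0.001, 1e-3,
                               allow_zero_velocity = TRUE)$value, 0)
  expect_error(reynolds_number(-1, 1, 0.001, 1e-3), "positive")
})

test_that("duct resistance and inertance follow the laminar-duct laws", {
  expect_equal(duct_resistance(1e-3, 8.7e-3, 4e-4),
               8 * 1e-3 * 8.7e-3 / (pi * (4e-4)^4))
  expect_equal(duct_resistance(1e-3, 8.7e-3, 4e-4), 8.65e8, tolerance = 1e-2)
  expect_equal(duct_resistance(1e-3, 8.7e-3, 2e-4),
               16 * duct_resistance(1e-3, 8.7e-3, 4e-4))
  expect_equal(duct_resistance(0, 8.7e-3, 4e-4), 0)
  expect_error(duct_resistance(1e-3, 8.7e-3, 0), "positive")

  expect_equal(duct_inertance(1000, 8.7e-3, 4e-4),
               1000 * 8.7e-3 / (pi * (4e-4)^2))
  expect_equal(duct_inertance(1000, 8.7e-3, 4e-4), 1.73e7, tolerance = 1e-2)
  expect_equal(duct_inertance(1000, 2 * 8.7e-3, 4e-4),
               2 * duct_inertance(1000, 8.7e-3, 4e-4))
  expect_equal(duct_inertance(0, 8.7e-3, 4e-4), 0)
  expect_error(duct_inertance(1000, 8.7e-3, 0), "positive")
})

test_that("half-sine load peaks at 6 ms and vanishes outside the pulse", {
  ld <- make_load(300e3)
  expect_equal(load_pressure(ld, 0.006), 300e3)
  expect_equal(load_pressure(ld, 0), 0)
  expect_equal(load_pressure(ld, 0.012), 0, tolerance = 1e-9)
  expect_equal(load_pressure(ld, 0.02), 0)
  expect_equal(load_pressure(ld, 0.003), 300e3 * sqrt(2) / 2)
  expect_error(make_load(1e4, t_peak = 0.004), "half-sine")
  asym <- make_load(1e4, t_peak = 0.004, allow_asymmetric = TRUE)
  expect_equal(load_pressure(asym, 0.004), 1e4)
  expect_equal(load_pressure(asym, 0.012), 0, tolerance = 1e-9)
  expect_error(make_load(-1), "non-negative")
  expect_error(make_load(1e4, duration = 0.03), "t_obs")
})

test_that("hydraulic assembly is positive, ordered by calibre, and guarded", {
  models <- make_reference_models()
  en <- assemble(models$Normal)
  eg <- assemble(models$G)
  for (el in list(en, eg)) {
    expect_true(all(is.finite(c(el$resistance, el$inertance, el$compliance))))
    expect_true(el$resistance > 0 && el$inertance > 0 && el$compliance > 0)
  }
  # wider aqueduct, lower impedance (quartic / quadratic laws)
  expect_lt(eg$resistance, en$resistance)
  expect_lt(eg$inertance, en$inertance)
  expect_equal(en$resistance / eg$resistance, (3.3 / 0.8)^4, tolerance = 1e-10)
  expect_error(assemble(models$Normal, alpha = 0), "alpha")
  # the compliance equals the analytic clamped-circle value
  a_eq <- sqrt(2.031 / pi) * 1e-3
  expect_equal(en$compliance,
               analytic_clamped_circle(1, a_eq, default_material)$compliance)
})

test_that("transient solver conserves volume and is step-size robust", {
  el <- assemble(make_reference_models()$Normal)
  sim <- simulate_transient(el, make_load(100e3), default_membrane)
  s <- sim$series
  # interface continuity in volume form: integral of q equals final V
  inflow <- sum(diff(s$t) * (head(s$q, -1) + tail(s$q, -1)) / 2)
  expect_lt(abs(inflow - s$V[nrow(s)]) / max(abs(s$V)), 1e-3)
  # halving dt moves the peak by far less than 0.1%
  sim2 <- simulate_transient(el, make_load(100e3), default_membrane, dt = 5e-6)
  expect_lt(abs(sim2$peaks$peak_deflection / sim$peaks$peak_deflection - 1),
            1e-3)
  # zero load: identically zero response
  z <- simulate_transient(el, make_load(0), default_membrane)
  expect_true(all(z$series$p_ie == 0))
  expect_true(all(z$series$w_max == 0))
  # linearity to near machine precision
  sa <- simulate_transient(el, make_load(150e3), default_membrane)
  sb <- simulate_transient(el, make_load(300e3), default_membrane)
  expect_lt(max(abs(sb$series$w_max - 2 * sa$series$w_max)) /
              max(sb$series$w_max), 1e-10)
  expect_error(simulate_transient(el, make_load(1e4), default_membrane,
                                  dt = 1e-3), "coarse")
})

test_that("step response settles on the static plate solution", {
  el <- assemble(make_reference_models()$Normal)
  sim <- simulate_transient(el, step_load(10e3, t_obs = 0.1), default_membrane)
  a_eq <- sqrt(default_membrane$area / pi) * 1e-3
  an <- analytic_clamped_circle(10e3, a_eq, default_material)
  s <- sim$series
  expect_lt(abs(s$p_ie[nrow(s)] / 10e3 - 1), 0.01)
  expect_lt(abs(s$w_max[nrow(s)] / an$w_max - 1), 0.01)
})

test_that("membrane load is driven by inner-ear pressure, not inlet pressure", {
  el <- assemble(make_reference_models()$Normal)
  sim <- simulate_transient(el, make_load(100e3), default_membrane)
  s <- sim$series
  expect_equal(s$w_max, s$p_ie * sim$w_unit)
  # early in the pulse P_in is large while P_ie still lags well behind
  k <- which.min(abs(s$t - 0.002))
  expect_lt(s$p_ie[k], 0.8 * s$p_in[k])
})

test_that("fem mode agrees with analytic mode at the few-percent level", {
  el <- assemble(make_reference_models()$A)
  sa <- simulate_transient(el, make_load(10e3), default_membrane,
                           mode = "analytic")
  sf <- simulate_transient(el, make_load(10e3), default_membrane, mode = "fem")
  # same hydraulics, slightly different membrane mapping (circle vs ellipse)
  expect_equal(sf$series$p_ie, sa$series$p_ie)
  expect_lt(abs(sf$peaks$peak_deflection / sa$peaks$peak_deflection - 1), 0.15)
})

test_that("peak metrics locate maxima and flag degenerate runs", {
  tri <- data.frame(t = (0:10) * 1e-3,
                    w_max = c(0:7, 6, 4, 2) * 1e-6)
  pk <- peak_metrics(tri, t_peak_load = 0.004)
  expect_equal(pk$t_peak_deflection, 0.007)
  expect_equal(pk$lag, 0.003)
  expect_identical(pk$flag, "ok")

  zero <- data.frame(t = (0:10) * 1e-3, w_max = numeric(11))
  pkz <- peak_metrics(zero)
  expect_identical(pkz$flag, "undefined")
  expect_true(is.na(pkz$lag))
  expect_equal(pkz$peak_deflection, 0)

  # monotone rise (short-window step): peak at the last sample, non-pulse
  el <- assemble(make_reference_models()$Normal)
  sim <- simulate_transient(el, step_load(10e3, t_obs = 0.002),
                            default_membrane, dt = 1e-5)
  pks <- peak_metrics(sim)
  expect_identical(pks$flag, "non-pulse")
  expect_equal(pks$t_peak_deflection, sim$series$t[nrow(sim$series)])
  expect_error(peak_metrics(data.frame(t = numeric(0), w_max = numeric(0))),
               "empty")
})
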