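# Reduced transient fluid-structure model: the inner-ear fluid balances
# collapse, for a laminar tapered duct feeding a closed incompressible cavity
# sealed by a compliant membrane, to a two-state hydraulic network
#
#   L_h dq/dt + R_tot q + V / C = P_in(t),    dV/dt = q,
#
# where q is the volume flow through the vestibular aqueduct, V the cumulative
# volume displaced into the cavity, C the membrane's volumetric compliance and
# P_ie = V / C the inner-ear pressure acting on the membrane (traction
# continuity at the fluid-solid interface; velocity continuity is the V-dot
# equation in volume form). Integration is implicit trapezoidal (A-stable),
# fixed step, seed-free.

#' Inner-ear fluid properties
#'
#' @param dynamic_viscosity Dynamic viscosity, Pa s (default 1e-3, water-like
#'   lymph).
#' @param density Density, kg/m^3 (default 1000).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(dynamic_viscosity = 1e-3, density = 1000) {
  if (dynamic_viscosity <= 0 || density <= 0)
    stop("fluid properties must be positive")
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: mu = %.3g Pa s, rho = %.0f kg/m^3\n",
              x$dynamic_viscosity, x$density))
  invisible(x)
}

#' Reynolds number and flow regime
#'
#' Re = rho v d / mu, with the flow tagged laminar when Re < 2000. The duct
#' flow in the aqueduct at physiological velocities gives Re of order 5,
#' firmly laminar, which justifies the Poiseuille reduction.
#'
#' @param density Fluid density, kg/m^3.
#' @param velocity Mean flow speed, m/s.
#' @param diameter Duct diameter, m.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param allow_zero_velocity If `TRUE`, `velocity = 0` yields Re = 0 instead
#'   of an error.
#' @return An object of class `reynolds_number`: list with `value` and
#'   `regime` (`"laminar"` or `"turbulent"`).
#' @examples
#' reynolds_number(1000, 0.00547, 0.00086, 1e-3)  # ~ 4.7, rounds to 5
#' @export
reynolds_number <- function(density, velocity, diameter, viscosity,
                            allow_zero_velocity = FALSE) {
  if (density <= 0 || diameter <= 0 || viscosity <= 0)
    stop("density, diameter and viscosity must be positive")
  if (velocity < 0 || (velocity == 0 && !allow_zero_velocity))
    stop("velocity must be positive (set allow_zero_velocity for Re = 0)")
  re <- density * velocity * diameter / viscosity
  structure(list(value = re,
                 regime = if (re < 2000) "laminar" else "turbulent"),
            class = "reynolds_number")
}

#' @export
print.reynolds_number <- function(x, ...) {
  cat(sprintf("Re = %.4g (%s)\n", x$value, x$regime))
  invisible(x)
}

#' Poiseuille resistance of a laminar duct
#'
#' R = 8 mu L / (pi r^4).
#'
#' @param viscosity Dynamic viscosity, Pa s (non-negative).
#' @param length Duct length, m.
#' @param radius Duct radius, m.
#' @return Resistance in Pa s/m^3.
#' @examples
#' duct_resistance(1e-3, 8.7e-3, 4e-4)  # ~ 8.65e8
#' @export
duct_resistance <- function(viscosity, length, radius) {
  if (length <= 0 || radius <= 0) stop("length and radius must be positive")
  if (viscosity < 0) stop("viscosity must be non-negative")
  8 * viscosity * length / (pi * radius^4)
}

#' Inertance of a fluid duct
#'
#' L_h = rho L / (pi r^2).
#'
#' @param density Fluid density, kg/m^3 (non-negative).
#' @param length Duct length, m.
#' @param radius Duct radius, m.
#' @return Inertance in kg/m^4.
#' @examples
#' duct_inertance(1000, 8.7e-3, 4e-4)  # ~ 1.73e7
#' @export
duct_inertance <- function(density, length, radius) {
  if (length <= 0 || radius <= 0) stop("length and radius must be positive")
  if (density < 0) stop("density must be non-negative")
  density * length / (pi * radius^2)
}

#' Half-sine inlet pressure pulse
#'
#' P_in(t) = p_max sin(pi t / duration) on [0, duration], zero afterwards.
#' The pulse peaks at t = duration / 2; the defaults (peak at 6 ms, 12 ms
#' pulse, 25 ms observation window) are the study's loading protocol for
#' cerebrospinal-fluid pressure transients.
#'
#' @param p_max Peak inlet pressure, Pa (>= 0).
#' @param t_peak Time of the pressure peak, s.
#' @param duration Pulse duration, s.
#' @param t_obs Observation window, s (>= duration).
#' @param allow_asymmetric If `TRUE`, `t_peak != duration / 2` selects a
#'   piecewise-sine pulse rising over `[0, t_peak]` and falling over
#'   `[t_peak, duration]`; otherwise such inputs are an error.
#' @return An object of class `load_waveform`.
#' @examples
#' load_pressure(make_load(300e3), 0.006)  # = 300 kPa at the peak
#' @export
make_load <- function(p_max, t_peak = 0.006, duration = 0.012,
                      t_obs = 0.025, allow_asymmetric = FALSE) {
  if (p_max < 0) stop("p_max must be non-negative")
  if (!(t_peak > 0 && t_peak < duration && duration <= t_obs))
    stop("need 0 < t_peak < duration <= t_obs")
  type <- "half-sine"
  if (abs(t_peak - duration / 2) > 1e-12 * duration) {
    if (!allow_asymmetric)
      stop(paste0("t_peak must equal duration/2 for a half-sine pulse; ",
                  "set allow_asymmetric = TRUE for a piecewise-sine pulse"))
    type <- "asymmetric-sine"
  }
  structure(list(type = type, p_max = p_max, t_peak = t_peak,
                 duration = duration, t_obs = t_obs),
            class = "load_waveform")
}

#' Constant (step) inlet pressure
#'
#' P_in(t) = p0 for t >= 0. Used to check the steady state of the coupled
#' solver against the static plate solution.
#'
#' @param p0 Held pressure, Pa.
#' @param t_obs Observation window, s.
#' @return An object of class `load_waveform`.
#' @export
step_load <- function(p0, t_obs = 0.05) {
  if (p0 < 0) stop("p0 must be non-negative")
  structure(list(type = "step", p_max = p0, t_peak = NA_real_,
                 duration = t_obs, t_obs = t_obs),
            class = "load_waveform")
}

#' Evaluate an inlet waveform
#'
#' @param load A [make_load()] or [step_load()] waveform.
#' @param t Time(s), s.
#' @return Inlet pressure(s) in Pa.
#' @export
load_pressure <- function(load, t) {
  stopifnot(inherits(load, "load_waveform"))
  switch(load$type,
    "half-sine" = ifelse(t >= 0 & t <= load$duration,
                         load$p_max * sin(pi * t / load$duration), 0),
    "asymmetric-sine" = {
      up <- load$p_max * sin(pi * t / (2 * load$t_peak))
      dn <- load$p_max *
        sin(pi / 2 * (load$duration - t) / (load$duration - load$t_peak))
      ifelse(t < 0 | t > load$duration, 0, ifelse(t <= load$t_peak, up, dn))
    },
    "step" = ifelse(t >= 0, load$p_max, 0))
}

#' @export
print.load_waveform <- function(x, ...) {
  cat(sprintf("%s load: p_max = %.4g Pa", x$type, x$p_max))
  if (!is.na(x$t_peak)) cat(sprintf(", peak at %.4g s", x$t_peak))
  cat(sprintf(", duration %.4g s, observed to %.4g s\n", x$duration, x$t_obs))
  invisible(x)
}

#' @export
plot.load_waveform <- function(x, n = 400, ...) {
  t <- seq(0, x$t_obs, length.out = n)
  graphics::plot(t * 1e3, load_pressure(x, t) / 1e3, type = "l",
                 xlab = "time (ms)", ylab = "inlet pressure (kPa)",
                 main = sprintf("%s inlet pulse", x$type), ...)
  invisible(x)
}

#' Lumped hydraulic elements
#'
#' Low-level constructor; [assemble()] derives the elements from an
#' [inner_ear_model()]. The added damping `zeta_add` (dimensionless damping
#' ratio of the duct-membrane mode) augments the Poiseuille resistance by
#' `2 * zeta_add * sqrt(L_h / C)` and stands in for the distributed viscous
#' losses a three-dimensional cavity has but a single lumped duct lacks.
#'
#' @param resistance Poiseuille duct resistance R, Pa s/m^3.
#' @param inertance Duct inertance L_h, kg/m^4.
#' @param compliance Membrane volumetric compliance C, m^3/Pa.
#' @param zeta_add Added damping ratio (>= 0).
#' @param radius Effective duct radius, m (kept for Reynolds reporting).
#' @param label Provenance label.
#' @return An object of class `hydraulic_elements`.
#' @export
hydraulic_elements <- function(resistance, inertance, compliance,
                               zeta_add = 0, radius = NA_real_,
                               label = "custom") {
  if (resistance < 0 || inertance <= 0 || compliance <= 0)
    stop("resistance must be >= 0; inertance and compliance must be positive")
  if (zeta_add < 0) stop("zeta_add must be non-negative")
  r_damp <- 2 * zeta_add * sqrt(inertance / compliance)
  structure(
    list(resistance = resistance, inertance = inertance,
         compliance = compliance, zeta_add = zeta_add, r_damp = r_damp,
         resistance_total = resistance + r_damp,
         radius = radius, label = label),
    class = "hydraulic_elements")
}

#' @export
print.hydraulic_elements <- function(x, ...) {
  omega0 <- 1 / sqrt(x$inertance * x$compliance)
  zeta <- x$resistance_total / 2 * sqrt(x$compliance / x$inertance)
  cat(sprintf("Hydraulic elements (%s)\n", x$label))
  cat(sprintf("  R = %.4g Pa s/m^3 (duct) + %.4g (added damping)\n",
              x$resistance, x$r_damp))
  cat(sprintf("  L_h = %.4g kg/m^4, C = %.4g m^3/Pa\n",
              x$inertance, x$compliance))
  cat(sprintf("  natural frequency %.1f Hz, total damping ratio %.3g\n",
              omega0 / (2 * pi), zeta))
  invisible(x)
}

#' Reduce an inner-ear model to hydraulic elements
#'
#' The VA becomes a Poiseuille resistance and inertance with effective radius
#' `alpha * width_midpoint / 2` (the midpoint calibre controls the hydraulic
#' bottleneck; `alpha` expresses how much of the bony lumen conducts, since CT
#' cannot separate the membranous duct from the bony channel). The membrane
#' becomes the analytic volumetric compliance of the clamped plate at the
#' circle-equivalent radius. All elements in SI units.
#'
#' @param model An [inner_ear_model()].
#' @param alpha Duct-narrowing factor in (0, 1]; default 1 (full bony lumen).
#' @param zeta_add Added damping ratio; default 1 (critically damped
#'   duct-membrane mode, representing the distributed losses of the full 3D
#'   cavity; see the package vignette).
#' @return An object of class `hydraulic_elements`.
#' @examples
#' assemble(make_reference_models()$Normal)
#' @export
assemble <- function(model, alpha = 1, zeta_add = 1) {
  stopifnot(inherits(model, "inner_ear_model"))
  if (is.null(model$membrane)) stop("model has no membrane specification")
  if (alpha <= 0) stop("alpha must be positive")
  r_eff <- alpha * (model$va$width_midpoint / 2) * 1e-3
  len <- model$va$length * 1e-3
  mu <- model$fluid$dynamic_viscosity
  rho <- model$fluid$density
  a_eq <- sqrt(model$membrane$area / pi) * 1e-3
  D <- flexural_rigidity(as_plate_material(model$membrane))
  hydraulic_elements(
    resistance = duct_resistance(mu, len, r_eff),
    inertance = duct_inertance(rho, len, r_eff),
    compliance = pi * a_eq^6 / (192 * D),
    zeta_add = zeta_add, radius = r_eff, label = model$label)
}

#' Transient coupled duct-membrane simulation
#'
#' Integrates the two-state hydraulic system from rest over `[0, t_obs]` with
#' a fixed-step implicit trapezoidal scheme (A-stable, deterministic). The
#' membrane load is the inner-ear pressure P_ie = V / C only, never the inlet
#' pressure directly (traction continuity); membrane deflection and stress
#' time series are obtained by scaling a per-unit-pressure membrane response:
#' closed-form clamped-circle expressions at the circle-equivalent radius in
#' `"analytic"` mode, or one discrete [solve_plate()] solve on the membrane
#' ellipse in `"fem"` mode (the system is linear, so one unit solve suffices).
#'
#' @param elements A [hydraulic_elements()] (see [assemble()]).
#' @param load A [make_load()] or [step_load()] waveform.
#' @param membrane A [membrane_spec()].
#' @param dt Time step, s; must not exceed `duration / 100`.
#' @param mode `"analytic"` or `"fem"` membrane response mapping.
#' @param mesh_size Element size (mm) of the `"fem"` membrane mesh.
#' @return An object of class `ie_simulation`: a `series` data.frame with
#'   columns `t` (s), `p_in`, `p_ie` (Pa), `q` (m^3/s), `V` (m^3), `w_max`
#'   (m), `sigma_max` (Pa), plus peak metrics (see [peak_metrics()]) and the
#'   configuration.
#' @examples
#' el <- assemble(make_reference_models()$G)
#' sim <- simulate_transient(el, make_load(10e3), membrane_spec())
#' sim
#' @export
simulate_transient <- function(elements, load, membrane = membrane_spec(),
                               dt = 1e-5, mode = c("analytic", "fem"),
                               mesh_size = 0.05) {
  stopifnot(inherits(elements, "hydraulic_elements"),
            inherits(load, "load_waveform"))
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be positive")
  if (dt > load$duration / 100)
    stop(sprintf("dt = %.3g s is too coarse: need dt <= duration/100 = %.3g s",
                 dt, load$duration / 100))
  R <- elements$resistance_total
  L <- elements$inertance
  C <- elements$compliance

  times <- seq(0, load$t_obs, by = dt)
  if (times[length(times)] < load$t_obs) times <- c(times, load$t_obs)
  n <- length(times)
  p_in <- load_pressure(load, times)

  A <- matrix(c(-R / L, 1, -1 / (C * L), 0), 2, 2)
  M1 <- diag(2) - dt / 2 * A
  M2 <- diag(2) + dt / 2 * A
  M1inv <- solve(M1)
  S <- M1inv %*% M2
  q <- numeric(n); V <- numeric(n)
  x <- c(0, 0)
  for (k in seq_len(n - 1)) {
    bsum <- (p_in[k] + p_in[k + 1]) / L
    x <- S %*% x + M1inv %*% c(dt / 2 * bsum, 0)
    q[k + 1] <- x[1]
    V[k + 1] <- x[2]
  }
  p_ie <- V / C

  # energy must not grow once the drive has ended (guards mis-sized steps)
  after <- times >= load$duration
  if (load$type != "step" && sum(after) > 2) {
    E <- L * q[after]^2 / 2 + V[after]^2 / (2 * C)
    if (max(E) > E[1] * (1 + 1e-3) + 1e-30)
      stop("unstable integration: energy grew after the pulse; reduce dt")
  }

  material <- as_plate_material(membrane)
  if (mode == "analytic") {
    a_eq <- sqrt(membrane$area / pi) * 1e-3
    unit <- analytic_clamped_circle(1, a_eq, material)
    w_unit <- unit$w_max
    s_unit <- unit$sigma_vm_edge
  } else {
    sol <- solve_plate(plate_mesh(membrane, mesh_size), 1, material)
    w_unit <- sol$max_deflection
    s_unit <- sol$max_stress
  }

  series <- data.frame(t = times, p_in = p_in, p_ie = p_ie, q = q, V = V,
                       w_max = p_ie * w_unit, sigma_max = p_ie * s_unit)
  out <- structure(
    list(series = series, elements = elements, load = load,
         membrane = membrane, dt = dt, mode = mode,
         w_unit = w_unit, sigma_unit = s_unit),
    class = "ie_simulation")
  out$peaks <- peak_metrics(out)
  out
}

#' Peak metrics of a coupled simulation
#'
#' Argmax over the sampled series: peak membrane deflection and stress, peak
#' inner-ear pressure, their times, and the lag of the deflection peak behind
#' the load peak. For an all-zero response the lag is `NA` with flag
#' `"undefined"`; when the response is still rising at the end of the window
#' (e.g. a step load) the flag is `"non-pulse"`.
#'
#' @param sim An [simulate_transient()] result, or a data.frame with columns
#'   `t` and `w_max` (optionally `sigma_max`, `p_ie`).
#' @param t_peak_load Load peak time, s; taken from the simulation's waveform
#'   when available.
#' @return An object of class `peak_metrics`: `peak_deflection` (m),
#'   `peak_stress` (Pa), `peak_pressure` (Pa), `t_peak_deflection` (s),
#'   `lag` (s) and `flag` (`"ok"`, `"undefined"` or `"non-pulse"`).
#' @export
peak_metrics <- function(sim, t_peak_load = NULL) {
  if (inherits(sim, "ie_simulation")) {
    series <- sim$series
    if (is.null(t_peak_load)) t_peak_load <- sim$load$t_peak
  } else if (is.data.frame(sim)) {
    series <- sim
  } else stop("sim must be an ie_simulation or a data.frame")
  if (nrow(series) == 0) stop("empty series")
  if (!all(c("t", "w_max") %in% names(series)))
    stop("series needs columns t and w_max")
  i <- which.max(series$w_max)
  peak_w <- series$w_max[i]
  flag <- "ok"
  lag <- NA_real_
  if (all(series$w_max == 0)) {
    flag <- "undefined"
  } else if (i == nrow(series)) {
    flag <- "non-pulse"
    lag <- NA_real_
  }
  t_peak_defl <- if (flag == "undefined") NA_real_ else series$t[i]
  if (flag == "ok" && !is.null(t_peak_load) && !is.na(t_peak_load))
    lag <- t_peak_defl - t_peak_load
  structure(
    list(peak_deflection = peak_w,
         peak_stress = if ("sigma_max" %in% names(series))
           max(series$sigma_max) else NA_real_,
         peak_pressure = if ("p_ie" %in% names(series))
           max(series$p_ie) else NA_real_,
         t_peak_deflection = t_peak_defl,
         lag = lag, flag = flag),
    class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat("Peak metrics\n")
  cat(sprintf("  peak deflection: %.4g m at t = %.4g s\n",
              x$peak_deflection, x$t_peak_deflection))
  cat(sprintf("  peak stress: %.4g Pa; peak inner-ear pressure: %.4g Pa\n",
              x$peak_stress, x$peak_pressure))
  cat(sprintf("  lag behind load peak: %s (flag: %s)\n",
              if (is.na(x$lag)) "NA" else sprintf("%.4g s", x$lag), x$flag))
  invisible(x)
}

#' @export
print.ie_simulation <- function(x, ...) {
  cat(sprintf("Coupled VA-membrane simulation (%s mode, dt = %.3g s)\n",
              x$mode, x$dt))
  print(x$load)
  print(x$elements)
  print(x$peaks)
  invisible(x)
}

#' @export
summary.ie_simulation <- function(object, ...) {
  pk <- object$peaks
  cat(sprintf("Model %s: peak deflection %.4g mm, peak von Mises %.4g MPa\n",
              object$elements$label, pk$peak_deflection * 1e3,
              pk$peak_stress / 1e6))
  cat(sprintf("  peak P_ie / peak P_in = %.4f; lag = %s\n",
              pk$peak_pressure / max(object$series$p_in),
              if (is.na(pk$lag)) "NA" else sprintf("%.2f ms", pk$lag * 1e3)))
  invisible(pk)
}

#' @export
plot.ie_simulation <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$t * 1e3, s$p_in / 1e3, type = "l", col = "grey40",
                 xlab = "time (ms)", ylab = "pressure (kPa)",
                 main = sprintf("model %s", x$elements$label), ...)
  graphics::lines(s$t * 1e3, s$p_ie / 1e3, col = "firebrick")
  graphics::legend("topright", c("inlet", "inner ear"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::plot(s$t * 1e3, s$w_max * 1e3, type = "l", col = "navy",
                 xlab = "time (ms)", ylab = "max deflection (mm)")
  invisible(x)
}

#' @export
as.data.frame.ie_simulation <- function(x, ...) x$series
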