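# Parametric inner-ear geometry: vestibular aqueduct (VA) channel, round-window
# membrane specification, and the reference model grid of normal and enlarged
# aqueducts. Lengths and widths are millimetres; membrane elastic constants and
# thickness are SI (Pa, m).

#' Parametric vestibular aqueduct channel
#'
#' Describes the VA as a tapered duct of circular cross-section: the width
#' (diameter) varies piecewise-linearly along the centerline from the inner
#' opening (at the vestibule) through the arc-length midpoint to the operculum
#' (the external aperture). The inner-opening width defaults to the midpoint
#' width, so the duct is cylindrical over its inner half and tapers (usually
#' widens) toward the operculum over its outer half.
#'
#' @param width_operculum Width (diameter) at the external aperture, mm.
#' @param width_midpoint Width at the arc-length midpoint, mm.
#' @param length Centerline length of the duct, mm. The adult average is
#'   8.7 mm, the default.
#' @param width_inner Width at the inner opening, mm; defaults to
#'   `width_midpoint`.
#' @return An object of class `va_channel`.
#' @examples
#' va_channel(width_operculum = 4.3, width_midpoint = 3.3)
#' @export
va_channel <- function(width_operculum, width_midpoint, length = 8.7,
                       width_inner = width_midpoint) {
  stopifnot(is.numeric(width_operculum), is.numeric(width_midpoint),
            is.numeric(length), is.numeric(width_inner))
  if (length <= 0) stop("VA length must be positive (mm)")
  if (width_operculum <= 0 || width_midpoint <= 0 || width_inner <= 0)
    stop("VA widths must be positive (mm)")
  structure(
    list(length = length,
         width_operculum = width_operculum,
         width_midpoint = width_midpoint,
         width_inner = width_inner),
    class = "va_channel")
}

#' @export
print.va_channel <- function(x, ...) {
  cat("Vestibular aqueduct channel\n")
  cat(sprintf("  length:          %.2f mm\n", x$length))
  cat(sprintf("  operculum width: %.2f mm\n", x$width_operculum))
  cat(sprintf("  midpoint width:  %.2f mm\n", x$width_midpoint))
  cat(sprintf("  inner width:     %.2f mm\n", x$width_inner))
  invisible(x)
}

#' Local VA width along the centerline
#'
#' Piecewise-linear taper: `width_inner` at arc length 0, `width_midpoint`
#' at `length/2`, `width_operculum` at `length`.
#'
#' @param va A [va_channel()].
#' @param s Arc length(s) from the inner opening, mm.
#' @return Width(s) in mm.
#' @export
va_width_at <- function(va, s) {
  stopifnot(inherits(va, "va_channel"))
  L <- va$length
  s <- pmin(pmax(s, 0), L)
  w <- ifelse(s <= L / 2,
              va$width_inner + (va$width_midpoint - va$width_inner) * s / (L / 2),
              va$width_midpoint +
                (va$width_operculum - va$width_midpoint) * (s - L / 2) / (L / 2))
  w
}

# Ramanujan's first approximation to the ellipse perimeter; exact for circles,
# relative error < 5e-5 over the eccentricities used here.
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Derive ellipse semi-axes from area and perimeter
#'
#' Finds the semi-axes (a >= b) of the ellipse whose area is `area` and whose
#' Ramanujan-approximate perimeter is `perimeter`. Used to turn the measured
#' round-window-membrane area and perimeter into a concrete planform. The
#' perimeter of an ellipse of fixed area is minimised by the circle, so a
#' solution exists iff `perimeter >= 2*sqrt(pi*area)`.
#'
#' @param area Ellipse area, mm^2.
#' @param perimeter Ellipse perimeter, mm.
#' @param tol Relative tolerance of the numeric solve.
#' @return Named numeric vector `c(a = , b = )` in mm, `a >= b`.
#' @examples
#' derive_membrane_ellipse(pi, 2 * pi)    # unit circle
#' derive_membrane_ellipse(2.031, 5.131)  # round-window membrane planform
#' @export
derive_membrane_ellipse <- function(area, perimeter, tol = 1e-10) {
  if (!is.numeric(area) || area <= 0) stop("area must be positive")
  p_circle <- 2 * sqrt(pi * area)
  if (perimeter < p_circle * (1 - 1e-12))
    stop(sprintf(paste0("infeasible: perimeter %.6g mm is below the ",
                        "equal-area circle circumference %.6g mm"),
                 perimeter, p_circle))
  if (perimeter <= p_circle * (1 + 1e-12)) {
    r <- sqrt(area / pi)
    return(c(a = r, b = r))
  }
  # parameterise by the aspect ratio m = a/b >= 1; perimeter is strictly
  # increasing in m at fixed area
  per_of_m <- function(m) {
    b <- sqrt(area / (pi * m))
    ellipse_perimeter(m * b, b) - perimeter
  }
  m_hi <- 2
  while (per_of_m(m_hi) < 0) m_hi <- m_hi * 2
  m <- stats::uniroot(per_of_m, c(1, m_hi), tol = tol)$root
  b <- sqrt(area / (pi * m))
  c(a = m * b, b = b)
}

#' Round-window membrane specification
#'
#' Planform (ellipse matching a measured area and perimeter, or the equal-area
#' circle) plus thin-plate material constants. The default area and perimeter
#' are the measured averages 2.031 mm^2 and 5.131 mm; the default elastic film
#' modulus is 3 MPa with Poisson ratio 0.3.
#'
#' The default thickness is 60 micrometres. Values below 1 micrometre trigger
#' a warning: a nanometre-scale membrane of this span would be mechanically
#' absurd (compliance inflated by ~1e9), and such inputs are almost certainly
#' unit slips.
#'
#' @param area Membrane area, mm^2.
#' @param perimeter Membrane perimeter, mm.
#' @param thickness Plate thickness, m.
#' @param youngs_modulus Young's modulus, Pa.
#' @param poisson_ratio Poisson ratio, in (0, 0.5).
#' @param shape `"ellipse"` (match both area and perimeter) or `"circle"`
#'   (equal-area circle; its perimeter then misses the measured one by ~1.6%).
#' @return An object of class `membrane_spec` with derived `semi_axes` (mm).
#' @examples
#' membrane_spec()
#' @export
membrane_spec <- function(area = 2.031, perimeter = 5.131,
                          thickness = 60e-6, youngs_modulus = 3e6,
                          poisson_ratio = 0.3,
                          shape = c("ellipse", "circle")) {
  shape <- match.arg(shape)
  if (area <= 0) stop("membrane area must be positive")
  if (thickness <= 0) stop("membrane thickness must be positive")
  if (youngs_modulus <= 0) stop("Young's modulus must be positive")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (0, 0.5)")
  if (thickness < 1e-6)
    warning(sprintf(paste0("membrane thickness %.3g m is below 1 um; ",
                           "a nanometre-scale thickness is almost certainly a ",
                           "unit slip (did you mean %.3g m?)"),
            thickness, thickness * 1e3))
  semi_axes <- switch(shape,
    ellipse = derive_membrane_ellipse(area, perimeter),
    circle  = {
      r <- sqrt(area / pi)
      c(a = r, b = r)
    })
  structure(
    list(area = area, perimeter = perimeter, semi_axes = semi_axes,
         thickness = thickness, youngs_modulus = youngs_modulus,
         poisson_ratio = poisson_ratio, shape = shape),
    class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("Round-window membrane specification\n")
  cat(sprintf("  planform: %s, semi-axes %.3f x %.3f mm\n",
              x$shape, x$semi_axes[["a"]], x$semi_axes[["b"]]))
  cat(sprintf("  area %.3f mm^2, perimeter %.3f mm\n", x$area, x$perimeter))
  cat(sprintf("  E = %.3g Pa, nu = %.2f, h = %.3g m\n",
              x$youngs_modulus, x$poisson_ratio, x$thickness))
  invisible(x)
}

#' Inner-ear model: cavity + VA channel + membrane + fluid
#'
#' @param va A [va_channel()].
#' @param membrane A [membrane_spec()].
#' @param fluid A [fluid_properties()].
#' @param cavity_volume Fluid cavity volume, mm^3. Irrelevant to the closed
#'   incompressible hydraulics (it cancels); stored for mesh/report realism.
#' @param label Free-text label, e.g. `"Normal"` or `"A"`..`"G"`.
#' @return An object of class `inner_ear_model`.
#' @export
inner_ear_model <- function(va, membrane = membrane_spec(),
                            fluid = fluid_properties(),
                            cavity_volume = 200, label = "model") {
  stopifnot(inherits(va, "va_channel"), inherits(membrane, "membrane_spec"),
            inherits(fluid, "fluid_properties"))
  if (cavity_volume <= 0) stop("cavity_volume must be positive (mm^3)")
  structure(
    list(va = va, membrane = membrane, fluid = fluid,
         cavity_volume = cavity_volume, label = as.character(label)),
    class = "inner_ear_model")
}

#' @export
print.inner_ear_model <- function(x, ...) {
  cat(sprintf("Inner-ear model \"%s\"\n", x$label))
  cat(sprintf("  VA: operculum %.2f mm, midpoint %.2f mm, length %.2f mm\n",
              x$va$width_operculum, x$va$width_midpoint, x$va$length))
  cat(sprintf("  membrane: %.3f mm^2 %s, h = %.3g m\n",
              x$membrane$area, x$membrane$shape, x$membrane$thickness))
  cat(sprintf("  LVA (Cincinnati): %s\n",
              classify_lva(x$va$width_midpoint, x$va$width_operculum)))
  invisible(x)
}

#' Reference inner-ear model grid
#'
#' The eight study geometries: one normally developed inner ear ("Normal") and
#' seven enlarged aqueducts ("A".."G", sorted by midpoint width). Only the VA
#' widths differ between models; membrane, fluid and cavity volume are shared.
#'
#' @param membrane Shared [membrane_spec()].
#' @param fluid Shared [fluid_properties()].
#' @param cavity_volume Shared cavity volume, mm^3.
#' @return Named list of eight [inner_ear_model()] objects.
#' @examples
#' models <- make_reference_models()
#' sapply(models, function(m) m$va$width_midpoint)
#' @export
make_reference_models <- function(membrane = membrane_spec(),
                                  fluid = fluid_properties(),
                                  cavity_volume = 200) {
  widths <- data.frame(
    label     = c("Normal", "A", "B", "C", "D", "E", "F", "G"),
    operculum = c(1.2, 3.6, 3.4, 3.2, 3.7, 3.6, 4.6, 4.3),
    midpoint  = c(0.8, 2.2, 2.2, 2.25, 2.3, 2.4, 2.8, 3.3),
    stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(widths)), function(i) {
    inner_ear_model(
      va = va_channel(width_operculum = widths$operculum[i],
                      width_midpoint = widths$midpoint[i]),
      membrane = membrane, fluid = fluid,
      cavity_volume = cavity_volume, label = widths$label[i])
  })
  names(models) <- widths$label
  models
}

#' Cincinnati-criteria LVA classification
#'
#' An aqueduct is classified as enlarged (LVA) iff its midpoint width strictly
#' exceeds 0.9 mm or its operculum width strictly exceeds 1.9 mm.
#'
#' @param width_midpoint Midpoint width, mm (positive).
#' @param width_operculum Operculum width, mm (positive).
#' @return `"LVA"` or `"not-LVA"` (vectorised).
#' @examples
#' classify_lva(2.2, 3.6)  # "LVA"
#' classify_lva(0.8, 1.2)  # "not-LVA"
#' classify_lva(0.9, 1.9)  # boundary: "not-LVA" (strict inequalities)
#' @export
classify_lva <- function(width_midpoint, width_operculum) {
  if (any(width_midpoint <= 0) || any(width_operculum <= 0))
    stop("VA widths must be positive (mm)")
  ifelse(width_midpoint > 0.9 | width_operculum > 1.9, "LVA", "not-LVA")
}
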