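test_that("flexural rigidity follows the plate formula", {
  # direct arithmetic: 3e6 * (60e-6)^3 / (12 * (1 - 0.09))
  expect_equal(flexural_rigidity(plate_material(3e6, 0.3, 60e-6)),
               3e6 * (60e-6)^3 / (12 * (1 - 0.3^2)))
  expect_equal(flexural_rigidity(plate_material(3e6, 0.3, 60e-6)), 5.934e-8,
               tolerance = 1e-4)
  expect_equal(flexural_rigidity(0, 0.3, 60e-6), 0)
  expect_equal(flexural_rigidity(3e6, 0.3, 120e-6),
               8 * flexural_rigidity(3e6, 0.3, 60e-6))
})

test_that("clamped-circle closed forms match direct arithmetic", {
  mat <- plate_material()
  a <- 0.804e-3
  D <- 5.934065934065934e-8
  an <- analytic_clamped_circle(10e3, a, mat)
  expect_equal(an$w_max, 10e3 * a^4 / (64 * D), tolerance = 1e-12)
  expect_equal(an$w_max, 1.10e-3, tolerance = 1e-2)
  expect_equal(an$sigma_max, 3 * 10e3 * a^2 / (4 * (60e-6)^2), tolerance = 1e-12)
  expect_equal(an$sigma_max, 1.35e6, tolerance = 1e-2)
  expect_equal(an$compliance, pi * a^6 / (192 * D), tolerance = 1e-12)
  expect_equal(an$compliance, 7.45e-14, tolerance = 1e-2)
  z <- analytic_clamped_circle(0, a, mat)
  expect_equal(z$w_max, 0)
  expect_equal(z$sigma_max, 0)
  expect_gt(z$compliance, 0)
  expect_error(analytic_clamped_circle(-1, a, mat), "non-negative")
  expect_error(analytic_clamped_circle(10, 0, mat), "positive")
})

test_that("discrete solve matches the clamped-circle oracle at fine mesh", {
  a_mm <- circle_radius_mm
  mesh <- plate_mesh(circle_membrane, size = a_mm / 20)
  sol <- solve_plate(mesh, 10e3, default_material)
  an <- analytic_clamped_circle(10e3, a_mm * 1e-3, default_material)
  expect_lt(abs(sol$max_deflection / an$w_max - 1), 0.02)
  expect_lt(abs(sol$max_bending_stress / an$sigma_max - 1), 0.05)
  expect_lt(abs(sol$max_stress / an$sigma_vm_edge - 1), 0.05)
  expect_lt(abs(sol$volume / an$volume - 1), 0.01)
})

test_that("plate solution fields respect the clamped-plate structure", {
  mesh <- plate_mesh(default_membrane, size = 0.1)
  sol <- solve_plate(mesh, 10e3, default_material)
  # clamped boundary: identically zero deflection on the boundary ring
  expect_true(all(sol$deflection[mesh$boundary] == 0))
  # symmetry: the maximum deflection sits at the centroid node
  expect_identical(sol$node_max_deflection, 1L)
  # maximum von Mises stress on the boundary ring
  expect_true(sol$node_max_stress %in% mesh$boundary)
  # zero load, zero fields
  z <- solve_plate(mesh, 0, default_material)
  expect_true(all(z$deflection == 0))
  expect_true(all(z$von_mises == 0))
})

test_that("plate solution scales exactly linearly in pressure", {
  mesh <- plate_mesh(default_membrane, size = 0.15)
  s1 <- solve_plate(mesh, 7e3, default_material)
  s3 <- solve_plate(mesh, 21e3, default_material)
  expect_lt(max(abs(s3$deflection - 3 * s1$deflection)) /
              max(abs(s3$deflection)), 1e-10)
  expect_lt(abs(s3$max_stress - 3 * s1$max_stress) / s3$max_stress, 1e-10)
})

test_that("elliptical membrane deflection is bracketed by its axis circles", {
  ms <- default_membrane
  sol <- solve_plate(plate_mesh(ms, 0.05), 10e3, default_material)
  lo <- analytic_clamped_circle(10e3, ms$semi_axes[["b"]] * 1e-3,
                                default_material)$w_max
  hi <- analytic_clamped_circle(10e3, ms$semi_axes[["a"]] * 1e-3,
                                default_material)$w_max
  expect_gt(sol$max_deflection, lo)
  expect_lt(sol$max_deflection, hi)
  # and it agrees with the exact clamped-ellipse solution
  ex <- analytic_clamped_ellipse(10e3, ms$semi_axes[["a"]] * 1e-3,
                                 ms$semi_axes[["b"]] * 1e-3, default_material)
  expect_lt(abs(sol$max_deflection / ex$w_max - 1), 1e-8)
})

test_that("discrete error vs the oracle shrinks (or stays tiny) with size", {
  a_mm <- circle_radius_mm
  an <- analytic_clamped_circle(10e3, a_mm * 1e-3, default_material)
  errs <- vapply(c(0.4, 0.2, 0.1, 0.05), function(sz) {
    abs(solve_plate(plate_mesh(circle_membrane, sz), 10e3,
                    default_material)$max_deflection / an$w_max - 1)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))   # non-increasing
  expect_lt(errs[length(errs)], 1e-8)     # converged far below any tolerance
})

test_that("degenerate meshes are rejected with the offending element", {
  mesh <- plate_mesh(default_membrane, 0.2)
  mesh$nodes[2, ] <- mesh$nodes[3, ]   # collapse one triangle
  expect_error(solve_plate(mesh, 1e3, default_material), "triangle")
  expect_error(plate_mesh(default_membrane, size = 0), "positive")
})

test_that("convergence study reports a plateau below 2%", {
  cs <- convergence_study(c(1, 0.5, 0.1), p = 10e3)
  tab <- cs$table
  expect_identical(nrow(tab), 3L)
  expect_lt(tab$rel_change[3], 0.02)
  # node/element counts grow under refinement
  expect_true(all(diff(tab$nodes) > 0))
  expect_true(all(diff(tab$elements) > 0))
  # single size: no change column
  one <- convergence_study(0.5)
  expect_identical(nrow(one$table), 1L)
  expect_false("rel_change" %in% names(one$table))
  expect_error(convergence_study(c(0.1, 0.5)), "descending")
})
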