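test_that("the default sweep covers the full grid with positive peaks", {
  sw <- get_default_sweep()
  expect_identical(nrow(sw$table), 48L)
  expect_true(all(sw$table$peak_deflection > 0))
  expect_true(all(sw$table$peak_stress > 0))
  expect_identical(nrow(unique(sw$table[, c("label", "p_max")])), 48L)
})

test_that("peak response increases with load for every geometry", {
  tab <- get_default_sweep()$table
  for (lab in unique(tab$label)) {
    r <- tab[tab$label == lab, ]
    r <- r[order(r$p_max), ]
    expect_true(all(diff(r$peak_deflection) > 0), label = lab)
    expect_true(all(diff(r$peak_stress) > 0), label = lab)
  }
})

test_that("peak deflection is non-decreasing in VA width, with exact ties", {
  tab <- get_default_sweep()$table
  r <- tab[tab$p_max == 300e3, ]
  r <- r[order(r$width_midpoint), ]
  expect_true(all(diff(r$peak_deflection) >= 0))
  # A and B share a 2.2 mm midpoint: identical hydraulics, identical peaks
  expect_identical(r$peak_deflection[r$label == "A"],
                   r$peak_deflection[r$label == "B"])
})

test_that("width curve extracts one sorted point per model", {
  sw <- get_default_sweep()
  wc <- width_curve(sw, 300e3)
  expect_identical(nrow(wc$table), 8L)
  expect_equal(range(wc$table$width_midpoint), c(0.8, 3.3))
  expect_true(!is.unsorted(wc$table$width_midpoint))
  expect_error(width_curve(sw, 42e3), "not in the sweep grid")
})

test_that("report is deterministic, laminar at 10 kPa, and config-guarded", {
  sw <- get_default_sweep()
  r1 <- report(sw)
  r2 <- report(sw)
  expect_identical(r1, r2)
  lam <- grep("\\| 10 \\|", r1, value = TRUE)
  expect_length(lam, 8)
  expect_true(all(grepl("laminar", lam)))
  expect_true(any(grepl("alpha", r1)))
  expect_true(any(grepl("zeta_add", r1)))
  expect_true(any(grepl("thickness", r1)))

  broken <- sw
  broken$config <- NULL
  expect_error(report(broken), "config")
  empty <- structure(list(table = sw$table[0, ], config = sw$config),
                     class = "va_sweep")
  expect_error(report(empty), "empty")
})

test_that("report units convert consistently from SI", {
  sw <- get_default_sweep()
  si <- as.data.frame(sw)
  rp <- as.data.frame(sw, units = "report")
  expect_equal(rp$peak_deflection_mm, si$peak_deflection * 1e3)
  expect_equal(rp$peak_stress_mpa, si$peak_stress / 1e6)
  expect_equal(rp$p_max_kpa, si$p_max / 1e3)
  tabs <- sweep_table(sw, "deflection")
  expect_identical(dim(tabs), c(8L, 7L))
})

test_that("sweep specification is validated", {
  expect_error(sweep_spec(labels = c("Normal", "X")), "unknown")
  expect_error(sweep_spec(p_grid = numeric(0)), "non-empty")
})

test_that("configuration round-trips through YAML and builds models", {
  cfg <- default_config()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back, cfg)
  # partial overrides keep defaults elsewhere
  writeLines("geometry:\n  label: G\n  width_midpoint_mm: 3.3\n  width_operculum_mm: 4.3",
             f)
  over <- read_config(f)
  expect_identical(over$geometry$label, "G")
  expect_equal(over$membrane$area_mm2, 2.031)
  mfc <- model_from_config(over)
  expect_equal(mfc$model$va$width_midpoint, 3.3)
  ref <- make_reference_models()$G
  expect_equal(mfc$model$va, ref$va)
  expect_length(mfc$loads, 6)
  expect_error(read_config("/nonexistent/path.yaml"), "not found")
})
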