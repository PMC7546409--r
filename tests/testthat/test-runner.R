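test_that("named configurations carry the exact contact sets", {
  c4 <- named_configuration("4")
  expect_setequal(c4$cathodes, "2B")
  expect_setequal(c4$anodes, c("3A", "3B", "3C"))
  c3 <- named_configuration("3")
  expect_setequal(c3$cathodes, c("2A", "2B", "2C"))
  expect_identical(c3$anodes, "CASE")
  c1 <- named_configuration("1")
  expect_setequal(c1$cathodes, "2B")
  c2a <- named_configuration("2a")
  expect_setequal(c2a$cathodes, c("2A", "2B"))
  c2b <- named_configuration("2b")
  expect_setequal(c2b$cathodes, c("2B", "3B"))
  c5 <- named_configuration("5")
  expect_setequal(c5$cathodes, c("2A", "2B", "2C"))
  expect_setequal(c5$anodes, c("3A", "3B", "3C"))
  expect_true(c5$coactivated)
  expect_false(c1$coactivated)
  expect_error(named_configuration("7"), "valid names")
})

test_that("configuration validation enforces the invariants", {
  expect_error(stim_configuration(character()), "nonempty")
  expect_error(stim_configuration("2B", "2B"), "disjoint")
  expect_error(stim_configuration("2B", amplitude_mA = 0), "amplitude")
  expect_error(stim_configuration("9Z"), "unknown contact")
})

test_that("the built-in sweep enumerates the study cells", {
  spec <- default_sweep_spec()
  cells <- spec$cells
  expect_equal(nrow(cells), 19L)
  het15 <- cells[cells$spacing_mm == 1.5 & cells$tissue_mode == "heterogeneous", ]
  expect_equal(nrow(het15), 12L)
  expect_setequal(unique(het15$config), c("1", "2a", "2b", "3", "4", "5"))
  het05 <- cells[cells$spacing_mm == 0.5, ]
  expect_equal(nrow(het05), 6L)
  expect_setequal(unique(het05$config), c("2b", "4", "5"))
  hom <- cells[cells$tissue_mode == "homogeneous", ]
  expect_equal(nrow(hom), 1L)
  expect_equal(hom$config, "4")
  expect_error(sweep_spec(data.frame()), "nonempty")
})

test_that("summaries are pure functions of the breakdown table", {
  tab <- data.frame(
    config = c("2b", "4", "5", "2b", "4", "5", "4"),
    spacing_mm = c(1.5, 1.5, 1.5, 0.5, 0.5, 0.5, 1.5),
    amplitude_mA = 1,
    tissue_mode = c(rep("heterogeneous", 6), "homogeneous"),
    n_axons = 100, n_activated = 50, eti_impedance_ohm = 1500,
    total_mm3 = c(100, 90, 95, 70, 60, 72, 120),
    in_GPi_mm3 = 0, lamina_mm3 = 0, in_GPe_mm3 = 0, outside_mm3 = 0,
    pct_in_GPi = c(100, 100, 100, 100, 100, 100, 90),
    pct_lamina = 0, pct_in_GPe = 0, pct_outside = 0,
    sidefx_mm3 = 0, asymmetry_index = 0.6,
    stringsAsFactors = FALSE)
  s <- summarize_sweep(tab)
  expect_equal(s$mean_pct_in_GPi$pct_in_GPi, c(100, 100))
  expect_equal(s$config_4_to_5$volume_change_pct[
    s$config_4_to_5$spacing_mm == 1.5], 100 * (95 - 90) / 90)
  expect_equal(s$homogeneous_vs_heterogeneous$percent_difference,
               100 * (120 - 90) / 90)
  td <- withr::local_tempdir()
  csv <- file.path(td, "tab.csv")
  write.csv(tab, csv, row.names = FALSE)
  s2 <- summarize_sweep(csv)
  expect_equal(s2$mean_pct_in_GPi, s$mean_pct_in_GPi)
  expect_equal(s2$config_4_to_5, s$config_4_to_5)
  expect_equal(s2$homogeneous_vs_heterogeneous,
               s$homogeneous_vs_heterogeneous)
})

test_that("a single-cell sweep produces exactly one row", {
  spec <- sweep_spec(
    cells = data.frame(config = "1", spacing_mm = 1.5, amplitude_mA = 1,
                       tissue_mode = "heterogeneous",
                       stringsAsFactors = FALSE),
    phantom = tiny_phantom_spec(),
    solver = fast_settings(),
    axon = axon_grid_spec(plane_extent_mm = 3, plane_spacing_mm = 1,
                          axial_margin_mm = 0.5),
    target_offsets = c(lateral = 2, posterior = 2))
  res <- run_sweep(spec, verbose = FALSE)
  expect_equal(nrow(res$table), 1L)
  expect_equal(length(res$failures), 0L)
  expect_gt(res$table$total_mm3, 0)
  expect_equal(res$table$config, "1")
})

test_that("sweep specs round-trip through YAML", {
  spec <- default_sweep_spec(phantom = tiny_phantom_spec())
  td <- withr::local_tempdir()
  p <- file.path(td, "sweep.yaml")
  write_sweep_spec(spec, p)
  spec2 <- read_sweep_spec(p)
  expect_equal(spec2$cells, spec$cells, ignore_attr = TRUE)
  expect_equal(spec2$phantom$gpi_ellipsoid$semi_axes,
               spec$phantom$gpi_ellipsoid$semi_axes)
  expect_equal(spec2$homogeneous_sigma, spec$homogeneous_sigma)
})
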