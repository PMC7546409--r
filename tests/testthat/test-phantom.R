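test_that("rasterized ellipsoid volume matches the analytic volume", {
  sp <- phantom_spec(domain_size_mm = c(20, 20, 20), voxel_size_mm = 0.25,
                     gpe_ellipsoid = list(center = c(10, 10, 10),
                                          semi_axes = c(8, 6, 5.5)),
                     gpi_ellipsoid = list(center = c(10, 10, 10),
                                          semi_axes = c(5, 3, 3)),
                     lamina_thickness_mm = 1,
                     ic_slab = list(point = c(0.5, 10, 10),
                                    normal = c(1, 0, 0), thickness = 0.5),
                     optic_tract_cylinder = list(point = c(10, 10, 1.2),
                                                 axis = c(0, 1, 0),
                                                 radius = 1),
                     ventricle_csf = NULL, cistern_csf = NULL,
                     dorsal_white = NULL, csf_rim_mm = 0,
                     case_thickness_mm = 0.25)
  m <- build_pallidum_phantom(sp)
  vol <- sum(m$label_grid == pallidal_labels[["gpi"]]) * 0.25^3
  expect_lt(abs(vol / (4 / 3 * pi * 5 * 3 * 3) - 1), 0.05)
})

test_that("zero lamina thickness yields no lamina voxels", {
  sp <- tiny_phantom_spec()
  sp$lamina_thickness_mm <- 0
  m <- build_pallidum_phantom(sp)
  expect_equal(sum(m$label_grid == pallidal_labels[["lamina"]]), 0)
})

test_that("phantom construction is deterministic and partitions space", {
  m1 <- tiny_phantom()
  m2 <- build_pallidum_phantom(tiny_phantom_spec())
  expect_identical(m1$label_grid, m2$label_grid)
  # every voxel carries exactly one positive label
  expect_true(all(m1$label_grid >= 1L))
  expect_equal(sum(table(m1$label_grid)), length(m1$label_grid))
})

test_that("the lamina separates GPi from GPe (no 6-connected contact)", {
  m <- tiny_phantom()  # lamina 1 mm = 2 voxels at 0.5 mm
  lab <- m$label_grid
  gpi <- pallidal_labels[["gpi"]]
  gpe <- pallidal_labels[["gpe"]]
  dm <- dim(lab)
  touches <- FALSE
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    idx <- lapply(dm, seq_len)
    src <- idx
    dst <- idx
    n <- dm[ax]
    src[[ax]] <- if (by > 0) 1:(n - 1) else 2:n
    dst[[ax]] <- if (by > 0) 2:n else 1:(n - 1)
    a <- lab[src[[1]], src[[2]], src[[3]]]
    b <- lab[dst[[1]], dst[[2]], dst[[3]]]
    if (any(a == gpi & b == gpe)) touches <- TRUE
  }
  expect_false(touches)
})

test_that("structures exceeding the domain raise a geometry error", {
  sp <- tiny_phantom_spec()
  sp$gpe_ellipsoid$semi_axes <- c(40, 6, 5)
  expect_error(build_pallidum_phantom(sp), "GPe")
  sp2 <- tiny_phantom_spec()
  sp2$optic_tract_cylinder$point <- c(12, 15, -5)
  expect_error(build_pallidum_phantom(sp2), "optic tract")
})

test_that("homogenize maps every internal label to the given conductivity", {
  m <- tiny_phantom()
  hm <- homogenize(m, 0.3)
  tab <- hm$conductivity_table
  internal <- tab$label %in% c(1:9, 10)
  expect_true(all(tab$sigma_S_per_m[internal] == 0.3))
  # electrode materials untouched
  expect_equal(tab$sigma_S_per_m[tab$label == 11],
               m$conductivity_table$sigma_S_per_m[m$conductivity_table$label == 11])
  # idempotent and geometry untouched
  expect_identical(homogenize(hm, 0.3)$conductivity_table, hm$conductivity_table)
  expect_identical(hm$label_grid, m$label_grid)
  expect_error(homogenize(m, 0), "positive")
  expect_error(homogenize(m, -1), "positive")
})

test_that("tissue model NIfTI/TSV round-trip preserves everything", {
  m <- tiny_phantom()
  td <- withr::local_tempdir()
  lp <- file.path(td, "labels.nii.gz")
  tp <- file.path(td, "sigma.tsv")
  write_tissue_model(m, lp, tp)
  m2 <- read_tissue_model(lp, tp)
  expect_equal(table(m2$label_grid), table(m$label_grid))
  expect_equal(m2$voxel_size_mm, m$voxel_size_mm)
  expect_equal(m2$origin_mm, m$origin_mm)
  expect_equal(m2$conductivity_table$sigma_S_per_m,
               m$conductivity_table$sigma_S_per_m)
})

test_that("a conductivity table missing a used label names the label", {
  m <- tiny_phantom()
  td <- withr::local_tempdir()
  lp <- file.path(td, "labels.nii.gz")
  tp <- file.path(td, "sigma.tsv")
  write_tissue_model(m, lp, tp)
  tab <- read.table(tp, header = TRUE, sep = "\t", comment.char = "#")
  tab <- tab[tab$label != pallidal_labels[["gpi"]], ]
  tp2 <- file.path(td, "sigma2.tsv")
  write.table(tab, tp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tissue_model(lp, tp2), as.character(pallidal_labels[["gpi"]]))
})

test_that("a non-integer volume is rejected", {
  td <- withr::local_tempdir()
  lp <- file.path(td, "float.nii.gz")
  arr <- array(runif(8 * 8 * 8) + 1, c(8, 8, 8))
  RNifti::writeNifti(RNifti::asNifti(arr), lp)
  m <- tiny_phantom()
  tp <- file.path(td, "sigma.tsv")
  write_tissue_model(m, file.path(td, "x.nii.gz"), tp)
  expect_error(read_tissue_model(lp, tp), "integer")
})
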