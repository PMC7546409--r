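cube_corners <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))

test_that("the hull of a unit-cube point set has unit volume", {
  v <- build_vta(cube_corners, voxel_size_mm = 0.05, mode = "hull")
  expect_equal(v$hull_volume_mm3, 1, tolerance = 1e-4)
  expect_equal(v$total_volume_mm3, 1, tolerance = 0.05)
  # every API site inside (or on) the mask
  idx <- vtasteer:::point_to_index(cube_corners + 1e-9, dim(v$mask),
                                   v$voxel_size_mm, v$origin_mm)
  expect_true(all(v$mask[vtasteer:::linear_index(idx, dim(v$mask))]))
})

test_that("alpha bounding is contained in the hull and contains the sites", {
  set.seed(7)
  pts <- matrix(rnorm(3 * 300, sd = 2), ncol = 3)
  vh <- build_vta(pts, voxel_size_mm = 0.25, mode = "hull")
  va <- build_vta(pts, voxel_size_mm = 0.25, mode = "alpha", alpha = 1)
  expect_lte(va$total_volume_mm3, vh$total_volume_mm3)
  idx <- vtasteer:::point_to_index(pts, dim(va$mask), va$voxel_size_mm,
                                   va$origin_mm)
  expect_true(all(va$mask[vtasteer:::linear_index(idx, dim(va$mask))]))
})

test_that("degenerate point sets give flagged zero-volume results", {
  expect_equal(build_vta(matrix(0, 0, 3), 0.5)$total_volume_mm3, 0)
  v3 <- build_vta(cube_corners[1:3, ], 0.5)
  expect_true(v3$degenerate)
  expect_equal(v3$total_volume_mm3, 0)
  # coplanar points
  flat <- cbind(matrix(runif(20), ncol = 2), 0.3)
  vf <- build_vta(flat, 0.5)
  expect_true(vf$degenerate)
})

test_that("partition conserves volume and classifies a pure-GPi VTA", {
  ph <- tiny_phantom()
  gpi_c <- tiny_phantom_spec()$gpi_ellipsoid$center
  pts <- sweep(matrix(rnorm(3 * 100, sd = 0.4), ncol = 3), 2, gpi_c, "+")
  v <- build_vta(pts, voxel_size_mm = 0.5, mode = "hull",
                 grid_origin_mm = ph$origin_mm)
  v <- partition_vta(v, ph)
  sv <- unlist(v$sub_volumes_mm3)
  expect_equal(sum(sv), v$total_volume_mm3, tolerance = 1e-12)
  expect_equal(v$percentages$in_GPi, 100)
  expect_equal(sum(unlist(v$percentages)), 100, tolerance = 1e-9)
})

test_that("a cube straddling a planar border splits 50/50", {
  # synthetic two-region model: GPi for x < 15, GPe for x >= 15
  lab <- array(pallidal_labels[["gpe"]], c(60, 60, 60))
  lab[1:30, , ] <- pallidal_labels[["gpi"]]
  m <- tissue_model(lab, voxel_size_mm = 0.5)
  corners <- cbind(c(11, 19, 11, 19, 11, 19, 11, 19),
                   c(11, 11, 19, 19, 11, 11, 19, 19),
                   c(11, 11, 11, 11, 19, 19, 19, 19))
  v <- build_vta(corners, voxel_size_mm = 0.5, mode = "hull")
  v <- partition_vta(v, m)
  expect_equal(v$percentages$in_GPi, 50, tolerance = 2)
  expect_equal(v$percentages$in_GPe, 100 - v$percentages$in_GPi)
})

test_that("VTA comparison metrics behave on identity, disjoint and scaled masks", {
  v <- build_vta(cube_corners, voxel_size_mm = 0.1, mode = "hull")
  self <- compare_vtas(v, v)
  expect_equal(self$dice, 1)
  expect_equal(self$percent_difference, 0)
  v2 <- build_vta(cube_corners + 10, voxel_size_mm = 0.1, mode = "hull")
  expect_equal(compare_vtas(v, v2)$dice, 0)
  # 1.429x the volume is a 42.9% difference
  a <- v
  a$total_volume_mm3 <- 1.429 * v$total_volume_mm3
  expect_equal(compare_vtas(a, v)$percent_difference, 42.9, tolerance = 1e-9)
  vz <- v
  vz$total_volume_mm3 <- 0
  expect_error(compare_vtas(v, vz), "zero volume")
})

test_that("the asymmetry index of a symmetric mask is one half", {
  v <- build_vta(cube_corners, voxel_size_mm = 0.05, mode = "hull")
  asym <- vta_asymmetry(v, origin_mm = c(0.5, 0.5, 0.5),
                        azimuth = c(1, 0, 0))
  expect_equal(asym, 0.5, tolerance = 0.05)
})

test_that("side-effect overlap is bounded and zero when disjoint", {
  ph <- tiny_phantom()
  gpi_c <- tiny_phantom_spec()$gpi_ellipsoid$center
  pts <- sweep(matrix(rnorm(3 * 60, sd = 0.4), ncol = 3), 2, gpi_c, "+")
  v <- partition_vta(build_vta(pts, 0.5, mode = "hull",
                               grid_origin_mm = ph$origin_mm), ph)
  ov <- flag_side_effect_overlap(v, ph)
  expect_equal(ov, 0)
  expect_lte(ov, v$total_volume_mm3)
  expect_error(flag_side_effect_overlap(v, ph, labels = "nonsense"),
               "unknown")
})

test_that("VTA export round-trips the voxel count and writes a surface", {
  v <- build_vta(cube_corners * 2, voxel_size_mm = 0.2, mode = "hull")
  td <- withr::local_tempdir()
  paths <- export_vta(v, file.path(td, "vta"))
  expect_true(all(file.exists(paths)))
  m <- RNifti::readNifti(paths[1])
  expect_equal(sum(as.array(m) > 0), sum(v$mask))
  stl <- readLines(paths[2])
  expect_gt(sum(grepl("^facet", stl)), 10)
  expect_equal(sum(grepl("endfacet", stl)), sum(grepl("^facet", stl)))
})
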