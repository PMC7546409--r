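test_that("row centre distances follow contact height plus spacing", {
  l15 <- build_lead(1.5)
  d <- vtasteer:::lead_row_center(l15, 3) - vtasteer:::lead_row_center(l15, 2)
  expect_equal(d, 3.0)
  l05 <- build_lead(0.5)
  d <- vtasteer:::lead_row_center(l05, 3) - vtasteer:::lead_row_center(l05, 2)
  expect_equal(d, 2.0)
})

test_that("zero implant angles give a vertical shaft", {
  l <- build_lead(1.5, sagittal_angle_deg = 0, coronal_angle_deg = 0)
  expect_equal(l$shaft_direction, c(0, 0, 1))
  expect_error(build_lead(1.5, segment_A_azimuth = c(0, 0, 1),
                          sagittal_angle_deg = 0, coronal_angle_deg = 0),
               "degenerate")
  expect_error(build_lead(0), "spacing")
})

test_that("the contact layout is 1-3-3-1 with disjoint extents", {
  l <- build_lead(1.5)
  cc <- l$contacts
  expect_equal(nrow(cc), 8L)
  expect_equal(cc$kind[cc$row %in% c(1, 4)], rep("ring", 2))
  expect_equal(sum(cc$kind == "segment"), 6L)
  # axial extents of different rows do not overlap
  rows <- split(cc, cc$row)
  spans <- t(vapply(rows, function(r) c(min(r$axial_lo), max(r$axial_hi)),
                    numeric(2)))
  o <- order(spans[, 1])
  expect_true(all(diff(as.vector(t(spans[o, ]))) >= 0))
  # segment arcs within a row are disjoint
  for (r in c(2, 3)) {
    s <- cc[cc$row == r, ]
    s <- s[order(s$ang_lo), ]
    expect_true(all(s$ang_lo[-1] > s$ang_hi[-nrow(s)]))
  }
  # total length strictly increases with spacing
  expect_gt(vtasteer:::lead_contact_span(build_lead(1.5)),
            vtasteer:::lead_contact_span(build_lead(0.5)))
})

test_that("rotating the azimuth by 120 degrees maps segment A onto B", {
  h <- 0.1
  dm <- c(44L, 44L, 70L)  # z covers the row-2 contacts (t = 4 to 5.5 mm)
  origin <- c(-2.2, -2.2, 0)
  base <- build_lead(1.5, tip_mm = c(0, 0, 0), sagittal_angle_deg = 0,
                     coronal_angle_deg = 0, segment_A_azimuth = c(1, 0, 0))
  rot <- build_lead(1.5, tip_mm = c(0, 0, 0), sagittal_angle_deg = 0,
                    coronal_angle_deg = 0,
                    segment_A_azimuth = c(-0.5, -sqrt(3) / 2, 0))
  ras_a <- vtasteer:::classify_lead_voxels(base, dm, h, origin)
  ras_b <- vtasteer:::classify_lead_voxels(rot, dm, h, origin)
  va <- which(ras_b == pallidal_labels[["contact_2A"]], arr.ind = TRUE)
  vb <- which(ras_a == pallidal_labels[["contact_2B"]], arr.ind = TRUE)
  # rotated-frame 2A should occupy (nearly) the voxel set of 2B
  expect_gt(nrow(va), 0)
  expect_lt(abs(nrow(va) / nrow(vb) - 1), 0.15)
  # every rotated-2A voxel within one voxel of some 2B voxel
  mind <- apply(va, 1, function(p)
    sqrt(min(colSums((t(vb) - p)^2))))
  expect_lt(max(mind) * h, 1.5 * h + 1e-9)
})

test_that("encapsulation shell thickness is honoured", {
  h <- 0.1
  dm <- rep(40L, 3)
  origin <- c(-2, -2, 0)
  l <- build_lead(1.5, tip_mm = c(0, 0, 0), sagittal_angle_deg = 0,
                  coronal_angle_deg = 0)
  ras <- vtasteer:::classify_lead_voxels(l, dm, h, origin)
  enc <- which(ras == pallidal_labels[["encapsulation"]], arr.ind = TRUE)
  expect_gt(nrow(enc), 0)
  ctr <- sweep(sweep(enc, 2, 0.5), 2, h, "*")
  ctr <- sweep(ctr, 2, origin, "+")
  rho <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)  # shaft on the z-axis
  r <- l$diameter_mm / 2
  expect_true(all(rho <= r + 0.5 + h))
  expect_true(all(rho >= r - h))
  # zero thickness: no encapsulation voxels
  l0 <- build_lead(1.5, tip_mm = c(0, 0, 0), sagittal_angle_deg = 0,
                   coronal_angle_deg = 0, encapsulation_thickness_mm = 0)
  ras0 <- vtasteer:::classify_lead_voxels(l0, dm, h, origin)
  expect_equal(sum(ras0 == pallidal_labels[["encapsulation"]]), 0)
})

test_that("no voxel carries two contact labels and rasterization is idempotent", {
  tp <- tiny_pipeline()
  m1 <- tp$model
  m2 <- rasterize_lead(tp$lead, m1)
  expect_identical(m1$label_grid, m2$label_grid)
  # single label per voxel is structural; verify contact labels present
  labs <- unique(as.vector(m1$label_grid))
  expect_true(all(21:28 %in% labs))
})

test_that("placement reaches the requested GPi border offsets", {
  tp <- tiny_pipeline()
  pl <- attr(tp$lead, "placement")
  h <- tp$phantom$voxel_size_mm
  expect_lt(abs(pl$achieved[["lateral"]] - pl$requested[["lateral"]]), h)
  expect_lt(abs(pl$achieved[["posterior"]] - pl$requested[["posterior"]]), h)
  # self-consistency: re-measuring reproduces the reported distances
  b <- vtasteer:::gpi_border_distances(
    tp$lead, tp$phantom, vtasteer:::lead_row_center(tp$lead, 2),
    tp$lead$diameter_mm / 2)
  expect_equal(b$lateral, unname(pl$achieved[["lateral"]]))
  expect_equal(b$posterior, unname(pl$achieved[["posterior"]]))
})

test_that("zero offsets put the contact surface at the borders", {
  ph <- tiny_phantom()
  lead <- build_lead(1.5)
  l0 <- place_at_target(lead, ph, target_offsets = c(lateral = 0, posterior = 0))
  pl <- attr(l0, "placement")
  expect_lt(abs(pl$achieved[["lateral"]]), ph$voxel_size_mm)
  expect_lt(abs(pl$achieved[["posterior"]]), ph$voxel_size_mm)
})

test_that("a model without GPi and an out-of-domain lead raise errors", {
  m <- tiny_phantom()
  m2 <- m
  m2$label_grid[m2$label_grid == pallidal_labels[["gpi"]]] <-
    pallidal_labels[["gpe"]]
  expect_error(place_at_target(build_lead(1.5), m2), "GPi")
  lead <- build_lead(1.5, tip_mm = c(200, 200, 200))
  expect_error(rasterize_lead(lead, m), "domain")
})

test_that("lead JSON round-trips", {
  l <- build_lead(0.5)
  td <- withr::local_tempdir()
  p <- file.path(td, "lead.json")
  write_lead(l, p)
  l2 <- read_lead(p)
  expect_equal(l2$shaft_direction, l$shaft_direction)
  expect_equal(l2$contacts$id, l$contacts$id)
  expect_equal(l2$vertical_spacing_mm, l$vertical_spacing_mm)
})
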