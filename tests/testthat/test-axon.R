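test_that("axon compartmentalization matches the fibre geometry", {
  ax <- test_axon()  # 20 mm at 0.5 mm internodal length
  expect_equal(ax$n_nodes, 41L)
  expect_equal(sum(ax$kinds == 0L), 41L)
  expect_equal(ax$kinds[1], 0L)
  expect_equal(ax$kinds[length(ax$kinds)], 0L)
  # nodes are equally spaced
  ns <- ax$s_mm[ax$kinds == 0L]
  expect_equal(diff(ns), rep(0.5, 40), tolerance = 1e-12)
})

test_that("the axon grid has the requested planes, orientations and exclusion", {
  lead <- build_lead(1.5, tip_mm = c(0, 0, 0), sagittal_angle_deg = 0,
                     coronal_angle_deg = 0)
  pop <- generate_axon_grid(lead, axon_grid_spec(plane_extent_mm = 4))
  expect_equal(length(pop$angles_deg), 6L)
  expect_equal(pop$angles_deg, seq(0, 150, by = 30))
  # no axon line passes through the lead body: perpendicular distance of
  # each axon line to the shaft axis is the lateral offset
  expect_true(all(abs(pop$meta$lateral_offset_mm) >= lead$diameter_mm / 2))
  # plane spacing along the shaft
  t1 <- pop$t_planes
  expect_equal(diff(t1), rep(0.5, length(t1) - 1), tolerance = 1e-12)
})

test_that("potential interpolation is exact on affine fields", {
  tp <- tiny_pipeline()
  f <- tp$field
  # zero field: zero profile
  f0 <- f
  f0$coarse$phi[] <- 0
  f0$fine$phi[] <- 0
  ax <- test_axon(origin = c(15, 15, 15))
  expect_equal(interpolate_potentials(f0, ax$positions),
               rep(0, nrow(ax$positions)))
  # affine field c * x is reproduced exactly by trilinear interpolation
  fa <- f
  fill_affine <- function(lev) {
    dm <- lev$dim
    xs <- vtasteer:::axis_centers(dm[1], lev$h, lev$origin[1])
    lev$phi <- outer(outer(0.01 * xs, rep(1, dm[2])), rep(1, dm[3]))
    lev
  }
  fa$coarse <- fill_affine(fa$coarse)
  fa$fine <- fill_affine(fa$fine)
  prof <- interpolate_potentials(fa, ax$positions)
  expect_equal(prof, 0.01 * ax$positions[, 1], tolerance = 1e-9)
})

test_that("a point-source profile peaks at the nearest compartment", {
  ax <- test_axon()
  src <- ax$positions[35, ] + c(0, 0.4, 0)
  prof <- point_source_profile(ax$positions, src)
  expect_equal(which.max(abs(prof)), 35L)
})

test_that("the membrane rests stably without stimulation", {
  par <- membrane_parameters(5.7)
  ax <- test_axon(par)
  wf <- stimulus_waveform(total_time_ms = 10)
  res <- simulate_axon(ax, rep(0, length(ax$kinds)), wf, par)
  expect_false(res$activated)
  expect_lt(max(abs(res$vm_final_mV - par$vrest_mV)), 1)
})

test_that("a strong cathodal source activates with the API at the nearest node", {
  par <- membrane_parameters(5.7)
  ax <- test_axon(par)
  wf <- stimulus_waveform(total_time_ms = 2.5)
  src <- c(0, 0.5, 0)  # closest to the centre node (node 21)
  prof <- point_source_profile(ax$positions, src)
  th <- find_threshold(ax, prof, wf, par, bracket = c(0.001, 20))
  res <- simulate_axon(ax, prof, wf, par, amplitude_scale = 1.5 * th)
  expect_true(res$activated)
  expect_lte(abs(res$api_node - 21L), 1L)
  expect_equal(ax$positions[which(ax$kinds == 0L)[res$api_node], ],
               res$api_position_mm)
})

test_that("thresholds fall with pulse width, rise with distance, fall with diameter", {
  par <- membrane_parameters(5.7)
  ax <- test_axon(par)
  wf60 <- stimulus_waveform(total_time_ms = 2.5)
  th <- function(d, wf = wf60, p = par, a = ax)
    find_threshold(a, point_source_profile(a$positions, c(0, d, 0)), wf, p,
                   bracket = c(0.001, 50))
  t1 <- th(1)
  t2 <- th(2)
  expect_gt(t2, t1)
  wf200 <- stimulus_waveform(pulse_width_us = 200, total_time_ms = 2.5)
  expect_lt(th(2, wf200), t2)
  par9 <- membrane_parameters(8.7)
  ax9 <- test_axon(par9)
  expect_lt(th(2, wf60, par9, ax9), t2)
})

test_that("bisection returns the smallest activating amplitude", {
  par <- membrane_parameters(5.7)
  ax <- test_axon(par)
  wf <- stimulus_waveform(total_time_ms = 2.5)
  prof <- point_source_profile(ax$positions, c(0, 2, 0))
  th <- find_threshold(ax, prof, wf, par, bracket = c(0.001, 50), tol = 0.005)
  expect_true(simulate_axon(ax, prof, wf, par, amplitude_scale = th)$activated)
  expect_false(simulate_axon(ax, prof, wf, par,
                             amplitude_scale = 0.99 * th)$activated)
  expect_error(find_threshold(ax, prof, wf, par, bracket = c(10, 50)),
               "bracket")
  expect_error(find_threshold(ax, prof, wf, par, bracket = c(1e-6, 1e-5)),
               "bracket")
})

test_that("threshold monotonicities hold across randomized placements", {
  set.seed(42)
  par <- membrane_parameters(5.7)
  ax <- test_axon(par)
  wf <- stimulus_waveform(total_time_ms = 2.5)
  nodes <- which(ax$kinds == 0L)
  for (i in 1:20) {
    node <- sample(10:32, 1)
    base <- ax$positions[nodes[node], ]
    off <- runif(2, -0.2, 0.2)
    d1 <- runif(1, 0.6, 1.4)
    d2 <- d1 + runif(1, 0.8, 2)
    p1 <- point_source_profile(ax$positions, base + c(off[1], d1, off[2]))
    p2 <- point_source_profile(ax$positions, base + c(off[1], d2, off[2]))
    t1 <- find_threshold(ax, p1, wf, par, bracket = c(1e-4, 20), tol = 0.02)
    t2 <- find_threshold(ax, p2, wf, par, bracket = c(1e-4, 20), tol = 0.02)
    expect_gt(t2, t1)
    # cathodal API locus at modest suprathreshold amplitude
    res <- simulate_axon(ax, p1, wf, par, amplitude_scale = 1.5 * t1)
    expect_lte(abs(res$api_node - node), 1L)
  }
})

test_that("population evaluation is monotone in amplitude and prescreen-safe", {
  tp <- tiny_pipeline()
  lead <- tp$lead
  pop <- generate_axon_grid(lead, axon_grid_spec(plane_extent_mm = 4,
                                                 axial_margin_mm = 0.5))
  wf <- stimulus_waveform(total_time_ms = 2)
  a1 <- evaluate_population(tp$field, pop, wf)
  expect_gt(a1$n_activated, 0)
  a2 <- evaluate_population(scale_to_current(tp$field, 2), pop, wf)
  expect_true(all(a2$table$activated >= a1$table$activated))
  # prescreen does not change the outcome
  a1b <- evaluate_population(tp$field, pop, wf, prescreen_mV = 0)
  expect_identical(a1$table$activated, a1b$table$activated)
  # null field: nothing activates
  f0 <- tp$field
  f0$coarse$phi[] <- 0
  f0$fine$phi[] <- 0
  a0 <- evaluate_population(f0, pop, wf)
  expect_equal(a0$n_activated, 0L)
})

test_that("profile length mismatches are rejected", {
  par <- membrane_parameters(5.7)
  ax <- test_axon(par)
  wf <- stimulus_waveform()
  expect_error(simulate_axon(ax, rep(0, 5), wf, par), "length")
})
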