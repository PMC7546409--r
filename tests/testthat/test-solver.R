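# small sphere-conductor fixture shared by several solver tests
sphere_fixture <- function(h = 0.4, L = 24, a = 1.5, Rsh = 10, sig0 = 0.3,
                           V0 = 1) {
  n <- round(L / h)
  ctr <- rep(L / 2, 3)
  xs <- (seq_len(n) - 0.5) * h
  r <- sqrt(outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+"),
                  (xs - ctr[3])^2, "+"))
  sigma <- array(sig0, rep(n, 3))
  dmask <- array(0L, rep(n, 3))
  dval <- array(0, rep(n, 3))
  inner <- r <= a
  sigma[inner] <- 1e6
  dmask[inner] <- 1L
  dval[inner] <- V0
  dmask[r >= Rsh] <- 1L
  list(sigma = sigma, dmask = dmask, dval = dval, r = r, h = h, a = a,
       Rsh = Rsh, sig0 = sig0, V0 = V0, inner = inner, n = n)
}

test_that("the solve reproduces the sphere-conductor closed form", {
  fx <- sphere_fixture()
  st <- solver_settings(max_iterations = 4000)
  res <- solve_voxel_potential(fx$sigma, fx$dmask, fx$dval, fx$h, st)
  exact <- function(r) fx$V0 * (1 / r - 1 / fx$Rsh) / (1 / fx$a - 1 / fx$Rsh)
  for (rt in c(3, 5, 8)) {
    i <- which(abs(fx$r - rt) < fx$h / 4)
    expect_lt(abs(mean(res$phi[i]) / exact(rt) - 1), 0.05)
  }
  I <- grid_electrode_current(res$phi, fx$sigma, fx$dmask,
                              array(fx$inner, dim = dim(fx$sigma)), fx$h)
  Iex <- 4 * pi * fx$sig0 * fx$V0 / (1 / (fx$a * 1e-3) - 1 / (fx$Rsh * 1e-3))
  expect_lt(abs(I / Iex - 1), 0.05)
  # conservation against the grounded shell
  shl <- array(fx$r >= fx$Rsh, dim = dim(fx$sigma))
  Ish <- grid_electrode_current(res$phi, fx$sigma, fx$dmask, shl, fx$h)
  expect_lt(abs(I + Ish) / abs(I), 0.01)
  # discrete maximum principle
  free <- fx$dmask == 0
  expect_true(all(res$phi[free] <= fx$V0 + 1e-12))
  expect_true(all(res$phi[free] >= -1e-12))
})

test_that("zero excitation gives an identically zero potential", {
  fx <- sphere_fixture(V0 = 0)
  res <- solve_voxel_potential(fx$sigma, fx$dmask, fx$dval, fx$h,
                               solver_settings())
  expect_true(all(res$phi == 0))
})

test_that("the operator is linear in sigma and in the applied voltage", {
  fx <- sphere_fixture(h = 0.5, L = 16, a = 1.2, Rsh = 7)
  st <- solver_settings(max_iterations = 3000)
  r1 <- solve_voxel_potential(fx$sigma, fx$dmask, fx$dval, fx$h, st)
  r2 <- solve_voxel_potential(2 * fx$sigma, fx$dmask, fx$dval, fx$h, st)
  expect_lt(max(abs(r2$phi - r1$phi), na.rm = TRUE), 1e-6)
  g <- array(fx$inner, dim = dim(fx$sigma))
  I1 <- grid_electrode_current(r1$phi, fx$sigma, fx$dmask, g, fx$h)
  I2 <- grid_electrode_current(r2$phi, 2 * fx$sigma, fx$dmask, g, fx$h)
  expect_lt(abs(I2 / I1 - 2), 1e-6)
  r3 <- solve_voxel_potential(fx$sigma, fx$dmask, 2 * fx$dval, fx$h, st)
  expect_lt(max(abs(r3$phi - 2 * r1$phi), na.rm = TRUE), 1e-6)
})

test_that("a resistive shell around the electrode raises the impedance", {
  fx <- sphere_fixture(h = 0.4, L = 20, a = 1.2, Rsh = 9)
  shellv <- fx$r > fx$a & fx$r <= fx$a + 0.6
  for (senc in c(0.1, 0.05)) {
    sig <- fx$sigma
    sig[shellv] <- senc
    res <- solve_voxel_potential(sig, fx$dmask, fx$dval, fx$h,
                                 solver_settings(max_iterations = 4000))
    I <- grid_electrode_current(res$phi, sig, fx$dmask,
                                array(fx$inner, dim = dim(sig)), fx$h)
    z <- fx$V0 / abs(I)
    if (senc == 0.1) z_ref <- z else expect_gt(z, z_ref)
  }
})

test_that("the pipeline field satisfies Ohm's law and current scaling", {
  tp <- tiny_pipeline()
  f <- tp$field  # scaled to 1 mA
  expect_equal(f$equivalent_current_mA, 1)
  flux <- compute_cathode_flux(f)
  expect_equal(1000 * flux, 1, tolerance = 1e-6)
  expect_equal(compute_eti_impedance(f), f$applied_voltage_V / flux,
               tolerance = 1e-6)
  # doubling the target current doubles the potential pointwise
  f2 <- scale_to_current(f, 2)
  expect_equal(f2$fine$phi, 2 * f$fine$phi, tolerance = 1e-12)
  expect_equal(1000 * compute_cathode_flux(f2), 2, tolerance = 1e-6)
  # identity scaling
  f3 <- scale_to_current(f, f$equivalent_current_mA)
  expect_equal(f3$fine$phi, f$fine$phi, tolerance = 1e-12)
})

test_that("monopolar return current balances the cathode flux", {
  tp <- tiny_pipeline()
  cf <- compute_cathode_flux(tp$field)
  af <- compute_anode_flux(tp$field)  # case return, coarse level
  expect_gt(af, 0)
  expect_lt(abs(af - cf) / cf, 0.02)
})

test_that("bipolar cathode and anode fluxes balance within tolerance", {
  tp <- tiny_pipeline()
  f <- solve_potential(tp$model, tp$lead, named_configuration("4"),
                       fast_settings())
  cf <- compute_cathode_flux(f)
  af <- compute_anode_flux(f)
  expect_lt(abs(af - cf) / cf, 0.02)
})

test_that("a configuration naming a missing contact is rejected", {
  tp <- tiny_pipeline()
  lead <- tp$lead
  lead$contacts <- lead$contacts[lead$contacts$id != "2B", ]
  expect_error(solve_potential(tp$model, lead, named_configuration("1"),
                               fast_settings()),
               "2B")
})

test_that("interpolation outside the solved domain is a bounds error", {
  tp <- tiny_pipeline()
  expect_error(interpolate_field(tp$field, rbind(c(1e3, 0, 0))), "bounds")
})

test_that("field export writes grids and metadata", {
  tp <- tiny_pipeline()
  td <- withr::local_tempdir()
  paths <- write_field(tp$field, file.path(td, "f"))
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[length(paths)])
  expect_equal(meta$equivalent_current_mA, 1)
})
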