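# shared fixtures, built once per test run

.fix <- new.env(parent = emptyenv())

# compact phantom used where the full 60 mm domain is unnecessary
tiny_phantom_spec <- function(voxel = 0.5) {
  phantom_spec(domain_size_mm = c(30, 30, 30), voxel_size_mm = voxel,
               gpe_ellipsoid = list(center = c(15, 15, 15),
                                    semi_axes = c(9, 6.5, 5.5)),
               gpi_ellipsoid = list(center = c(14, 14.5, 14.5),
                                    semi_axes = c(5.5, 3.2, 2.8)),
               lamina_thickness_mm = 1,
               ic_slab = list(point = c(3.5, 15, 15), normal = c(1, 0, 0),
                              thickness = 2),
               optic_tract_cylinder = list(point = c(12, 15, 7),
                                           axis = c(0, 1, 0), radius = 1),
               ventricle_csf = NULL, cistern_csf = NULL, dorsal_white = NULL,
               csf_rim_mm = 1, case_thickness_mm = 0.5)
}

tiny_phantom <- function() {
  if (is.null(.fix$tiny_phantom))
    .fix$tiny_phantom <- build_pallidum_phantom(tiny_phantom_spec())
  .fix$tiny_phantom
}

default_phantom <- function() {
  if (is.null(.fix$default_phantom))
    .fix$default_phantom <- build_pallidum_phantom()
  .fix$default_phantom
}

# fast solver settings for pipeline-level tests (coarse physics, small ROI)
fast_settings <- function() {
  solver_settings(roi_resolution_mm = 0.5, coarse_resolution_mm = 1.5,
                  roi_margin_radial_mm = 5, roi_margin_axial_mm = 3,
                  relative_tolerance = 1e-7)
}

# one placed, rasterized lead plus a solved monopolar field on the tiny
# phantom, reused across solver/axon/VTA tests
tiny_pipeline <- function() {
  if (is.null(.fix$tiny_pipeline)) {
    ph <- tiny_phantom()
    lead <- build_lead(1.5)
    lead <- place_at_target(lead, ph,
                            target_offsets = c(lateral = 2, posterior = 2))
    model <- rasterize_lead(lead, ph)
    field <- solve_potential(model, lead, named_configuration("1"),
                             fast_settings())
    .fix$tiny_pipeline <- list(phantom = ph, lead = lead, model = model,
                               field = scale_to_current(field, 1))
  }
  .fix$tiny_pipeline
}

# straight test axon along +x: compartment kinds and positions
test_axon <- function(params = membrane_parameters(5.7), length_mm = 20,
                      origin = c(0, 0, 0), dir = c(1, 0, 0)) {
  delta <- params$internodal_length_um / 1000
  n_nodes <- floor(length_mm / delta) + 1
  node_s <- (seq_len(n_nodes) - (n_nodes + 1) / 2) * delta
  inter_s <- (node_s[-1] + node_s[-n_nodes]) / 2
  s <- c(rbind(node_s[-n_nodes], inter_s), node_s[n_nodes])
  kinds <- c(rbind(rep(0L, n_nodes - 1), rep(1L, n_nodes - 1)), 0L)
  pos <- sweep(outer(s, dir), 2, origin, "+")
  list(kinds = kinds, positions = pos, s_mm = s, n_nodes = n_nodes)
}

# cathodal point-source extracellular profile (volts at 1 mA) in a uniform
# medium of conductivity sigma
point_source_profile <- function(positions, source_mm, sigma = 0.275) {
  r <- sqrt(rowSums(sweep(positions, 2, source_mm)^2)) * 1e-3
  -1e-3 / (4 * pi * sigma * r)
}
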