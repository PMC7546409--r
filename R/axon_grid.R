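#' Axon grid specification
#'
#' Straight multicompartment axons are laid out on planes perpendicular
#' to the lead, 0.5 mm apart by default; within each plane the axons run
#' parallel with 0.25 mm lateral spacing and the family is replicated at
#' `n_rotations` additional orientations of `rotation_step_deg` each
#' (5 x 30 degrees by default, i.e. six orientation families 0-150
#' degrees; 180 degrees would duplicate 0 for straight fibres). Axons
#' whose line passes through the lead body are removed.
#'
#' `plane_extent_mm` is the lateral width sampled on each side of the
#' lead; `axial_extent_mm` the span of planes along the shaft relative to
#' the contact array (NULL: contact span plus a margin).
#'
#' @param plane_spacing_mm spacing of axonal planes along the shaft, mm.
#' @param axon_spacing_mm lateral spacing between parallel axons, mm.
#' @param n_rotations number of additional orientation families.
#' @param rotation_step_deg rotation between families, degrees.
#' @param axon_length_mm fibre length, mm.
#' @param fiber_diameter_um fibre diameter, um.
#' @param plane_extent_mm lateral extent of the axon sheet, mm.
#' @param axial_extent_mm length-2 vector along the shaft (mm from the
#'   tip) or NULL for automatic.
#' @param axial_margin_mm margin beyond the contact span when
#'   `axial_extent_mm` is NULL.
#' @return An object of class `axon_grid_spec`.
#' @export
axon_grid_spec <- function(plane_spacing_mm = 0.5,
                           axon_spacing_mm = 0.25,
                           n_rotations = 5L,
                           rotation_step_deg = 30,
                           axon_length_mm = 20,
                           fiber_diameter_um = 5.7,
                           plane_extent_mm = 10,
                           axial_extent_mm = NULL,
                           axial_margin_mm = 1.75) {
  stopifnot(plane_spacing_mm > 0, axon_spacing_mm > 0, n_rotations >= 1,
            axon_length_mm > 0, plane_extent_mm > 0)
  structure(list(plane_spacing_mm = plane_spacing_mm,
                 axon_spacing_mm = axon_spacing_mm,
                 n_rotations = as.integer(n_rotations),
                 rotation_step_deg = rotation_step_deg,
                 axon_length_mm = axon_length_mm,
                 fiber_diameter_um = fiber_diameter_um,
                 plane_extent_mm = plane_extent_mm,
                 axial_extent_mm = axial_extent_mm,
                 axial_margin_mm = axial_margin_mm),
            class = "axon_grid_spec")
}

#' Generate the perpendicular-plane axon population
#'
#' @param lead a placed [build_lead()] geometry.
#' @param spec an [axon_grid_spec()].
#' @param params a [membrane_parameters()] supplying the compartment
#'   geometry (defaults to the spec's fibre diameter).
#' @return An object of class `axon_population`: a shared compartment
#'   template (offsets `s_mm` along the axon and `kinds`: 0 node,
#'   1 internode) plus per-axon origins and directions.
#' @export
generate_axon_grid <- function(lead, spec = axon_grid_spec(),
                               params = NULL) {
  params <- params %||% membrane_parameters(spec$fiber_diameter_um)
  fr <- lead_frame(lead)
  delta <- params$internodal_length_um / 1000  # node-to-node, mm
  n_nodes <- floor(spec$axon_length_mm / delta) + 1
  node_s <- (seq_len(n_nodes) - (n_nodes + 1) / 2) * delta
  inter_s <- (node_s[-1] + node_s[-n_nodes]) / 2
  s <- c(rbind(node_s[-n_nodes], inter_s), node_s[n_nodes])
  kinds <- c(rbind(rep(0L, n_nodes - 1), rep(1L, n_nodes - 1)), 0L)

  ax <- spec$axial_extent_mm
  if (is.null(ax))
    ax <- c(min(lead$contacts$axial_lo) - spec$axial_margin_mm,
            max(lead$contacts$axial_hi) + spec$axial_margin_mm)
  t_planes <- seq(ax[1], ax[2], by = spec$plane_spacing_mm)
  angles <- (0:spec$n_rotations) * spec$rotation_step_deg
  offsets <- seq(-spec$plane_extent_mm / 2, spec$plane_extent_mm / 2,
                 by = spec$axon_spacing_mm)
  r_excl <- lead$diameter_mm / 2

  rows <- expand.grid(lateral = seq_along(offsets),
                      orientation = seq_along(angles),
                      plane = seq_along(t_planes))
  keep <- abs(offsets[rows$lateral]) >= r_excl  # line through the lead body
  rows <- rows[keep, , drop = FALSE]
  th <- angles[rows$orientation] * pi / 180
  dirs <- outer(cos(th), fr$e1) + outer(sin(th), fr$e2)
  normals <- outer(-sin(th), fr$e1) + outer(cos(th), fr$e2)
  centers <- t(vapply(t_planes[rows$plane],
                      function(t) lead_point(lead, t), numeric(3)))
  origins <- centers + offsets[rows$lateral] * normals

  structure(list(origins = origins, dirs = dirs,
                 s_mm = s, kinds = kinds,
                 meta = data.frame(axon = seq_len(nrow(rows)),
                                   plane = rows$plane,
                                   orientation = rows$orientation,
                                   lateral_offset_mm = offsets[rows$lateral]),
                 spec = spec, params = params,
                 t_planes = t_planes, angles_deg = angles),
            class = "axon_population")
}

#' @export
print.axon_population <- function(x, ...) {
  cat(sprintf("axon population: %d axons (%d planes x %d orientations), %d compartments each (%d nodes), %.1f um fibres\n",
              nrow(x$origins), length(x$t_planes), length(x$angles_deg),
              length(x$s_mm), sum(x$kinds == 0L),
              x$params$fiber_diameter_um))
  invisible(x)
}

#' Compartment positions of one axon
#'
#' @param population an [generate_axon_grid()] population.
#' @param i axon index.
#' @return n_compartments x 3 matrix of positions (mm).
#' @export
axon_positions <- function(population, i) {
  sweep(outer(population$s_mm, population$dirs[i, ]), 2,
        population$origins[i, ], "+")
}

#' Interpolate a field along an axon
#'
#' Trilinear interpolation of the solved potential at each compartment
#' centre.
#'
#' @param field a solved [solve_potential()] field.
#' @param axon either an n x 3 position matrix or a list with element
#'   `positions`.
#' @return Per-compartment potentials, volts.
#' @export
interpolate_potentials <- function(field, axon) {
  pos <- if (is.matrix(axon)) axon else axon$positions
  interpolate_field(field, pos)
}
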