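#' Membrane and cable parameters for a myelinated axon
#'
#' Double-cable mammalian myelinated fibre in the style of the standard
#' DBS axon model: nodes of Ranvier carry fast Na+, persistent Na+, slow
#' K+ and leak conductances; internodes are passive axolemma beneath a
#' passive myelin sheath with a thin periaxonal space opening to the
#' extracellular medium at the flanking nodes. Diameter-dependent
#' geometry (internodal length, node/axon calibre, lamella count) is
#' linearly interpolated from the published fibre table, which spans
#' 5.7-16 um; smaller calibres (e.g. 4.7 um) extrapolate linearly.
#'
#' @param fiber_diameter_um outer fibre diameter, micrometres.
#' @param celsius temperature, degrees C.
#' @param gnaf,gnap,gks,gl nodal maximum conductances, S/cm^2.
#' @param ena_mV,ek_mV,vrest_mV reversal and resting potentials, mV.
#' @param cn_uF_cm2 nodal membrane capacitance, uF/cm^2.
#' @param rho_axial_ohm_cm,rho_peri_ohm_cm axoplasmic and periaxonal
#'   resistivities, ohm cm.
#' @param gi_S_cm2,ci_uF_cm2 internodal axolemma passive conductance and
#'   capacitance.
#' @param gmy_lamella_S_cm2,cmy_lamella_uF_cm2 conductance/capacitance of
#'   a single myelin lamella membrane (the sheath stacks `2 * lamellae`
#'   membranes in series).
#' @param periaxonal_width_um width of the periaxonal space.
#' @param node_length_um length of a node of Ranvier.
#' @return An object of class `membrane_parameters`.
#' @export
membrane_parameters <- function(fiber_diameter_um = 5.7,
                                celsius = 36,
                                gnaf = 3.0, gnap = 0.01, gks = 0.08,
                                gl = 0.007,
                                ena_mV = 50, ek_mV = -90, vrest_mV = -80,
                                cn_uF_cm2 = 2,
                                rho_axial_ohm_cm = 70,
                                rho_peri_ohm_cm = 70,
                                gi_S_cm2 = 1e-4, ci_uF_cm2 = 2,
                                gmy_lamella_S_cm2 = 1e-3,
                                cmy_lamella_uF_cm2 = 0.1,
                                periaxonal_width_um = 0.004,
                                node_length_um = 1) {
  stopifnot(fiber_diameter_um > 0, gnaf >= 0, gnap >= 0, gks >= 0, gl > 0)
  geo <- fiber_geometry(fiber_diameter_um)
  structure(c(list(fiber_diameter_um = fiber_diameter_um,
                   celsius = celsius,
                   gnaf = gnaf, gnap = gnap, gks = gks, gl = gl,
                   ena_mV = ena_mV, ek_mV = ek_mV, vrest_mV = vrest_mV,
                   cn_uF_cm2 = cn_uF_cm2,
                   rho_axial_ohm_cm = rho_axial_ohm_cm,
                   rho_peri_ohm_cm = rho_peri_ohm_cm,
                   gi_S_cm2 = gi_S_cm2, ci_uF_cm2 = ci_uF_cm2,
                   gmy_lamella_S_cm2 = gmy_lamella_S_cm2,
                   cmy_lamella_uF_cm2 = cmy_lamella_uF_cm2,
                   periaxonal_width_um = periaxonal_width_um,
                   node_length_um = node_length_um),
              geo),
            class = "membrane_parameters")
}

# diameter-dependent fibre geometry, linear inter/extrapolation of the
# published table (diameters in um)
fiber_geometry <- function(d) {
  tab <- data.frame(
    D = c(5.7, 7.3, 8.7, 10, 11.5, 12.8, 14, 15, 16),
    internodal_um = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
    node_diam_um = c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
    axon_diam_um = c(3.4, 4.6, 5.8, 6.9, 8.1, 8.8, 9.2, 9.6, 10.4),
    lamellae = c(80, 100, 110, 120, 130, 135, 140, 145, 150))
  interp <- function(y) {
    if (d >= min(tab$D) && d <= max(tab$D))
      return(approx(tab$D, y, xout = d)$y)
    # linear extrapolation on the nearest segment
    if (d < min(tab$D)) i <- 1:2 else i <- (nrow(tab) - 1):nrow(tab)
    slope <- diff(y[i]) / diff(tab$D[i])
    y[i[1]] + slope * (d - tab$D[i[1]])
  }
  list(internodal_length_um = interp(tab$internodal_um),
       node_diameter_um = interp(tab$node_diam_um),
       axon_diameter_um = interp(tab$axon_diam_um),
       lamellae = max(interp(tab$lamellae), 1))
}

# absolute electrical quantities for one axon (units: mS, uF), given the
# compartment kinds produced by generate_axon_grid()
axon_electrics <- function(kinds, params) {
  nc <- length(kinds)
  ln <- params$node_length_um
  li <- params$internodal_length_um - ln
  dn <- params$node_diameter_um
  da <- params$axon_diameter_um
  um2_to_cm2 <- 1e-8
  area <- ifelse(kinds == 0L, pi * dn * ln, pi * da * li) * um2_to_cm2
  Cm <- ifelse(kinds == 0L, params$cn_uF_cm2, params$ci_uF_cm2) * area
  Gi <- ifelse(kinds == 0L, 0, params$gi_S_cm2 * area * 1000)
  nl2 <- 2 * params$lamellae
  Cmy <- ifelse(kinds == 0L, 0, params$cmy_lamella_uF_cm2 / nl2 * area)
  Gmy <- ifelse(kinds == 0L, 0, params$gmy_lamella_S_cm2 / nl2 * area * 1000)
  # periaxonal end conductance (internode centre to each flanking node)
  Ap <- pi * da * params$periaxonal_width_um            # um^2 annulus
  Rp <- params$rho_peri_ohm_cm * (li / 2) / Ap * 1e4    # ohms
  Gp <- ifelse(kinds == 0L, 0, 1 / Rp * 1000)
  # axial conductances between successive compartment centres
  halfR <- function(k) {
    l <- if (k == 0L) ln else li
    dd <- if (k == 0L) dn else da
    params$rho_axial_ohm_cm * (l / 2) / (pi * (dd / 2)^2) * 1e4  # ohms
  }
  hr <- vapply(kinds, halfR, numeric(1))
  Gax <- 1000 / (hr[-nc] + hr[-1])
  chan <- function(g) ifelse(kinds == 0L, g * area * 1000, 0)
  list(Cm_uF = Cm, Gax_mS = Gax, Gi_mS = Gi, Cmy_uF = Cmy, Gmy_mS = Gmy,
       Gp_mS = Gp,
       gnaf_mS = chan(params$gnaf), gnap_mS = chan(params$gnap),
       gks_mS = chan(params$gks), gl_mS = chan(params$gl),
       ena_mV = params$ena_mV, ek_mV = params$ek_mV,
       vrest_mV = params$vrest_mV, celsius = params$celsius)
}
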