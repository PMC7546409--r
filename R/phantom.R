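#' Specification of the synthetic pallidal phantom
#'
#' Describes a voxelized head region emulating the heterogeneous anatomy
#' around the globus pallidus: nested GPe/GPi ellipsoids separated by a
#' medial medullary lamina shell, an internal-capsule slab medial to the
#' pallidum, an optic-tract cylinder ventral to it, cerebrospinal-fluid
#' compartments standing in for the lateral/third ventricles and the basal
#' cisterns, a dorsal white-matter cap, a subarachnoid CSF rim, and an
#' outer case/epidermis shell that acts as the monopolar current return.
#' All coordinates are millimetres in the model frame (+x lateral,
#' +y anterior, +z dorsal).
#'
#' The defaults approximate adult pallidal scale: a GPe of semi-axes
#' 10.5 x 7.3 x 6.3 mm and a GPi of 7 x 4.2 x 3.6 mm (approx. 440 mm^3) displaced ventromedially,
#' a 1 mm lamina, the internal capsule ~1.5 mm medial to the GPi border,
#' the optic tract ~3 mm below the ventral GPi border, ventricular CSF
#' ~12 mm dorsomedial and cisternal CSF ~6 mm ventral of the GPi.
#'
#' @param domain_size_mm extent of the rectangular domain (3-vector, mm).
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param gpe_ellipsoid,gpi_ellipsoid lists with `center` (mm) and
#'   `semi_axes` (mm); axis-aligned.
#' @param lamina_thickness_mm thickness of the medullary lamina shell
#'   around the GPi (mm); 0 suppresses the lamina.
#' @param ic_slab internal capsule as a slab: list with `point`, unit
#'   `normal` and `thickness` (mm).
#' @param optic_tract_cylinder list with `point`, unit `axis`, `radius`.
#' @param ventricle_csf,cistern_csf,dorsal_white axis-aligned boxes given
#'   as lists of `xrange`/`yrange`/`zrange` (any may be NULL to span the
#'   domain); set to NULL to omit the structure.
#' @param csf_rim_mm thickness of the subarachnoid CSF layer inside the
#'   case shell.
#' @param case_thickness_mm thickness of the outer case shell.
#' @param rng_seed integer; the construction is deterministic, the seed is
#'   recorded for provenance.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(domain_size_mm = c(60, 60, 60),
                         voxel_size_mm = 0.5,
                         gpe_ellipsoid = list(center = c(28, 30, 30),
                                              semi_axes = c(10.5, 7.3, 6.3)),
                         gpi_ellipsoid = list(center = c(26.5, 29, 29),
                                              semi_axes = c(7, 4.2, 3.6)),
                         lamina_thickness_mm = 1,
                         ic_slab = list(point = c(16, 30, 30),
                                        normal = c(1, 0, 0),
                                        thickness = 3),
                         optic_tract_cylinder = list(point = c(23, 30, 21.5),
                                                     axis = c(0, 1, 0),
                                                     radius = 1.5),
                         ventricle_csf = list(xrange = c(8, 15),
                                              yrange = c(12, 48),
                                              zrange = c(40, 48)),
                         cistern_csf = list(xrange = c(6, 30),
                                            yrange = NULL,
                                            zrange = c(17, 20)),
                         dorsal_white = list(xrange = NULL, yrange = NULL,
                                             zrange = c(44, 56)),
                         csf_rim_mm = 2,
                         case_thickness_mm = 1,
                         rng_seed = 1L) {
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be > 0")
  if (lamina_thickness_mm < 0) stop("lamina_thickness_mm must be >= 0")
  spec <- structure(
    list(domain_size_mm = as.numeric(domain_size_mm),
         voxel_size_mm = voxel_size_mm,
         gpe_ellipsoid = gpe_ellipsoid,
         gpi_ellipsoid = gpi_ellipsoid,
         lamina_thickness_mm = lamina_thickness_mm,
         ic_slab = ic_slab,
         optic_tract_cylinder = optic_tract_cylinder,
         ventricle_csf = ventricle_csf,
         cistern_csf = cistern_csf,
         dorsal_white = dorsal_white,
         csf_rim_mm = csf_rim_mm,
         case_thickness_mm = case_thickness_mm,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec")
  spec
}

check_inside_domain <- function(lo, hi, dom, what) {
  if (any(lo < 0) || any(hi > dom))
    stop("geometry error: structure '", what, "' exceeds the domain")
}

#' Build the synthetic pallidal phantom
#'
#' Rasterizes the structures of a [phantom_spec()] into a labelled voxel
#' grid. Every voxel gets exactly one label; precedence runs
#' case > CSF rim > GPi > lamina > GPe > internal capsule > optic tract >
#' ventricular CSF > cisternal CSF > dorsal white matter > grey-matter
#' background. Construction is deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return A [tissue_model()] with the default conductivity table.
#' @export
build_pallidum_phantom <- function(spec = phantom_spec()) {
  h <- spec$voxel_size_mm
  dom <- spec$domain_size_mm
  dm <- as.integer(round(dom / h))
  if (any(dm < 2)) stop("domain too small for the voxel size")
  xs <- axis_centers(dm[1], h)
  ys <- axis_centers(dm[2], h)
  zs <- axis_centers(dm[3], h)

  gpe <- spec$gpe_ellipsoid
  gpi <- spec$gpi_ellipsoid
  lam <- spec$lamina_thickness_mm
  check_inside_domain(gpe$center - gpe$semi_axes, gpe$center + gpe$semi_axes,
                      dom, "GPe")
  check_inside_domain(gpi$center - gpi$semi_axes - lam,
                      gpi$center + gpi$semi_axes + lam, dom, "GPi")
  ot <- spec$optic_tract_cylinder
  check_inside_domain(ot$point - ot$radius, ot$point + ot$radius, dom,
                      "optic tract")

  # squared normalised ellipsoid coordinate, evaluated separably
  ell_q <- function(e, grow = 0) {
    qx <- ((xs - e$center[1]) / (e$semi_axes[1] + grow))^2
    qy <- ((ys - e$center[2]) / (e$semi_axes[2] + grow))^2
    qz <- ((zs - e$center[3]) / (e$semi_axes[3] + grow))^2
    outer(outer(qx, qy, "+"), qz, "+")
  }
  in_box <- function(b) {
    fx <- if (is.null(b$xrange)) rep(TRUE, dm[1]) else xs >= b$xrange[1] & xs <= b$xrange[2]
    fy <- if (is.null(b$yrange)) rep(TRUE, dm[2]) else ys >= b$yrange[1] & ys <= b$yrange[2]
    fz <- if (is.null(b$zrange)) rep(TRUE, dm[3]) else zs >= b$zrange[1] & zs <= b$zrange[2]
    outer(outer(fx, fy, "&"), fz, "&")
  }

  lab <- array(pallidal_labels[["grey_matter"]], dim = dm)

  if (!is.null(spec$dorsal_white))
    lab[in_box(spec$dorsal_white)] <- pallidal_labels[["white_matter"]]
  if (!is.null(spec$cistern_csf))
    lab[in_box(spec$cistern_csf)] <- pallidal_labels[["csf"]]
  if (!is.null(spec$ventricle_csf))
    lab[in_box(spec$ventricle_csf)] <- pallidal_labels[["csf"]]

  # optic tract: infinite cylinder clipped to the domain
  otaxis <- unit3(ot$axis, "optic tract axis")
  px <- outer(outer(xs - ot$point[1], rep(1, dm[2])), rep(1, dm[3]))
  py <- outer(outer(rep(1, dm[1]), ys - ot$point[2]), rep(1, dm[3]))
  pz <- outer(outer(rep(1, dm[1]), rep(1, dm[2])), zs - ot$point[3])
  dotv <- px * otaxis[1] + py * otaxis[2] + pz * otaxis[3]
  r2 <- (px - dotv * otaxis[1])^2 + (py - dotv * otaxis[2])^2 +
        (pz - dotv * otaxis[3])^2
  lab[r2 <= ot$radius^2] <- pallidal_labels[["optic_tract"]]

  # internal capsule slab
  ic <- spec$ic_slab
  icn <- unit3(ic$normal, "internal capsule normal")
  dist <- (px + ot$point[1] - ic$point[1]) * icn[1] +
          (py + ot$point[2] - ic$point[2]) * icn[2] +
          (pz + ot$point[3] - ic$point[3]) * icn[3]
  lab[abs(dist) <= ic$thickness / 2] <- pallidal_labels[["internal_capsule"]]
  rm(px, py, pz, dotv, r2, dist)

  lab[ell_q(gpe) <= 1] <- pallidal_labels[["gpe"]]
  if (lam > 0)
    lab[ell_q(gpi, grow = lam) <= 1] <- pallidal_labels[["lamina"]]
  lab[ell_q(gpi) <= 1] <- pallidal_labels[["gpi"]]

  # subarachnoid CSF rim and the outer case shell
  case_vox <- max(1L, as.integer(round(spec$case_thickness_mm / h)))
  rim_vox <- as.integer(round(spec$csf_rim_mm / h))
  ii <- slice.index(lab, 1)
  jj <- slice.index(lab, 2)
  kk <- slice.index(lab, 3)
  edge <- pmin(ii - 1L, dm[1] - ii, jj - 1L, dm[2] - jj, kk - 1L, dm[3] - kk)
  if (rim_vox > 0)
    lab[edge < case_vox + rim_vox] <- pallidal_labels[["csf"]]
  lab[edge < case_vox] <- pallidal_labels[["case"]]

  tissue_model(lab, voxel_size_mm = h, origin_mm = c(0, 0, 0))
}
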