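#' Solver settings
#'
#' Controls the two-level composite solve: a coarse full-domain grid
#' provides far-field boundary values for a refined region of interest
#' (ROI) around the contact array. Convergence follows the iterative
#' residual: relative 1e-8 or absolute 1e-10 by default.
#'
#' @param relative_tolerance,absolute_tolerance PCG convergence criteria.
#' @param max_iterations iteration cap; exceeding it is a solver error.
#' @param roi_bounds_mm optional list(lo =, hi =) box for the refined
#'   region; NULL derives it from the contact array plus margins.
#' @param roi_resolution_mm refined-grid voxel edge (mm).
#' @param electrode_resolution_mm optional still finer edge used only to
#'   rasterize the contacts on the refined grid (NULL: same as ROI).
#' @param coarse_resolution_mm coarse full-domain voxel edge (mm).
#' @param roi_margin_radial_mm,roi_margin_axial_mm margins around the
#'   contact array when deriving the ROI box.
#' @param frequency_hz stimulus frequency (carried for metadata; the
#'   operator is purely resistive).
#' @param applied_voltage_V Dirichlet cathode magnitude for the solve.
#' @param refine logical; FALSE solves the coarse level only.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(relative_tolerance = 1e-8,
                            absolute_tolerance = 1e-10,
                            max_iterations = 20000L,
                            roi_bounds_mm = NULL,
                            roi_resolution_mm = 0.25,
                            electrode_resolution_mm = NULL,
                            coarse_resolution_mm = 1,
                            roi_margin_radial_mm = 8,
                            roi_margin_axial_mm = 6,
                            frequency_hz = 130,
                            applied_voltage_V = 1,
                            refine = TRUE) {
  if (relative_tolerance <= 0 || absolute_tolerance <= 0)
    stop("tolerances must be > 0")
  if (!is.null(electrode_resolution_mm) &&
      electrode_resolution_mm > roi_resolution_mm)
    stop("electrode_resolution_mm must be <= roi_resolution_mm")
  if (roi_resolution_mm > coarse_resolution_mm)
    stop("roi_resolution_mm must be <= coarse_resolution_mm")
  structure(list(relative_tolerance = relative_tolerance,
                 absolute_tolerance = absolute_tolerance,
                 max_iterations = as.integer(max_iterations),
                 roi_bounds_mm = roi_bounds_mm,
                 roi_resolution_mm = roi_resolution_mm,
                 electrode_resolution_mm = electrode_resolution_mm,
                 coarse_resolution_mm = coarse_resolution_mm,
                 roi_margin_radial_mm = roi_margin_radial_mm,
                 roi_margin_axial_mm = roi_margin_axial_mm,
                 frequency_hz = frequency_hz,
                 applied_voltage_V = applied_voltage_V,
                 refine = refine),
            class = "solver_settings")
}

#' Low-level potential solve on a conductivity grid
#'
#' Solves the discrete quasi-static problem div(sigma grad phi) = 0 with
#' cell-centred finite volumes, harmonic face conductivities, fixed
#' potentials where `dirichlet_mask` is TRUE and zero normal current on
#' the outer box. Voxels with sigma = 0 are perfect insulators and are
#' excluded (phi = NA there).
#'
#' @param sigma 3-D conductivity array, S/m.
#' @param dirichlet_mask logical/integer array marking clamped voxels.
#' @param dirichlet_values array of clamped potentials, volts.
#' @param voxel_size_mm voxel edge (mm).
#' @param settings a [solver_settings()].
#' @return list with `phi` (volts), `iterations`, `relative_residual`,
#'   `converged`.
#' @export
solve_voxel_potential <- function(sigma, dirichlet_mask, dirichlet_values,
                                  voxel_size_mm,
                                  settings = solver_settings()) {
  dm <- dim(sigma)
  res <- cpp_fd_solve(as.numeric(sigma), as.integer(dm),
                      as.integer(dirichlet_mask != 0),
                      as.numeric(dirichlet_values),
                      settings$relative_tolerance,
                      settings$absolute_tolerance,
                      settings$max_iterations)
  if (!res$converged)
    stop(sprintf("solver error: no convergence in %d iterations (relative residual %.3g)",
                 settings$max_iterations, res$relative_residual))
  res$voxel_size_mm <- voxel_size_mm
  res
}

#' Current through a Dirichlet electrode group
#'
#' Face-summed current (amperes) leaving the clamped voxels selected by
#' `group_mask`; positive when the group acts as an anode.
#'
#' @inheritParams solve_voxel_potential
#' @param phi solved potential array, volts.
#' @param group_mask logical array selecting the electrode voxels.
#' @export
grid_electrode_current <- function(phi, sigma, dirichlet_mask, group_mask,
                                   voxel_size_mm) {
  cpp_dirichlet_flux(as.numeric(phi), as.numeric(sigma),
                     as.integer(dim(sigma)),
                     as.integer(dirichlet_mask != 0),
                     as.logical(group_mask), voxel_size_mm)
}

# fill excluded (NA) voxels with the nearest solved value so that
# trilinear interpolation next to the lead body stays finite
fill_na_nearest <- function(arr) {
  dm <- dim(arr)
  shift <- function(a, ax, by) {
    n <- dm[ax]
    src <- if (by > 0) 1:(n - by) else (1 - by):n
    dst <- if (by > 0) (1 + by):n else 1:(n + by)
    out <- array(NA_real_, dm)
    isrc <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    idst <- isrc
    isrc[[ax]] <- src
    idst[[ax]] <- dst
    out[idst[[1]], idst[[2]], idst[[3]]] <- a[isrc[[1]], isrc[[2]], isrc[[3]]]
    out
  }
  while (anyNA(arr)) {
    na <- is.na(arr)
    acc <- array(0, dm)
    cnt <- array(0L, dm)
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      s <- shift(arr, ax, by)
      ok <- na & !is.na(s)
      acc[ok] <- acc[ok] + s[ok]
      cnt[ok] <- cnt[ok] + 1L
    }
    fillable <- na & cnt > 0L
    if (!any(fillable)) break
    arr[fillable] <- acc[fillable] / cnt[fillable]
  }
  arr
}

# labels sampled from a tissue model onto an arbitrary grid (nearest voxel),
# with the lead re-rasterized analytically at that grid's resolution
grid_labels_for_solve <- function(model, lead, dm, h, origin) {
  base <- attr(model, "base_label_grid") %||% model$label_grid
  bdm <- dim(base)
  xs <- pmin(pmax(floor((axis_centers(dm[1], h, origin[1]) - model$origin_mm[1]) /
                        model$voxel_size_mm) + 1, 1), bdm[1])
  ys <- pmin(pmax(floor((axis_centers(dm[2], h, origin[2]) - model$origin_mm[2]) /
                        model$voxel_size_mm) + 1, 1), bdm[2])
  zs <- pmin(pmax(floor((axis_centers(dm[3], h, origin[3]) - model$origin_mm[3]) /
                        model$voxel_size_mm) + 1, 1), bdm[3])
  lab <- base[xs, ys, zs, drop = FALSE]
  if (!is.null(lead)) {
    ras <- classify_lead_voxels(lead, dm, h, origin)
    lab[ras != 0L] <- ras[ras != 0L]
  }
  lab
}

sigma_from_labels <- function(lab, tab, exclude_labels = integer()) {
  maxl <- max(tab$label, lab, 1L)
  lut <- numeric(maxl + 1L)
  lut[tab$label + 1L] <- tab$sigma_S_per_m
  if (length(exclude_labels)) lut[exclude_labels + 1L] <- 0
  arr <- lut[lab + 1L]
  dim(arr) <- dim(lab)
  arr
}

build_level <- function(model, lead, config, dm, h, origin, v0,
                        full_domain = FALSE) {
  lab <- grid_labels_for_solve(model, lead, dm, h, origin)
  # the case return is the outermost labelled shell; a coarse grid can
  # lose a thin shell to nearest-sampling, so reimpose it on full-domain
  # levels
  if (full_domain && any(model$label_grid == pallidal_labels[["case"]])) {
    cs <- pallidal_labels[["case"]]
    lab[c(1, dm[1]), , ] <- cs
    lab[, c(1, dm[2]), ] <- cs
    lab[, , c(1, dm[3])] <- cs
  }
  cath_lab <- contact_label(config$cathodes)
  an_lab <- if (identical(config$anodes, "CASE"))
    pallidal_labels[["case"]] else contact_label(config$anodes)
  # a coarse grid can miss a thin contact shell entirely; fall back to
  # marking the voxels containing sample points on the contact surface
  active_ids <- c(config$cathodes,
                  if (!identical(config$anodes, "CASE")) config$anodes)
  if (!is.null(lead)) {
    for (id in active_ids) {
      cl <- contact_label(id)
      if (any(lab == cl)) next
      pts <- contact_surface_points(lead, id)
      idx <- point_to_index(pts, dm, h, origin)
      idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
      if (nrow(idx)) lab[unique(linear_index(idx, dm))] <- cl
    }
  }
  active <- c(cath_lab, an_lab)
  inactive_metal <- setdiff(21L:28L, active)
  sig <- sigma_from_labels(lab, model$conductivity_table,
                           exclude_labels = inactive_metal)
  cath <- lab %in% cath_lab
  an <- lab %in% an_lab
  dim(cath) <- dim(an) <- dm
  dmask <- cath | an
  dval <- array(0, dm)
  dval[cath] <- -v0
  list(lab = lab, sigma = sig, dmask = dmask, dval = dval, cath = cath,
       an = an, h = h, origin = origin, dim = dm)
}

#' Solve the quasi-static potential for a stimulation configuration
#'
#' Two-level composite solve of `div(sigma grad phi) = 0` on the
#' heterogeneous voxel model: cathode contacts clamped to
#' `-applied_voltage_V` (co-activated cathodes share the potential),
#' anode contacts or the outer case shell clamped to 0 V, zero normal
#' current on the bounding box. A coarse full-domain solve supplies
#' Dirichlet boundary values for the refined ROI around the contacts,
#' where the lead is re-rasterized at the ROI resolution. The cathode
#' current flux, electrode-tissue-interface (ETI) impedance and
#' equivalent delivered current are computed from the refined solution.
#'
#' @param model a rasterized [tissue_model()] containing the lead labels.
#' @param lead the placed [build_lead()] geometry (defaults to the lead
#'   recorded by [rasterize_lead()]).
#' @param config a [stim_configuration()].
#' @param settings a [solver_settings()].
#' @return An object of class `potential_field`.
#' @export
solve_potential <- function(model, lead = NULL, config,
                            settings = solver_settings()) {
  lead <- lead %||% attr(model, "lead")
  if (is.null(lead)) stop("no lead geometry: rasterize a lead or pass one")
  ids <- lead$contacts$id
  bad <- setdiff(c(config$cathodes,
                   if (!identical(config$anodes, "CASE")) config$anodes),
                 ids)
  if (length(bad))
    stop("configuration references contacts absent from the lead: ",
         paste(bad, collapse = ", "))
  v0 <- settings$applied_voltage_V
  h0 <- model$voxel_size_mm
  dm0 <- dim(model$label_grid)

  # coarse level on the full domain
  hc <- max(settings$coarse_resolution_mm, h0)
  dmc <- pmax(as.integer(floor(dm0 * h0 / hc)), 2L)
  coarse <- build_level(model, lead, config, dmc, hc, model$origin_mm, v0,
                        full_domain = TRUE)
  sc <- solve_voxel_potential(coarse$sigma, coarse$dmask, coarse$dval, hc,
                              settings)
  coarse$phi <- fill_na_nearest(sc$phi)
  coarse$iterations <- sc$iterations

  fine <- NULL
  if (isTRUE(settings$refine) && settings$roi_resolution_mm < hc) {
    hf <- settings$roi_resolution_mm
    if (is.null(settings$roi_bounds_mm)) {
      t_lo <- min(lead$contacts$axial_lo) - settings$roi_margin_axial_mm
      t_hi <- max(lead$contacts$axial_hi) + settings$roi_margin_axial_mm
      p_lo <- lead_point(lead, t_lo)
      p_hi <- lead_point(lead, t_hi)
      mr <- settings$roi_margin_radial_mm + lead$diameter_mm / 2 +
        lead$encapsulation_thickness_mm
      lo <- pmin(p_lo, p_hi) - mr
      hi <- pmax(p_lo, p_hi) + mr
    } else {
      lo <- settings$roi_bounds_mm$lo
      hi <- settings$roi_bounds_mm$hi
    }
    dom_lo <- model$origin_mm
    dom_hi <- model$origin_mm + dm0 * h0
    lo <- pmax(lo, dom_lo + h0)
    hi <- pmin(hi, dom_hi - h0)
    origin_f <- dom_lo + floor((lo - dom_lo) / hf) * hf
    dmf <- as.integer(ceiling((hi - origin_f) / hf))
    fine <- build_level(model, lead, config, dmf, hf, origin_f, v0)
    i_coarse <- abs(grid_electrode_current(coarse$phi, coarse$sigma,
                                           coarse$dmask, coarse$cath, hc))
    if (identical(config$anodes, "CASE")) {
      # Monopolar: current leaves the ROI toward the case return, so the
      # ROI boundary shell takes interpolated coarse potentials. The
      # coarse electrodes are geometrically fatter than the refined
      # ones, so the raw coarse solution carries more current than the
      # ROI solve delivers; since the far field of a source scales with
      # its current, the coarse field is rescaled to the self-consistent
      # ROI cathode flux. The ROI flux is affine in the boundary scale,
      # so two evaluations determine the fixed point exactly.
      shell <- array(FALSE, dmf)
      shell[c(1, dmf[1]), , ] <- TRUE
      shell[, c(1, dmf[2]), ] <- TRUE
      shell[, , c(1, dmf[3])] <- TRUE
      shell <- shell & fine$sigma > 0 & !fine$dmask
      sidx <- which(shell, arr.ind = TRUE)
      pts <- sweep((sidx - 0.5) * hf, 2, origin_f, "+")
      fine$dmask <- fine$dmask | shell
      bvals <- trilinear(coarse$phi, hc, coarse$origin, pts)
      solve_roi <- function(s) {
        dv <- fine$dval
        dv[shell] <- s * bvals
        sf <- solve_voxel_potential(fine$sigma, fine$dmask, dv, hf,
                                    settings)
        fine$dval <<- dv
        fine$phi <<- fill_na_nearest(sf$phi)
        fine$iterations <<- (fine$iterations %||% 0L) + sf$iterations
        abs(grid_electrode_current(fine$phi, fine$sigma, fine$dmask,
                                   fine$cath, hf))
      }
      i1 <- solve_roi(1)
      s_star <- 1
      if (i_coarse > 0 && i1 > 0 && abs(i1 / i_coarse - 1) > 0.02) {
        s2 <- i1 / i_coarse
        i2 <- solve_roi(s2)
        k <- (i2 - i1) / (s2 - 1)
        s_star <- (i1 - k) / (i_coarse - k)
        solve_roi(s_star)
      }
    } else {
      # Bipolar: in net, no current crosses a distant boundary, so the
      # ROI outer box is left as a natural zero-flux boundary and every
      # streamline closes on the anode contacts inside the ROI
      # (conservation is then exact on the refined grid).
      sf <- solve_voxel_potential(fine$sigma, fine$dmask, fine$dval, hf,
                                  settings)
      fine$phi <- fill_na_nearest(sf$phi)
      fine$iterations <- sf$iterations
      i1 <- abs(grid_electrode_current(fine$phi, fine$sigma, fine$dmask,
                                       fine$cath, hf))
      s_star <- if (i_coarse > 0) i1 / i_coarse else 1
    }
    coarse$phi <- coarse$phi * s_star
    coarse$far_field_scale <- s_star
  }

  lev <- fine %||% coarse
  for (id in config$cathodes)
    if (!any(lev$lab == contact_label(id)))
      stop("consistency error: contact ", id,
           " has no voxels on the solve grid")
  flux <- grid_electrode_current(lev$phi, lev$sigma, lev$dmask, lev$cath,
                                 lev$h)
  field <- structure(
    list(applied_voltage_V = v0,
         cathode_flux_A = abs(flux),
         eti_impedance_ohm = if (flux != 0) v0 / abs(flux) else Inf,
         equivalent_current_mA = abs(flux) * 1000,
         config = config, lead = lead,
         coarse = coarse, fine = fine,
         settings = settings),
    class = "potential_field")
  field
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("potential field, configuration %s: V = %.4g V, cathode flux %.4g mA, ETI %.0f ohm, equivalent current %.4g mA\n",
              x$config$name, x$applied_voltage_V,
              1000 * x$cathode_flux_A, x$eti_impedance_ohm,
              x$equivalent_current_mA))
  invisible(x)
}

#' Cathode current flux
#'
#' Magnitude of the current delivered through the cathode contact
#' boundary (surface integral of -sigma grad phi over the cathode faces).
#'
#' @param field a solved [solve_potential()] field.
#' @return Current in amperes (positive magnitude).
#' @export
compute_cathode_flux <- function(field) {
  lev <- field$fine %||% field$coarse
  if (is.null(lev$phi)) stop("state error: field has not been solved")
  abs(grid_electrode_current(lev$phi, lev$sigma, lev$dmask, lev$cath, lev$h))
}

#' Anode / return current flux (signed, positive = anodic)
#'
#' Uses the refined grid when the anode contacts lie inside the ROI,
#' otherwise the coarse grid (monopolar case return).
#' @rdname compute_cathode_flux
#' @export
compute_anode_flux <- function(field) {
  lev <- field$fine %||% field$coarse
  if (is.null(lev$phi)) stop("state error: field has not been solved")
  if (!any(lev$an)) lev <- field$coarse
  grid_electrode_current(lev$phi, lev$sigma, lev$dmask, lev$an, lev$h)
}

#' Electrode-tissue-interface impedance
#'
#' Applied voltage divided by the cathode current flux.
#'
#' @param field a solved [solve_potential()] field.
#' @return Impedance in ohms.
#' @export
compute_eti_impedance <- function(field) {
  flux <- field$cathode_flux_A
  if (!is.finite(flux) || flux == 0)
    stop("arithmetic error: zero cathode flux")
  field$applied_voltage_V / flux
}

#' Rescale a solved field to a target current
#'
#' Multiplies the potential everywhere by
#' `target_mA / (1000 * cathode_flux_A)`; exact by linearity of the
#' operator.
#'
#' @param field a solved [solve_potential()] field.
#' @param target_mA requested equivalent current, mA.
#' @return The rescaled `potential_field`.
#' @export
scale_to_current <- function(field, target_mA) {
  flux <- field$cathode_flux_A
  if (!is.finite(flux) || flux == 0)
    stop("arithmetic error: zero cathode flux")
  s <- target_mA / (1000 * flux)
  field$coarse$phi <- field$coarse$phi * s
  field$coarse$dval <- field$coarse$dval * s
  if (!is.null(field$fine)) {
    field$fine$phi <- field$fine$phi * s
    field$fine$dval <- field$fine$dval * s
  }
  field$applied_voltage_V <- field$applied_voltage_V * s
  field$cathode_flux_A <- field$cathode_flux_A * s
  field$equivalent_current_mA <- target_mA
  field
}

#' Interpolate the potential at arbitrary points
#'
#' Trilinear interpolation, using the refined ROI block where the point
#' lies inside it and the coarse grid elsewhere.
#'
#' @param field a solved [solve_potential()] field.
#' @param points n x 3 matrix of positions (mm).
#' @return Potentials in volts.
#' @export
interpolate_field <- function(field, points) {
  points <- rbind(points)
  out <- rep(NA_real_, nrow(points))
  cg <- field$coarse
  okc <- in_grid_interior(points, cg$dim, cg$h, cg$origin)
  if (any(!okc))
    stop("bounds error: ", sum(!okc), " point(s) outside the solved domain")
  out <- trilinear(cg$phi, cg$h, cg$origin, points)
  fg <- field$fine
  if (!is.null(fg)) {
    okf <- in_grid_interior(points, fg$dim, fg$h, fg$origin)
    if (any(okf))
      out[okf] <- trilinear(fg$phi, fg$h, fg$origin,
                            points[okf, , drop = FALSE])
  }
  out
}

#' Export a solved field
#'
#' Writes the coarse (and refined, if present) potential grids as NIfTI
#' volumes with a JSON sidecar holding grid metadata, impedance and
#' current scaling.
#'
#' @param field a solved [solve_potential()] field.
#' @param path_prefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_field <- function(field, path_prefix) {
  paths <- character()
  for (levname in c("coarse", "fine")) {
    lev <- field[[levname]]
    if (is.null(lev)) next
    p <- paste0(path_prefix, "_", levname, ".nii.gz")
    arr <- lev$phi
    attr(arr, "pixdim") <- rep(lev$h, 3)
    RNifti::writeNifti(RNifti::asNifti(arr), p)
    paths <- c(paths, p)
  }
  meta <- list(applied_voltage_V = field$applied_voltage_V,
               cathode_flux_A = field$cathode_flux_A,
               eti_impedance_ohm = field$eti_impedance_ohm,
               equivalent_current_mA = field$equivalent_current_mA,
               configuration = field$config$name,
               coarse = list(h_mm = field$coarse$h,
                             origin_mm = field$coarse$origin,
                             dim = field$coarse$dim),
               fine = if (!is.null(field$fine))
                 list(h_mm = field$fine$h, origin_mm = field$fine$origin,
                      dim = field$fine$dim))
  jp <- paste0(path_prefix, "_field.json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
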