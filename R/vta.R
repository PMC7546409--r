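#' Bound API sites into a volume of tissue activated
#'
#' Direct bounding of the action-potential initiation sites: the point
#' set is enclosed by either its 3-D convex hull (`mode = "hull"`) or an
#' alpha bounding volume (`mode = "alpha"`, the default): a morphological
#' closing of the sites with a ball of radius `alpha`, intersected with
#' the convex hull. The closing captures concavity at the scale the axon
#' sampling supports (default `alpha` = twice the axonal plane spacing)
#' and is always contained in the hull, so hull-mode volume bounds
#' alpha-mode volume from above. The interior is voxelized at
#' `voxel_size_mm` on a lattice anchored at `grid_origin_mm`, so masks
#' align with a tissue model sharing that origin and voxel size.
#'
#' Fewer than four non-coplanar sites give a degenerate zero-volume
#' result with `degenerate = TRUE`.
#'
#' @param activation an [evaluate_population()] result, or an n x 3
#'   matrix of API positions (mm).
#' @param voxel_size_mm voxelization edge length, mm.
#' @param mode "alpha" or "hull".
#' @param alpha closing radius, mm (default: 2 x plane spacing when
#'   known, else 1).
#' @param grid_origin_mm lattice anchor (use the tissue model's origin).
#' @return An object of class `vta_result`.
#' @export
build_vta <- function(activation, voxel_size_mm = 0.5,
                      mode = c("alpha", "hull"), alpha = NULL,
                      grid_origin_mm = c(0, 0, 0)) {
  mode <- match.arg(mode)
  pts <- if (is.matrix(activation)) activation else activation$api_sites_mm
  if (is.null(alpha)) {
    ps <- if (is.matrix(activation)) NULL else activation$plane_spacing_mm
    alpha <- 2 * (ps %||% 0.5)
  }
  h <- voxel_size_mm
  empty <- function(flag) {
    structure(list(mask = array(FALSE, c(1, 1, 1)), voxel_size_mm = h,
                   origin_mm = grid_origin_mm, mode = mode, alpha_mm = alpha,
                   total_volume_mm3 = 0, hull_volume_mm3 = 0,
                   n_api = if (is.null(pts)) 0L else nrow(pts),
                   degenerate = flag,
                   sub_volumes_mm3 = NULL, percentages = NULL),
              class = "vta_result")
  }
  if (is.null(pts) || nrow(pts) == 0L) return(empty(FALSE))
  if (nrow(pts) < 4L) return(empty(TRUE))

  # degeneracy is judged on the raw points; the jittered copy only makes
  # the hull construction robust on lattice-like inputs
  if (!isTRUE(cpp_convex_hull(pts)$ok)) return(empty(TRUE))
  jit <- matrix(det_jitter(3L * nrow(pts), 1e-6), ncol = 3)
  hull <- cpp_convex_hull(pts + jit)
  if (!isTRUE(hull$ok)) return(empty(TRUE))

  pad <- if (mode == "alpha") alpha + 2 * h else 2 * h
  lo <- grid_origin_mm + floor((apply(pts, 2, min) - pad - grid_origin_mm) / h) * h
  hi <- apply(pts, 2, max) + pad
  dm <- as.integer(ceiling((hi - lo) / h))
  ctrs <- as.matrix(expand.grid(axis_centers(dm[1], h, lo[1]),
                                axis_centers(dm[2], h, lo[2]),
                                axis_centers(dm[3], h, lo[3])))
  hull_mask <- array(cpp_points_in_hull(hull$normals, hull$offsets, ctrs,
                                        1e-7), dim = dm)
  # voxels containing the sites themselves are always part of the VTA
  # (a site on a voxel boundary may sit in a voxel whose centre is just
  # outside the hull)
  idx <- point_to_index(pts, dm, h, lo)
  seeds <- array(FALSE, dm)
  seeds[linear_index(idx, dm)] <- TRUE
  if (mode == "hull") {
    mask <- hull_mask | seeds
  } else {
    dil <- cpp_sqedt(seeds, dm, h) <= alpha^2 + 1e-9
    dim(dil) <- dm
    ero <- cpp_sqedt(!dil, dm, h) > alpha^2 - 1e-9
    dim(ero) <- dm
    mask <- (ero & hull_mask) | seeds
  }
  structure(list(mask = mask, voxel_size_mm = h, origin_mm = lo,
                 mode = mode, alpha_mm = alpha,
                 total_volume_mm3 = sum(mask) * h^3,
                 hull_volume_mm3 = hull$volume,
                 n_api = nrow(pts), degenerate = FALSE,
                 sub_volumes_mm3 = NULL, percentages = NULL),
            class = "vta_result")
}

#' @export
print.vta_result <- function(x, ...) {
  cat(sprintf("VTA (%s bounding): %.2f mm3 from %d API sites%s\n",
              x$mode, x$total_volume_mm3, x$n_api,
              if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$sub_volumes_mm3)) {
    sv <- x$sub_volumes_mm3
    pc <- x$percentages
    for (k in names(sv))
      cat(sprintf("  %-10s %8.2f mm3  %6.2f%%\n", k, sv[[k]], pc[[k]]))
  }
  invisible(x)
}

# model labels at the VTA mask voxel centers (NA outside the model)
vta_voxel_labels <- function(vta, model) {
  dm <- dim(vta$mask)
  idxm <- which(vta$mask, arr.ind = TRUE)
  if (!nrow(idxm)) return(integer())
  ctrs <- sweep((idxm - 0.5) * vta$voxel_size_mm, 2, vta$origin_mm, "+")
  mi <- point_to_index(ctrs, dim(model$label_grid), model$voxel_size_mm,
                       model$origin_mm)
  if (anyNA(mi[, 1]))
    stop("alignment error: VTA voxels fall outside the tissue model")
  model$label_grid[linear_index(mi, dim(model$label_grid))]
}

#' Partition a VTA into pallidal sub-regions
#'
#' Counts VTA voxels inside the GPi, the medial medullary lamina
#' (between GPi and GPe), the GPe, and everything else (outside GP,
#' including side-effect structures), converting counts to mm^3 and
#' percentages of the total.
#'
#' @param vta a [build_vta()] result.
#' @param model the [tissue_model()] defining the regions.
#' @return The `vta_result` with `sub_volumes_mm3` and `percentages`
#'   filled.
#' @export
partition_vta <- function(vta, model) {
  h3 <- vta$voxel_size_mm^3
  labs <- vta_voxel_labels(vta, model)
  n <- length(labs)
  counts <- c(in_GPi = sum(labs == pallidal_labels[["gpi"]]),
              lamina = sum(labs == pallidal_labels[["lamina"]]),
              in_GPe = sum(labs == pallidal_labels[["gpe"]]))
  counts <- c(counts, outside_GP = n - sum(counts))
  vta$sub_volumes_mm3 <- as.list(counts * h3)
  vta$percentages <- as.list(if (n > 0) 100 * counts / n else counts * NA)
  vta
}

#' Compare two VTAs
#'
#' @param a,b [build_vta()] results on the same voxel lattice.
#' @param azimuth,origin_mm optional steering azimuth (3-vector) and
#'   lead-axis origin for the asymmetry index of `a`.
#' @return list with `volume_ratio`, `percent_difference`
#'   (`100 (V_a - V_b) / V_b`), `dice`, and `asymmetry_index` (fraction
#'   of `a`'s volume in the half-space toward `azimuth`).
#' @export
compare_vtas <- function(a, b, azimuth = NULL, origin_mm = NULL) {
  if (abs(a$voxel_size_mm - b$voxel_size_mm) > 1e-9)
    stop("VTAs are on different voxel sizes")
  off <- (a$origin_mm - b$origin_mm) / a$voxel_size_mm
  if (max(abs(off - round(off))) > 1e-6)
    stop("VTA grids are not aligned")
  key <- function(v) {
    idx <- which(v$mask, arr.ind = TRUE)
    if (!nrow(idx)) return(character())
    lat <- sweep(idx, 2, round(v$origin_mm / v$voxel_size_mm), "+")
    apply(lat, 1, paste, collapse = ",")
  }
  ka <- key(a)
  kb <- key(b)
  inter <- length(intersect(ka, kb))
  dice <- if (length(ka) + length(kb) > 0)
    2 * inter / (length(ka) + length(kb)) else 1
  va <- a$total_volume_mm3
  vb <- b$total_volume_mm3
  if (vb == 0) stop("arithmetic error: reference VTA has zero volume")
  asym <- if (!is.null(azimuth) && !is.null(origin_mm))
    vta_asymmetry(a, origin_mm, azimuth) else NA_real_
  list(volume_ratio = va / vb,
       percent_difference = 100 * (va - vb) / vb,
       dice = dice,
       asymmetry_index = asym)
}

#' Asymmetry index of a VTA
#'
#' Fraction of the VTA volume lying in the half-space on the `azimuth`
#' side of the plane through `origin_mm`.
#'
#' @param vta a [build_vta()] result.
#' @param origin_mm point on the lead axis (mm).
#' @param azimuth direction toward the active segment (3-vector).
#' @export
vta_asymmetry <- function(vta, origin_mm, azimuth) {
  idx <- which(vta$mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NA_real_)
  ctrs <- sweep((idx - 0.5) * vta$voxel_size_mm, 2, vta$origin_mm, "+")
  az <- unit3(as.numeric(azimuth), "azimuth")
  d <- sweep(ctrs, 2, as.numeric(origin_mm)) %*% az
  mean(d > 0)
}

#' VTA overlap with side-effect structures
#'
#' Volume of the VTA intersecting the named model labels (e.g. optic
#' tract, internal capsule).
#'
#' @param vta a [build_vta()] result.
#' @param model the [tissue_model()].
#' @param labels label names (as in [pallidal_labels]) or integer ids.
#' @return Overlap volume, mm^3.
#' @export
flag_side_effect_overlap <- function(vta, model,
                                     labels = c("optic_tract",
                                                "internal_capsule")) {
  if (is.character(labels)) {
    bad <- setdiff(labels, names(pallidal_labels))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    labels <- pallidal_labels[labels]
  }
  bad <- setdiff(labels, model$conductivity_table$label)
  if (length(bad))
    stop("label(s) absent from the model: ", paste(bad, collapse = ", "))
  labs <- vta_voxel_labels(vta, model)
  sum(labs %in% labels) * vta$voxel_size_mm^3
}

#' Export a VTA
#'
#' Writes the voxel mask as NIfTI and the boundary surface (exposed
#' voxel faces, triangulated) as ASCII STL.
#'
#' @param vta a [build_vta()] result.
#' @param path_prefix output path prefix; writes
#'   `<prefix>_mask.nii.gz` and `<prefix>_surface.stl`.
#' @return Invisibly, the written paths.
#' @export
export_vta <- function(vta, path_prefix) {
  mask_path <- paste0(path_prefix, "_mask.nii.gz")
  arr <- array(as.integer(vta$mask), dim(vta$mask))
  attr(arr, "pixdim") <- rep(vta$voxel_size_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), mask_path)
  stl_path <- paste0(path_prefix, "_surface.stl")
  write_mask_stl(vta$mask, vta$voxel_size_mm, vta$origin_mm, stl_path)
  invisible(c(mask_path, stl_path))
}

# boundary faces of a voxel mask as ASCII STL triangles
write_mask_stl <- function(mask, h, origin, path) {
  dm <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vta", con)
  if (nrow(idx)) {
    pad <- array(FALSE, dm + 2L)
    pad[cbind(idx[, 1] + 1L, idx[, 2] + 1L, idx[, 3] + 1L)] <- TRUE
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    lines <- character()
    for (f in seq_len(6)) {
      d <- dirs[f, ]
      nb <- cbind(idx[, 1] + 1L + d[1], idx[, 2] + 1L + d[2],
                  idx[, 3] + 1L + d[3])
      open <- !pad[nb]
      if (!any(open)) next
      vox <- idx[open, , drop = FALSE]
      lo <- sweep((vox - 1) * h, 2, origin, "+")
      # four corners of the exposed face
      ax <- which(d != 0)
      u <- setdiff(1:3, ax)
      base <- lo
      base[, ax] <- base[, ax] + ifelse(d[ax] > 0, h, 0)
      for (r in seq_len(nrow(base))) {
        p0 <- base[r, ]
        p1 <- p0; p1[u[1]] <- p1[u[1]] + h
        p2 <- p0; p2[u] <- p2[u] + h
        p3 <- p0; p3[u[2]] <- p3[u[2]] + h
        tri <- list(list(p0, p1, p2), list(p0, p2, p3))
        for (tt in tri) {
          lines <- c(lines,
                     sprintf("facet normal %g %g %g", d[1], d[2], d[3]),
                     "  outer loop",
                     sprintf("    vertex %g %g %g", tt[[1]][1], tt[[1]][2], tt[[1]][3]),
                     sprintf("    vertex %g %g %g", tt[[2]][1], tt[[2]][2], tt[[2]][3]),
                     sprintf("    vertex %g %g %g", tt[[3]][1], tt[[3]][2], tt[[3]][3]),
                     "  endloop",
                     "endfacet")
        }
      }
    }
    writeLines(lines, con)
  }
  writeLines("endsolid vta", con)
  invisible(path)
}
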