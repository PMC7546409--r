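#' Build a parametric directional eight-contact lead
#'
#' Constructs a 1-3-3-1 segmented lead: ring contact 1 nearest the tip,
#' two segmented rows (2A/2B/2C and 3A/3B/3C, 90 degree arcs with
#' 30 degree insulation gaps), and ring contact 4, with an edge-to-edge
#' vertical gap of `spacing_mm` between adjacent rows. Segment A of each
#' row is centred on the azimuth reference. The shaft direction points
#' from the tip up the shaft: a `sagittal_angle_deg` tilt toward anterior
#' (+y) and a `coronal_angle_deg` tilt toward lateral (+x) give
#' `direction = normalize(c(tan(coronal), tan(sagittal), 1))`, so (0, 0)
#' is a vertical lead.
#'
#' Contact dimensions default to the common directional lead family:
#' 1.27 mm diameter, 1.5 mm contact height, 90 degree segments, and the
#' first contact starting 1 mm above the rounded tip; all are
#' configurable.
#'
#' @param spacing_mm edge-to-edge gap between adjacent contact rows (mm);
#'   the 0.5 and 1.5 mm variants are the two modelled leads.
#' @param tip_mm position of the lead tip (3-vector, mm).
#' @param sagittal_angle_deg,coronal_angle_deg implant angles (degrees).
#' @param segment_A_azimuth direction segment A faces (3-vector; its
#'   component orthogonal to the shaft is used). Default anterior.
#' @param diameter_mm,contact_height_mm,tip_to_first_contact_mm,
#'   encapsulation_thickness_mm,segment_arc_deg lead dimensions (mm, deg).
#' @return An object of class `lead_geometry`.
#' @export
build_lead <- function(spacing_mm,
                       tip_mm = c(26, 28, 22),
                       sagittal_angle_deg = 23,
                       coronal_angle_deg = 11,
                       segment_A_azimuth = c(0, 1, 0),
                       diameter_mm = 1.27,
                       contact_height_mm = 1.5,
                       tip_to_first_contact_mm = 1,
                       encapsulation_thickness_mm = 0.5,
                       segment_arc_deg = 90) {
  if (spacing_mm <= 0) stop("spacing_mm must be > 0")
  if (encapsulation_thickness_mm < 0)
    stop("encapsulation_thickness_mm must be >= 0")
  d <- unit3(c(tan(coronal_angle_deg * pi / 180),
               tan(sagittal_angle_deg * pi / 180), 1), "shaft direction")
  az <- as.numeric(segment_A_azimuth)
  az <- az - sum(az * d) * d
  az <- unit3(az, "segment-A azimuth (parallel to shaft?)")

  rows <- vapply(1:4, function(r) {
    z0 <- tip_to_first_contact_mm +
      (r - 1) * (contact_height_mm + spacing_mm)
    c(z0, z0 + contact_height_mm)
  }, numeric(2))
  half <- segment_arc_deg / 2
  seg_centers <- c(A = 0, B = 120, C = 240)
  contacts <- do.call(rbind, lapply(1:4, function(r) {
    if (r %in% c(1, 4)) {
      data.frame(id = as.character(r), kind = "ring", row = r,
                 axial_lo = rows[1, r], axial_hi = rows[2, r],
                 ang_lo = NA_real_, ang_hi = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = paste0(r, names(seg_centers)), kind = "segment",
                 row = r, axial_lo = rows[1, r], axial_hi = rows[2, r],
                 ang_lo = seg_centers - half, ang_hi = seg_centers + half,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(contacts) <- NULL
  structure(
    list(tip_position_mm = as.numeric(tip_mm),
         shaft_direction = d,
         azimuth_reference = az,
         diameter_mm = diameter_mm,
         contact_height_mm = contact_height_mm,
         vertical_spacing_mm = spacing_mm,
         tip_to_first_contact_mm = tip_to_first_contact_mm,
         encapsulation_thickness_mm = encapsulation_thickness_mm,
         segment_arc_deg = segment_arc_deg,
         contacts = contacts),
    class = "lead_geometry")
}

#' @export
print.lead_geometry <- function(x, ...) {
  cat(sprintf("directional lead: %.2f mm diameter, %.1f mm contacts, %.1f mm row gap\n",
              x$diameter_mm, x$contact_height_mm, x$vertical_spacing_mm))
  cat(sprintf("tip at (%.2f, %.2f, %.2f) mm, shaft (%.3f, %.3f, %.3f)\n",
              x$tip_position_mm[1], x$tip_position_mm[2], x$tip_position_mm[3],
              x$shaft_direction[1], x$shaft_direction[2], x$shaft_direction[3]))
  print(x$contacts, row.names = FALSE)
  invisible(x)
}

# local orthonormal frame: e1 = azimuth reference (segment A), e2 = e1 x d.
# With an anterior reference on a near-vertical shaft e2 points lateral, so
# segment B (120 degrees) faces posterolateral and C posteromedial — the
# segment order that makes 2B the posterolateral "sensorimotor" contact.
lead_frame <- function(lead) {
  e1 <- lead$azimuth_reference
  d <- lead$shaft_direction
  e2 <- c(e1[2] * d[3] - e1[3] * d[2],
          e1[3] * d[1] - e1[1] * d[3],
          e1[1] * d[2] - e1[2] * d[1])
  list(e1 = e1, e2 = unit3(e2), d = d)
}

# total length from tip to the proximal edge of contact 4
lead_contact_span <- function(lead) {
  max(lead$contacts$axial_hi)
}

# axial position (mm along the shaft from the tip) of a contact row centre
lead_row_center <- function(lead, row) {
  cc <- lead$contacts[lead$contacts$row == row, ]
  mean(c(min(cc$axial_lo), max(cc$axial_hi)))
}

lead_point <- function(lead, t) lead$tip_position_mm + t * lead$shaft_direction

#' Place a lead at the posterolateral GPi target
#'
#' Translates the lead so that the outer surface of the row-2 contacts
#' sits at the requested distances from the lateral (+x) and posterior
#' (-y) borders of the GPi, with the row-2 centre in the ventral half of
#' the nucleus. Border distances are measured on the voxelized GPi mask
#' along the +x and -y rays through the row-2 centre and refined by fixed
#' point iteration; the achieved distances are reported in the
#' `placement` attribute.
#'
#' @param lead a [build_lead()] geometry.
#' @param model a [tissue_model()] containing a GPi label.
#' @param target_offsets named numeric vector `c(lateral = , posterior = )`
#'   in millimetres (contact surface to border).
#' @param ventral_fraction fraction of the GPi semi-axis below the centre
#'   at which the row-2 centre is placed (0 = mid-height).
#' @return The translated `lead_geometry` with attribute `placement`.
#' @export
place_at_target <- function(lead, model,
                            target_offsets = c(lateral = 2.25, posterior = 2.3),
                            ventral_fraction = 0.45) {
  lab <- model$label_grid
  h <- model$voxel_size_mm
  gpi <- pallidal_labels[["gpi"]]
  if (!any(lab == gpi)) stop("model contains no GPi label")
  idx <- which(lab == gpi, arr.ind = TRUE)
  ctr <- (colMeans(idx) - 0.5) * h + model$origin_mm
  zspan <- range(idx[, 3])
  z_target <- ctr[3] - ventral_fraction * (ctr[3] - ((zspan[1] - 0.5) * h + model$origin_mm[3]))

  r_out <- lead$diameter_mm / 2
  t2 <- lead_row_center(lead, 2)
  req_lat <- target_offsets[["lateral"]]
  req_post <- target_offsets[["posterior"]]

  # start with the row-2 centre at the ventral posterolateral octant
  p2 <- c(ctr[1], ctr[2], z_target)
  cur <- lead
  for (it in 1:6) {
    cur$tip_position_mm <- p2 - t2 * cur$shaft_direction
    b <- gpi_border_distances(cur, model, t2, r_out)
    if (!is.finite(b$lateral) || !is.finite(b$posterior))
      stop("placement error: row-2 centre left the GPi during placement ",
           "(achieved lateral ", round(b$lateral, 2), ", posterior ",
           round(b$posterior, 2), " vs requested ", req_lat, "/", req_post, ")")
    dx <- b$lateral - req_lat
    dy <- req_post - b$posterior
    p2 <- p2 + c(dx, dy, 0)
    if (abs(dx) < h / 4 && abs(dy) < h / 4) break
  }
  cur$tip_position_mm <- p2 - t2 * cur$shaft_direction
  b <- gpi_border_distances(cur, model, t2, r_out)
  ach <- c(lateral = b$lateral, posterior = b$posterior)
  if (any(abs(ach - c(req_lat, req_post)) > max(2 * h, 1)))
    stop("placement error: GPi too small for the requested offsets ",
         "(achieved ", paste(round(ach, 2), collapse = "/"),
         " vs requested ", req_lat, "/", req_post, ")")
  attr(cur, "placement") <- list(requested = c(lateral = req_lat,
                                               posterior = req_post),
                                 achieved = ach,
                                 row2_center_mm = p2)
  cur
}

# distances from the row-2 contact surface to the GPi lateral (+x) and
# posterior (-y) borders, measured along rays through the row-2 centre
gpi_border_distances <- function(lead, model, t2, r_out) {
  h <- model$voxel_size_mm
  p2 <- lead_point(lead, t2)
  lab <- model$label_grid
  gpi <- pallidal_labels[["gpi"]]
  dm <- dim(lab)
  step <- h / 2
  ray_extent <- function(dirv) {
    # full line through the row-2 centre, so the border distance can be
    # negative when the contact surface sits outside the border
    ext <- max(dm * h)
    s <- seq(-ext, ext, by = step)
    pts <- cbind(p2[1] + s * dirv[1], p2[2] + s * dirv[2], p2[3] + s * dirv[3])
    idx <- point_to_index(pts, dm, h, model$origin_mm)
    ok <- !is.na(idx[, 1])
    if (!any(ok)) return(NA_real_)
    inside <- logical(length(s))
    inside[ok] <- lab[linear_index(idx[ok, , drop = FALSE], dm)] == gpi
    last <- which(inside)
    if (!length(last)) return(NA_real_)
    s[max(last)]
  }
  list(lateral = ray_extent(c(1, 0, 0)) - r_out,
       posterior = ray_extent(c(0, -1, 0)) - r_out)
}

# sample points on a contact's outer surface (used when a solve grid is
# too coarse to capture the metal shell)
contact_surface_points <- function(lead, id, n_ang = 8, n_ax = 3) {
  cc <- lead$contacts[lead$contacts$id == id, ]
  fr <- lead_frame(lead)
  r <- lead$diameter_mm / 2
  ts <- seq(cc$axial_lo, cc$axial_hi, length.out = n_ax)
  angs <- if (cc$kind == "ring") seq(0, 360, length.out = n_ang + 1)[-1]
          else seq(cc$ang_lo, cc$ang_hi, length.out = n_ang)
  g <- expand.grid(t = ts, a = angs * pi / 180)
  t(vapply(seq_len(nrow(g)), function(i) {
    lead$tip_position_mm + g$t[i] * fr$d +
      r * (cos(g$a[i]) * fr$e1 + sin(g$a[i]) * fr$e2)
  }, numeric(3)))
}

# analytic voxel classification of the lead at arbitrary resolution;
# returns an integer array of lead labels (0 where no lead material)
classify_lead_voxels <- function(lead, dim, h, origin,
                                 metal_thickness_mm = 0.35) {
  fr <- lead_frame(lead)
  tip <- lead$tip_position_mm
  r <- lead$diameter_mm / 2
  enc <- lead$encapsulation_thickness_mm
  xs <- axis_centers(dim[1], h, origin[1])
  ys <- axis_centers(dim[2], h, origin[2])
  zs <- axis_centers(dim[3], h, origin[3])
  px <- outer(outer(xs - tip[1], rep(1, dim[2])), rep(1, dim[3]))
  py <- outer(outer(rep(1, dim[1]), ys - tip[2]), rep(1, dim[3]))
  pz <- outer(outer(rep(1, dim[1]), rep(1, dim[2])), zs - tip[3])
  t <- px * fr$d[1] + py * fr$d[2] + pz * fr$d[3]
  qx <- px - t * fr$d[1]
  qy <- py - t * fr$d[2]
  qz <- pz - t * fr$d[3]
  rho2 <- qx^2 + qy^2 + qz^2
  # distance to the tip-capped shaft: below the tip use the spherical cap
  below <- t < 0
  d2 <- rho2
  d2[below] <- rho2[below] + t[below]^2
  out <- array(0L, dim = dim)
  if (enc > 0)
    out[d2 <= (r + enc)^2] <- pallidal_labels[["encapsulation"]]
  body <- d2 <= r^2
  out[body] <- pallidal_labels[["insulation"]]
  # contacts: metal shell within each row's axial/angular extent
  ang <- atan2(qx * fr$e2[1] + qy * fr$e2[2] + qz * fr$e2[3],
               qx * fr$e1[1] + qy * fr$e1[2] + qz * fr$e1[3]) * 180 / pi
  ang <- (ang + 360) %% 360
  shell <- body & rho2 >= (r - metal_thickness_mm)^2 & t >= 0
  cc <- lead$contacts
  for (i in seq_len(nrow(cc))) {
    sel <- shell & t >= cc$axial_lo[i] & t <= cc$axial_hi[i]
    if (cc$kind[i] == "segment") {
      lo <- (cc$ang_lo[i] + 360) %% 360
      hi <- (cc$ang_hi[i] + 360) %% 360
      if (lo < hi) sel <- sel & ang >= lo & ang <= hi
      else sel <- sel & (ang >= lo | ang <= hi)
    }
    out[sel] <- contact_label(cc$id[i])
  }
  out
}

#' Rasterize a lead into a tissue model
#'
#' Adds contact-metal labels (one per contact), polyurethane insulation
#' for the shaft body, and an encapsulation shell of the configured
#' thickness around the lead. Ties at label boundaries resolve with
#' precedence metal > insulation > encapsulation > tissue. Rasterizing
#' the same lead twice is idempotent: the pre-lead tissue grid is kept
#' alongside the result and restored before re-classification.
#'
#' @param lead a placed [build_lead()] geometry.
#' @param model a [tissue_model()].
#' @return A tissue model with the lead labels added and the conductivity
#'   table extended with the electrode materials.
#' @export
rasterize_lead <- function(lead, model) {
  base <- attr(model, "base_label_grid") %||% model$label_grid
  dm <- dim(base)
  h <- model$voxel_size_mm
  tip_idx <- point_to_index(rbind(lead$tip_position_mm), dm, h,
                            model$origin_mm)
  if (anyNA(tip_idx)) stop("geometry error: lead tip outside the domain")
  ras <- classify_lead_voxels(lead, dm, h, model$origin_mm)
  lab <- base
  lab[ras != 0L] <- ras[ras != 0L]
  tab <- model$conductivity_table
  need <- c(pallidal_labels[["encapsulation"]], pallidal_labels[["insulation"]],
            contact_label(lead$contacts$id))
  missing <- setdiff(need, tab$label)
  if (length(missing)) {
    def <- default_conductivity_table()
    tab <- rbind(tab, def[def$label %in% missing, , drop = FALSE])
  }
  out <- tissue_model(lab, voxel_size_mm = h, origin_mm = model$origin_mm,
                      conductivity_table = tab)
  attr(out, "base_label_grid") <- base
  attr(out, "lead") <- lead
  out
}

#' Read / write a lead geometry as JSON
#'
#' @param lead a `lead_geometry`; `path` a file path.
#' @return `read_lead` returns a `lead_geometry`.
#' @export
write_lead <- function(lead, path) {
  obj <- unclass(lead)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_lead
#' @export
read_lead <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$contacts <- as.data.frame(obj$contacts, stringsAsFactors = FALSE)
  structure(obj, class = "lead_geometry")
}
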