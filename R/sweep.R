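#' Sweep specification
#'
#' Describes a full study sweep: one phantom, one lead placement per
#' vertical spacing, and a table of cells keyed by
#' (configuration, spacing, amplitude, tissue mode).
#'
#' @param cells data frame with columns `config`, `spacing_mm`,
#'   `amplitude_mA`, `tissue_mode` ("heterogeneous"/"homogeneous").
#' @param phantom a [phantom_spec()].
#' @param solver a [solver_settings()].
#' @param axon an [axon_grid_spec()].
#' @param vta_mode bounding mode passed to [build_vta()].
#' @param vta_voxel_mm VTA voxelization edge (NULL: the phantom's).
#' @param homogeneous_sigma conductivity of the homogeneous model, S/m.
#' @param lead_args extra arguments for [build_lead()].
#' @param target_offsets offsets for [place_at_target()].
#' @param pulse_width_us,frequency_hz stimulus pulse parameters.
#' @param total_time_ms,dt_us integrator window and step.
#' @param prescreen_mV population prescreen (see
#'   [evaluate_population()]).
#' @param output_dir directory for the breakdown CSV, manifest and
#'   optional masks (NULL: nothing written).
#' @param write_masks also export per-cell VTA masks and surfaces.
#' @param seed integer seed recorded in the manifest; the pipeline is
#'   deterministic.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(cells,
                       phantom = phantom_spec(),
                       solver = solver_settings(),
                       axon = axon_grid_spec(),
                       vta_mode = "alpha",
                       vta_voxel_mm = NULL,
                       homogeneous_sigma = 0.3,
                       lead_args = list(),
                       target_offsets = c(lateral = 2.25, posterior = 2.3),
                       pulse_width_us = 60,
                       frequency_hz = 130,
                       total_time_ms = 2.5,
                       dt_us = 5,
                       prescreen_mV = 5,
                       output_dir = NULL,
                       write_masks = FALSE,
                       seed = 1L) {
  if (!nrow(cells)) stop("cells must be nonempty")
  need <- c("config", "spacing_mm", "amplitude_mA", "tissue_mode")
  if (!all(need %in% names(cells)))
    stop("cells must have columns ", paste(need, collapse = ", "))
  if (!all(cells$amplitude_mA > 0)) stop("amplitudes must be positive")
  structure(list(cells = cells, phantom = phantom, solver = solver,
                 axon = axon, vta_mode = vta_mode,
                 vta_voxel_mm = vta_voxel_mm,
                 homogeneous_sigma = homogeneous_sigma,
                 lead_args = lead_args, target_offsets = target_offsets,
                 pulse_width_us = pulse_width_us,
                 frequency_hz = frequency_hz,
                 total_time_ms = total_time_ms, dt_us = dt_us,
                 prescreen_mV = prescreen_mV,
                 output_dir = output_dir, write_masks = write_masks,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' The built-in study sweep
#'
#' Nineteen cells: the six named configurations at 1 and 2 mA on the
#' 1.5 mm-spacing lead, the three vertically active configurations
#' (2b, 4, 5) at 1 and 2 mA on the 0.5 mm-spacing lead, and one
#' homogeneous-tissue cell (configuration 4, 1.5 mm, 1 mA) for the
#' heterogeneity contrast.
#'
#' @param ... overrides passed to [sweep_spec()].
#' @return A [sweep_spec()].
#' @export
default_sweep_spec <- function(...) {
  het15 <- expand.grid(config = c("1", "2a", "2b", "3", "4", "5"),
                       spacing_mm = 1.5, amplitude_mA = c(1, 2),
                       tissue_mode = "heterogeneous",
                       stringsAsFactors = FALSE)
  het05 <- expand.grid(config = c("2b", "4", "5"),
                       spacing_mm = 0.5, amplitude_mA = c(1, 2),
                       tissue_mode = "heterogeneous",
                       stringsAsFactors = FALSE)
  hom <- data.frame(config = "4", spacing_mm = 1.5, amplitude_mA = 1,
                    tissue_mode = "homogeneous", stringsAsFactors = FALSE)
  sweep_spec(cells = rbind(het15, het05, hom), ...)
}

#' Run a study sweep
#'
#' For each cell: solve the quasi-static field, rescale to the cell's
#' current, evaluate axon activation, bound the API sites into a VTA and
#' partition it. One row per cell; failures are caught, recorded and the
#' sweep continues. Deterministic for a fixed seed.
#'
#' @param spec a [sweep_spec()].
#' @param verbose print per-cell progress.
#' @return An object of class `sweep_result` with elements `table` (the
#'   breakdown data frame), `summary` (see [summarize_sweep()]),
#'   `failures`, and `paths`.
#' @export
run_sweep <- function(spec, verbose = TRUE) {
  set.seed(spec$seed)
  t0 <- proc.time()[3]
  say <- function(...) if (verbose) message(sprintf(...))
  phantom <- build_pallidum_phantom(spec$phantom)
  say("phantom built (%d voxels)", length(phantom$label_grid))

  spacings <- sort(unique(spec$cells$spacing_mm))
  ctx <- list()
  for (sp in spacings) {
    lead <- do.call(build_lead, c(list(spacing_mm = sp), spec$lead_args))
    lead <- place_at_target(lead, phantom, spec$target_offsets)
    model <- rasterize_lead(lead, phantom)
    axons <- generate_axon_grid(lead, spec$axon)
    ctx[[as.character(sp)]] <- list(lead = lead, model = model,
                                    axons = axons,
                                    homog = homogenize(model,
                                                       spec$homogeneous_sigma))
    say("lead placed at %.1f mm spacing: %d axons",
        sp, nrow(axons$origins))
  }

  fields <- list()
  rows <- list()
  failures <- list()
  vtas <- list()
  for (ci in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[ci, ]
    key <- sprintf("%s|%s|%s", cell$config, cell$spacing_mm,
                   cell$tissue_mode)
    res <- tryCatch({
      cx <- ctx[[as.character(cell$spacing_mm)]]
      model <- if (cell$tissue_mode == "homogeneous") cx$homog else cx$model
      if (is.null(fields[[key]])) {
        tsolve <- system.time(
          f <- solve_potential(model, cx$lead,
                               named_configuration(cell$config),
                               spec$solver))[3]
        say("cell %d/%d: solved %s (%s, %.1f mm) in %.1f s, ETI %.0f ohm",
            ci, nrow(spec$cells), cell$config, cell$tissue_mode,
            cell$spacing_mm, tsolve, f$eti_impedance_ohm)
        fields[[key]] <- f
      }
      f <- scale_to_current(fields[[key]], cell$amplitude_mA)
      wf <- stimulus_waveform(pulse_width_us = spec$pulse_width_us,
                              frequency_hz = spec$frequency_hz,
                              total_time_ms = spec$total_time_ms,
                              dt_us = spec$dt_us)
      act <- evaluate_population(f, cx$axons, wf,
                                 prescreen_mV = spec$prescreen_mV)
      vta <- build_vta(act,
                       voxel_size_mm = spec$vta_voxel_mm %||%
                         phantom$voxel_size_mm,
                       mode = spec$vta_mode,
                       grid_origin_mm = phantom$origin_mm)
      vta <- partition_vta(vta, phantom)
      cfg <- named_configuration(cell$config)
      fr <- lead_frame(cx$lead)
      th <- cfg$steer_azimuth_deg * pi / 180
      az <- cos(th) * fr$e1 + sin(th) * fr$e2
      p2 <- lead_point(cx$lead, lead_row_center(cx$lead, 2))
      asym <- vta_asymmetry(vta, p2, az)
      sidefx <- if (vta$total_volume_mm3 > 0)
        flag_side_effect_overlap(vta, phantom) else 0
      say("cell %d/%d: %s %.1f mm %.0f mA %s -> %d activated, VTA %.2f mm3 (%.1f%% GPi)",
          ci, nrow(spec$cells), cell$config, cell$spacing_mm,
          cell$amplitude_mA, cell$tissue_mode, act$n_activated,
          vta$total_volume_mm3, vta$percentages$in_GPi %||% NA)
      list(row = data.frame(
        config = cell$config, spacing_mm = cell$spacing_mm,
        amplitude_mA = cell$amplitude_mA, tissue_mode = cell$tissue_mode,
        n_axons = nrow(cx$axons$origins), n_activated = act$n_activated,
        eti_impedance_ohm = fields[[key]]$eti_impedance_ohm,
        total_mm3 = vta$total_volume_mm3,
        in_GPi_mm3 = vta$sub_volumes_mm3$in_GPi %||% 0,
        lamina_mm3 = vta$sub_volumes_mm3$lamina %||% 0,
        in_GPe_mm3 = vta$sub_volumes_mm3$in_GPe %||% 0,
        outside_mm3 = vta$sub_volumes_mm3$outside_GP %||% 0,
        pct_in_GPi = vta$percentages$in_GPi %||% NA_real_,
        pct_lamina = vta$percentages$lamina %||% NA_real_,
        pct_in_GPe = vta$percentages$in_GPe %||% NA_real_,
        pct_outside = vta$percentages$outside_GP %||% NA_real_,
        sidefx_mm3 = sidefx,
        asymmetry_index = asym,
        stringsAsFactors = FALSE), vta = vta)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        list(cell = cell, message = conditionMessage(res))
      say("cell %d/%d FAILED: %s", ci, nrow(spec$cells),
          conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res$row
      vtas[[sprintf("%s_%smm_%smA_%s", cell$config, cell$spacing_mm,
                    cell$amplitude_mA, cell$tissue_mode)]] <- res$vta
    }
  }
  tab <- do.call(rbind, rows)
  out <- structure(list(table = tab, failures = failures,
                        spec = spec, vtas = vtas,
                        elapsed_s = proc.time()[3] - t0,
                        paths = character()),
                   class = "sweep_result")
  out$summary <- tryCatch(summarize_sweep(tab), error = function(e) NULL)

  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(spec$output_dir, "vta_breakdown.csv")
    write.csv(tab, csv, row.names = FALSE)
    manifest <- list(seed = spec$seed,
                     package_version =
                       as.character(utils::packageVersion("vtasteer")),
                     n_cells = nrow(spec$cells),
                     n_rows = nrow(tab),
                     n_failures = length(failures),
                     csv_md5 = unname(tools::md5sum(csv)))
    mp <- file.path(spec$output_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
    paths <- c(csv, mp)
    if (isTRUE(spec$write_masks))
      for (nm in names(vtas))
        paths <- c(paths, export_vta(vtas[[nm]],
                                     file.path(spec$output_dir, nm)))
    out$paths <- paths
  }
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep: %d rows, %d failures, %.0f s\n",
              nrow(x$table), length(x$failures), x$elapsed_s))
  print(x$table[, c("config", "spacing_mm", "amplitude_mA", "tissue_mode",
                    "total_mm3", "pct_in_GPi", "pct_outside")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summarize a sweep
#'
#' Derived statistics over the breakdown table: the mean percentage of
#' the VTA inside the GPi over the vertically active configurations
#' (2b, 4, 5) per spacing and amplitude, the volume and composition
#' shifts when switching configuration 4 to 5, the
#' homogeneous-vs-heterogeneous volume difference, and side-effect
#' (outside-GP ventral structure) overlap volumes.
#'
#' @param x a `sweep_result`, its `table`, or a breakdown CSV path.
#' @return A list of summary tables.
#' @export
summarize_sweep <- function(x) {
  tab <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE)
         else if (inherits(x, "sweep_result")) x$table else x
  tab$config <- as.character(tab$config)
  het <- tab[tab$tissue_mode == "heterogeneous", ]
  vert <- het[het$config %in% c("2b", "4", "5"), ]
  mean_gpi <- NULL
  if (nrow(vert))
    mean_gpi <- aggregate(pct_in_GPi ~ spacing_mm + amplitude_mA,
                          data = vert, FUN = mean)
  shift45 <- NULL
  k4 <- het[het$config == "4", ]
  k5 <- het[het$config == "5", ]
  if (nrow(k4) && nrow(k5)) {
    m <- merge(k4, k5, by = c("spacing_mm", "amplitude_mA"),
               suffixes = c("_4", "_5"))
    if (nrow(m))
      shift45 <- data.frame(
        spacing_mm = m$spacing_mm, amplitude_mA = m$amplitude_mA,
        volume_change_pct = 100 * (m$total_mm3_5 - m$total_mm3_4) /
          m$total_mm3_4,
        pct_in_GPi_4 = m$pct_in_GPi_4, pct_in_GPi_5 = m$pct_in_GPi_5)
  }
  hom <- tab[tab$tissue_mode == "homogeneous", ]
  hom_vs_het <- NULL
  if (nrow(hom)) {
    m <- merge(hom, het, by = c("config", "spacing_mm", "amplitude_mA"),
               suffixes = c("_hom", "_het"))
    if (nrow(m))
      hom_vs_het <- data.frame(
        config = m$config, spacing_mm = m$spacing_mm,
        amplitude_mA = m$amplitude_mA,
        percent_difference = 100 * (m$total_mm3_hom - m$total_mm3_het) /
          m$total_mm3_het)
  }
  missing <- character()
  list(mean_pct_in_GPi = mean_gpi,
       config_4_to_5 = shift45,
       homogeneous_vs_heterogeneous = hom_vs_het,
       side_effect_mm3 = tab[, c("config", "spacing_mm", "amplitude_mA",
                                 "tissue_mode", "sidefx_mm3")],
       missing_cells = missing)
}

#' Read / write a sweep cell table as YAML
#'
#' Serializes the cell table and scalar options of a sweep spec; the
#' component objects (phantom, solver, axon grid) are rebuilt from their
#' stored fields.
#'
#' @param spec a [sweep_spec()]; `path` a YAML file path.
#' @export
write_sweep_spec <- function(spec, path) {
  obj <- list(cells = as.list(spec$cells),
              phantom = unclass(spec$phantom),
              axon = unclass(spec$axon),
              vta_mode = spec$vta_mode,
              homogeneous_sigma = spec$homogeneous_sigma,
              pulse_width_us = spec$pulse_width_us,
              frequency_hz = spec$frequency_hz,
              seed = spec$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sweep_spec
#' @export
read_sweep_spec <- function(path, ...) {
  obj <- yaml::read_yaml(path)
  cells <- as.data.frame(obj$cells, stringsAsFactors = FALSE)
  phantom <- do.call(phantom_spec,
                     obj$phantom[setdiff(names(obj$phantom), "rng_seed")])
  axon <- do.call(axon_grid_spec,
                  obj$axon[!vapply(obj$axon, is.null, logical(1))])
  sweep_spec(cells = cells, phantom = phantom, axon = axon,
             vta_mode = obj$vta_mode,
             homogeneous_sigma = obj$homogeneous_sigma,
             pulse_width_us = obj$pulse_width_us,
             frequency_hz = obj$frequency_hz,
             seed = obj$seed, ...)
}
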