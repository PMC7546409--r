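#' Construct a stimulation configuration
#'
#' A configuration names the cathode contact set, the anode set (contact
#' ids or `"CASE"` for a monopolar return through the outer case shell)
#' and the stimulus parameters. Multi-contact sets are co-activated: tied
#' to a single potential, as with hardware parallel connections on a
#' single-source device.
#'
#' @param cathodes character vector of contact ids (subset of
#'   1, 2A, 2B, 2C, 3A, 3B, 3C, 4).
#' @param anodes character vector of contact ids, or `"CASE"`.
#' @param amplitude_mA stimulus current amplitude (mA), positive.
#' @param pulse_width_us,frequency_hz stimulus pulse parameters.
#' @param name configuration label.
#' @param steer_azimuth_deg azimuth (degrees from the segment-A reference)
#'   toward which the configuration steers; used for asymmetry metrics.
#' @return An object of class `stim_configuration`.
#' @export
stim_configuration <- function(cathodes, anodes = "CASE", amplitude_mA = 1,
                               pulse_width_us = 60, frequency_hz = 130,
                               name = "custom", steer_azimuth_deg = NA_real_) {
  cathodes <- as.character(cathodes)
  anodes <- as.character(anodes)
  if (!length(cathodes)) stop("cathodes must be nonempty")
  contact_label(cathodes)  # validates ids
  if (!identical(anodes, "CASE")) contact_label(anodes)
  if (length(intersect(cathodes, anodes)))
    stop("cathodes and anodes must be disjoint")
  if (!is.numeric(amplitude_mA) || amplitude_mA <= 0)
    stop("amplitude_mA must be > 0")
  structure(
    list(name = name, cathodes = cathodes, anodes = anodes,
         amplitude_mA = amplitude_mA, pulse_width_us = pulse_width_us,
         frequency_hz = frequency_hz,
         waveform = "biphasic-passive-discharge",
         coactivated = length(cathodes) > 1L,
         steer_azimuth_deg = steer_azimuth_deg),
    class = "stim_configuration")
}

#' Named study configurations
#'
#' The six contact configurations of the pallidal steering study:
#' \describe{
#'   \item{1}{single-segment monopole, 2B- / Case+}
#'   \item{2a}{two-segment row monopole, 2A- 2B- / Case+}
#'   \item{2b}{vertically stacked two-segment monopole, 2B- 3B- / Case+}
#'   \item{3}{ring monopole, 2A- 2B- 2C- / Case+}
#'   \item{4}{one-cathode ring-anode bipole, 2B- / 3A+ 3B+ 3C+}
#'   \item{5}{ring-cathode ring-anode bipole, 2A- 2B- 2C- / 3A+ 3B+ 3C+}
#' }
#'
#' @param name one of "1", "2a", "2b", "3", "4", "5".
#' @param amplitude_mA stimulus amplitude, mA.
#' @return A [stim_configuration()].
#' @export
named_configuration <- function(name, amplitude_mA = 1) {
  name <- as.character(name)
  defs <- list(
    "1" = list(cat = "2B", an = "CASE", az = 120),
    "2a" = list(cat = c("2A", "2B"), an = "CASE", az = 60),
    "2b" = list(cat = c("2B", "3B"), an = "CASE", az = 120),
    "3" = list(cat = c("2A", "2B", "2C"), an = "CASE", az = 120),
    "4" = list(cat = "2B", an = c("3A", "3B", "3C"), az = 120),
    "5" = list(cat = c("2A", "2B", "2C"), an = c("3A", "3B", "3C"), az = 120)
  )
  if (!name %in% names(defs))
    stop("unknown configuration '", name, "'; valid names: ",
         paste(names(defs), collapse = ", "))
  d <- defs[[name]]
  stim_configuration(cathodes = d$cat, anodes = d$an,
                     amplitude_mA = amplitude_mA, name = name,
                     steer_azimuth_deg = d$az)
}

#' @export
print.stim_configuration <- function(x, ...) {
  cat(sprintf("configuration %s: %s- / %s+, %.3g mA, %.0f us, %.0f Hz%s\n",
              x$name, paste(x$cathodes, collapse = " "),
              paste(x$anodes, collapse = " "), x$amplitude_mA,
              x$pulse_width_us, x$frequency_hz,
              if (x$coactivated) " (co-activated)" else ""))
  invisible(x)
}
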