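#' Stimulus waveform
#'
#' Biphasic pulse with passive discharge: a rectangular cathodic phase of
#' `pulse_width_us`, followed by an opposite-sign exponential recharge
#' with the given time constant, scaled so the two phases are
#' charge-balanced over the available discharge window. By convention a
#' single pulse decides activation (`n_pulses = 1`); pulse trains at
#' `frequency_hz` are available.
#'
#' @param amplitude_scale dimensionless multiplier applied to the
#'   unit-current extracellular profile.
#' @param pulse_width_us cathodic phase width, microseconds.
#' @param frequency_hz pulse train rate, Hz.
#' @param passive_discharge_time_constant_us recharge time constant.
#' @param n_pulses number of pulses delivered.
#' @param total_time_ms simulated time window, ms.
#' @param dt_us integrator time step, microseconds.
#' @return An object of class `stimulus_waveform`.
#' @export
stimulus_waveform <- function(amplitude_scale = 1,
                              pulse_width_us = 60,
                              frequency_hz = 130,
                              passive_discharge_time_constant_us = 500,
                              n_pulses = 1L,
                              total_time_ms = 3,
                              dt_us = 5) {
  if (pulse_width_us * frequency_hz >= 1e6)
    stop("pulse does not fit the period: pulse_width_us * frequency_hz must be < 1e6")
  if (dt_us >= pulse_width_us / 4)
    stop("dt_us must be < pulse_width_us / 4")
  period_ms <- if (n_pulses > 1L) 1000 / frequency_hz else total_time_ms
  pw_ms <- pulse_width_us / 1000
  tau_ms <- passive_discharge_time_constant_us / 1000
  window <- period_ms - pw_ms
  a2 <- pw_ms / (tau_ms * (1 - exp(-window / tau_ms)))  # charge balance
  structure(list(amplitude_scale = amplitude_scale,
                 pulse_width_us = pulse_width_us,
                 frequency_hz = frequency_hz,
                 passive_discharge_time_constant_us =
                   passive_discharge_time_constant_us,
                 n_pulses = as.integer(n_pulses),
                 total_time_ms = total_time_ms,
                 dt_us = dt_us,
                 pulse_width_ms = pw_ms, tau_ms = tau_ms, a2 = a2,
                 period_ms = period_ms, total_ms = total_time_ms,
                 dt_ms = dt_us / 1000),
            class = "stimulus_waveform")
}

# list consumed by the C++ integrator, with an optional amplitude override
waveform_cpp <- function(wf, amplitude_scale = NULL) {
  list(amplitude_scale = amplitude_scale %||% wf$amplitude_scale,
       pulse_width_ms = wf$pulse_width_ms, tau_ms = wf$tau_ms, a2 = wf$a2,
       period_ms = wf$period_ms, total_ms = wf$total_ms, dt_ms = wf$dt_ms,
       n_pulses = wf$n_pulses)
}
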