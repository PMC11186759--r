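#' Causal calcium-indicator kernel
#'
#' Single-spike dF/F response of a slow genetically encoded calcium
#' indicator (GCaMP6s-like): linear rise to `amplitude` over `rise` seconds,
#' then exponential decay with constant `decay_tau`.
#'
#' @param t_s Time since the spike, seconds (vectorised; negative = 0).
#' @param rise Rise time, s.
#' @param decay_tau Decay constant, s.
#' @param amplitude Peak dF/F per spike.
#' @return Kernel values (dF/F).
#' @export
ca_kernel <- function(t_s, rise = 0.2, decay_tau = 26.2, amplitude = 0.5) {
  out <- numeric(length(t_s))
  rising <- t_s >= 0 & t_s < rise
  decaying <- t_s >= rise
  out[rising] <- amplitude * t_s[rising] / rise
  out[decaying] <- amplitude * exp(-(t_s[decaying] - rise) / decay_tau)
  out
}

#' Simulate a fluorescence dF/F trace from a spike train
#'
#' The trace is the sum over spikes of the causal calcium kernel
#' ([ca_kernel()]), sampled on the camera frame grid, plus optional
#' Gaussian frame noise. Per-spike true peak times (`spike + rise`) and
#' onset times are returned for recovery tests.
#'
#' @param spike_times Spike times on the master clock, seconds.
#' @param config A [synth_config()].
#' @param duration Trace duration, s (default `config$duration`).
#' @return A `calcium_trace` tibble with columns `frame_time_s`, `dff`,
#'   attributes `frame_rate` and `truth` (tibble of per-spike
#'   `spike_time_s`, `onset_time_s`, `peak_time_s`, `peak_dff`).
#' @export
#' @examples
#' tr <- simulate_calcium_trace(5, synth_config(seed = 1, duration = 60))
#' max(tr$dff)
simulate_calcium_trace <- function(spike_times, config, duration = config$duration) {
  stopifnot(inherits(config, "synth_config"), config$frame_rate > 0)
  frames <- seq(0, duration, by = 1 / config$frame_rate)
  dff <- numeric(length(frames))
  for (s in spike_times) {
    dff <- dff + ca_kernel(frames - s,
      rise = config$ca_rise, decay_tau = config$ca_decay_tau,
      amplitude = config$ca_amplitude
    )
  }
  if (config$ca_noise_sd > 0) {
    dff <- dff + with_substream(
      config$seed, "calcium_noise",
      rnorm(length(frames), sd = config$ca_noise_sd)
    )
  }
  truth <- tibble(
    spike_time_s = as.numeric(spike_times),
    onset_time_s = as.numeric(spike_times),
    peak_time_s = as.numeric(spike_times) + config$ca_rise,
    peak_dff = config$ca_amplitude
  )
  structure(
    tibble(frame_time_s = frames, dff = dff),
    frame_rate = config$frame_rate, truth = truth,
    class = c("calcium_trace", class(tibble()))
  )
}

#' Plot a calcium trace
#'
#' @param object A `calcium_trace`.
#' @param ... Unused.
#' @return A ggplot of dF/F against time.
#' @export
autoplot.calcium_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame_time_s, y = .data$dff)) +
    ggplot2::geom_line(colour = "seagreen") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * I / I)) +
    ggplot2::theme_minimal()
}
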