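#' Unit-amplitude biphasic template shape
#'
#' Stereotyped extracellular action-potential shape used by the footprint
#' generator: a negative Gaussian trough (depth 1 at `trough_time_ms`,
#' width `trough_sd` ms) followed by a positive Gaussian rebound
#' (`rebound_frac` of the trough depth, width `rebound_sd` ms). The two
#' lobes are separated widely enough that the sampled trough depth and the
#' trough full width at half maximum, `2*sqrt(2*log(2))*trough_sd`, are
#' analytically known to better than 1e-5 relative.
#'
#' @param t_ms Sample times, milliseconds.
#' @param trough_sd,rebound_sd Gaussian widths, ms.
#' @param rebound_frac Rebound amplitude fraction.
#' @param trough_time_ms,rebound_time_ms Lobe centres, ms.
#' @return Dimensionless waveform values (trough = -1).
#' @export
template_shape <- function(t_ms, trough_sd = 0.14, rebound_sd = 0.3,
                           rebound_frac = 0.25, trough_time_ms = 1,
                           rebound_time_ms = 2.5) {
  -exp(-(t_ms - trough_time_ms)^2 / (2 * trough_sd^2)) +
    rebound_frac * exp(-(t_ms - rebound_time_ms)^2 / (2 * rebound_sd^2))
}

#' Simulate the extracellular footprint of one unit
#'
#' Places electrodes on the HD-MEA pitch grid around the unit centre and
#' assigns each a copy of the biphasic template scaled by
#' `base_amplitude * g(dist)`, with `g(d) = exp(-d / footprint_decay_length)`
#' (monotone non-increasing, `g(0) = 1`). For the `"during"` epoch all
#' templates are additionally multiplied by `config$during_scale`, the
#' injected compression fold-change that the waveform-feature analysis is
#' meant to recover.
#'
#' @param config A [synth_config()].
#' @param unit_center Unit position `(x, y)` in micrometres. Snapped to the
#'   nearest grid electrode, which becomes the target electrode.
#' @param epochs Epoch labels to generate templates for.
#' @param grid_extent Number of electrode rows/columns on each side of the
#'   target electrode.
#' @param unit_id Identifier stored with the footprint.
#' @return A `unit_footprint` tibble with columns `unit_id`, `electrode_id`,
#'   `x_um`, `y_um`, `distance_um`, `epoch`, `time_ms`, `voltage_uv`, and
#'   attributes `target_electrode`, `sampling`, `pitch`.
#' @export
#' @examples
#' fp <- simulate_footprint(synth_config(seed = 1), grid_extent = 1)
#' dplyr::count(fp, electrode_id, epoch)
simulate_footprint <- function(config, unit_center = c(0, 0),
                               epochs = c("before", "during", "after"),
                               grid_extent = 2L, unit_id = 1L) {
  stopifnot(inherits(config, "synth_config"), length(unit_center) == 2)
  pitch <- config$grid_pitch
  center <- round(unit_center / pitch) * pitch
  offsets <- seq(-grid_extent, grid_extent) * pitch
  grid <- tidyr::expand_grid(x_um = center[1] + offsets, y_um = center[2] + offsets)
  grid <- mutate(grid,
    electrode_id = seq_len(nrow(grid)),
    distance_um = sqrt((.data$x_um - center[1])^2 + (.data$y_um - center[2])^2)
  )
  target <- grid$electrode_id[which.min(grid$distance_um)]

  n <- round(config$template_ms * config$mea_sampling / 1000)
  t_ms <- (seq_len(n) - 1) / config$mea_sampling * 1000
  shape <- template_shape(
    t_ms,
    trough_sd = config$trough_sd, rebound_sd = config$rebound_sd,
    rebound_frac = config$rebound_frac
  )

  out <- tidyr::expand_grid(grid, epoch = epochs) |>
    mutate(scale = config$base_amplitude *
      exp(-.data$distance_um / config$footprint_decay_length) *
      ifelse(.data$epoch == "during", config$during_scale, 1))
  out <- tidyr::expand_grid(out, tibble(time_ms = t_ms, shape = shape)) |>
    mutate(
      unit_id = unit_id,
      voltage_uv = .data$scale * .data$shape
    ) |>
    select(
      "unit_id", "electrode_id", "x_um", "y_um", "distance_um",
      "epoch", "time_ms", "voltage_uv"
    )
  structure(out,
    target_electrode = target, sampling = config$mea_sampling, pitch = pitch,
    class = c("unit_footprint", class(out))
  )
}

#' Simulate noisy spike-aligned waveforms around a mean template
#'
#' Draws `n_spikes` realizations per electrode and epoch by adding i.i.d.
#' Gaussian sample noise to the footprint's mean template, emulating the
#' spike-aligned waveform snippets from which epoch-mean templates are
#' computed.
#'
#' @param footprint A `unit_footprint` from [simulate_footprint()].
#' @param n_spikes Spikes (waveform snippets) per epoch.
#' @param noise_sd Per-sample Gaussian noise, microvolts.
#' @param seed Seed for the noise stream.
#' @return A tibble like `footprint` with an additional `spike` column.
#' @export
simulate_spike_waveforms <- function(footprint, n_spikes, noise_sd, seed = 1L) {
  stopifnot(n_spikes >= 1, noise_sd >= 0)
  base <- as_tibble(footprint)
  out <- tidyr::expand_grid(spike = seq_len(n_spikes), base)
  if (noise_sd > 0) {
    out$voltage_uv <- out$voltage_uv + with_substream(
      seed, "spike_waveforms", rnorm(nrow(out), sd = noise_sd)
    )
  }
  out
}
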