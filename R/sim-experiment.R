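#' Simulate a complete synchronized experiment
#'
#' Composes all generator stages into one bundle emulating a synchronized
#' AFM + HD-MEA + fluorescence recording: AFM force curves collected at
#' `curve_rate` Hz, a population of bursty spike trains (with any
#' stimulus-evoked spikes and rate modulation from the schedule), waveform
#' footprints for the compressed unit in before/during/after epochs, a
#' calcium trace for the compressed unit, and TTL event tables on each
#' stream clock together with their master-clock (FPGA) timestamps. Every
#' injected parameter is recorded in the ground-truth manifest.
#'
#' @param config A [synth_config()].
#' @param n_curves Number of force curves to generate.
#' @param curve_rate Force-curve collection rate, Hz (5 Hz mirrors the
#'   burst/inter-burst stiffness-sampling protocol).
#' @param curves_start Master time of the first curve, seconds.
#' @param target_indentation_nm Indentation depth of each curve, nm.
#' @param sync_interval Spacing of TTL sync markers, seconds.
#' @return An `experiment_bundle` list with elements `config`,
#'   `force_curves`, `spikes`, `bursts`, `evoked`, `footprint`, `calcium`,
#'   `ttl_events`, `schedule`, `manifest`.
#' @export
#' @examples
#' bundle <- simulate_experiment(synth_config(seed = 1, duration = 30, n_units = 3))
#' names(bundle)
simulate_experiment <- function(config, n_curves = 5, curve_rate = 5,
                                curves_start = 1.0,
                                target_indentation_nm = 900,
                                sync_interval = 10) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(config$schedule) > 0 &&
    any(config$schedule$contact_off > config$duration)) {
    abort("stimulus schedule extends past the recording duration.")
  }

  curve_times <- curves_start + (seq_len(n_curves) - 1) / curve_rate
  curve_times <- curve_times[curve_times < config$duration]
  force_curves <- map(seq_along(curve_times), function(i) {
    simulate_force_curve(config,
      target_indentation_nm = target_indentation_nm,
      timestamp = to_stream_time(config, curve_times[i], "afm"),
      curve_id = i
    )
  })

  pop <- simulate_spike_population(config)
  footprint <- if (config$n_units > 0) {
    simulate_footprint(config, unit_center = c(0, 0), unit_id = 1L)
  } else {
    NULL
  }
  calcium <- if (config$n_units > 0) {
    simulate_calcium_trace(
      pop$spikes$time_s[pop$spikes$unit_id == 1], config
    )
  } else {
    simulate_calcium_trace(numeric(), config)
  }

  master_events <- tibble(
    master_time_s = numeric(), label = character(), stream = character()
  )
  sched <- config$schedule
  if (nrow(sched) > 0) {
    master_events <- bind_rows(
      master_events,
      tibble(
        master_time_s = c(sched$contact_on, sched$contact_off),
        label = rep(c("contact_on", "contact_off"), each = nrow(sched)),
        stream = "afm"
      )
    )
  }
  sync_times <- seq(sync_interval / 2, config$duration, by = sync_interval)
  master_events <- bind_rows(
    master_events,
    tibble(master_time_s = sync_times, label = "sync", stream = "afm"),
    tibble(master_time_s = sync_times, label = "sync", stream = "camera")
  ) |> arrange(.data$stream, .data$master_time_s)

  ttl_events <- bind_rows(
    tibble(
      stream = "master",
      event_time_s = master_events$master_time_s,
      label = master_events$label,
      source_stream = master_events$stream
    ),
    tibble(
      stream = master_events$stream,
      event_time_s = to_stream_time(
        config, master_events$master_time_s, "afm"
      ) * (master_events$stream == "afm") +
        to_stream_time(
          config, master_events$master_time_s, "camera"
        ) * (master_events$stream == "camera"),
      label = master_events$label,
      source_stream = master_events$stream
    )
  )

  manifest <- list(
    seed = config$seed,
    true_E_pa = config$E_true,
    true_contact_height_um = config$contact_height,
    base_rate_hz = config$base_rate,
    burst_rate_hz = config$burst_rate,
    rate_factor_during = config$rate_factor_during,
    during_scale = config$during_scale,
    base_amplitude_uv = config$base_amplitude,
    trough_fwhm_ms = 2 * sqrt(2 * log(2)) * config$trough_sd,
    ca_decay_tau_s = config$ca_decay_tau,
    ca_rise_s = config$ca_rise,
    clock_offsets = config$clock_offsets,
    curve_master_times_s = curve_times,
    curve_epochs = classify_curve_epoch(curve_times, pop$bursts),
    bursts = pop$bursts,
    evoked = pop$evoked,
    calcium_truth = attr(calcium, "truth")
  )

  structure(
    list(
      config = config, force_curves = force_curves,
      spikes = pop$spikes, bursts = pop$bursts, evoked = pop$evoked,
      footprint = footprint, calcium = calcium,
      ttl_events = ttl_events, schedule = sched, manifest = manifest
    ),
    class = "experiment_bundle"
  )
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf(
    "<experiment_bundle> %d force curves | %d units, %d spikes | %d bursts | %d TTL events\n",
    length(x$force_curves), x$config$n_units, nrow(x$spikes),
    nrow(x$bursts), nrow(x$ttl_events)
  ))
  invisible(x)
}
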