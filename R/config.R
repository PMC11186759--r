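#' Configuration for a synthetic multimodal experiment
#'
#' Builds the parameter set for the synthetic-data generator that emulates a
#' synchronized AFM + HD-MEA + fluorescence recording of a cultured neuronal
#' network. Every generated artefact (force curves, spike trains, waveform
#' footprints, calcium trace, TTL events) is derived deterministically from
#' `seed`, and every injected ground-truth value is recorded in the bundle's
#' manifest so that analysis functions can be tested by parameter recovery.
#'
#' Rate parameters describe a network whose units share a two-state
#' (burst / inter-burst) Markov rate schedule: each unit fires as an
#' inhomogeneous Poisson process at `base_rate` between bursts and at
#' `burst_rate` inside bursts, with burst onsets at `burst_onset_rate` and
#' exits at `burst_exit_rate` (exponential sojourns, so mean burst duration
#' is `1/burst_exit_rate` and mean inter-burst interval `1/burst_onset_rate`).
#'
#' @param seed Integer master seed. All per-artefact RNG streams are derived
#'   from it, so adding one artefact never perturbs the others.
#' @param n_units Number of spike-sorted units.
#' @param duration Recording duration in seconds (master clock).
#' @param base_rate Per-unit firing rate outside bursts, Hz.
#' @param burst_rate Per-unit firing rate inside network bursts, Hz.
#' @param burst_onset_rate Rate of entering a network burst, Hz.
#' @param burst_exit_rate Rate of leaving a network burst, Hz.
#' @param E_true True apparent Young's modulus of the simulated soma, Pa.
#' @param bead_radius Radius of the spherical AFM probe, micrometres.
#' @param poisson_ratio Poisson ratio of the sample; 0.5 is the
#'   incompressible-cell limit commonly assumed in AFM cell mechanics.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param approach_speed Piezo approach/retract speed, micrometres per second.
#' @param afm_sampling AFM sampling rate, Hz.
#' @param force_noise_sd Gaussian force noise, N (e.g. `10e-12` for 10 pN).
#' @param baseline_drift Optional linear baseline force drift, N/s.
#' @param contact_height Piezo height of the true contact point, micrometres.
#' @param grid_pitch Electrode pitch of the HD-MEA, micrometres.
#' @param footprint_decay_length Length constant of the exponential decay of
#'   spike amplitude with distance from the unit centre, micrometres.
#' @param base_amplitude Trough amplitude of the template on the closest
#'   electrode, microvolts.
#' @param during_scale Multiplicative template scale applied during
#'   compression epochs (the injected fold-change recovered by the
#'   waveform-feature analysis).
#' @param trough_sd,rebound_sd Gaussian widths of the biphasic template's
#'   negative trough and positive rebound, milliseconds.
#' @param rebound_frac Rebound amplitude as a fraction of trough amplitude.
#' @param template_ms Template duration, milliseconds.
#' @param mea_sampling HD-MEA sampling rate, Hz.
#' @param ca_rise Linear rise time of the calcium kernel, seconds.
#' @param ca_decay_tau Exponential decay constant of the calcium kernel,
#'   seconds.
#' @param ca_amplitude Kernel amplitude per spike, dF/F units.
#' @param ca_noise_sd Gaussian frame noise on the dF/F trace.
#' @param frame_rate Camera frame rate, frames per second (warning above 45,
#'   the hardware bound of the emulated camera).
#' @param clock_offsets Named list with elements `afm` and `camera`, each a
#'   list `list(offset = s, drift = dimensionless)`. Stream clocks read
#'   `t_stream = drift * t_master + offset`, so with `drift = 1` a stream
#'   timestamp equals the master time plus the offset.
#' @param schedule Stimulus schedule, a tibble as built by [mech_stimulus()]
#'   (zero-row default = spontaneous activity only).
#' @param evoked_latency_mean,evoked_latency_sd Mean and s.d. (seconds) of
#'   the evoked-spike latency injected after each stimulus contact for
#'   stimuli flagged `evoke = TRUE`.
#' @param rate_factor_during Multiplicative firing-rate change applied during
#'   the contact window of stimuli flagged `modulates_rate = TRUE`.
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1, n_units = 4, duration = 30)
#' cfg$base_rate
synth_config <- function(seed = 1L,
                         n_units = 10L,
                         duration = 300,
                         base_rate = 2,
                         burst_rate = 50,
                         burst_onset_rate = 0.05,
                         burst_exit_rate = 0.5,
                         E_true = 400,
                         bead_radius = 2.5,
                         poisson_ratio = 0.5,
                         spring_constant = 0.02,
                         approach_speed = 10,
                         afm_sampling = 1e5,
                         force_noise_sd = 10e-12,
                         baseline_drift = 0,
                         contact_height = 1.0,
                         grid_pitch = 17.5,
                         footprint_decay_length = 30,
                         base_amplitude = 190,
                         during_scale = 1.13,
                         trough_sd = 0.14,
                         rebound_sd = 0.3,
                         rebound_frac = 0.25,
                         template_ms = 4,
                         mea_sampling = 2e4,
                         ca_rise = 0.2,
                         ca_decay_tau = 26.2,
                         ca_amplitude = 0.5,
                         ca_noise_sd = 0,
                         frame_rate = 45,
                         clock_offsets = list(
                           afm = list(offset = 0.5, drift = 1),
                           camera = list(offset = 0.25, drift = 1)
                         ),
                         schedule = mech_stimulus(),
                         evoked_latency_mean = 0.130,
                         evoked_latency_sd = 0.05,
                         rate_factor_during = 1.25) {
  stopifnot(
    is.numeric(seed), length(seed) == 1, is.finite(seed),
    n_units >= 0, duration > 0,
    base_rate >= 0, burst_rate >= 0,
    burst_onset_rate >= 0, burst_exit_rate > 0,
    E_true > 0, bead_radius > 0, spring_constant > 0,
    approach_speed > 0, afm_sampling > 0, force_noise_sd >= 0,
    grid_pitch > 0, footprint_decay_length > 0, base_amplitude > 0,
    during_scale > 0, frame_rate > 0, ca_rise > 0, ca_decay_tau > 0,
    rate_factor_during >= 0
  )
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    abort("`poisson_ratio` must lie in [0, 0.5] (0.5 = incompressible limit).")
  }
  if (frame_rate > 45) {
    warn("`frame_rate` exceeds the 45 fps bound of the emulated camera.")
  }
  stopifnot(is.list(clock_offsets), all(c("afm", "camera") %in% names(clock_offsets)))
  schedule <- validate_schedule(schedule, duration)
  cfg <- list(
    seed = as.integer(seed), n_units = as.integer(n_units),
    duration = duration, base_rate = base_rate, burst_rate = burst_rate,
    burst_onset_rate = burst_onset_rate, burst_exit_rate = burst_exit_rate,
    E_true = E_true, bead_radius = bead_radius,
    poisson_ratio = poisson_ratio, spring_constant = spring_constant,
    approach_speed = approach_speed, afm_sampling = afm_sampling,
    force_noise_sd = force_noise_sd, baseline_drift = baseline_drift,
    contact_height = contact_height,
    grid_pitch = grid_pitch,
    footprint_decay_length = footprint_decay_length,
    base_amplitude = base_amplitude, during_scale = during_scale,
    trough_sd = trough_sd, rebound_sd = rebound_sd,
    rebound_frac = rebound_frac, template_ms = template_ms,
    mea_sampling = mea_sampling,
    ca_rise = ca_rise, ca_decay_tau = ca_decay_tau,
    ca_amplitude = ca_amplitude, ca_noise_sd = ca_noise_sd,
    frame_rate = frame_rate, clock_offsets = clock_offsets,
    schedule = schedule,
    evoked_latency_mean = evoked_latency_mean,
    evoked_latency_sd = evoked_latency_sd,
    rate_factor_during = rate_factor_during
  )
  structure(cfg, class = "synth_config")
}

#' Build a mechanical-stimulus schedule
#'
#' Each row describes one mechanical stimulation of a neuronal soma by the
#' beaded cantilever: a fast `transient` touch, a `static` compression held
#' at the setpoint force, or a `staircase` of stepwise increasing setpoints.
#'
#' @param kind Stimulus kind, one of `"transient"`, `"static"`, `"staircase"`.
#' @param setpoint_force Setpoint force, nN.
#' @param approach_speed Indentation speed, micrometres per second.
#' @param contact_on,contact_off Contact window on the master clock, seconds.
#' @param evoke Should an evoked spike (latency drawn from the configured
#'   distribution) be injected at contact for every unit?
#' @param modulates_rate Should the during-contact firing rate be multiplied
#'   by the configured `rate_factor_during`?
#' @param staircase_start,staircase_stop,staircase_step Force staircase
#'   parameters in nN (only for `kind = "staircase"`).
#' @param staircase_interval Dwell per staircase step, seconds.
#'
#' @return A tibble with one row per stimulus (zero rows if called with no
#'   arguments).
#' @export
#' @examples
#' mech_stimulus("static", setpoint_force = 200, contact_on = 170, contact_off = 230)
mech_stimulus <- function(kind = character(), setpoint_force = numeric(),
                          approach_speed = 10,
                          contact_on = numeric(), contact_off = numeric(),
                          evoke = FALSE, modulates_rate = FALSE,
                          staircase_start = NA_real_, staircase_stop = NA_real_,
                          staircase_step = NA_real_, staircase_interval = NA_real_) {
  if (length(kind) == 0) {
    return(tibble(
      stimulus_id = integer(), kind = character(), setpoint_force = numeric(),
      approach_speed = numeric(), contact_on = numeric(), contact_off = numeric(),
      evoke = logical(), modulates_rate = logical(),
      staircase_start = numeric(), staircase_stop = numeric(),
      staircase_step = numeric(), staircase_interval = numeric()
    ))
  }
  out <- tibble(
    kind = kind, setpoint_force = setpoint_force,
    approach_speed = approach_speed,
    contact_on = contact_on, contact_off = contact_off,
    evoke = evoke, modulates_rate = modulates_rate,
    staircase_start = staircase_start, staircase_stop = staircase_stop,
    staircase_step = staircase_step, staircase_interval = staircase_interval
  )
  out <- mutate(out, stimulus_id = seq_len(nrow(out)), .before = 1)
  out
}

validate_schedule <- function(schedule, duration) {
  schedule <- as_tibble(schedule)
  if (nrow(schedule) == 0) return(schedule)
  stopifnot(all(schedule$kind %in% c("transient", "static", "staircase")))
  if (any(schedule$contact_on >= schedule$contact_off)) {
    abort("stimulus schedule: `contact_on` must precede `contact_off`.")
  }
  if (any(schedule$contact_on < 0) || any(schedule$contact_off > duration)) {
    abort("stimulus schedule extends past the recording duration.")
  }
  has_stairs <- !is.na(schedule$staircase_start)
  if (any(has_stairs & schedule$kind != "staircase")) {
    abort("staircase parameters are only allowed with kind = \"staircase\".")
  }
  schedule
}

#' Map times between a stream clock and the master clock
#'
#' Stream clocks (AFM, camera) are modelled as affine functions of the
#' HD-MEA master clock: `t_stream = drift * t_master + offset`.
#'
#' @param config A [synth_config()].
#' @param t Times to convert, seconds.
#' @param stream `"afm"` or `"camera"`.
#' @return Converted times, seconds.
#' @export
to_stream_time <- function(config, t, stream) {
  ck <- config$clock_offsets[[match.arg(stream, c("afm", "camera"))]]
  ck$drift * t + ck$offset
}

#' @rdname to_stream_time
#' @export
to_master_time <- function(config, t, stream) {
  ck <- config$clock_offsets[[match.arg(stream, c("afm", "camera"))]]
  (t - ck$offset) / ck$drift
}

# Run `code` under a deterministic RNG substream derived from (seed, key),
# restoring the caller's RNG state afterwards. Keyed substreams mean adding
# one artefact to the generator never perturbs the others.
with_substream <- function(seed, key, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  sub <- (as.double(seed) * 1000003 + sum(utf8ToInt(key)) * 7919) %% 2147483647
  set.seed(as.integer(sub))
  force(code)
}
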