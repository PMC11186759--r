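#' Simulate the shared network-burst schedule
#'
#' The network alternates between an inter-burst state and a burst state
#' according to a two-state Markov process with exponential sojourn times
#' (mean inter-burst interval `1/burst_onset_rate`, mean burst duration
#' `1/burst_exit_rate`). The schedule is shared by all units, which is what
#' makes the simulated bursts network-synchronous.
#'
#' @param config A [synth_config()].
#' @return A tibble of burst intervals with columns `start`, `end` (s),
#'   clipped to `[0, duration]`.
#' @export
simulate_burst_schedule <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$burst_onset_rate <= 0) {
    return(tibble(start = numeric(), end = numeric()))
  }
  with_substream(config$seed, "burst_schedule", {
    t <- 0
    starts <- numeric()
    ends <- numeric()
    while (t < config$duration) {
      t <- t + rexp(1, config$burst_onset_rate)
      if (t >= config$duration) break
      dur <- rexp(1, config$burst_exit_rate)
      starts <- c(starts, t)
      ends <- c(ends, min(t + dur, config$duration))
      t <- t + dur
    }
    tibble(start = starts, end = ends)
  })
}

# Piecewise-constant rate profile for one unit: base rate outside bursts,
# burst rate inside, multiplied by the stimulus rate factor inside the
# contact window of rate-modulating stimuli.
rate_breakpoints <- function(config, bursts) {
  edges <- c(0, config$duration, bursts$start, bursts$end)
  sched <- config$schedule
  if (nrow(sched) > 0) {
    mod <- sched[sched$modulates_rate, , drop = FALSE]
    edges <- c(edges, mod$contact_on, mod$contact_off)
  }
  edges <- sort(unique(pmin(pmax(edges, 0), config$duration)))
  lo <- head(edges, -1)
  hi <- tail(edges, -1)
  mid <- (lo + hi) / 2
  in_burst <- vapply(mid, function(m) any(m >= bursts$start & m <= bursts$end), logical(1))
  rate <- ifelse(in_burst, config$burst_rate, config$base_rate)
  if (nrow(sched) > 0) {
    mod <- sched[sched$modulates_rate, , drop = FALSE]
    if (nrow(mod) > 0) {
      in_stim <- vapply(mid, function(m) any(m >= mod$contact_on & m <= mod$contact_off), logical(1))
      rate <- rate * ifelse(in_stim, config$rate_factor_during, 1)
    }
  }
  tibble(lo = lo, hi = hi, rate = rate)
}

#' Simulate a population of spike trains
#'
#' Each unit is an inhomogeneous Poisson process whose rate follows the
#' shared burst schedule (see [simulate_burst_schedule()]), optionally
#' modified by the stimulus schedule: stimuli flagged `modulates_rate`
#' multiply the rate inside their contact window by
#' `config$rate_factor_during`, and stimuli flagged `evoke` inject one
#' evoked spike per unit at `contact_on + latency`, with the latency drawn
#' from `Normal(evoked_latency_mean, evoked_latency_sd)` truncated at zero.
#' All injected ground truth (burst intervals, per-stimulus latencies, rate
#' factors) is returned for parameter-recovery tests.
#'
#' @param config A [synth_config()].
#' @param bursts Optional pre-computed burst schedule (a tibble with
#'   `start`/`end`); defaults to [simulate_burst_schedule()].
#' @return A list with elements `spikes` (tibble `unit_id`, `time_s`,
#'   sorted within unit, deduplicated at the HD-MEA sampling resolution),
#'   `bursts`, and `evoked` (tibble `stimulus_id`, `unit_id`,
#'   `true_latency_s`, `spike_time_s`).
#' @export
#' @examples
#' pop <- simulate_spike_population(synth_config(seed = 1, duration = 20))
#' head(pop$spikes)
simulate_spike_population <- function(config, bursts = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(bursts)) bursts <- simulate_burst_schedule(config)
  profile <- rate_breakpoints(config, bursts)

  spike_list <- vector("list", config$n_units)
  for (i in seq_len(config$n_units)) {
    times <- with_substream(config$seed, paste0("unit_", i), {
      seg_times <- pmap(profile, function(lo, hi, rate) {
        if (rate <= 0 || hi <= lo) return(numeric())
        n <- rpois(1, rate * (hi - lo))
        sort(runif(n, lo, hi))
      })
      unlist(seg_times)
    })
    spike_list[[i]] <- tibble(unit_id = i, time_s = times)
  }
  spikes <- bind_rows(spike_list)

  evoked <- tibble(
    stimulus_id = integer(), unit_id = integer(),
    true_latency_s = numeric(), spike_time_s = numeric()
  )
  sched <- config$schedule
  if (nrow(sched) > 0 && any(sched$evoke) && config$n_units > 0) {
    ev <- sched[sched$evoke, , drop = FALSE]
    evoked <- with_substream(config$seed, "evoked_latencies", {
      grid <- tidyr::expand_grid(stimulus_id = ev$stimulus_id, unit_id = seq_len(config$n_units))
      lat <- rnorm(nrow(grid), config$evoked_latency_mean, config$evoked_latency_sd)
      while (any(lat <= 0)) {
        bad <- lat <= 0
        lat[bad] <- rnorm(sum(bad), config$evoked_latency_mean, config$evoked_latency_sd)
      }
      grid$true_latency_s <- lat
      grid$spike_time_s <- ev$contact_on[match(grid$stimulus_id, ev$stimulus_id)] + lat
      grid
    })
    evoked <- filter(evoked, .data$spike_time_s <= config$duration)
    spikes <- bind_rows(
      spikes,
      tibble(unit_id = evoked$unit_id, time_s = evoked$spike_time_s)
    )
  }

  if (nrow(spikes) > 0) {
    res <- 1 / config$mea_sampling
    spikes <- spikes |>
      arrange(.data$unit_id, .data$time_s) |>
      group_by(.data$unit_id) |>
      filter(is.na(dplyr::lag(.data$time_s)) |
        .data$time_s - dplyr::lag(.data$time_s) >= res) |>
      ungroup()
  }
  list(spikes = spikes, bursts = bursts, evoked = evoked)
}
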