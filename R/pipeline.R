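#' Configuration of an end-to-end analysis run
#'
#' Collects every tunable of the pipeline with its default. Unknown keys
#' are rejected, so configs serialize losslessly and typos fail loudly.
#'
#' @param seed Master seed for the synthetic bundle.
#' @param synth Named list of overrides passed to [synth_config()].
#' @param n_curves Force curves to simulate and fit.
#' @param cutoff_nm Indentation depth cutoff for Hertz fits, nm.
#' @param threshold_multiple Contact-detection threshold, baseline-sd units.
#' @param nu Poisson ratio for Hertz fits.
#' @param baseline_fraction Baseline window, fraction of the approach.
#' @param min_curves Minimum usable curves per stiffness cycle.
#' @param bin_s Firing-rate bin width, s.
#' @param epoch_pre_s,epoch_post_s Before/after epoch lengths, s.
#' @param burst_bin,burst_threshold,burst_min_duration,burst_merge_gap
#'   Network-burst detector parameters ([detect_network_bursts()]).
#' @param latency_window_s Evoked-spike search window, s.
#' @param responder_k,responder_window_s Responder-classification
#'   threshold (pre-stimulus-sd units) and search window, s.
#' @param pairing_tolerance_s TTL pairing tolerance, s.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(seed = 1L, synth = list(), n_curves = 5,
                            cutoff_nm = 750, threshold_multiple = 5, nu = 0.5,
                            baseline_fraction = 0.3, min_curves = 3,
                            bin_s = 30, epoch_pre_s = 150, epoch_post_s = 150,
                            burst_bin = 0.025, burst_threshold = 3,
                            burst_min_duration = 0.05, burst_merge_gap = 0.1,
                            latency_window_s = 0.5,
                            responder_k = 5, responder_window_s = 10,
                            pairing_tolerance_s = 1) {
  cfg <- as.list(environment())
  allowed <- names(formals(synth_config))
  unknown <- setdiff(names(cfg$synth), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown synth config keys: ", paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "analysis_config")
}

default_schedule <- function(duration) {
  mech_stimulus(
    kind = "static", setpoint_force = 200, approach_speed = 10,
    contact_on = duration / 2 - 30, contact_off = duration / 2 + 30,
    evoke = TRUE, modulates_rate = TRUE
  )
}

run_stage <- function(stage, errors_env, code) {
  tryCatch(force(code), error = function(e) {
    errors_env$errors[[stage]] <- conditionMessage(e)
    NULL
  })
}

#' Run the full mechano-electrophysiology analysis pipeline
#'
#' Simulates (or loads) a synchronized experiment bundle, aligns the
#' stream clocks from TTL events, then runs the mechanics (Hertz fits and
#' cycle stiffness, burst/IBI labelling of curve times), spike-train
#' (epoch rates, burst detection, evoked latency), waveform-feature and
#' calcium stages, assembles the statistics table, and, for synthetic
#' input, a parameter-recovery table comparing every estimate with the
#' generator's manifest truth. Fully deterministic given the config.
#'
#' @param config An [analysis_config()].
#' @param input_dir Optional directory written by [write_bundle()]; when
#'   given, artefacts are loaded from disk instead of simulated (stages
#'   whose inputs are missing are reported as stage errors).
#' @return A `results_report` list of tibbles (`stiffness_curves`,
#'   `stiffness_cycles`, `curve_epochs`, `epoch_rates`, `rate_change`,
#'   `latencies`, `bursts_detected`, `feature_change`,
#'   `calcium_responses`, `sync`, `statistics`, `recovery`, `provenance`),
#'   plus `stage_errors`.
#' @export
#' @examples
#' \donttest{
#' cfg <- analysis_config(seed = 1, synth = list(duration = 60, n_units = 4))
#' rep <- run_pipeline(cfg)
#' rep$statistics
#' }
run_pipeline <- function(config, input_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  errs <- new.env()
  errs$errors <- list()

  synth_args <- config$synth
  synth_args$seed <- config$seed
  if (is.null(synth_args$duration)) synth_args$duration <- 400
  if (is.null(synth_args$schedule)) {
    synth_args$schedule <- default_schedule(synth_args$duration)
  }
  scfg <- do.call(synth_config, synth_args)

  if (is.null(input_dir)) {
    bundle <- simulate_experiment(scfg, n_curves = config$n_curves)
    curves <- bundle$force_curves
    spikes <- bundle$spikes
    templates <- bundle$footprint
    calcium <- bundle$calcium
    ttl <- bundle$ttl_events
    manifest <- bundle$manifest
  } else {
    loaded <- run_stage("load", errs, read_bundle(input_dir))
    curves <- loaded$force_curves
    spikes <- loaded$spikes
    templates <- loaded$templates
    calcium <- if (!is.null(loaded$calcium)) {
      structure(
        tibble(
          frame_time_s = to_master_time(scfg, loaded$calcium$frame_time_s, "camera"),
          dff = loaded$calcium$dff
        ),
        frame_rate = scfg$frame_rate,
        class = c("calcium_trace", class(tibble()))
      )
    }
    ttl <- loaded$ttl_events
    manifest <- loaded$manifest
  }
  sched <- scfg$schedule

  # --- synchronization ------------------------------------------------
  sync_tab <- run_stage("sync", errs, {
    maps <- map(c("afm", "camera"), function(stm) {
      se <- ttl[ttl$stream == stm & ttl$label == "sync", ]
      me <- ttl[ttl$stream == "master" & ttl$label == "sync", ]
      if (!is.null(ttl$source_stream)) me <- me[me$source_stream == stm, ]
      build_sync_map(se$event_time_s, me$event_time_s,
        pairing_tolerance = config$pairing_tolerance_s, stream = stm
      )
    })
    list_rbind(map(maps, tidy))
  })

  # --- mechanics ------------------------------------------------------
  fits <- run_stage("mechanics", errs, {
    map(curves, fit_force_curve,
      cutoff_nm = config$cutoff_nm,
      threshold_multiple = config$threshold_multiple, nu = config$nu,
      baseline_fraction = config$baseline_fraction
    )
  })
  stiffness_curves <- if (!is.null(fits)) list_rbind(map(fits, tidy))
  stiffness_cycles <- run_stage("mechanics", errs, {
    cycle_stiffness(stiffness_curves, min_curves = config$min_curves,
      neuron_id = 1L, cycle_time = stiffness_curves$timestamp[1]
    )
  })

  # --- spike-train analytics -----------------------------------------
  bursts_detected <- run_stage("ephys", errs, {
    detect_network_bursts(spikes,
      span = c(0, scfg$duration), bin = config$burst_bin,
      rate_threshold = config$burst_threshold,
      min_duration = config$burst_min_duration,
      merge_gap = config$burst_merge_gap
    )
  })
  curve_epochs <- run_stage("ephys", errs, if (!is.null(stiffness_curves) && !is.null(bursts_detected)) {
    afm_map <- build_sync_map(
      ttl$event_time_s[ttl$stream == "afm" & ttl$label == "sync"],
      ttl$event_time_s[ttl$stream == "master" & ttl$label == "sync" &
        ttl$source_stream == "afm"],
      pairing_tolerance = config$pairing_tolerance_s, stream = "afm"
    )
    master_ts <- map_time(afm_map, stiffness_curves$timestamp)
    tibble(
      curve_id = stiffness_curves$curve_id,
      master_time_s = master_ts,
      epoch = classify_curve_epoch(master_ts, bursts_detected)
    )
  })

  epoch_rates <- NULL
  rate_change <- NULL
  latencies <- NULL
  if (nrow(sched) > 0) {
    stim <- sched[1, ]
    epochs <- epoch_set(stim$contact_on, stim$contact_off,
      pre_s = config$epoch_pre_s, post_s = config$epoch_post_s
    )
    epoch_rates <- run_stage("ephys", errs, epoch_firing_rates(spikes, epochs))
    rate_change <- run_stage("ephys", errs, {
      wide <- tidyr::pivot_wider(
        epoch_rates[, c("unit_id", "epoch", "rate_hz")],
        names_from = "epoch", values_from = "rate_hz"
      )
      wide <- filter(wide, .data$before > 0)
      mutate(wide, pct_change_during = percent_rate_change(.data$before, .data$during))
    })
    latencies <- run_stage("ephys", errs, {
      list_rbind(map(which(sched$evoke), function(i) {
        evoked_spike_latency(spikes, sched$contact_on[i],
          search_window = config$latency_window_s
        ) |>
          mutate(stimulus_id = sched$stimulus_id[i], .before = 1)
      }))
    })
  }

  # --- waveform features ---------------------------------------------
  feature_change <- run_stage("waveforms", errs, {
    if (is.null(templates)) abort("no templates available")
    amplitude_change_vs_distance(templates,
      target_electrode = attr(templates, "target_electrode") %||%
        templates$electrode_id[which.min(
          (templates$x_um - 0)^2 + (templates$y_um - 0)^2
        )],
      sampling = attr(templates, "sampling") %||% scfg$mea_sampling
    )
  })

  # --- calcium --------------------------------------------------------
  calcium_responses <- run_stage("calcium", errs, if (!is.null(calcium) && nrow(sched) > 0) {
    stim <- sched[1, ]
    resp <- classify_responder(calcium, stim$contact_on,
      k = config$responder_k, search_window_s = config$responder_window_s
    )
    if (resp$responded) {
      pk <- which(calcium$frame_time_s == resp$peak_time_s)[1]
      onset <- response_onset(calcium, pk)
      tau <- fit_decay_tau(calcium, pk)
      dplyr::bind_cols(resp, onset[, c("onset_time_s", "flagged")], tau[, "tau_s"])
    } else {
      dplyr::bind_cols(resp,
        tibble(onset_time_s = NA_real_, flagged = NA, tau_s = NA_real_)
      )
    }
  })

  # --- statistics -----------------------------------------------------
  statistics <- run_stage("stats", errs, {
    rows <- list()
    if (!is.null(rate_change) && nrow(rate_change) >= 3) {
      wt <- paired_wilcoxon(rate_change$during, rate_change$before)
      rows$wilcoxon <- tibble(
        test = "wilcoxon_signed_rank", inputs = "rate during vs before",
        n = wt$n, statistic = wt$statistic, p_value = wt$p_value
      )
    }
    if (!is.null(stiffness_curves) && !is.null(curve_epochs)) {
      eb <- stiffness_curves$E_apparent_pa[curve_epochs$epoch == "burst"]
      ei <- stiffness_curves$E_apparent_pa[curve_epochs$epoch == "IBI"]
      if (length(eb) > 0 && length(ei) > 0) {
        mw <- mannwhitney_u(eb, ei)
        rows$mw <- tibble(
          test = "mann_whitney_u", inputs = "E burst vs IBI",
          n = mw$n_x + mw$n_y, statistic = mw$statistic, p_value = mw$p_value
        )
      }
    }
    list_rbind(rows)
  })

  # --- parameter recovery against the manifest ------------------------
  recovery <- run_stage("recovery", errs, if (!is.null(manifest)) {
    rows <- list()
    if (!is.null(stiffness_cycles)) {
      rows$E <- tibble(
        parameter = "E_pa", truth = as.numeric(manifest$true_E_pa),
        estimate = stiffness_cycles$E_mean_pa
      )
    }
    if (!is.null(feature_change)) {
      rows$scale <- tibble(
        parameter = "during_scale", truth = as.numeric(manifest$during_scale),
        estimate = mean(feature_change$amplitude_ratio)
      )
    }
    if (!is.null(rate_change) && nrow(rate_change) > 0) {
      rows$rate <- tibble(
        parameter = "rate_factor_during",
        truth = as.numeric(manifest$rate_factor_during),
        estimate = 1 + median(rate_change$pct_change_during) / 100
      )
    }
    if (!is.null(bursts_detected)) {
      man_bursts <- as_tibble(manifest$bursts)
      rows$bursts <- tibble(
        parameter = "burst_jaccard", truth = 1,
        estimate = interval_jaccard(bursts_detected, man_bursts)
      )
    }
    if (!is.null(sync_tab)) {
      for (stm in sync_tab$stream) {
        ck <- manifest$clock_offsets[[stm]]
        row <- sync_tab[sync_tab$stream == stm, ]
        # config convention t_stream = drift * t_master + offset; the map
        # estimates the inverse direction
        rows[[paste0("off_", stm)]] <- tibble(
          parameter = paste0("clock_offset_", stm),
          truth = as.numeric(ck$offset),
          estimate = -row$offset_s / row$drift
        )
      }
    }
    list_rbind(rows) |>
      mutate(abs_error = abs(.data$estimate - .data$truth))
  })

  report <- structure(
    list(
      stiffness_curves = stiffness_curves,
      stiffness_cycles = stiffness_cycles,
      curve_epochs = curve_epochs,
      epoch_rates = epoch_rates,
      rate_change = rate_change,
      latencies = latencies,
      bursts_detected = bursts_detected,
      feature_change = feature_change,
      calcium_responses = calcium_responses,
      sync = sync_tab,
      statistics = statistics,
      recovery = recovery,
      provenance = tibble(
        package_version = as.character(utils::packageVersion("mechanoephys")),
        seed = config$seed,
        config_hash = rlang::hash(unclass(config))
      ),
      stage_errors = errs$errors
    ),
    class = "results_report"
  )
  if (length(errs$errors) > 0) {
    warn(paste0(
      "pipeline stages failed: ",
      paste(names(errs$errors), unlist(errs$errors), sep = ": ", collapse = "; ")
    ))
  }
  report
}

#' @export
print.results_report <- function(x, ...) {
  cat("<results_report>\n")
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) {
      cat(sprintf("  %-18s %d rows\n", nm, nrow(x[[nm]])))
    }
  }
  if (length(x$stage_errors) > 0) {
    cat("  stage errors:", paste(names(x$stage_errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a results report to a directory of CSV tables
#'
#' Every tibble of the report becomes `<name>.csv`; a `summary.json`
#' captures headline quantities and provenance. Output is deterministic:
#' rerunning the same config reproduces byte-identical files.
#'
#' @param report A `results_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "results_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    tab <- report[[nm]]
    if (is.data.frame(tab) && nrow(tab) > 0) {
      readr::write_csv(tab, file.path(dir, paste0(nm, ".csv")), progress = FALSE)
    }
  }
  summary <- list(
    provenance = as.list(report$provenance),
    stage_errors = report$stage_errors,
    headline = list(
      E_mean_pa = if (!is.null(report$stiffness_cycles)) report$stiffness_cycles$E_mean_pa,
      median_rate_change_pct = if (!is.null(report$rate_change) &&
        nrow(report$rate_change) > 0) {
        median(report$rate_change$pct_change_during)
      },
      mean_amplitude_ratio = if (!is.null(report$feature_change)) {
        mean(report$feature_change$amplitude_ratio)
      },
      calcium_tau_s = if (!is.null(report$calcium_responses)) {
        report$calcium_responses$tau_s
      }
    )
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(dir)
}
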