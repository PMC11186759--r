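#' Extract features from a mean spike waveform
#'
#' Standard extracellular waveform features of a (negative-trough) mean
#' template: `amplitude_uv` is the baseline-to-trough magnitude, with the
#' baseline taken as the mean of the first 10% of samples;
#' `halfwidth_ms` is the full width of the trough at half its depth, with
#' linear interpolation between samples (first crossing on each side of
#' the trough); `repolarization_slope_uv_ms` is the least-squares slope of
#' the waveform from the trough to the first sample that re-crosses the
#' baseline (an alternative definition, the maximum post-trough
#' derivative, is available via `slope_method`).
#'
#' @param voltage_uv Template samples, microvolts.
#' @param sampling Sampling rate, Hz.
#' @param baseline_fraction Fraction of leading samples defining the
#'   baseline (default 0.1).
#' @param amplitude_mode `"trough"` (baseline-to-trough, default) or
#'   `"peak_to_peak"`.
#' @param slope_method `"recross_fit"` (default) or `"max_derivative"`.
#' @return One-row tibble with `amplitude_uv`, `halfwidth_ms`,
#'   `repolarization_slope_uv_ms`.
#' @export
#' @examples
#' t <- seq(0, 4, by = 0.05)
#' w <- 200 * template_shape(t)
#' extract_waveform_features(w, sampling = 2e4)
extract_waveform_features <- function(voltage_uv, sampling,
                                      baseline_fraction = 0.1,
                                      amplitude_mode = c("trough", "peak_to_peak"),
                                      slope_method = c("recross_fit", "max_derivative")) {
  amplitude_mode <- match.arg(amplitude_mode)
  slope_method <- match.arg(slope_method)
  stopifnot(sampling > 0, length(voltage_uv) >= 10)
  if (max(voltage_uv) == min(voltage_uv)) abort("no spike deflection: flat template.")
  n_base <- max(1L, floor(length(voltage_uv) * baseline_fraction))
  baseline <- mean(voltage_uv[seq_len(n_base)])
  w <- voltage_uv - baseline
  dt_ms <- 1000 / sampling
  t_ms <- (seq_along(w) - 1) * dt_ms

  i_tr <- which.min(w)
  depth <- -w[i_tr]
  if (depth <= 0) abort("no spike deflection: template has no negative trough.")
  amplitude <- switch(amplitude_mode,
    trough = depth,
    peak_to_peak = max(w) - min(w)
  )

  half <- -depth / 2
  # first half-depth crossing walking left, then right, from the trough
  left <- NA_real_
  for (i in if (i_tr >= 2) seq(i_tr, 2) else integer()) {
    if (w[i - 1] > half && w[i] <= half) {
      left <- t_ms[i - 1] + (half - w[i - 1]) / (w[i] - w[i - 1]) * dt_ms
      break
    }
  }
  right <- NA_real_
  if (i_tr < length(w)) {
    for (i in seq(i_tr, length(w) - 1)) {
      if (w[i] <= half && w[i + 1] > half) {
        right <- t_ms[i] + (half - w[i]) / (w[i + 1] - w[i]) * dt_ms
        break
      }
    }
  }
  halfwidth <- right - left

  i_re <- which(w >= 0 & seq_along(w) > i_tr)[1]
  slope <- if (slope_method == "max_derivative") {
    if (i_tr < length(w)) max(diff(w[i_tr:length(w)])) / dt_ms else NA_real_
  } else if (!is.na(i_re) && i_re > i_tr) {
    idx <- i_tr:i_re
    if (length(idx) >= 2) unname(coef(lm(w[idx] ~ t_ms[idx]))[2]) else NA_real_
  } else {
    NA_real_
  }

  tibble(
    amplitude_uv = amplitude, halfwidth_ms = halfwidth,
    repolarization_slope_uv_ms = slope
  )
}

#' Epoch-mean template from spike-aligned waveforms
#'
#' Pointwise mean of the waveform snippets of each electrode and epoch,
#' with the number of contributing spikes recorded. Epochs with no
#' waveforms are simply absent from the output (with a warning if an
#' expected epoch is requested).
#'
#' @param waveforms Long tibble with `electrode_id`, `epoch`, `spike`,
#'   `time_ms`, `voltage_uv` (e.g. from [simulate_spike_waveforms()]).
#' @param expected_epochs Optional epochs to warn about when missing.
#' @return Tibble with `electrode_id`, `epoch`, `time_ms`, `voltage_uv`,
#'   `n_spikes`.
#' @export
epoch_mean_template <- function(waveforms, expected_epochs = NULL) {
  stopifnot(all(c("electrode_id", "epoch", "spike", "time_ms", "voltage_uv")
    %in% names(waveforms)))
  out <- waveforms |>
    group_by(.data$electrode_id, .data$epoch, .data$time_ms) |>
    summarise(
      voltage_uv = mean(.data$voltage_uv),
      n_spikes = dplyr::n_distinct(.data$spike),
      .groups = "drop"
    )
  if (!is.null(expected_epochs)) {
    missing <- setdiff(expected_epochs, unique(out$epoch))
    if (length(missing) > 0) {
      warn(paste0("no waveforms for epoch(s): ", paste(missing, collapse = ", ")))
    }
  }
  out
}

#' Relative change of waveform features between epochs
#'
#' Ratio of each feature during compression to its value before
#' compression (`during / before`); every before-feature must be positive.
#'
#' @param before,during One-row feature tibbles from
#'   [extract_waveform_features()].
#' @return One-row tibble with `amplitude_ratio`, `halfwidth_ratio`,
#'   `repolarization_slope_ratio`.
#' @export
relative_feature_change <- function(before, during) {
  feats <- c("amplitude_uv", "halfwidth_ms", "repolarization_slope_uv_ms")
  b <- unlist(before[1, feats])
  d <- unlist(during[1, feats])
  if (any(!is.finite(b)) || any(b == 0)) {
    abort("before-epoch features must be finite and nonzero.")
  }
  r <- d / b
  tibble(
    amplitude_ratio = r[[1]], halfwidth_ratio = r[[2]],
    repolarization_slope_ratio = r[[3]]
  )
}

#' Waveform-feature change as a function of distance from the target
#'
#' For every electrode of a footprint with `before` and `during` epoch
#' templates, computes the Euclidean distance from the target electrode
#' (the electrode under the compression site) and the during/before ratio
#' of each waveform feature. This is the distance-resolved amplitude-change
#' analysis used to separate electrode-contact artefacts (target electrode)
#' from genuine excitability changes (distant electrodes).
#'
#' @param templates Long tibble with `electrode_id`, `x_um`, `y_um`,
#'   `epoch`, `time_ms`, `voltage_uv` (a `unit_footprint` or an epoch-mean
#'   table joined to electrode coordinates).
#' @param target_electrode Electrode id under the compression site;
#'   defaults to the footprint's `target_electrode` attribute.
#' @param sampling Sampling rate, Hz; defaults to the footprint attribute
#'   or 20 kHz.
#' @return Tibble with one row per electrode: `electrode_id`,
#'   `distance_um`, `amplitude_ratio`, `halfwidth_ratio`,
#'   `repolarization_slope_ratio`, sorted by distance.
#' @export
amplitude_change_vs_distance <- function(templates, target_electrode = NULL,
                                         sampling = NULL) {
  if (is.null(target_electrode)) target_electrode <- attr(templates, "target_electrode")
  if (is.null(sampling)) sampling <- attr(templates, "sampling") %||% 2e4
  if (is.null(target_electrode)) abort("`target_electrode` must be supplied.")
  templates <- as_tibble(templates)
  stopifnot(all(c("electrode_id", "x_um", "y_um", "epoch", "time_ms", "voltage_uv")
    %in% names(templates)))
  if (!target_electrode %in% templates$electrode_id) {
    abort("target electrode not present in the footprint.")
  }
  coords <- templates |>
    dplyr::distinct(.data$electrode_id, .data$x_um, .data$y_um)
  tgt <- coords[coords$electrode_id == target_electrode, ]

  feats <- templates |>
    filter(.data$epoch %in% c("before", "during")) |>
    group_by(.data$electrode_id, .data$epoch) |>
    arrange(.data$time_ms, .by_group = TRUE) |>
    summarise(
      feat = list(extract_waveform_features(.data$voltage_uv, sampling)),
      .groups = "drop"
    ) |>
    tidyr::unnest("feat")
  have_both <- feats |>
    dplyr::count(.data$electrode_id) |>
    filter(.data$n == 2) |>
    pull("electrode_id")
  if (length(have_both) < 2) {
    abort("need before and during templates on at least 2 electrodes.")
  }

  wide <- feats |>
    filter(.data$electrode_id %in% have_both) |>
    tidyr::pivot_wider(
      names_from = "epoch",
      values_from = c("amplitude_uv", "halfwidth_ms", "repolarization_slope_uv_ms")
    )
  wide |>
    left_join(coords, by = "electrode_id") |>
    mutate(
      distance_um = sqrt((.data$x_um - tgt$x_um)^2 + (.data$y_um - tgt$y_um)^2),
      amplitude_ratio = .data$amplitude_uv_during / .data$amplitude_uv_before,
      halfwidth_ratio = .data$halfwidth_ms_during / .data$halfwidth_ms_before,
      repolarization_slope_ratio =
        .data$repolarization_slope_uv_ms_during / .data$repolarization_slope_uv_ms_before
    ) |>
    select(
      "electrode_id", "distance_um", "amplitude_ratio", "halfwidth_ratio",
      "repolarization_slope_ratio"
    ) |>
    arrange(.data$distance_um)
}

#' Plot amplitude change against distance from the compression site
#'
#' @param change_table Output of [amplitude_change_vs_distance()].
#' @return A ggplot.
#' @export
plot_amplitude_distance <- function(change_table) {
  ggplot2::ggplot(change_table, ggplot2::aes(
    x = .data$distance_um, y = .data$amplitude_ratio
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      x = "distance from target electrode (µm)",
      y = "amplitude ratio (during / before)"
    ) +
    ggplot2::theme_minimal()
}
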