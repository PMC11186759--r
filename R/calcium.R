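#' Compute a dF/F trace from raw fluorescence intensities
#'
#' `dF/F = (I - I0) / I0` with the baseline intensity `I0` either the mean
#' over a pre-stimulus window (default) or a low percentile of the whole
#' trace (robust to activity in the baseline window). The baseline mode is
#' recorded on the result.
#'
#' @param intensity Tibble with `frame_time_s` and `intensity` (> 0).
#' @param baseline_mode `"pre_stim_mean"` or `"percentile"`.
#' @param stim_time_s End of the pre-stimulus baseline window, s (required
#'   for `"pre_stim_mean"`).
#' @param percentile Percentile for `"percentile"` mode (default 0.08).
#' @return A `calcium_trace` tibble (`frame_time_s`, `dff`) with attributes
#'   `frame_rate`, `baseline_mode`, `baseline_intensity`.
#' @export
compute_dff <- function(intensity, baseline_mode = c("pre_stim_mean", "percentile"),
                        stim_time_s = NULL, percentile = 0.08) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(all(c("frame_time_s", "intensity") %in% names(intensity)))
  if (any(intensity$intensity <= 0)) abort("intensities must be positive.")
  if (any(diff(intensity$frame_time_s) <= 0)) {
    abort("frame times must be strictly increasing.")
  }
  i0 <- switch(baseline_mode,
    pre_stim_mean = {
      if (is.null(stim_time_s)) abort("supply `stim_time_s` for pre_stim_mean baseline.")
      pre <- intensity$intensity[intensity$frame_time_s < stim_time_s]
      if (length(pre) == 0) abort("no frames before `stim_time_s`.")
      mean(pre)
    },
    percentile = unname(quantile(intensity$intensity, percentile))
  )
  if (i0 <= 0) abort("non-positive baseline intensity.")
  fr <- 1 / median(diff(intensity$frame_time_s))
  structure(
    tibble(frame_time_s = intensity$frame_time_s, dff = (intensity$intensity - i0) / i0),
    frame_rate = fr, baseline_mode = baseline_mode, baseline_intensity = i0,
    class = c("calcium_trace", class(tibble()))
  )
}

#' Detect calcium transient peaks
#'
#' A frame is a peak iff its dF/F value is the strict maximum of all
#' frames within `window / 2` seconds on either side (window truncated at
#' the trace edges). Deterministic; plateau frames tied with a neighbour
#' are not peaks.
#'
#' @param trace A `calcium_trace` (columns `frame_time_s`, `dff`).
#' @param window Comparison window, s (default 3; must exceed one frame
#'   interval).
#' @param min_dff Optional minimum dF/F for a reported peak.
#' @return Tibble with `peak_index`, `peak_time_s`, `peak_dff`.
#' @export
detect_ca_peaks <- function(trace, window = 3, min_dff = -Inf) {
  t <- trace$frame_time_s
  y <- trace$dff
  if (length(t) >= 2 && window <= min(diff(t))) {
    abort("`window` must exceed the frame interval.")
  }
  half <- window / 2
  is_peak <- vapply(seq_along(y), function(i) {
    nb <- which(abs(t - t[i]) <= half)
    nb <- nb[nb != i]
    length(nb) > 0 && all(y[i] > y[nb]) && y[i] >= min_dff
  }, logical(1))
  tibble(
    peak_index = which(is_peak),
    peak_time_s = t[is_peak],
    peak_dff = y[is_peak]
  )
}

#' Onset time of a calcium response
#'
#' The response start is where the signal reaches `fraction` (default 10%)
#' of the peak amplitude: the latest pre-peak up-crossing of the threshold
#' that stays above threshold until the peak, located by linear
#' interpolation between frames. If the trace never falls below the
#' threshold before the peak, the first frame is returned with
#' `flagged = TRUE`.
#'
#' @param trace A `calcium_trace`.
#' @param peak_index Index of the peak frame (e.g. from [detect_ca_peaks()]).
#' @param fraction Threshold as a fraction of peak amplitude.
#' @return One-row tibble with `onset_time_s`, `threshold_dff`, `flagged`.
#' @export
response_onset <- function(trace, peak_index, fraction = 0.10) {
  t <- trace$frame_time_s
  y <- trace$dff
  stopifnot(peak_index >= 1, peak_index <= length(y))
  if (peak_index == 1) abort("peak has no pre-peak segment.")
  thr <- fraction * y[peak_index]
  below <- which(y[seq_len(peak_index - 1)] < thr)
  if (length(below) == 0) {
    return(tibble(onset_time_s = t[1], threshold_dff = thr, flagged = TRUE))
  }
  i <- max(below) # last sub-threshold frame before the peak
  onset <- t[i] + (thr - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
  tibble(onset_time_s = onset, threshold_dff = thr, flagged = FALSE)
}

#' Align a trace window to the response onset
#'
#' Extracts frames from `pre` seconds before to `post` seconds after `t0`
#' and re-zeroes the time axis at `t0`. Windows reaching past the trace
#' are truncated with a flag.
#'
#' @param trace A `calcium_trace`.
#' @param t0 Alignment time (response onset), s.
#' @param pre,post Window extent, s (defaults 2.5 and 10).
#' @return A tibble with `time_rel_s`, `dff` and attribute `truncated`.
#' @export
align_response_window <- function(trace, t0, pre = 2.5, post = 10) {
  keep <- trace$frame_time_s >= t0 - pre & trace$frame_time_s <= t0 + post
  truncated <- (t0 - pre) < min(trace$frame_time_s) ||
    (t0 + post) > max(trace$frame_time_s)
  if (truncated) warn("alignment window truncated at the trace boundary.")
  out <- tibble(
    time_rel_s = trace$frame_time_s[keep] - t0,
    dff = trace$dff[keep]
  )
  attr(out, "truncated") <- truncated
  out
}

#' Fit the decay constant of a calcium transient
#'
#' Least-squares fit of `dff(t) = A * exp(-(t - t_peak) / tau)` on the
#' post-peak segment down to 10% of the peak amplitude (nonlinear fit
#' seeded by the log-linear slope). A non-decaying tail yields a missing
#' tau with a warning; the estimate is invariant to positive rescaling of
#' the trace.
#'
#' @param trace A `calcium_trace`.
#' @param peak_index Index of the peak frame.
#' @param min_frames Minimum number of post-peak frames (default 10).
#' @param floor_fraction Tail is fit down to this fraction of peak.
#' @return One-row tibble with `tau_s`, `amplitude_dff`, `n_frames`.
#' @export
fit_decay_tau <- function(trace, peak_index, min_frames = 10, floor_fraction = 0.10) {
  t <- trace$frame_time_s
  y <- trace$dff
  stopifnot(peak_index >= 1, peak_index <= length(y))
  peak <- y[peak_index]
  if (peak <= 0) abort("peak amplitude must be positive to fit a decay.")
  idx <- seq(peak_index, length(y))
  below <- which(y[idx] < floor_fraction * peak)
  if (length(below) > 0) idx <- idx[seq_len(min(below) - 1)]
  if (length(idx) < min_frames) {
    warn("too few post-peak frames; decay constant not fitted.")
    return(tibble(tau_s = NA_real_, amplitude_dff = NA_real_, n_frames = length(idx)))
  }
  ts <- t[idx] - t[peak_index]
  ys <- y[idx]
  pos <- ys > 0
  if (sum(pos) < min_frames) {
    warn("non-decaying or non-positive tail; decay constant not fitted.")
    return(tibble(tau_s = NA_real_, amplitude_dff = NA_real_, n_frames = length(idx)))
  }
  sl <- unname(coef(lm(log(ys[pos]) ~ ts[pos]))[2])
  if (!is.finite(sl) || sl >= 0) {
    warn("non-decaying tail; decay constant not fitted.")
    return(tibble(tau_s = NA_real_, amplitude_dff = NA_real_, n_frames = length(idx)))
  }
  start <- list(A = peak, tau = -1 / sl)
  # the log-linear start is already near-exact for clean data, where the
  # refinement step can hit its iteration cap at machine precision
  fit <- tryCatch(
    suppressWarnings(nls(ys ~ A * exp(-ts / tau), start = start,
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble(tau_s = -1 / sl, amplitude_dff = peak, n_frames = length(idx)))
  }
  cf <- coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) {
    warn("non-decaying tail; decay constant not fitted.")
    return(tibble(tau_s = NA_real_, amplitude_dff = NA_real_, n_frames = length(idx)))
  }
  tibble(
    tau_s = cf[["tau"]], amplitude_dff = cf[["A"]], n_frames = length(idx)
  )
}

#' Classify whether a neuron responded to a mechanical stimulus
#'
#' A neuron is a responder iff a detected calcium peak inside the search
#' window after contact exceeds `k` times the pre-stimulus dF/F noise sd.
#' All criteria are recorded on the result.
#'
#' @param trace A `calcium_trace`.
#' @param contact_on Stimulus contact time on the trace clock, s.
#' @param k Peak threshold in pre-stimulus-sd units (default 5).
#' @param search_window_s Post-contact search window, s (default 10).
#' @param peak_window Peak-detection window passed to [detect_ca_peaks()].
#' @return One-row tibble with `responded`, `peak_time_s`, `peak_dff`,
#'   `threshold_dff`, `baseline_sd`.
#' @export
classify_responder <- function(trace, contact_on, k = 5, search_window_s = 10,
                               peak_window = 3) {
  pre <- trace$dff[trace$frame_time_s < contact_on]
  if (length(pre) < 2) abort("no pre-stimulus baseline segment available.")
  noise_sd <- stats::sd(pre)
  thr <- k * noise_sd
  peaks <- detect_ca_peaks(trace, window = peak_window)
  peaks <- filter(peaks,
    .data$peak_time_s > contact_on,
    .data$peak_time_s <= contact_on + search_window_s,
    .data$peak_dff - mean(pre) > thr
  )
  responded <- nrow(peaks) > 0
  best <- if (responded) peaks[which.max(peaks$peak_dff), ] else NULL
  tibble(
    responded = responded,
    peak_time_s = if (responded) best$peak_time_s else NA_real_,
    peak_dff = if (responded) best$peak_dff else NA_real_,
    threshold_dff = thr, baseline_sd = noise_sd
  )
}
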