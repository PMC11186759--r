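check_spikes <- function(spikes) {
  stopifnot(is.data.frame(spikes), all(c("unit_id", "time_s") %in% names(spikes)))
  as_tibble(spikes)
}

#' Mean firing rate in a time window
#'
#' Spike count inside the window divided by the window length, per unit.
#' Units present in `spikes` but silent in the window get rate 0.
#'
#' @param spikes Tibble with `unit_id`, `time_s`.
#' @param window Numeric `c(start, end)`, seconds; spikes are counted in
#'   the half-open interval `[start, end)`.
#' @return Tibble with `unit_id`, `n_spikes`, `rate_hz`.
#' @export
#' @examples
#' sp <- tibble::tibble(unit_id = 1, time_s = seq(0.25, 4.75, by = 0.5))
#' mean_firing_rate(sp, c(0, 5))
mean_firing_rate <- function(spikes, window) {
  spikes <- check_spikes(spikes)
  stopifnot(length(window) == 2)
  len <- window[2] - window[1]
  if (len <= 0) abort("window must have positive length.")
  units <- unique(spikes$unit_id)
  inside <- filter(spikes, .data$time_s >= window[1], .data$time_s < window[2])
  counts <- dplyr::count(inside, .data$unit_id, name = "n_spikes")
  tibble(unit_id = units) |>
    left_join(counts, by = "unit_id") |>
    mutate(
      n_spikes = ifelse(is.na(.data$n_spikes), 0L, .data$n_spikes),
      rate_hz = .data$n_spikes / len
    )
}

#' Binned firing rate
#'
#' Places spikes in consecutive left-closed right-open bins tiling the
#' span, so a spike exactly on a bin edge is assigned to the bin on its
#' right and every spike in the span falls in exactly one bin.
#'
#' @param spikes Tibble with `unit_id`, `time_s`.
#' @param bin_width Bin width, seconds (default 30, the stiffness-tracking
#'   convention).
#' @param span `c(start, end)` of the binning range; defaults to
#'   `c(0, max spike time)` rounded up to a whole bin.
#' @return Tibble with `unit_id`, `bin_start_s`, `bin_end_s`, `n_spikes`,
#'   `rate_hz`.
#' @export
binned_firing_rate <- function(spikes, bin_width = 30, span = NULL) {
  spikes <- check_spikes(spikes)
  stopifnot(bin_width > 0)
  if (is.null(span)) {
    top <- if (nrow(spikes) > 0) max(spikes$time_s) else bin_width
    # one bin past the last spike so a spike on the final edge still counts
    span <- c(0, (floor(top / bin_width) + 1) * bin_width)
  }
  edges <- seq(span[1], span[2], by = bin_width)
  if (tail(edges, 1) < span[2]) edges <- c(edges, tail(edges, 1) + bin_width)
  starts <- head(edges, -1)
  grid <- tidyr::expand_grid(unit_id = unique(spikes$unit_id), bin_start_s = starts)
  inside <- filter(spikes, .data$time_s >= span[1], .data$time_s < tail(edges, 1))
  if (nrow(inside) > 0) {
    inside$bin_start_s <- starts[
      findInterval(inside$time_s, edges, rightmost.closed = FALSE)
    ]
  }
  counts <- dplyr::count(inside, .data$unit_id, .data$bin_start_s, name = "n_spikes")
  grid |>
    left_join(counts, by = c("unit_id", "bin_start_s")) |>
    mutate(
      n_spikes = ifelse(is.na(.data$n_spikes), 0L, .data$n_spikes),
      bin_end_s = .data$bin_start_s + bin_width,
      rate_hz = .data$n_spikes / bin_width
    ) |>
    select("unit_id", "bin_start_s", "bin_end_s", "n_spikes", "rate_hz")
}

#' Epoch windows around a mechanical stimulus
#'
#' Builds the before/during/after analysis windows of one stimulus:
#' `during` is the contact window and `before`/`after` extend `pre_s` /
#' `post_s` seconds on either side (default 150 s, i.e. 2.5 min).
#'
#' @param contact_on,contact_off Contact window on the master clock, s.
#' @param pre_s,post_s Length of the before/after windows, s.
#' @return Tibble with `epoch`, `start`, `end` (ordered, non-overlapping).
#' @export
epoch_set <- function(contact_on, contact_off, pre_s = 150, post_s = 150) {
  stopifnot(contact_on < contact_off, pre_s > 0, post_s > 0)
  tibble(
    epoch = c("before", "during", "after"),
    start = c(contact_on - pre_s, contact_on, contact_off),
    end = c(contact_on, contact_off, contact_off + post_s)
  )
}

#' Firing rate per analysis epoch
#'
#' [mean_firing_rate()] applied to each epoch window (before, during,
#' after compression), per unit.
#'
#' @param spikes Tibble with `unit_id`, `time_s`.
#' @param epochs Tibble from [epoch_set()] (`epoch`, `start`, `end`).
#' @return Tibble with `unit_id`, `epoch`, `n_spikes`, `rate_hz`.
#' @export
epoch_firing_rates <- function(spikes, epochs) {
  stopifnot(all(c("epoch", "start", "end") %in% names(epochs)))
  list_rbind(map(seq_len(nrow(epochs)), function(i) {
    mean_firing_rate(spikes, c(epochs$start[i], epochs$end[i])) |>
      mutate(epoch = epochs$epoch[i], .after = "unit_id")
  }))
}

#' Percent change between two firing rates
#'
#' `100 * (r_new - r_ref) / r_ref`; undefined (error) for a zero reference
#' rate.
#'
#' @param r_ref,r_new Reference and new rates, Hz (vectorised).
#' @return Percent change.
#' @export
#' @examples
#' percent_rate_change(2, 2.5) # +25
percent_rate_change <- function(r_ref, r_new) {
  if (any(r_ref <= 0)) abort("percent change undefined for zero reference rate.")
  100 * (r_new - r_ref) / r_ref
}

#' Inter-spike intervals of each unit
#'
#' Consecutive differences of the sorted spike times, per unit. Units with
#' fewer than two spikes contribute no intervals (with a warning).
#'
#' @param spikes Tibble with `unit_id`, `time_s`.
#' @return Tibble with `unit_id`, `isi_s`.
#' @export
isi_distribution <- function(spikes) {
  spikes <- check_spikes(spikes)
  few <- dplyr::count(spikes, .data$unit_id)
  if (any(few$n < 2)) {
    warn("some units have fewer than 2 spikes; they contribute no intervals.")
  }
  spikes |>
    arrange(.data$unit_id, .data$time_s) |>
    group_by(.data$unit_id) |>
    summarise(isi_s = list(diff(.data$time_s)), .groups = "drop") |>
    tidyr::unnest("isi_s")
}

#' Spike-sorting quality metrics for one unit
#'
#' Inter-spike-interval violation ratio (fraction of intervals shorter
#' than the refractory period) and template signal-to-noise ratio (peak
#' trough magnitude across the footprint divided by the recording noise
#' sd). A unit passes curation iff the violation ratio is at most
#' `isi_threshold` and the SNR at least `snr_threshold` (defaults 0.5 and
#' 5.0, conservative spike-sorting curation thresholds).
#'
#' @param spikes Tibble with `unit_id`, `time_s` (one unit's rows used).
#' @param unit_id Unit to evaluate.
#' @param trough_uv Peak template trough magnitude, microvolts (e.g. the
#'   `amplitude_uv` of [extract_waveform_features()] on the best electrode).
#' @param noise_sd_uv Recording noise sd, microvolts (> 0).
#' @param refractory_s Refractory period, seconds (default 2 ms).
#' @param isi_threshold,snr_threshold Curation thresholds.
#' @return One-row tibble with `unit_id`, `isi_violation_ratio`, `snr`,
#'   `passes`.
#' @export
unit_quality <- function(spikes, unit_id, trough_uv, noise_sd_uv,
                         refractory_s = 0.002,
                         isi_threshold = 0.5, snr_threshold = 5.0) {
  stopifnot(noise_sd_uv > 0, trough_uv >= 0)
  times <- sort(spikes$time_s[spikes$unit_id == unit_id])
  isi <- diff(times)
  ratio <- if (length(isi) == 0) 0 else mean(isi < refractory_s)
  snr <- trough_uv / noise_sd_uv
  tibble(
    unit_id = unit_id, isi_violation_ratio = ratio, snr = snr,
    passes = ratio <= isi_threshold && snr >= snr_threshold
  )
}

#' Latency of the first spike evoked by a mechanical contact
#'
#' Time from `contact_on` to the first spike strictly after contact and
#' within `search_window` seconds, per unit; `NA` when no spike falls in
#' the window (never imputed).
#'
#' @param spikes Tibble with `unit_id`, `time_s`.
#' @param contact_on Contact time on the master clock, s.
#' @param search_window Search window after contact, s (default 0.5, the
#'   scale of a transient stimulus).
#' @return Tibble with `unit_id`, `latency_s`.
#' @export
#' @examples
#' sp <- tibble::tibble(unit_id = 1, time_s = c(2.130, 2.4))
#' evoked_spike_latency(sp, contact_on = 2.0)
evoked_spike_latency <- function(spikes, contact_on, search_window = 0.5) {
  spikes <- check_spikes(spikes)
  spikes |>
    group_by(.data$unit_id) |>
    summarise(
      latency_s = {
        t <- .data$time_s[.data$time_s > contact_on &
          .data$time_s <= contact_on + search_window]
        if (length(t) == 0) NA_real_ else min(t) - contact_on
      },
      .groups = "drop"
    )
}

#' Raster plot of a spike population
#'
#' @param spikes Tibble with `unit_id`, `time_s`.
#' @param bursts Optional burst intervals (`start`, `end`) shaded behind
#'   the raster.
#' @return A ggplot.
#' @export
plot_raster <- function(spikes, bursts = NULL) {
  p <- ggplot2::ggplot(spikes, ggplot2::aes(x = .data$time_s, y = .data$unit_id))
  if (!is.null(bursts) && nrow(bursts) > 0) {
    p <- p + ggplot2::geom_rect(
      data = bursts,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "indianred", alpha = 0.25
    )
  }
  p + ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "unit") +
    ggplot2::theme_minimal()
}
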