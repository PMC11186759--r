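#' Detect network bursts from a spike population
#'
#' Population-rate threshold detector for the synchronous bursts of
#' cultured networks. The population rate is the summed spike count per
#' time bin divided by `n_units * bin`; bins whose rate reaches
#' `rate_threshold` times the baseline rate level are burst candidates.
#' The baseline level is the lower quartile of the nonzero bin rates: for
#' dense background activity this equals the median nonzero rate, and it
#' stays at the out-of-burst level even when bursts contribute a large
#' share of the nonzero bins (where the median would be dragged up to the
#' burst level and suppress all detections). Candidate runs shorter than
#' `min_duration` are dropped (suppressing isolated high-count bins),
#' then runs separated by gaps shorter than `merge_gap` are merged
#' (bridging brief within-burst dips). The detector is fully
#' deterministic.
#'
#' @param spikes Tibble with `unit_id`, `time_s`.
#' @param span Analysis span `c(start, end)`, s; defaults to `c(0, max time)`.
#' @param bin Bin width, s (default 25 ms).
#' @param rate_threshold Threshold as a multiple of the baseline
#'   (lower-quartile nonzero) population rate (default 3).
#' @param min_duration Minimum burst duration, s (default 50 ms).
#' @param merge_gap Maximum gap merged into one burst, s (default 100 ms).
#' @return A tibble of burst intervals (`start`, `end`, `duration`), with
#'   attribute `ibis` holding the inter-burst intervals.
#' @export
#' @examples
#' sp <- tibble::tibble(
#'   unit_id = rep(1:5, each = 60),
#'   time_s = rep(seq(10, 11, length.out = 60), 5)
#' )
#' detect_network_bursts(sp, span = c(0, 20))
detect_network_bursts <- function(spikes, span = NULL, bin = 0.025,
                                  rate_threshold = 3, min_duration = 0.05,
                                  merge_gap = 0.1) {
  spikes <- check_spikes(spikes)
  empty <- tibble(start = numeric(), end = numeric(), duration = numeric())
  attr(empty, "ibis") <- numeric()
  if (nrow(spikes) == 0) return(empty)
  if (is.null(span)) span <- c(0, max(spikes$time_s))
  n_units <- length(unique(spikes$unit_id))
  edges <- seq(span[1], span[2] + bin, by = bin)
  counts <- graphics::hist(
    spikes$time_s[spikes$time_s >= span[1] & spikes$time_s <= span[2]],
    breaks = edges, plot = FALSE, right = FALSE
  )$counts
  rate <- counts / (n_units * bin)
  nonzero <- rate[rate > 0]
  if (length(nonzero) == 0) return(empty)
  thr <- rate_threshold * unname(quantile(nonzero, 0.25, type = 1))
  above <- rate >= thr

  runs <- rle(above)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- ends_idx - runs$lengths + 1
  keep <- runs$values
  iv <- tibble(
    start = edges[starts_idx[keep]],
    end = edges[ends_idx[keep] + 1]
  )
  iv <- filter(iv, .data$end - .data$start >= min_duration)
  if (nrow(iv) > 1) {
    merged_start <- iv$start[1]
    merged_end <- iv$end[1]
    out_s <- numeric()
    out_e <- numeric()
    for (i in 2:nrow(iv)) {
      if (iv$start[i] - merged_end < merge_gap) {
        merged_end <- iv$end[i]
      } else {
        out_s <- c(out_s, merged_start)
        out_e <- c(out_e, merged_end)
        merged_start <- iv$start[i]
        merged_end <- iv$end[i]
      }
    }
    iv <- tibble(start = c(out_s, merged_start), end = c(out_e, merged_end))
  }
  iv <- mutate(iv, duration = .data$end - .data$start)
  attr(iv, "ibis") <- if (nrow(iv) > 1) iv$start[-1] - iv$end[-nrow(iv)] else numeric()
  iv
}

#' Temporal overlap (Jaccard index) of two interval sets
#'
#' Length of the intersection of the two interval unions divided by the
#' length of their union; used to compare detected with true bursts.
#'
#' @param a,b Tibbles of intervals with `start`, `end`.
#' @return Jaccard index in `[0, 1]` (1 if both are empty).
#' @export
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  merge_union <- function(x) {
    x <- arrange(x, .data$start)
    s <- x$start[1]; e <- x$end[1]
    out <- NULL
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= e) {
        e <- max(e, x$end[i])
      } else {
        out <- rbind(out, c(s, e)); s <- x$start[i]; e <- x$end[i]
      }
    }
    rbind(out, c(s, e))
  }
  ua <- merge_union(a)
  ub <- merge_union(b)
  inter <- 0
  for (i in seq_len(nrow(ua))) {
    lo <- pmax(ua[i, 1], ub[, 1])
    hi <- pmin(ua[i, 2], ub[, 2])
    inter <- inter + sum(pmax(hi - lo, 0))
  }
  len_a <- sum(ua[, 2] - ua[, 1])
  len_b <- sum(ub[, 2] - ub[, 1])
  inter / (len_a + len_b - inter)
}
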