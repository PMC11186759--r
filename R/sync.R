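#' Align a stream clock to the master clock from paired TTL events
#'
#' The same physical events (stimulus contacts, sync pulses) are
#' time-stamped both on an instrument's own clock and, via the TTL chain,
#' on the master clock of the HD-MEA acquisition. Events are paired
#' greedily in time order (a stream and a master event are paired when
#' they differ by at most `pairing_tolerance`), then the affine clock
#' model `t_master = drift * t_stream + offset` is estimated by least
#' squares. Unpaired events on either side are counted and reported.
#'
#' @param stream_events Event times on the stream clock, s.
#' @param master_events Event times on the master clock, s.
#' @param pairing_tolerance Maximum |master - stream| difference for a
#'   pair, s (default 1).
#' @param stream Label stored with the map.
#' @return A `sync_map` with fields `offset`, `drift`, `n_paired_events`,
#'   `rms_residual_s`, `n_unpaired`.
#' @export
#' @examples
#' build_sync_map(c(1, 2, 3), c(1.5, 2.5, 3.5)) # offset 0.5, drift 1
build_sync_map <- function(stream_events, master_events, pairing_tolerance = 1,
                           stream = "stream") {
  s <- sort(stream_events)
  m <- sort(master_events)
  pairs_s <- numeric()
  pairs_m <- numeric()
  i <- 1L; j <- 1L
  while (i <= length(s) && j <= length(m)) {
    d <- m[j] - s[i]
    if (abs(d) <= pairing_tolerance) {
      pairs_s <- c(pairs_s, s[i]); pairs_m <- c(pairs_m, m[j])
      i <- i + 1L; j <- j + 1L
    } else if (d > 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  if (length(pairs_s) < 2 || length(unique(pairs_s)) < 2) {
    abort("cannot align: fewer than 2 paired events.")
  }
  fit <- lm(pairs_m ~ pairs_s)
  drift <- unname(coef(fit)[2])
  offset <- unname(coef(fit)[1])
  if (drift < 0.99 || drift > 1.01) {
    warn(sprintf("estimated clock drift %.6f is outside [0.99, 1.01].", drift))
  }
  structure(
    list(
      stream = stream, offset = offset, drift = drift,
      n_paired_events = length(pairs_s),
      rms_residual_s = sqrt(mean(stats::residuals(fit)^2)),
      n_unpaired = (length(s) - length(pairs_s)) + (length(m) - length(pairs_m))
    ),
    class = "sync_map"
  )
}

#' @export
print.sync_map <- function(x, ...) {
  cat(sprintf(
    "<sync_map %s> t_master = %.9g * t_stream + %.9g | %d pairs | rms %.3g s\n",
    x$stream, x$drift, x$offset, x$n_paired_events, x$rms_residual_s
  ))
  invisible(x)
}

#' Tidy a sync map
#'
#' @param x A `sync_map`.
#' @param ... Unused.
#' @return One-row tibble of the map parameters.
#' @export
tidy.sync_map <- function(x, ...) {
  tibble(
    stream = x$stream, offset_s = x$offset, drift = x$drift,
    n_paired_events = x$n_paired_events, rms_residual_s = x$rms_residual_s,
    n_unpaired = x$n_unpaired
  )
}

#' Map stream-clock times onto the master clock (and back)
#'
#' @param map A `sync_map`.
#' @param t Times, s.
#' @return `map_time()` returns master-clock times
#'   `drift * t + offset`; `unmap_time()` inverts the map.
#' @export
map_time <- function(map, t) {
  stopifnot(inherits(map, "sync_map"))
  map$drift * t + map$offset
}

#' @rdname map_time
#' @export
unmap_time <- function(map, t) {
  stopifnot(inherits(map, "sync_map"))
  (t - map$offset) / map$drift
}
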