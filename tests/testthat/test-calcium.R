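test_that("dF/F is zero for constant intensity and exact for known steps", {
  frames <- tibble::tibble(
    frame_time_s = seq(0, 10, by = 1 / 45),
    intensity = 100
  )
  tr <- compute_dff(frames, stim_time_s = 5)
  expect_true(all(tr$dff == 0))
  frames$intensity[200] <- 200
  tr2 <- compute_dff(frames, baseline_mode = "percentile")
  expect_equal(tr2$dff[200], 1.0)
  expect_error(compute_dff(dplyr::mutate(frames, intensity = 0)), "positive")
})

test_that("dF/F round-trips the generator's trace", {
  cfg <- synth_config(seed = 1, duration = 60)
  gen <- simulate_calcium_trace(30, cfg)
  i0 <- 500
  frames <- tibble::tibble(
    frame_time_s = gen$frame_time_s,
    intensity = i0 * (1 + gen$dff)
  )
  tr <- compute_dff(frames, stim_time_s = 30)
  expect_equal(tr$dff, gen$dff, tolerance = 1e-12)
})

test_that("peak detection equals the exhaustive brute-force scan", {
  for (s in 1:5) {
    set.seed(s)
    t <- seq(0, 60, by = 1 / 10)
    y <- as.numeric(stats::filter(rnorm(length(t)), rep(1 / 15, 15),
      sides = 2))
    y[is.na(y)] <- 0
    tr <- tibble::tibble(frame_time_s = t, dff = y)
    got <- detect_ca_peaks(tr, window = 3)$peak_index
    expect_identical(got, brute_force_peaks(t, y, window = 3))
  }
})

test_that("peak detection resolves bumps and rejects monotone traces", {
  t <- seq(0, 20, by = 1 / 45)
  bump <- function(c0) exp(-(t - c0)^2 / 0.5)
  one <- tibble::tibble(frame_time_s = t, dff = bump(10))
  expect_equal(nrow(detect_ca_peaks(one)), 1)
  expect_equal(detect_ca_peaks(one)$peak_time_s, 10, tolerance = 1 / 45)
  two <- tibble::tibble(frame_time_s = t, dff = bump(7) + bump(12))
  expect_equal(nrow(detect_ca_peaks(two)), 2)
  mono <- tibble::tibble(frame_time_s = t, dff = t / 20)
  peaks <- detect_ca_peaks(mono)
  expect_true(all(peaks$peak_index != seq_along(t)[-length(t)][1]))
  expect_lte(nrow(peaks), 1) # at most the right edge can dominate its window
})

test_that("response onset finds the 10% crossing with interpolation", {
  t <- seq(0, 10, by = 0.01)
  ramp <- tibble::tibble(frame_time_s = t, dff = t / 10)
  on <- response_onset(ramp, length(t))
  expect_equal(on$onset_time_s, 1.0, tolerance = 1e-9)
  expect_false(on$flagged)
  # step response: onset within one frame of the step time
  step <- tibble::tibble(frame_time_s = t, dff = as.numeric(t >= 4))
  pk <- which(t >= 4)[5]
  ons <- response_onset(step, pk)
  expect_lt(abs(ons$onset_time_s - 4), 0.011)
  # never below threshold: flagged, onset at first frame
  high <- tibble::tibble(frame_time_s = t, dff = 0.5 + t / 100)
  onh <- response_onset(high, length(t))
  expect_true(onh$flagged)
  expect_equal(onh$onset_time_s, 0)
})

test_that("onset precedes the peak and matches the generator at zero noise", {
  cfg <- synth_config(seed = 1, duration = 60)
  tr <- simulate_calcium_trace(20, cfg)
  pk <- detect_ca_peaks(tr)
  expect_equal(nrow(pk), 1)
  on <- response_onset(tr, pk$peak_index)
  expect_lte(on$onset_time_s, pk$peak_time_s)
  truth <- attr(tr, "truth")
  expect_lt(abs(on$onset_time_s - truth$onset_time_s), 1 / cfg$frame_rate)
  expect_lt(abs(pk$peak_time_s - truth$peak_time_s), 1 / cfg$frame_rate + 1e-9)
})

test_that("alignment window re-zeroes time and respects the frame budget", {
  t <- seq(0, 60, by = 1 / 45)
  tr <- tibble::tibble(frame_time_s = t, dff = sin(t))
  win <- align_response_window(tr, t0 = t[226])
  expect_true(any(win$time_rel_s == 0))
  expect_lte(nrow(win), ceiling(12.5 * 45))
  expect_gte(min(win$time_rel_s), -2.5 - 1e-9)
  expect_lte(max(win$time_rel_s), 10 + 1e-9)
  expect_warning(align_response_window(tr, t0 = 0.5), "truncated")
})

test_that("decay fitting recovers tau and is scale invariant", {
  cfg <- synth_config(seed = 1, duration = 120, ca_decay_tau = 26.2)
  tr <- simulate_calcium_trace(1, cfg)
  pk <- which.max(tr$dff)
  fit <- fit_decay_tau(tr, pk)
  expect_lt(abs(fit$tau_s - 26.2) / 26.2, 1e-6)
  scaled <- tr
  scaled$dff <- scaled$dff * 7.3
  fit2 <- fit_decay_tau(scaled, pk)
  expect_equal(fit2$tau_s, fit$tau_s, tolerance = 1e-6)
})

test_that("flat or short tails yield a missing tau with a warning", {
  t <- seq(0, 30, by = 1 / 45)
  flat <- tibble::tibble(frame_time_s = t, dff = c(rep(0.01, 100), rep(1, length(t) - 100)))
  expect_warning(out <- fit_decay_tau(flat, 101), "not fitted")
  expect_true(is.na(out$tau_s))
  short <- tibble::tibble(frame_time_s = t[1:105], dff = c(rep(0, 100), 1, 0.5, 0.3, 0.1, 0.05))
  expect_warning(outs <- fit_decay_tau(short, 101), "not fitted")
  expect_true(is.na(outs$tau_s))
})

test_that("responder classification needs a supra-threshold evoked peak", {
  t <- seq(0, 60, by = 1 / 45)
  flat <- tibble::tibble(frame_time_s = t, dff = rep(0, length(t)))
  expect_false(classify_responder(flat, contact_on = 30)$responded)
  # injected transient at 20x the noise sd
  set.seed(5)
  noise <- rnorm(length(t), sd = 0.01)
  y <- noise + 0.2 * exp(-pmax(t - 31, 0) / 5) * (t >= 31)
  tr <- tibble::tibble(frame_time_s = t, dff = y)
  res <- classify_responder(tr, contact_on = 30)
  expect_true(res$responded)
  expect_gt(res$peak_dff, res$threshold_dff)
  expect_error(classify_responder(tr, contact_on = -1), "baseline")
})
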