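test_that("mean firing rate is count over window length", {
  sp <- tibble::tibble(unit_id = 1, time_s = seq(0.25, 4.75, by = 0.5))
  expect_equal(mean_firing_rate(sp, c(0, 5))$rate_hz, 2)
  # a unit with no spikes in the window gets rate 0
  sp2 <- tibble::tibble(unit_id = c(1, 2), time_s = c(1, 7))
  r <- mean_firing_rate(sp2, c(0, 5))
  expect_equal(r$rate_hz[r$unit_id == 2], 0)
  expect_error(mean_firing_rate(sp, c(3, 3)), "positive length")
})

test_that("rate estimate is unbiased on homogeneous Poisson trains", {
  rates <- vapply(1:200, function(s) {
    cfg <- synth_config(seed = s, n_units = 1, duration = 100,
      base_rate = 10, burst_onset_rate = 0)
    sp <- simulate_spike_population(cfg)$spikes
    if (nrow(sp) == 0) 0 else mean_firing_rate(sp, c(0, 100))$rate_hz
  }, numeric(1))
  se <- sqrt(10 / 100) / sqrt(200)
  expect_lt(abs(mean(rates) - 10), 3 * se)
})

test_that("binned rates use half-open bins and conserve spike counts", {
  sp <- tibble::tibble(unit_id = 1, time_s = c(1, 31, 61))
  b <- binned_firing_rate(sp, 30, span = c(0, 90))
  expect_equal(b$n_spikes, c(1L, 1L, 1L))
  # bin-edge spike goes to the right bin
  sp_edge <- tibble::tibble(unit_id = 1, time_s = 30)
  be <- binned_firing_rate(sp_edge, 30, span = c(0, 90))
  expect_equal(be$n_spikes, c(0L, 1L, 0L))
  # conservation across bin widths on a random train
  set.seed(8)
  spr <- tibble::tibble(unit_id = 1, time_s = sort(runif(500, 0, 200)))
  for (bw in c(7, 30, 61)) {
    expect_equal(sum(binned_firing_rate(spr, bw)$n_spikes), 500)
  }
})

test_that("epoch rates split before/during/after correctly", {
  ep <- epoch_set(100, 160, pre_s = 100, post_s = 100)
  expect_equal(ep$start, c(0, 100, 160))
  expect_equal(ep$end, c(100, 160, 260))
  # uniform 2 Hz train: all epochs at 2 Hz
  sp <- tibble::tibble(unit_id = 1, time_s = seq(0.25, 259.75, by = 0.5))
  r <- epoch_firing_rates(sp, ep)
  expect_equal(r$rate_hz, rep(2, 3), tolerance = 0.01)
  # empty during epoch
  sp2 <- tibble::tibble(unit_id = 1, time_s = c(10, 200))
  r2 <- epoch_firing_rates(sp2, ep)
  expect_equal(r2$rate_hz[r2$epoch == "during"], 0)
})

test_that("percent rate change follows its definition", {
  expect_equal(percent_rate_change(2, 2.5), 25)
  expect_equal(percent_rate_change(2, 2), 0)
  expect_equal(percent_rate_change(2, 1), -50)
  expect_error(percent_rate_change(0, 1), "undefined")
})

test_that("inter-spike intervals are consecutive differences", {
  sp <- tibble::tibble(unit_id = 1, time_s = c(0, 1, 3))
  expect_equal(isi_distribution(sp)$isi_s, c(1, 2))
  reg <- tibble::tibble(unit_id = 1, time_s = seq(0, 10, by = 0.5))
  expect_true(all(isi_distribution(reg)$isi_s == 0.5))
  expect_warning(
    out <- isi_distribution(tibble::tibble(unit_id = 1, time_s = 1)),
    "fewer than 2"
  )
  expect_equal(nrow(out), 0)
})

test_that("Poisson train intervals pass an exponentiality test", {
  cfg <- synth_config(seed = 17, n_units = 1, duration = 600,
    base_rate = 10, burst_onset_rate = 0)
  sp <- simulate_spike_population(cfg)$spikes
  isi <- isi_distribution(sp)$isi_s
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 1 / mean(isi)))
  expect_gt(ks$p.value, 0.01)
})

test_that("quality filter applies the curation thresholds", {
  sp <- tibble::tibble(unit_id = 1, time_s = seq(0, 10, by = 0.5))
  q <- unit_quality(sp, 1, trough_uv = 200, noise_sd_uv = 10)
  expect_equal(q$isi_violation_ratio, 0)
  expect_equal(q$snr, 20)
  expect_true(q$passes)
  # 6 of 10 intervals below the refractory period: ratio 0.6 > 0.5 fails
  t_bad <- cumsum(c(0, rep(0.001, 6), rep(0.1, 4)))
  qb <- unit_quality(tibble::tibble(unit_id = 1, time_s = t_bad), 1,
    trough_uv = 200, noise_sd_uv = 10)
  expect_equal(qb$isi_violation_ratio, 0.6)
  expect_false(qb$passes)
  # SNR just below threshold fails
  qs <- unit_quality(sp, 1, trough_uv = 49, noise_sd_uv = 10)
  expect_equal(qs$snr, 4.9)
  expect_false(qs$passes)
})

test_that("quality filter is monotone in noise", {
  sp <- tibble::tibble(unit_id = 1, time_s = seq(0, 10, by = 0.5))
  passes <- vapply(seq(5, 100, by = 5), function(nsd) {
    unit_quality(sp, 1, trough_uv = 200, noise_sd_uv = nsd)$passes
  }, logical(1))
  expect_true(all(diff(as.integer(passes)) <= 0))
})

test_that("evoked latency is the first spike in the search window", {
  sp <- tibble::tibble(unit_id = 1, time_s = c(2.130, 2.4))
  expect_equal(evoked_spike_latency(sp, 2.0)$latency_s, 0.130)
  # no spike in window
  sp2 <- tibble::tibble(unit_id = 1, time_s = 3.5)
  expect_true(is.na(evoked_spike_latency(sp2, 2.0)$latency_s))
  # spike exactly at contact is excluded (strictly after contact)
  sp3 <- tibble::tibble(unit_id = 1, time_s = c(2.0, 2.2))
  expect_equal(evoked_spike_latency(sp3, 2.0)$latency_s, 0.2)
})

test_that("injected latencies are recovered exactly without background", {
  sched <- mech_stimulus("transient", setpoint_force = 200,
    contact_on = 5, contact_off = 5.5, evoke = TRUE)
  cfg <- synth_config(seed = 2, n_units = 10, duration = 10, base_rate = 0,
    burst_onset_rate = 0, schedule = sched, evoked_latency_sd = 0.05)
  pop <- simulate_spike_population(cfg)
  lat <- evoked_spike_latency(pop$spikes, 5)
  truth <- pop$evoked
  joined <- dplyr::left_join(lat, truth, by = "unit_id")
  expect_equal(joined$latency_s, joined$true_latency_s, tolerance = 1e-12)
})
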