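# triangular trough: depth 200 uV, linear flanks 0.3 ms each side,
# sampled at 20 kHz with flat baseline padding
triangle_template <- function(depth = 200, half_ms = 0.3, dt_ms = 0.05,
                              pad = 20) {
  flank <- seq(0, depth, length.out = round(half_ms / dt_ms) + 1)
  c(rep(0, pad), -flank, rev(-flank)[-1], rep(0, pad))
}

test_that("triangular trough geometry is recovered exactly", {
  w <- triangle_template()
  f <- extract_waveform_features(w, sampling = 2e4)
  expect_equal(f$amplitude_uv, 200)
  # half depth of a triangle with 0.3 ms base half-widths: width 0.3 ms
  expect_equal(f$halfwidth_ms, 0.3, tolerance = 1e-9)
  expect_gt(f$repolarization_slope_uv_ms, 0)
})

test_that("time dilation scales halfwidth and slope but not amplitude", {
  w <- triangle_template()
  f1 <- extract_waveform_features(w, sampling = 2e4)
  f2 <- extract_waveform_features(w, sampling = 1e4) # dt doubled
  expect_equal(f2$amplitude_uv, f1$amplitude_uv)
  expect_equal(f2$halfwidth_ms, 2 * f1$halfwidth_ms)
  expect_equal(f2$repolarization_slope_uv_ms, f1$repolarization_slope_uv_ms / 2)
})

test_that("flat templates raise the no-deflection error", {
  expect_error(extract_waveform_features(rep(1, 50), 2e4), "no spike deflection")
})

test_that("epoch-mean templates equal copies and single waveforms", {
  base <- tibble::tibble(
    electrode_id = 1L, epoch = "before",
    time_ms = seq(0, 3.95, by = 0.05),
    voltage_uv = 100 * template_shape(seq(0, 3.95, by = 0.05))
  )
  wf <- dplyr::bind_rows(
    dplyr::mutate(base, spike = 1L), dplyr::mutate(base, spike = 2L),
    dplyr::mutate(base, spike = 3L)
  )
  mt <- epoch_mean_template(wf)
  expect_equal(mt$voltage_uv, base$voltage_uv)
  one <- epoch_mean_template(dplyr::mutate(base, spike = 1L))
  expect_equal(one$voltage_uv, base$voltage_uv)
  expect_warning(
    epoch_mean_template(dplyr::mutate(base, spike = 1L),
      expected_epochs = c("before", "during")),
    "during"
  )
})

test_that("feature ratios separate amplitude scaling from time dilation", {
  t_ms <- seq(0, 3.95, by = 0.05)
  before <- extract_waveform_features(100 * template_shape(t_ms), 2e4)
  same <- relative_feature_change(before, before)
  expect_equal(same$amplitude_ratio, 1)
  expect_equal(same$halfwidth_ratio, 1)
  # pure amplitude scaling: amplitude ratio 1.13, halfwidth unchanged
  during <- extract_waveform_features(1.13 * 100 * template_shape(t_ms), 2e4)
  rc <- relative_feature_change(before, during)
  expect_equal(rc$amplitude_ratio, 1.13, tolerance = 1e-9)
  expect_equal(rc$halfwidth_ratio, 1, tolerance = 1e-9)
  # pure time dilation x1.1: halfwidth ratio 1.1, amplitude unchanged
  dilated <- extract_waveform_features(100 * template_shape(t_ms / 1.1), 2e4)
  rd <- relative_feature_change(before, dilated)
  expect_equal(rd$amplitude_ratio, 1, tolerance = 1e-4)
  expect_equal(rd$halfwidth_ratio, 1.1, tolerance = 0.05)
})

test_that("distance table has exact grid distances and injected ratios", {
  cfg <- synth_config(seed = 1, during_scale = 1.13)
  fp <- simulate_footprint(cfg, grid_extent = 2)
  tab <- amplitude_change_vs_distance(fp)
  expect_equal(min(tab$distance_um), 0)
  expect_true(any(abs(tab$distance_um - 35) < 1e-9))
  expect_true(any(abs(tab$distance_um - sqrt(35^2 + 35^2)) < 1e-9))
  expect_true(any(abs(tab$distance_um - 49.497) < 0.001))
  expect_equal(tab$amplitude_ratio, rep(1.13, nrow(tab)), tolerance = 1e-9)
  expect_equal(tab$halfwidth_ratio, rep(1, nrow(tab)), tolerance = 1e-9)
})

test_that("electrode order does not affect the distance table", {
  cfg <- synth_config(seed = 2)
  fp <- simulate_footprint(cfg, grid_extent = 1)
  tgt <- attr(fp, "target_electrode")
  shuffled <- as_tibble(fp)[sample(nrow(fp)), ]
  t1 <- amplitude_change_vs_distance(fp)
  t2 <- amplitude_change_vs_distance(shuffled, target_electrode = tgt,
    sampling = cfg$mea_sampling)
  expect_equal(
    dplyr::arrange(t1, electrode_id), dplyr::arrange(t2, electrode_id),
    tolerance = 1e-12
  )
})

test_that("grid distances are symmetric and satisfy the triangle inequality", {
  cfg <- synth_config(seed = 1)
  fp <- simulate_footprint(cfg, grid_extent = 1)
  xy <- dplyr::distinct(as_tibble(fp), electrode_id, x_um, y_um)
  d <- as.matrix(dist(xy[, c("x_um", "y_um")]))
  expect_equal(d, t(d))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  }
})

test_that("missing target electrode is an error", {
  cfg <- synth_config(seed = 1)
  fp <- simulate_footprint(cfg, grid_extent = 1)
  expect_error(
    amplitude_change_vs_distance(fp, target_electrode = 999),
    "target electrode"
  )
})
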