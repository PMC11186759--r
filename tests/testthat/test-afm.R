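test_that("baseline statistics are exact on a clean curve and recover noise", {
  cv <- oracle_curve(noise_nn = 0)
  bl <- estimate_baseline(cv)
  expect_equal(bl$baseline_mean_nn, 0)
  expect_equal(bl$baseline_sd_nn, 0)
  # injected 5 pN Gaussian noise recovered within 5% on ~10^4 samples
  k <- 0.02
  cvn <- force_curve(
    time_s = seq_len(3e4) * 1e-4,
    height_um = seq(0, 3, length.out = 3e4),
    deflection_nm = {
      set.seed(1)
      rnorm(3e4, sd = 0.005 / k) # 5 pN in deflection units
    },
    spring_constant = k
  )
  bln <- estimate_baseline(cvn, baseline_fraction = 1)
  expect_lt(abs(bln$baseline_sd_nn - 0.005) / 0.005, 0.05)
})

test_that("too few baseline samples raise an error", {
  cv <- force_curve(
    time_s = 1:30 * 1e-4, height_um = seq(0, 1, length.out = 30),
    deflection_nm = rep(0, 30), spring_constant = 0.02
  )
  expect_error(estimate_baseline(cv, baseline_fraction = 0.1), "insufficient baseline")
})

test_that("contact point is recovered within 2 z-samples on a clean curve", {
  cv <- oracle_curve(E = 1000, z0 = 5.0, dz_um = 0.001) # 1 nm z-sampling
  det <- detect_contact_point(cv)
  expect_lt(abs(det$z_contact_um - 5.0), 2 * 0.001)
  expect_false(det$review_flag)
})

test_that("an all-zero force curve has no detectable contact", {
  cv <- force_curve(
    time_s = 1:200 * 1e-4, height_um = seq(0, 2, length.out = 200),
    deflection_nm = rep(0, 200), spring_constant = 0.02
  )
  expect_error(detect_contact_point(cv), "no contact detected")
})

test_that("an isolated noise spike is not accepted as contact", {
  set.seed(3)
  n <- 2000
  k <- 0.02
  sigma_nn <- 0.01
  defl <- rnorm(n, sd = sigma_nn / k)
  defl[800] <- 6 * sigma_nn / k # isolated 6-sigma spike, returns to baseline
  ramp <- 1500:n
  defl[ramp] <- defl[ramp] + seq(0, 40, length.out = length(ramp))
  cv <- force_curve(
    time_s = seq_len(n) * 1e-4, height_um = seq(0, 2, length.out = n),
    deflection_nm = defl, spring_constant = k
  )
  det <- detect_contact_point(cv, baseline_fraction = 0.2)
  # contact must be located at the ramp, far past the spike at sample 800
  expect_gt(det$z_contact_um, cv$height_um[1300])
})

test_that("indentation is zero at contact and on a rigid surface", {
  cv <- oracle_curve(E = 1000, z0 = 5.0)
  pairs <- compute_indentation(cv, 5.0)
  expect_equal(min(pairs$indentation_nm), 0, tolerance = 1e-9)
  # rigid surface: deflection tracks piezo one-to-one past contact
  h <- seq(0, 2, length.out = 501) # grid includes the contact height exactly
  defl <- pmax(h - 1, 0) * 1e3
  rigid <- force_curve(seq_len(501) * 1e-4, h, defl, spring_constant = 0.02)
  pr <- compute_indentation(rigid, 1.0)
  expect_true(all(abs(pr$indentation_nm) < 1e-6))
})

test_that("indentation matches the generator's ground truth", {
  cfg <- synth_config(seed = 5, force_noise_sd = 0, E_true = 1000)
  cv <- simulate_force_curve(cfg, retract = FALSE)
  pairs <- compute_indentation(cv, cfg$contact_height)
  truth <- (cv$height_um - cfg$contact_height) * 1e3 - cv$deflection_nm
  truth <- truth[truth >= 0]
  expect_equal(sort(pairs$indentation_nm), sort(truth), tolerance = 1e-6)
})

test_that("z_contact outside the approach range is an error", {
  cv <- oracle_curve()
  expect_error(compute_indentation(cv, 99), "outside")
})

test_that("depth cutoff keeps exactly the shallow samples", {
  pairs <- tibble::tibble(
    indentation_nm = seq(0, 1500, by = 10),
    force_nn = seq(0, 1500, by = 10)
  )
  kept <- apply_depth_cutoff(pairs, 750)
  expect_equal(nrow(kept), 76)
  expect_equal(attr(kept, "n_discarded"), 75)
  # no-op when everything is shallow
  all_in <- apply_depth_cutoff(pairs[pairs$indentation_nm <= 750, ], 750)
  expect_equal(nrow(all_in), 76)
  # cutoff 0 retains only the contact sample
  expect_equal(nrow(apply_depth_cutoff(pairs, 0)), 1)
})

test_that("cutoff is monotone: shrinking it never increases the fit size", {
  cv <- oracle_curve(E = 1000, noise_nn = 0.01, seed = 2)
  det <- detect_contact_point(cv)
  pairs <- compute_indentation(cv, det$z_contact_um)
  ns <- vapply(seq(900, 100, by = -100), function(cut) {
    nrow(apply_depth_cutoff(pairs, cut))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("the Hertz fit recovers the modulus from exact samples", {
  delta <- seq(5, 750, by = 5)
  pairs <- tibble::tibble(
    indentation_nm = delta,
    force_nn = hertz_force(delta, 1000, 2.5, 0.5)
  )
  fit <- fit_hertz_sphere(pairs, radius_um = 2.5, nu = 0.5)
  expect_true(fit$usable)
  expect_lt(abs(fit$E_apparent - 1000) / 1000, 1e-3)
  expect_lt(fit$residual_rms_nn, 1e-9)
  # scale equivariance: doubling all forces doubles E exactly
  pairs2 <- dplyr::mutate(pairs, force_nn = 2 * force_nn)
  fit2 <- fit_hertz_sphere(pairs2, radius_um = 2.5, nu = 0.5)
  expect_equal(fit2$E_apparent, 2 * fit$E_apparent, tolerance = 1e-12)
})

test_that("fits with fewer than 10 samples are unusable, not errors", {
  delta <- seq(100, 750, length.out = 8)
  pairs <- tibble::tibble(
    indentation_nm = delta, force_nn = hertz_force(delta, 1000, 2.5, 0.5)
  )
  fit <- fit_hertz_sphere(pairs, radius_um = 2.5)
  expect_false(fit$usable)
  expect_equal(fit$n_points_fit, 8)
})

test_that("full curve processing recovers E on independent oracle curves", {
  cv <- oracle_curve(E = 800, z0 = 5.0, noise_nn = 0)
  fit <- fit_force_curve(cv)
  expect_lt(abs(fit$E_apparent - 800) / 800, 1e-3)
  expect_lt(abs(fit$z_contact_um - 5.0), 0.005)
  tdy <- tidy(fit)
  expect_equal(tdy$E_apparent_pa, fit$E_apparent)
  expect_true(all(c("baseline_sd_nn", "review_flag", "usable") %in% names(tdy)))
})

test_that("cycle stiffness averages usable fits and enforces the minimum", {
  mk <- function(E) {
    tibble::tibble(
      curve_id = NA, timestamp = NA_real_, E_apparent_pa = E,
      z_contact_um = NA_real_, baseline_mean_nn = 0, baseline_sd_nn = 0,
      n_points_fit = 100L, max_indentation_used_nm = 750,
      residual_rms_nn = 0, nu = 0.5, radius_um = 2.5,
      review_flag = FALSE, usable = TRUE
    )
  }
  five <- dplyr::bind_rows(lapply(rep(1000, 5), mk))
  cyc <- cycle_stiffness(five)
  expect_equal(cyc$E_mean_pa, 1000)
  expect_equal(cyc$E_sd_pa, 0)
  three <- dplyr::bind_rows(lapply(c(1000, 2000, 3000), mk))
  cyc3 <- cycle_stiffness(three)
  expect_equal(cyc3$E_mean_pa, 2000)
  expect_equal(cyc3$E_sd_pa, 1000) # sample sd
  expect_error(
    cycle_stiffness(dplyr::bind_rows(lapply(c(1000, 2000), mk))),
    "insufficient curves"
  )
})

test_that("burst/IBI labels use closed intervals", {
  bursts <- tibble::tibble(start = c(10, 30), end = c(11, 31))
  expect_equal(classify_curve_epoch(10.5, bursts), "burst")
  expect_equal(classify_curve_epoch(5.0, bursts), "IBI")
  expect_equal(classify_curve_epoch(10, bursts), "burst") # boundary: closed
  expect_equal(classify_curve_epoch(11, bursts), "burst")
  expect_equal(
    classify_curve_epoch(c(10.5, 20), bursts), c("burst", "IBI")
  )
})

test_that("nominal pressure supports both area models", {
  p1 <- nominal_pressure(200, radius_um = 2.5)
  expect_equal(p1$pressure_kpa, 200e-9 / (pi * 2.5e-6^2) / 1e3, tolerance = 1e-12)
  expect_equal(round(p1$pressure_kpa, 2), 10.19)
  p2 <- nominal_pressure(200, area_model = "effective_area", effective_area_um2 = 40)
  expect_equal(p2$pressure_kpa, 5.0)
  expect_equal(nominal_pressure(0, radius_um = 2.5)$pressure_kpa, 0)
  expect_error(
    nominal_pressure(100, area_model = "effective_area", effective_area_um2 = 0),
    "positive"
  )
})
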