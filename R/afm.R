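approach_segment <- function(curve) {
  app <- curve[curve$segment == "approach", , drop = FALSE]
  if (nrow(app) == 0) abort("force curve has no approach segment.")
  app
}

#' Baseline force statistics of a force curve
#'
#' Mean and standard deviation of the force over the first
#' `baseline_fraction` of the approach segment, i.e. the out-of-contact
#' baseline used to set the contact-detection threshold.
#'
#' @param curve A `force_curve`.
#' @param baseline_fraction Fraction of the approach segment treated as
#'   baseline (default 0.3).
#' @param detrend Remove a linear drift from the baseline before computing
#'   the sd? Default keeps the raw baseline.
#' @return A tibble with columns `baseline_mean_nn`, `baseline_sd_nn`,
#'   `n_baseline`.
#' @export
estimate_baseline <- function(curve, baseline_fraction = 0.3, detrend = FALSE) {
  stopifnot(baseline_fraction > 0, baseline_fraction <= 1)
  app <- approach_segment(curve)
  n <- floor(nrow(app) * baseline_fraction)
  if (n < 20) abort("insufficient baseline: fewer than 20 approach samples in the baseline window.")
  f <- app$force_nn[seq_len(n)]
  if (detrend) {
    t <- app$time_s[seq_len(n)]
    f <- stats::residuals(lm(f ~ t)) + mean(f)
  }
  tibble(
    baseline_mean_nn = mean(f),
    baseline_sd_nn = stats::sd(f),
    n_baseline = n
  )
}

#' Detect the contact point of a force curve
#'
#' Implements the threshold rule used for AFM cell indentation: the contact
#' point is located where the baseline-subtracted approach force first
#' exceeds `threshold_multiple` times the baseline noise sd *and remains
#' above it for the rest of the approach* (the persistence requirement is a
#' deterministic stand-in for manual curation; an isolated noise spike does
#' not qualify). The reported `z_contact` is the x-intercept at zero force
#' of the line through the accepted sample and the interpolated threshold
#' crossing. Crossings in the last 5% of the approach are flagged for
#' review.
#'
#' @inheritParams estimate_baseline
#' @param threshold_multiple Threshold in baseline-sd units (default 5).
#' @return A tibble with `z_contact_um`, `review_flag`, `baseline_mean_nn`,
#'   `baseline_sd_nn`.
#' @export
detect_contact_point <- function(curve, threshold_multiple = 5,
                                 baseline_fraction = 0.3, detrend = FALSE) {
  app <- approach_segment(curve)
  bl <- estimate_baseline(curve, baseline_fraction, detrend)
  f <- app$force_nn - bl$baseline_mean_nn
  thr <- threshold_multiple * bl$baseline_sd_nn
  above <- f > thr
  # first index from which the force stays above threshold to segment end
  persistent <- rev(cumprod(rev(above))) == 1
  if (!any(persistent)) abort("no contact detected")
  i <- which(persistent)[1]
  if (i == 1) abort("no contact detected: approach is entirely in contact (no baseline).")

  z_i <- app$height_um[i]
  # interpolated threshold crossing between the last sub-threshold sample
  # and the accepted sample
  f0 <- f[i - 1]
  f1 <- f[i]
  z_cross <- if (f1 > f0) {
    app$height_um[i - 1] + (thr - f0) / (f1 - f0) *
      (z_i - app$height_um[i - 1])
  } else {
    z_i
  }
  slope <- if (z_i > z_cross) (f1 - thr) / (z_i - z_cross) else NA_real_
  z_contact <- if (is.finite(slope) && slope > 0) z_i - f1 / slope else z_cross
  # never extrapolate below the observed baseline range
  z_contact <- max(z_contact, app$height_um[1])
  review <- i > 0.95 * nrow(app)
  tibble(
    z_contact_um = z_contact, review_flag = review,
    baseline_mean_nn = bl$baseline_mean_nn, baseline_sd_nn = bl$baseline_sd_nn
  )
}

#' Compute indentation depth past the contact point
#'
#' Sample indentation is piezo travel past contact minus the additional
#' cantilever deflection, `delta = (z - z_contact) - (d - d_contact)`,
#' reported in nm for in-contact approach samples (`delta >= 0`). The
#' sample of maximal force defines the deepest indentation, consistent
#' with zeroing the displacement axis at maximal force.
#'
#' @param curve A `force_curve`.
#' @param z_contact_um Contact height, micrometres (within the approach range).
#' @return A tibble of in-contact approach samples with columns
#'   `indentation_nm` and `force_nn` (baseline NOT subtracted).
#' @export
compute_indentation <- function(curve, z_contact_um) {
  app <- approach_segment(curve)
  if (z_contact_um < min(app$height_um) || z_contact_um > max(app$height_um)) {
    abort("`z_contact_um` lies outside the approach height range.")
  }
  d_contact <- approx(app$height_um, app$deflection_nm, xout = z_contact_um,
    ties = mean
  )$y
  contact <- app[app$height_um >= z_contact_um, , drop = FALSE]
  delta <- (contact$height_um - z_contact_um) * 1e3 -
    (contact$deflection_nm - d_contact)
  keep <- delta >= 0
  tibble(indentation_nm = delta[keep], force_nn = contact$force_nn[keep])
}

#' Filter force/indentation pairs by an indentation-depth cutoff
#'
#' Discards all samples whose indentation exceeds `cutoff_nm`, so the fit
#' is restricted to depths where the contact model is considered valid.
#'
#' @param pairs A tibble with `indentation_nm` and `force_nn`.
#' @param cutoff_nm Depth cutoff, nm (default 750).
#' @return The filtered tibble, with attribute `n_discarded`.
#' @export
apply_depth_cutoff <- function(pairs, cutoff_nm = 750) {
  stopifnot(cutoff_nm >= 0)
  keep <- pairs$indentation_nm <= cutoff_nm
  out <- pairs[keep, , drop = FALSE]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Fit the spherical-indenter Hertz model
#'
#' Least-squares estimate of the apparent Young's modulus E from
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)`. With R and nu
#' fixed the model is linear in E, so the least-squares problem has the
#' closed-form solution of a regression of F on `delta^(3/2)` through the
#' origin; the positivity constraint on E (a fit in log E) is inactive
#' whenever the force-indentation correlation is positive, and a
#' non-positive estimate marks the fit unusable rather than clipping.
#'
#' @param pairs A tibble with `indentation_nm` and `force_nn` (baseline
#'   subtracted), approach segment only.
#' @param radius_um Bead radius, micrometres.
#' @param nu Poisson ratio (default 0.5, incompressible cell).
#' @param min_points Minimum number of in-contact samples (default 10).
#' @return A `hertz_fit` object; see [tidy.hertz_fit()].
#' @export
#' @examples
#' delta <- seq(10, 750, by = 10)
#' pairs <- tibble::tibble(
#'   indentation_nm = delta,
#'   force_nn = hertz_force(delta, 1000, 2.5, 0.5)
#' )
#' fit_hertz_sphere(pairs, radius_um = 2.5)
fit_hertz_sphere <- function(pairs, radius_um, nu = 0.5, min_points = 10) {
  stopifnot(radius_um > 0, nu^2 < 1)
  n <- nrow(pairs)
  if (n < min_points) {
    return(new_hertz_fit(
      E_apparent = NA_real_, usable = FALSE, n_points_fit = n,
      residual_rms_nn = NA_real_, max_indentation_used_nm = suppressWarnings(
        max(pairs$indentation_nm, -Inf)
      ), nu = nu, radius_um = radius_um
    ))
  }
  x <- (pairs$indentation_nm * 1e-9)^1.5 # m^(3/2)
  f <- pairs$force_nn * 1e-9 # N
  c_hat <- sum(f * x) / sum(x^2)
  E <- c_hat * (1 - nu^2) * 3 / (4 * sqrt(radius_um * 1e-6))
  resid <- f - c_hat * x
  new_hertz_fit(
    E_apparent = E, usable = is.finite(E) && E > 0, n_points_fit = n,
    residual_rms_nn = sqrt(mean(resid^2)) * 1e9,
    max_indentation_used_nm = max(pairs$indentation_nm),
    nu = nu, radius_um = radius_um
  )
}

new_hertz_fit <- function(E_apparent, usable, n_points_fit, residual_rms_nn,
                          max_indentation_used_nm, nu, radius_um,
                          z_contact_um = NA_real_, baseline_mean_nn = NA_real_,
                          baseline_sd_nn = NA_real_, review_flag = FALSE,
                          curve_id = NA, timestamp = NA_real_) {
  structure(
    list(
      E_apparent = E_apparent, usable = usable, n_points_fit = n_points_fit,
      residual_rms_nn = residual_rms_nn,
      max_indentation_used_nm = max_indentation_used_nm,
      nu = nu, radius_um = radius_um, z_contact_um = z_contact_um,
      baseline_mean_nn = baseline_mean_nn, baseline_sd_nn = baseline_sd_nn,
      review_flag = review_flag, curve_id = curve_id, timestamp = timestamp
    ),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit> E = %.4g Pa | %d points | residual rms %.3g nN | usable: %s\n",
    x$E_apparent, x$n_points_fit, x$residual_rms_nn, x$usable
  ))
  invisible(x)
}

#' Tidy a Hertz fit
#'
#' @param x A `hertz_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fitted modulus and fit diagnostics.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(
    curve_id = x$curve_id, timestamp = x$timestamp,
    E_apparent_pa = x$E_apparent, z_contact_um = x$z_contact_um,
    baseline_mean_nn = x$baseline_mean_nn, baseline_sd_nn = x$baseline_sd_nn,
    n_points_fit = x$n_points_fit,
    max_indentation_used_nm = x$max_indentation_used_nm,
    residual_rms_nn = x$residual_rms_nn,
    nu = x$nu, radius_um = x$radius_um,
    review_flag = x$review_flag, usable = x$usable
  )
}

#' @rdname tidy.hertz_fit
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(
    E_apparent_pa = x$E_apparent, residual_rms_nn = x$residual_rms_nn,
    n_points_fit = x$n_points_fit, usable = x$usable
  )
}

#' Process one force curve into a Hertz fit
#'
#' Full curve pipeline: baseline statistics, contact-point detection
#' (threshold rule of [detect_contact_point()]), indentation computation,
#' depth cutoff, and the spherical Hertz fit on the approach segment.
#' Because the threshold crossing systematically falls past the true
#' contact on soft samples, the contact point is by default refined by
#' minimising the Hertz-fit residual over candidate contact heights around
#' the detected value (golden-section search); the detection result seeds
#' the search and its review flag is propagated.
#'
#' @param curve A `force_curve`.
#' @param cutoff_nm Indentation depth cutoff, nm.
#' @param threshold_multiple Contact threshold in baseline-sd units.
#' @param nu Poisson ratio.
#' @param baseline_fraction Baseline window as a fraction of the approach.
#' @param refine_contact Refine the contact point by residual minimisation?
#' @param refine_halfwidth_um Search half-width around the detected contact
#'   point, micrometres.
#' @param min_points Minimum in-contact samples for a usable fit.
#' @return A `hertz_fit`.
#' @export
fit_force_curve <- function(curve, cutoff_nm = 750, threshold_multiple = 5,
                            nu = 0.5, baseline_fraction = 0.3,
                            refine_contact = TRUE, refine_halfwidth_um = 0.5,
                            min_points = 10) {
  radius_um <- attr(curve, "bead_radius")
  det <- detect_contact_point(curve, threshold_multiple, baseline_fraction)
  app <- approach_segment(curve)

  fit_at <- function(z0) {
    pairs <- compute_indentation(curve, z0)
    pairs$force_nn <- pairs$force_nn - det$baseline_mean_nn
    pairs <- apply_depth_cutoff(pairs, cutoff_nm)
    fit_hertz_sphere(pairs, radius_um, nu, min_points)
  }
  # mean squared residual, so candidate contact points with different
  # numbers of in-cutoff samples are comparable
  rss_at <- function(z0) {
    ft <- fit_at(z0)
    if (!ft$usable) return(Inf)
    ft$residual_rms_nn^2
  }

  z0 <- det$z_contact_um
  if (refine_contact) {
    lo <- max(min(app$height_um), z0 - refine_halfwidth_um)
    hi <- min(max(app$height_um) - 1e-6, z0 + refine_halfwidth_um)
    if (hi > lo) {
      opt <- optimize(rss_at, c(lo, hi), tol = 1e-5)
      if (is.finite(opt$objective)) z0 <- opt$minimum
    }
  }
  fit <- fit_at(z0)
  fit$z_contact_um <- z0
  fit$baseline_mean_nn <- det$baseline_mean_nn
  fit$baseline_sd_nn <- det$baseline_sd_nn
  fit$review_flag <- det$review_flag
  fit$curve_id <- attr(curve, "curve_id")
  fit$timestamp <- attr(curve, "timestamp")
  fit
}

#' Aggregate Hertz fits of one measurement cycle
#'
#' A stiffness measurement is the average of the usable fits of one cycle
#' of repeated force curves (at least `min_curves`, mirroring the
#' at-least-three convention for reported soma stiffness).
#'
#' @param fits A list of `hertz_fit` objects or a tibble from
#'   [tidy.hertz_fit()] rows.
#' @param min_curves Minimum usable curves per cycle (default 3).
#' @param neuron_id,cycle_time Identifiers stored with the measurement.
#' @return One-row tibble with `E_mean_pa`, `E_sd_pa`, `n_curves`.
#' @export
cycle_stiffness <- function(fits, min_curves = 3, neuron_id = NA,
                            cycle_time = NA_real_) {
  df <- if (inherits(fits, "data.frame")) {
    as_tibble(fits)
  } else {
    list_rbind(map(fits, tidy))
  }
  df <- filter(df, .data$usable)
  if (nrow(df) < min_curves) {
    abort(sprintf(
      "insufficient curves: %d usable fits, need at least %d.",
      nrow(df), min_curves
    ))
  }
  tibble(
    neuron_id = neuron_id, cycle_time = cycle_time,
    E_mean_pa = mean(df$E_apparent_pa), E_sd_pa = stats::sd(df$E_apparent_pa),
    n_curves = nrow(df)
  )
}

#' Classify curve timestamps as burst or inter-burst
#'
#' A timestamp is labelled `"burst"` if it falls inside any burst interval
#' (closed intervals, so a time exactly at a burst boundary counts as
#' burst), else `"IBI"`.
#'
#' @param timestamps Master-clock times, seconds (vectorised).
#' @param bursts A tibble of burst intervals with `start` and `end`.
#' @return Character vector of labels.
#' @export
classify_curve_epoch <- function(timestamps, bursts) {
  if (nrow(bursts) == 0) return(rep("IBI", length(timestamps)))
  stopifnot(all(bursts$end > bursts$start))
  vapply(timestamps, function(t) {
    if (any(t >= bursts$start & t <= bursts$end)) "burst" else "IBI"
  }, character(1))
}

#' Nominal pressure of a setpoint force
#'
#' Converts a setpoint force to a nominal pressure `P = F / A`. The default
#' contact-area model is the bead cross-section `A = pi * R^2`; an
#' effective contact area (micrometres squared) may be supplied instead.
#' The area model used is recorded in the output, since the two models can
#' differ by about a factor of two for micrometre beads on soft cells.
#'
#' @param setpoint_force_nn Setpoint force, nN (vectorised).
#' @param radius_um Bead radius, micrometres.
#' @param area_model `"bead_cross_section"` or `"effective_area"`.
#' @param effective_area_um2 Contact area for `area_model = "effective_area"`.
#' @return A tibble with `pressure_kpa`, `area_um2`, `area_model`.
#' @export
#' @examples
#' nominal_pressure(200, radius_um = 2.5) # ~10.19 kPa
#' nominal_pressure(200, area_model = "effective_area", effective_area_um2 = 40) # 5 kPa
nominal_pressure <- function(setpoint_force_nn, radius_um = 2.5,
                             area_model = c("bead_cross_section", "effective_area"),
                             effective_area_um2 = NULL) {
  area_model <- match.arg(area_model)
  stopifnot(all(setpoint_force_nn >= 0))
  area_um2 <- switch(area_model,
    bead_cross_section = pi * radius_um^2,
    effective_area = {
      if (is.null(effective_area_um2)) abort("supply `effective_area_um2`.")
      effective_area_um2
    }
  )
  if (any(area_um2 <= 0)) abort("contact area must be positive.")
  tibble(
    pressure_kpa = setpoint_force_nn * 1e-9 / (area_um2 * 1e-12) / 1e3,
    area_um2 = area_um2, area_model = area_model
  )
}
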