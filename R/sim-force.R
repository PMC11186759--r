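#' Hertz force for a spherical indenter (closed form)
#'
#' Force exerted by a rigid sphere indenting an elastic half-space,
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)`.
#'
#' @param delta_nm Indentation depth, nm (vectorised).
#' @param E Apparent Young's modulus, Pa.
#' @param radius_um Sphere radius, micrometres.
#' @param nu Poisson ratio (`nu^2 < 1`).
#' @return Force in nN.
#' @export
#' @examples
#' hertz_force(750, E = 1000, radius_um = 2.5, nu = 0.5) # ~1.826 nN
hertz_force <- function(delta_nm, E, radius_um, nu = 0.5) {
  stopifnot(E > 0, radius_um > 0, nu^2 < 1)
  prefac <- (4 / 3) * (E / (1 - nu^2)) * sqrt(radius_um * 1e-6)
  prefac * (pmax(delta_nm, 0) * 1e-9)^1.5 * 1e9
}

# Solve the cantilever-sample force balance k*d = C*((z - z0) - d)^(3/2)
# for the deflection d (metres) at each piezo extension u = z - z0 (metres).
# Newton iteration from d = 0; the balance g(d) = k*d - C*(u-d)^(3/2) is
# increasing and concave, so Newton converges monotonically from the left.
solve_deflection <- function(u, k, C, rel_tol = 1e-12, max_iter = 200) {
  d <- numeric(length(u))
  pos <- u > 0
  if (!any(pos)) return(d)
  up <- u[pos]
  dp <- numeric(length(up))
  for (i in seq_len(max_iter)) {
    rem <- up - dp
    g <- k * dp - C * rem^1.5
    gp <- k + 1.5 * C * sqrt(rem)
    step <- g / gp
    dp <- dp - step
    if (max(abs(step) / pmax(dp, 1e-30)) <= rel_tol) break
  }
  resid <- abs(k * dp - C * (up - dp)^1.5)
  if (any(resid > 1e-10 * pmax(k * dp, 1e-15))) {
    abort("deflection solver failed to converge to the requested tolerance.")
  }
  d[pos] <- dp
  d
}

#' Simulate one AFM force curve on a Hertzian sample
#'
#' Generates the time, piezo-height and cantilever-deflection record of one
#' approach(-dwell)(-retract) cycle on an elastic half-space with modulus
#' `config$E_true`. Past the contact point the deflection solves the
#' implicit cantilever-sample balance
#' `k * d = (4/3) * (E / (1 - nu^2)) * sqrt(R) * ((z - z0) - d)^(3/2)`
#' (Newton iteration, relative tolerance 1e-12), which makes the synthetic
#' curve physically consistent with what the Hertz fitter assumes. The
#' baseline segment has exactly zero force before noise; Gaussian force
#' noise of sd `config$force_noise_sd` (and optional linear drift) is added
#' last, as deflection noise.
#'
#' @param config A [synth_config()].
#' @param target_indentation_nm Depth reached at the end of the approach, nm.
#'   The approach extends one baseline span below the contact point and up
#'   to the piezo height that yields exactly this indentation.
#' @param baseline_um Length of the out-of-contact approach baseline,
#'   micrometres. The default (`NULL`) uses the in-contact piezo span, so
#'   half of every approach is baseline regardless of sample stiffness.
#' @param dwell_s Dwell duration at maximal extension, seconds (0 = none).
#' @param retract Include a retract segment mirroring the approach?
#' @param timestamp Curve start time on the AFM clock, seconds.
#' @param curve_id Identifier stored with the curve.
#' @param heights,segments Optional explicit piezo trajectory (micrometres)
#'   and per-sample segment labels, overriding the built-in plan. The
#'   trajectory must be monotone within each segment.
#'
#' @return A `force_curve` tibble with columns `time_s`, `height_um`,
#'   `deflection_nm`, `force_nn`, `segment` and attributes
#'   `spring_constant`, `bead_radius`, `speed`, `timestamp`, `curve_id`,
#'   `true_contact_height`, `true_E`.
#' @export
#' @examples
#' curve <- simulate_force_curve(synth_config(seed = 1, force_noise_sd = 0))
#' max(curve$force_nn)
simulate_force_curve <- function(config,
                                 target_indentation_nm = 900,
                                 baseline_um = NULL,
                                 dwell_s = 0,
                                 retract = TRUE,
                                 timestamp = 0,
                                 curve_id = 1L,
                                 heights = NULL,
                                 segments = NULL) {
  stopifnot(inherits(config, "synth_config"))
  k <- config$spring_constant
  C <- (4 / 3) * (config$E_true / (1 - config$poisson_ratio^2)) *
    sqrt(config$bead_radius * 1e-6)
  z0 <- config$contact_height
  dz <- config$approach_speed / config$afm_sampling # micrometres per sample

  if (is.null(heights)) {
    delta_m <- target_indentation_nm * 1e-9
    d_max_m <- (C * delta_m^1.5) / k # deflection at target depth
    z_max <- z0 + (delta_m + d_max_m) * 1e6
    if (is.null(baseline_um)) baseline_um <- z_max - z0
    z_start <- z0 - baseline_um
    # grid anchored at z_max so the deepest sample hits the target depth
    n_steps <- ceiling((z_max - z_start) / dz)
    approach <- z_max - rev(seq(0, n_steps)) * dz
    heights <- approach
    segments <- rep("approach", length(approach))
    if (dwell_s > 0) {
      n_dwell <- max(1L, round(dwell_s * config$afm_sampling))
      heights <- c(heights, rep(z_max, n_dwell))
      segments <- c(segments, rep("dwell", n_dwell))
    }
    if (retract) {
      retr <- seq(z_max - dz, z_start, by = -dz)
      heights <- c(heights, retr)
      segments <- c(segments, rep("retract", length(retr)))
    }
  } else {
    stopifnot(length(heights) == length(segments))
    for (seg in unique(segments)) {
      h <- heights[segments == seg]
      if (length(h) > 1 && !(all(diff(h) >= 0) || all(diff(h) <= 0))) {
        abort(paste0("non-monotone piezo trajectory in segment '", seg, "'."))
      }
    }
  }

  time_s <- (seq_along(heights) - 1) / config$afm_sampling
  u <- (heights - z0) * 1e-6
  d_m <- solve_deflection(u, k, C)
  deflection_nm <- d_m * 1e9

  if (config$baseline_drift != 0) {
    deflection_nm <- deflection_nm + config$baseline_drift * time_s / k * 1e9
  }
  if (config$force_noise_sd > 0) {
    noise <- with_substream(config$seed, paste0("force_curve_", curve_id),
      rnorm(length(heights), sd = config$force_noise_sd / k * 1e9)
    )
    deflection_nm <- deflection_nm + noise
  }

  out <- tibble(
    time_s = time_s, height_um = heights,
    deflection_nm = deflection_nm,
    force_nn = k * deflection_nm,
    segment = segments
  )
  new_force_curve(out,
    spring_constant = k, bead_radius = config$bead_radius,
    speed = config$approach_speed, timestamp = timestamp,
    curve_id = curve_id, true_contact_height = z0, true_E = config$E_true
  )
}

#' Construct a force curve from sample vectors
#'
#' Assembles a `force_curve` from time, piezo-height and deflection
#' samples plus probe metadata; force is derived as
#' `spring_constant * deflection`. Use this to wrap real AFM text exports
#' after mapping their columns.
#'
#' @param time_s Sample times, s (strictly increasing).
#' @param height_um Piezo height, micrometres (increasing towards the sample).
#' @param deflection_nm Cantilever deflection, nm.
#' @param segment Per-sample segment label (`"approach"`, `"dwell"`,
#'   `"retract"`); defaults to all-approach.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param bead_radius Bead radius, micrometres.
#' @param speed Piezo speed, micrometres per second.
#' @param timestamp Curve start on the AFM clock, s.
#' @param curve_id Identifier.
#' @return A `force_curve` tibble.
#' @export
force_curve <- function(time_s, height_um, deflection_nm,
                        segment = rep("approach", length(time_s)),
                        spring_constant, bead_radius = 2.5, speed = 10,
                        timestamp = 0, curve_id = NA) {
  stopifnot(
    length(time_s) == length(height_um),
    length(time_s) == length(deflection_nm),
    length(time_s) == length(segment),
    spring_constant > 0, !is.unsorted(time_s, strictly = TRUE)
  )
  new_force_curve(
    tibble(
      time_s = time_s, height_um = height_um, deflection_nm = deflection_nm,
      force_nn = spring_constant * deflection_nm, segment = segment
    ),
    spring_constant = spring_constant, bead_radius = bead_radius,
    speed = speed, timestamp = timestamp, curve_id = curve_id
  )
}

new_force_curve <- function(df, spring_constant, bead_radius, speed,
                            timestamp = 0, curve_id = NA, true_contact_height = NA,
                            true_E = NA) {
  structure(
    as_tibble(df),
    spring_constant = spring_constant, bead_radius = bead_radius,
    speed = speed, timestamp = timestamp, curve_id = curve_id,
    true_contact_height = true_contact_height, true_E = true_E,
    class = c("force_curve", class(as_tibble(df)))
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve> %d samples | k = %.3g N/m | R = %.3g um | speed = %.3g um/s\n",
    nrow(x), attr(x, "spring_constant"), attr(x, "bead_radius"),
    attr(x, "speed")
  ))
  NextMethod()
}

#' Plot a force curve
#'
#' @param object A `force_curve`.
#' @param ... Unused.
#' @return A ggplot of force against piezo height, coloured by segment.
#' @export
autoplot.force_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$height_um, y = .data$force_nn, colour = .data$segment
  )) +
    ggplot2::geom_path() +
    ggplot2::labs(
      x = "piezo height (µm)", y = "force (nN)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
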