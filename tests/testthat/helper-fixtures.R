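# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A hand-built noiseless Hertzian approach curve with known contact point,
# constructed independently of simulate_force_curve(): heights on a uniform
# grid, deflection from the closed-form force at the true indentation
# (solved by uniroot, not the package's Newton solver).
oracle_curve <- function(E = 1000, z0 = 5.0, k = 0.02, R = 2.5, nu = 0.5,
                         dz_um = 0.001, z_start = 3.0, z_max = 6.2,
                         noise_nn = 0, seed = 1) {
  heights <- seq(z_start, z_max, by = dz_um)
  C <- (4 / 3) * (E / (1 - nu^2)) * sqrt(R * 1e-6)
  defl_m <- vapply(heights, function(z) {
    u <- (z - z0) * 1e-6
    if (u <= 0) return(0)
    stats::uniroot(
      function(d) k * d - C * (u - d)^1.5,
      c(0, u), tol = 1e-18
    )$root
  }, numeric(1))
  defl_nm <- defl_m * 1e9
  if (noise_nn > 0) {
    set.seed(seed)
    defl_nm <- defl_nm + rnorm(length(defl_nm), sd = noise_nn / k)
  }
  force_curve(
    time_s = seq_along(heights) * 1e-4,
    height_um = heights, deflection_nm = defl_nm,
    spring_constant = k, bead_radius = R
  )
}

# Regular n-gon outline of radius r centred at (cx, cy)
regular_polygon <- function(n, r, cx = 0, cy = 0, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Exhaustive peak-detection oracle: a frame is a peak iff it strictly
# dominates every other frame within +/- window/2.
brute_force_peaks <- function(t, y, window = 3) {
  which(vapply(seq_along(y), function(i) {
    nb <- setdiff(which(abs(t - t[i]) <= window / 2), i)
    length(nb) > 0 && all(y[i] > y[nb])
  }, logical(1)))
}

# Full-enumeration oracle for the signed-rank two-sided p-value (all 2^n
# sign assignments, average ranks for ties).
enumerate_wilcoxon_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  center <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mean(abs(vs - center) >= abs(v_obs - center) - 1e-9)
}

# Enumeration oracle for the Mann-Whitney two-sided p-value that computes
# U by directly counting x > y pairs (ties count 1/2) for every
# assignment of the pooled values to the first group.
enumerate_mw_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  center <- m * length(y) / 2
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}
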