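# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Perpendicular distance from the origin O to the line through points a and
# c in the sagittal xz plane, via the 2-D cross product.
point_line_distance_xz <- function(a, c) {
  ax <- a[1]; az <- a[3]; cx <- c[1]; cz <- c[3]
  abs(ax * cz - cx * az) / sqrt((ax - cx)^2 + (az - cz)^2)
}

# Step-by-step Hill force assembly written out from the closed forms,
# independent of the package's factor functions.
hill_force_by_hand <- function(a, l_m, v_n, l_mopt, F_0, phi0,
                               gamma = 0.5, A_s = 0.25, f_M = 1.8,
                               k_PE = 4, eps0_M = 0.5) {
  f_l <- exp(-(l_m / l_mopt - 1)^2 / gamma)
  f_v <- if (v_n < -1) {
    0
  } else if (v_n <= 0) {
    (1 + v_n) / (1 - v_n / A_s)
  } else {
    (f_M * v_n + A_s * (f_M - 1) / 2 + 2 * A_s) /
      (v_n + A_s * (f_M - 1) / 2 + 2 * A_s)
  }
  f_PE <- if (l_m <= l_mopt) {
    0
  } else {
    (exp(k_PE * (l_m / l_mopt - 1) / eps0_M) - 1) / (exp(k_PE) - 1)
  }
  phi <- asin(l_mopt * sin(phi0) / l_m)
  (a * f_l * f_v + f_PE) * F_0 * cos(phi)
}

# A single short-fibered flexor whose fiber stays at or below its resting
# length over the whole default motion: with zero activation it must
# produce zero force.
slack_flexor <- function() {
  muscle_params("slack_flexor", "flexor", l_mopt = 0.30, l_topt = 0.05,
                F_0 = 100, phi0_deg = 0,
                origin = c(0, 0, 0.10), insertion = c(0, 0, -0.10),
                l_0 = 0.10)
}

# Constant activation set over a trajectory's time base.
constant_activations <- function(trajectory, muscles, level = 0.02) {
  cols <- stats::setNames(
    rep(list(rep(level, nrow(trajectory))), length(muscles)),
    vapply(muscles, `[[`, character(1), "name"))
  activation_set(trajectory$time, as.data.frame(cols),
                 floor = min(level, 0.02))
}
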