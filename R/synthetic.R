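#' Joint-angle trajectory container
#'
#' A uniformly sampled elbow flexion-angle series. Angles are in degrees,
#' with 0 at full extension and flexion positive; the physiological range
#' accepted is \[0, 150\] degrees.
#'
#' @param time Time samples (s), strictly increasing with a uniform step.
#' @param theta_deg Flexion angles (degrees), same length as `time`.
#' @return A data frame of class `joint_trajectory` with columns `time`
#'   and `theta`.
#' @seealso [planned_trajectory()]
#' @export
joint_trajectory <- function(time, theta_deg) {
  if (length(time) != length(theta_deg) || length(time) < 2L) {
    stop("`time` and `theta_deg` must have equal length >= 2",
         call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("`time` must be strictly increasing with a uniform step",
         call. = FALSE)
  }
  if (any(!is.finite(theta_deg)) ||
      any(theta_deg < -1e-9 | theta_deg > 150 + 1e-9)) {
    stop("`theta_deg` must lie in [0, 150] degrees", call. = FALSE)
  }
  structure(data.frame(time = time, theta = pmin(pmax(theta_deg, 0), 150)),
            class = c("joint_trajectory", "data.frame"))
}

#' Planned flexion-extension trajectory
#'
#' The standard planned elbow motion: flex from 0 degrees to `theta_peak`
#' and return to 0 within `duration_s` seconds, following
#' \deqn{\theta(t) = \frac{\theta_{peak}}{2}\Big(1 +
#'   \sin\big(2\pi t / T - \pi/2\big)\Big),}
#' which at the defaults (T = 2 s, peak 90 degrees) is
#' \eqn{\theta = 45 + 45 \sin(\pi t - \pi/2)}: 0 degrees at t = 0, peak at
#' mid-motion, back to 0 at the end.
#'
#' @param duration_s Motion duration (s); default 2.
#' @param dt Sampling step (s); default 0.01 (201 samples at the default
#'   duration).
#' @param theta_peak Peak flexion angle (degrees); default 90.
#' @return A [joint_trajectory()].
#' @examples
#' tr <- planned_trajectory()
#' tr$theta[tr$time == 1]  # 90 degrees at mid-motion
#' @export
planned_trajectory <- function(duration_s = 2, dt = 0.01, theta_peak = 90) {
  check_scalar(duration_s, "duration_s", lower = 0)
  check_scalar(dt, "dt", lower = 0)
  check_scalar(theta_peak, "theta_peak", lower = 0)
  if (theta_peak > 150) stop("`theta_peak` must be <= 150", call. = FALSE)
  t <- seq(0, duration_s, by = dt)
  theta <- (theta_peak / 2) * (1 + sin(2 * pi * t / duration_s - pi / 2))
  joint_trajectory(t, theta)
}

#' Activation-set container
#'
#' Per-muscle activation time series aligned to a joint trajectory. Values
#' must lie within \[`floor`, 1\]; simulation tooling keeps a small nonzero
#' floor (default 0.02) because fully silent muscles make muscle-driven
#' trackers ill-conditioned.
#'
#' @param time Time samples (s), uniform step.
#' @param activations Data frame or matrix, one named column per muscle.
#' @param floor Lower admissible bound; default 0.02.
#' @return A data frame of class `activation_set` with column `time`
#'   followed by one column per muscle.
#' @export
activation_set <- function(time, activations, floor = 0.02) {
  a <- as.data.frame(activations)
  if (is.null(names(a)) || any(!nzchar(names(a)))) {
    stop("activation columns must be named after muscles", call. = FALSE)
  }
  if (nrow(a) != length(time)) {
    stop("`activations` must have one row per time sample", call. = FALSE)
  }
  vals <- as.matrix(a)
  if (any(!is.finite(vals)) ||
      any(vals < floor - 1e-12) || any(vals > 1 + 1e-12)) {
    stop("activations must lie within [", format(floor), ", 1]",
         call. = FALSE)
  }
  structure(cbind(data.frame(time = time), a),
            class = c("activation_set", "data.frame"),
            floor = floor)
}

#' Default activation profiles for the six-muscle model
#'
#' Gaussian-bump profile parameters emulating muscle-driven tracking
#' (computed muscle control) output for the planned flexion-extension
#' motion: bell-shaped flexor activations peaking during flexion, with the
#' long head of biceps carrying the largest drive, and small triceps bumps
#' centred near peak flexion where the extensors stabilise the joint.
#' Timings scale with the motion duration.
#'
#' @param duration_s Motion duration (s); default 2.
#' @return Named list of profiles, each `list(peak, t_peak, width)` with
#'   `t_peak` and `width` in seconds.
#' @seealso [synthetic_activations()]
#' @export
default_activation_profiles <- function(duration_s = 2) {
  s <- duration_s / 2
  list(
    biceps_long     = list(peak = 0.55, t_peak = 0.60 * s, width = 0.35 * s),
    biceps_short    = list(peak = 0.40, t_peak = 0.65 * s, width = 0.35 * s),
    brachialis      = list(peak = 0.45, t_peak = 0.70 * s, width = 0.35 * s),
    triceps_long    = list(peak = 0.15, t_peak = 1.00 * s, width = 0.25 * s),
    triceps_lateral = list(peak = 0.08, t_peak = 1.00 * s, width = 0.30 * s),
    triceps_medial  = list(peak = 0.08, t_peak = 1.00 * s, width = 0.30 * s))
}

#' Generate synthetic activation traces
#'
#' Builds smooth per-muscle activation series over a trajectory's time base
#' from Gaussian-bump profiles,
#' \deqn{a(t) = floor + (peak - floor)\, e^{-(t - t_{peak})^2 / (2 w^2)},}
#' optionally adding seeded Gaussian noise, then clipping to
#' \[`floor`, 1\]. This emulates the qualitative shape of muscle-driven
#' tracking (CMC) exports so the full pipeline can run without an external
#' simulator; it does not reproduce any particular tracker's output.
#'
#' @param trajectory A [joint_trajectory()] supplying the time base.
#' @param profiles Named list of `list(peak, t_peak, width)` profiles, one
#'   per muscle; default [default_activation_profiles()] scaled to the
#'   trajectory duration.
#' @param floor Activation floor in \[0, 1); default 0.02.
#' @param noise_sd Standard deviation of additive Gaussian noise; default 0.
#' @param seed Optional integer seed making the noise reproducible.
#' @return An [activation_set()] aligned to `trajectory`.
#' @examples
#' act <- synthetic_activations(planned_trajectory(), seed = 1)
#' range(act$biceps_long)
#' @export
synthetic_activations <- function(trajectory, profiles = NULL, floor = 0.02,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(inherits(trajectory, "joint_trajectory"))
  check_scalar(floor, "floor", lower = -1e-300)
  if (floor < 0 || floor >= 1) {
    stop("`floor` must lie in [0, 1)", call. = FALSE)
  }
  check_scalar(noise_sd, "noise_sd", lower = -1e-300)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(profiles)) {
    dur <- max(trajectory$time) - min(trajectory$time)
    profiles <- default_activation_profiles(dur)
  }
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("`profiles` must be a named list (one entry per muscle)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t <- trajectory$time
  cols <- lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    if (is.null(p$peak) || is.null(p$t_peak) || is.null(p$width)) {
      stop("profile '", nm, "' needs `peak`, `t_peak` and `width`",
           call. = FALSE)
    }
    if (p$width <= 0) {
      stop("profile '", nm, "': `width` must be > 0", call. = FALSE)
    }
    if (p$peak < floor || p$peak > 1) {
      stop("profile '", nm, "': need floor <= peak <= 1", call. = FALSE)
    }
    a <- floor + (p$peak - floor) * exp(-(t - p$t_peak)^2 / (2 * p$width^2))
    if (noise_sd > 0) a <- a + stats::rnorm(length(t), sd = noise_sd)
    pmin(pmax(a, floor), 1)
  })
  names(cols) <- names(profiles)
  activation_set(t, as.data.frame(cols), floor = floor)
}

#' Lump per-head activations for the two-muscle baseline
#'
#' The baseline model drives one lumped biceps and one lumped triceps line.
#' This helper collapses a six-muscle activation set into those two
#' columns by maximum-isometric-force-weighted averaging of the flexor
#' heads (brachialis included) and of the extensor heads.
#'
#' @param activations An [activation_set()] with the six-muscle columns.
#' @param muscles The six-muscle parameter list supplying weights and
#'   groups; default [arm_muscles()].
#' @return An [activation_set()] with columns `biceps` and `triceps`.
#' @export
baseline_activations <- function(activations, muscles = arm_muscles()) {
  stopifnot(inherits(activations, "activation_set"))
  missing <- setdiff(names(muscles), names(activations))
  if (length(missing)) {
    stop("activation set lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wmean <- function(group) {
    ms <- Filter(function(m) m$group == group, muscles)
    w <- vapply(ms, `[[`, numeric(1), "F_0")
    cols <- sapply(ms, function(m) activations[[m$name]])
    as.numeric(cols %*% (w / sum(w)))
  }
  activation_set(activations$time,
                 data.frame(biceps = wmean("flexor"),
                            triceps = wmean("extensor")),
                 floor = attr(activations, "floor") %||% 0.02)
}
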