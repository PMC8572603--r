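#' Rotate an insertion point with the forearm
#'
#' Rotates a point fixed on the forearm about the elbow flexion axis (+y)
#' by the flexion angle. In the elbow-centred frame (x anterior, y medial,
#' z superior; forearm along -z at full extension) the rotation is
#' \deqn{R(\theta) = \begin{pmatrix} \cos\theta & 0 & -\sin\theta \\
#'   0 & 1 & 0 \\ \sin\theta & 0 & \cos\theta \end{pmatrix}.}
#'
#' @param point_ext Numeric length-3 point (m) at full extension.
#' @param theta_deg Flexion angle(s) in degrees, vectorised.
#' @return For a single angle, a length-3 numeric vector; for `n` angles an
#'   `n x 3` matrix with one rotated point per row.
#' @examples
#' rotate_insertion(c(0.007, 0, -0.047), 90)
#' @export
rotate_insertion <- function(point_ext, theta_deg) {
  point_ext <- as.numeric(point_ext)
  if (length(point_ext) != 3L || any(!is.finite(point_ext))) {
    stop("`point_ext` must be a finite length-3 vector", call. = FALSE)
  }
  if (!is.numeric(theta_deg) || any(!is.finite(theta_deg))) {
    stop("`theta_deg` must be finite numeric", call. = FALSE)
  }
  th <- theta_deg * pi / 180
  out <- cbind(cos(th) * point_ext[1] - sin(th) * point_ext[3],
               rep_len(point_ext[2], length(th)),
               sin(th) * point_ext[1] + cos(th) * point_ext[3])
  colnames(out) <- c("x", "y", "z")
  if (length(th) == 1L) as.numeric(out) else out
}

#' Musculotendon length of a straight-line (flexor) path
#'
#' Euclidean distance from the origin point to the (rotated) insertion
#' point, plus the fixed path length `l_0` lying outside the triangular
#' relation (e.g. the shoulder-crossing segment of a biarticular head).
#'
#' @param origin Length-3 origin point (m).
#' @param insertion_rotated Length-3 insertion point, or an `n x 3` matrix
#'   of insertion points (one per sample), already rotated to the current
#'   flexion angle(s).
#' @param l_0 Extra path length (m), default 0.
#' @return Musculotendon length(s) in metres.
#' @export
flexor_mt_length <- function(origin, insertion_rotated, l_0 = 0) {
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must be length 3", call. = FALSE)
  check_scalar(l_0, "l_0")
  p <- if (is.matrix(insertion_rotated)) insertion_rotated
       else matrix(as.numeric(insertion_rotated), nrow = 1L)
  if (ncol(p) != 3L) {
    stop("`insertion_rotated` must have 3 coordinates", call. = FALSE)
  }
  d <- sqrt((p[, 1] - origin[1])^2 + (p[, 2] - origin[2])^2 +
            (p[, 3] - origin[3])^2)
  if (any(d == 0)) {
    stop("degenerate geometry: origin and insertion coincide", call. = FALSE)
  }
  d + l_0
}

#' Split a musculotendon length into fiber and tendon lengths
#'
#' Tendon length change over the elbow's range of motion is small; it is
#' held at a fixed multiple (default 1.02) of the resting tendon length, so
#' the fiber length is \eqn{l_m = l_{mt} - 1.02\, l_t^{opt}}.
#'
#' @param l_mt Musculotendon length(s), m.
#' @param l_topt Resting tendon length, m.
#' @param tendon_scale Tendon length multiple; default 1.02.
#' @param muscle Optional muscle name for error messages.
#' @param theta_deg Optional flexion angle(s) aligned with `l_mt`, used in
#'   error messages.
#' @return List with `l_m` (fiber length vector, m) and `l_t` (tendon
#'   length, m).
#' @export
fiber_length <- function(l_mt, l_topt, tendon_scale = 1.02,
                         muscle = NULL, theta_deg = NULL) {
  if (l_topt < 0) stop("`l_topt` must be >= 0", call. = FALSE)
  check_scalar(tendon_scale, "tendon_scale")
  l_t <- tendon_scale * l_topt
  l_m <- l_mt - l_t
  if (any(l_m <= 0)) {
    who <- if (is.null(muscle)) "muscle" else paste0("muscle '", muscle, "'")
    bad <- which(l_m <= 0)[1]
    at <- if (is.null(theta_deg)) "" else
      sprintf(" at theta = %g deg", rep_len(theta_deg, length(l_m))[bad])
    stop("infeasible posture for ", who, at, ": musculotendon length ",
         format(l_mt[bad]), " m does not exceed the tendon length ",
         format(l_t), " m", call. = FALSE)
  }
  list(l_m = l_m, l_t = l_t)
}

#' Moment arm of a straight-line (flexor) path
#'
#' Perpendicular distance, in the sagittal xOz plane, from the elbow
#' rotation centre (the origin O) to the muscle's line of action through
#' the origin point A and the rotated insertion point C. Computed from the
#' slope-intercept form \eqn{r = |b| / \sqrt{k^2 + 1}} with
#' \eqn{k = (z_C - z_A)/(x_C - x_A)}, \eqn{b = -k x_A + z_A}; a vertical
#' line of action (equal x coordinates) falls back to \eqn{r = |x_A|}.
#'
#' @inheritParams flexor_mt_length
#' @return Moment arm(s) in metres (>= 0).
#' @export
flexor_moment_arm <- function(origin, insertion_rotated) {
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must be length 3", call. = FALSE)
  p <- if (is.matrix(insertion_rotated)) insertion_rotated
       else matrix(as.numeric(insertion_rotated), nrow = 1L)
  dx <- p[, 1] - origin[1]
  dz <- p[, 3] - origin[3]
  if (any(dx == 0 & dz == 0)) {
    stop("degenerate geometry: origin and insertion coincide in the ",
         "sagittal plane", call. = FALSE)
  }
  k <- dz / dx
  r <- abs(-k * origin[1] + origin[3]) / sqrt(k^2 + 1)
  vertical <- abs(dx) < 1e-12
  r[vertical] <- abs(origin[1])
  r
}

#' Moment arm of the trochlea-wrapped extensor path
#'
#' The triceps insertions converge on the olecranon tendon, which wraps the
#' humeral trochlea, so all three heads share one moment arm. It shrinks
#' slightly and linearly with flexion:
#' \eqn{r(\theta) = r_0 - k_s\, \theta / 90}.
#'
#' @param theta_deg Flexion angle(s), degrees.
#' @param r_0 Moment arm at full extension (m, > 0).
#' @param k_s Arm shape parameter (m per 90 degrees); default 0.004.
#' @return Moment arm(s) in metres.
#' @export
extensor_moment_arm <- function(theta_deg, r_0, k_s = 0.004) {
  check_scalar(r_0, "r_0", lower = 0)
  check_scalar(k_s, "k_s")
  if (!is.numeric(theta_deg) || any(!is.finite(theta_deg))) {
    stop("`theta_deg` must be finite numeric", call. = FALSE)
  }
  r <- r_0 - k_s * theta_deg / 90
  if (any(r <= 0)) {
    stop("extensor moment arm becomes nonpositive (r_0 = ", format(r_0),
         ", k_s = ", format(k_s), "); check the parameters", call. = FALSE)
  }
  r
}

#' Musculotendon length of the trochlea-wrapped extensor path
#'
#' As the ulna rotates about the trochlea the olecranon insertion travels
#' an arc, so the extensor path lengthens by the arc length swept at the
#' current moment arm: \eqn{l_{mt} = l_{base} + \theta_{rad}\, r}. Setting
#' `literal = TRUE` uses the degree-based variant \eqn{l_{base} + \theta
#' r / 180} instead (no pi), kept for auditability against sources that
#' print it that way.
#'
#' @param theta_deg Flexion angle(s), degrees (>= 0).
#' @param r Moment arm(s) (m), typically from [extensor_moment_arm()].
#' @param base_length Path length at full extension (m).
#' @param literal Use the degree-based arc term without pi; default FALSE.
#' @return Musculotendon length(s) in metres.
#' @export
extensor_mt_length <- function(theta_deg, r, base_length, literal = FALSE) {
  check_scalar(base_length, "base_length", lower = 0)
  if (any(theta_deg < 0)) stop("`theta_deg` must be >= 0", call. = FALSE)
  arc <- if (literal) theta_deg * r / 180 else theta_deg * pi / 180 * r
  base_length + arc
}

#' Normalised fiber velocity from a fiber-length series
#'
#' Differentiates a uniformly sampled fiber-length series (central
#' differences in the interior, one-sided at the ends) and normalises by
#' the maximum contraction speed `v_max_factor * l_mopt`, giving the
#' dimensionless `v_n` used by [force_velocity_factor()] (shortening
#' negative).
#'
#' @param l_m Fiber length series (m), >= 3 samples.
#' @param t Time samples (s), uniform step.
#' @param l_mopt Optimal fiber length (m).
#' @param v_max_factor Maximum contraction speed in optimal fiber lengths
#'   per second; default 8.
#' @return Normalised velocity series, same length as `l_m`.
#' @export
fiber_velocity <- function(l_m, t, l_mopt, v_max_factor = 8) {
  n <- length(l_m)
  if (n < 3L || length(t) != n) {
    stop("need >= 3 samples with `t` the same length as `l_m`",
         call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("`t` must be strictly increasing with a uniform step",
         call. = FALSE)
  }
  check_scalar(l_mopt, "l_mopt", lower = 0)
  check_scalar(v_max_factor, "v_max_factor", lower = 0)
  h <- mean(dt)
  dl <- numeric(n)
  dl[1] <- (l_m[2] - l_m[1]) / h
  dl[n] <- (l_m[n] - l_m[n - 1]) / h
  if (n > 2L) dl[2:(n - 1)] <- (l_m[3:n] - l_m[1:(n - 2)]) / (2 * h)
  dl / (v_max_factor * l_mopt)
}
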