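#' EMG excitation to muscle activation
#'
#' Maps a normalised sEMG excitation \eqn{u \in [0,1]} to muscle activation
#' through the exponential nonlinearity
#' \deqn{a = \frac{e^{A u} - 1}{e^{A} - 1},}
#' where negative shape values of `A_nl` give the concave activation curves
#' observed physiologically. The map is monotone with a(0) = 0 and a(1) = 1.
#'
#' @param u Numeric vector of normalised excitations in \[0, 1\].
#' @param A_nl Nonlinearity shape (nonzero scalar); default -1.
#' @return Activation vector in \[0, 1\], same length as `u`.
#' @examples
#' emg_to_activation(c(0, 0.5, 1))
#' @export
emg_to_activation <- function(u, A_nl = -1) {
  check_scalar(A_nl, "A_nl")
  if (A_nl == 0) {
    stop("`A_nl` must be nonzero; its -> 0 limit is the linear map a = u",
         call. = FALSE)
  }
  if (!is.numeric(u) || any(!is.finite(u))) {
    stop("`u` must be finite numeric", call. = FALSE)
  }
  if (any(u < 0 | u > 1)) {
    stop("`u` must lie in [0, 1]; got values in [",
         format(min(u)), ", ", format(max(u)), "]", call. = FALSE)
  }
  (exp(A_nl * u) - 1) / (exp(A_nl) - 1)
}

#' Active force--length factor
#'
#' Gaussian-shaped active force--length relation
#' \eqn{f_l = \exp(-(l_m/l_m^{opt} - 1)^2 / \gamma)}: unity at the optimal
#' fiber length, falling off symmetrically with fractional deviation.
#'
#' @param l_m Current fiber length (m), vectorised.
#' @param l_mopt Optimal fiber length (m).
#' @param gamma Shape coefficient (> 0); default 0.5.
#' @return `f_l` in (0, 1\].
#' @export
force_length_factor <- function(l_m, l_mopt, gamma = 0.5) {
  check_scalar(l_mopt, "l_mopt", lower = 0)
  check_scalar(gamma, "gamma", lower = 0)
  if (!is.numeric(l_m) || any(!is.finite(l_m)) || any(l_m <= 0)) {
    stop("`l_m` must be positive and finite", call. = FALSE)
  }
  exp(-(l_m / l_mopt - 1)^2 / gamma)
}

#' Force--velocity factor
#'
#' Hill-type force--velocity relation on the normalised fiber velocity
#' `v_n` (shortening negative, in units of maximum contraction speed):
#' \deqn{f_v = \frac{1 + v_n}{1 - v_n / A_s} \quad (v_n \le 0), \qquad
#'       f_v = \frac{f_M v_n + A_s (f_M - 1)/2 + 2 A_s}
#'                  {v_n + A_s (f_M - 1)/2 + 2 A_s} \quad (v_n > 0).}
#' Continuous at rest with \eqn{f_v(0) = 1}, zero at the maximum shortening
#' speed \eqn{v_n = -1}, saturating at `f_M` for fast lengthening.
#' Velocities below -1 (faster than the model's maximum shortening speed)
#' are clamped to zero force rather than extrapolated to negative values.
#'
#' @param v_n Normalised fiber velocity, vectorised.
#' @param A_s Curve parameter (> 0); default 0.25.
#' @param f_M Maximum normalised lengthening force (> 1); default 1.8.
#' @return `f_v` in \[0, f_M).
#' @export
force_velocity_factor <- function(v_n, A_s = 0.25, f_M = 1.8) {
  check_scalar(A_s, "A_s", lower = 0)
  check_scalar(f_M, "f_M", lower = 1)
  if (!is.numeric(v_n) || any(!is.finite(v_n))) {
    stop("`v_n` must be finite numeric", call. = FALSE)
  }
  shortening <- (1 + v_n) / (1 - v_n / A_s)
  c0 <- A_s * (f_M - 1) / 2 + 2 * A_s
  lengthening <- (f_M * v_n + c0) / (v_n + c0)
  out <- ifelse(v_n > 0, lengthening, shortening)
  out[v_n < -1] <- 0
  out
}

#' Passive force factor
#'
#' Exponential passive fiber tension, zero at or below the resting fiber
#' length and reaching 1 (the maximum isometric force) at a fiber strain of
#' `eps0_M`:
#' \deqn{f_{PE} = \frac{e^{k_{PE} (l_m/l_m^{opt} - 1)/\varepsilon_0^M} - 1}
#'                     {e^{k_{PE}} - 1} \quad (l_m > l_m^{opt}).}
#'
#' @param l_m Current fiber length (m), vectorised.
#' @param l_mopt Optimal fiber length (m).
#' @param k_PE Curve shape parameter; default 4.
#' @param eps0_M Maximum passive tension strain; default 0.5.
#' @return `f_PE` >= 0.
#' @export
passive_force_factor <- function(l_m, l_mopt, k_PE = 4, eps0_M = 0.5) {
  check_scalar(l_mopt, "l_mopt", lower = 0)
  check_scalar(k_PE, "k_PE", lower = 0)
  check_scalar(eps0_M, "eps0_M", lower = 0)
  if (!is.numeric(l_m) || any(!is.finite(l_m)) || any(l_m <= 0)) {
    stop("`l_m` must be positive and finite", call. = FALSE)
  }
  strain <- l_m / l_mopt - 1
  f <- (exp(k_PE * strain / eps0_M) - 1) / (exp(k_PE) - 1)
  f[strain <= 0] <- 0
  f
}

#' Pennation angle at a given fiber length
#'
#' Constant-thickness pennation model: the fiber's transverse component
#' \eqn{l_m \sin\varphi} is conserved, so
#' \eqn{\varphi = \arcsin(l_m^{opt} \sin\varphi_0 / l_m)}.
#'
#' @param l_m Current fiber length (m), vectorised.
#' @param l_mopt Optimal fiber length (m).
#' @param phi0 Pennation angle at the optimal fiber length (radians).
#' @param muscle Optional muscle name used in error messages.
#' @return Pennation angle in radians, in \[0, pi/2).
#' @export
pennation_angle <- function(l_m, l_mopt, phi0, muscle = NULL) {
  check_scalar(l_mopt, "l_mopt", lower = 0)
  check_scalar(phi0, "phi0")
  if (phi0 < 0 || phi0 >= pi / 2) {
    stop("`phi0` must lie in [0, pi/2) radians", call. = FALSE)
  }
  if (!is.numeric(l_m) || any(!is.finite(l_m)) || any(l_m <= 0)) {
    stop("`l_m` must be positive and finite", call. = FALSE)
  }
  arg <- l_mopt * sin(phi0) / l_m
  if (any(arg > 1)) {
    who <- if (is.null(muscle)) "muscle" else paste0("muscle '", muscle, "'")
    stop("infeasible fiber length for ", who, ": l_m = ",
         format(min(l_m[arg > 1])), " m is shorter than the transverse ",
         "thickness l_mopt*sin(phi0) = ", format(l_mopt * sin(phi0)), " m",
         call. = FALSE)
  }
  asin(arg)
}

#' Hill-type muscle force
#'
#' Assembles the full Hill-type fiber force from activation, fiber length
#' and normalised fiber velocity:
#' \deqn{F_M = (a f_l f_v + f_{PE})\, F_0 \cos\varphi,}
#' i.e. the active factor \eqn{f_{CE} = a f_l f_v} plus the passive factor
#' \eqn{f_{PE}}, scaled by the maximum isometric force and projected through
#' the pennation angle. Viscous damping is negligible at physiological
#' elbow speeds and is not modelled.
#'
#' @param a Activation in \[0, 1\], vectorised.
#' @param l_m Fiber length (m), vectorised.
#' @param v_n Normalised fiber velocity, vectorised.
#' @param params A [muscle_params()] object (uses `l_mopt`, `F_0`, `phi0`).
#' @param fp A [formula_params()] object.
#' @return List with `F_M` (force vector, N) and `state`, a data frame of
#'   the per-sample mechanical state (`l_m`, `v_n`, `phi`, `f_l`, `f_v`,
#'   `f_PE`, `f_CE`, `F_M`).
#' @examples
#' bl <- arm_muscles()$biceps_long
#' muscle_force(1, bl$l_mopt, 0, bl)$F_M  # = F_0 at rest, full drive
#' @export
muscle_force <- function(a, l_m, v_n, params, fp = formula_params()) {
  stopifnot(inherits(params, "muscle_params"), inherits(fp, "formula_params"))
  n <- max(length(a), length(l_m), length(v_n))
  a <- rep_len(a, n); l_m <- rep_len(l_m, n); v_n <- rep_len(v_n, n)
  if (any(!is.finite(a)) || any(a < 0 | a > 1)) {
    stop("`a` must lie in [0, 1]", call. = FALSE)
  }
  f_l <- force_length_factor(l_m, params$l_mopt, fp$gamma)
  f_v <- force_velocity_factor(v_n, fp$A_s, fp$f_M)
  f_PE <- passive_force_factor(l_m, params$l_mopt, fp$k_PE, fp$eps0_M)
  phi <- pennation_angle(l_m, params$l_mopt, params$phi0, params$name)
  f_CE <- a * f_l * f_v
  F_M <- (f_CE + f_PE) * params$F_0 * cos(phi)
  list(F_M = F_M,
       state = data.frame(l_m = l_m, v_n = v_n, phi = phi, f_l = f_l,
                          f_v = f_v, f_PE = f_PE, f_CE = f_CE, F_M = F_M))
}
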