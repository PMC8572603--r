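#' Simulate elbow muscle torques along a trajectory
#'
#' Runs the full planar neuromusculoskeletal pipeline for every muscle in
#' the model: path geometry (straight-line flexor triangles or trochlea-arc
#' extensor path) gives the musculotendon length and moment arm at each
#' flexion angle; the fixed tendon scaling gives the fiber length; the
#' fiber-length series is differentiated into a normalised velocity; the
#' Hill model turns activation, length and velocity into force; and each
#' muscle's torque \eqn{\tau_i = \pm r_i F_M^i} (flexors positive,
#' extensors negative) is summed into the resultant elbow torque
#' \eqn{\tau_{sum}(t) = \sum_i r_i(\theta) F_M^i(\theta, t)} with the sign
#' convention applied.
#'
#' @param trajectory A [joint_trajectory()].
#' @param activations An [activation_set()] on the same time base, with one
#'   column per model muscle.
#' @param muscles Named list of [muscle_params()]; default [arm_muscles()].
#' @param fp Shared [formula_params()].
#' @param extensor_baseline Path length of a trochlea-arc extensor at full
#'   extension: `"musculotendon"` (default) uses `l_mopt + tendon_scale *
#'   l_topt`, placing the fiber exactly at its resting length at 0 degrees;
#'   `"fiber"` uses `l_mopt` alone (a variant kept for auditability; with
#'   typical triceps parameters it yields infeasibly short fibers).
#' @param literal_extensor_arc Passed to [extensor_mt_length()]; default
#'   FALSE (dimensionally consistent radian arc).
#' @return An object of class `torque_result`: a list with `time`,
#'   `samples` (long data frame: `time, muscle, l_mt, l_m, v_n, phi, f_l,
#'   f_v, f_PE, F_M, r, tau`), `tau` (wide matrix of per-muscle torques,
#'   N m) and `resultant` (data frame `time, tau_sum`).
#' @examples
#' tr <- planned_trajectory()
#' act <- synthetic_activations(tr)
#' res <- simulate_elbow_torque(tr, act)
#' max(res$resultant$tau_sum)
#' @export
simulate_elbow_torque <- function(trajectory, activations,
                                  muscles = arm_muscles(),
                                  fp = formula_params(),
                                  extensor_baseline = c("musculotendon",
                                                        "fiber"),
                                  literal_extensor_arc = FALSE) {
  stopifnot(inherits(trajectory, "joint_trajectory"),
            inherits(activations, "activation_set"),
            inherits(fp, "formula_params"))
  extensor_baseline <- match.arg(extensor_baseline)
  t <- trajectory$time
  if (nrow(activations) != length(t) ||
      max(abs(activations$time - t)) > 1e-9) {
    stop("trajectory and activations are on different time bases",
         call. = FALSE)
  }
  missing <- setdiff(names(muscles), names(activations))
  if (length(missing)) {
    stop("no activation column for muscle(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  theta <- trajectory$theta
  per <- lapply(muscles, function(m) {
    if (m$path == "line") {
      ins <- rotate_insertion(m$insertion, theta)
      if (!is.matrix(ins)) ins <- matrix(ins, nrow = 1L)
      l_mt <- flexor_mt_length(m$origin, ins, m$l_0)
      r <- flexor_moment_arm(m$origin, ins)
    } else {
      r <- extensor_moment_arm(theta, m$r_0, fp$k_s)
      base <- switch(extensor_baseline,
                     musculotendon = m$l_mopt + fp$tendon_scale * m$l_topt,
                     fiber = m$l_mopt)
      l_mt <- extensor_mt_length(theta, r, base,
                                 literal = literal_extensor_arc)
    }
    fl <- fiber_length(l_mt, m$l_topt, fp$tendon_scale,
                       muscle = m$name, theta_deg = theta)
    v_n <- fiber_velocity(fl$l_m, t, m$l_mopt, fp$v_max_factor)
    force <- muscle_force(activations[[m$name]], fl$l_m, v_n, m, fp)
    sgn <- if (m$group == "flexor") 1 else -1
    cbind(data.frame(time = t, muscle = m$name, l_mt = l_mt),
          force$state[c("l_m", "v_n", "phi", "f_l", "f_v", "f_PE", "F_M")],
          data.frame(r = r, tau = sgn * r * force$F_M))
  })
  samples <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  tau <- vapply(per, function(d) d$tau, numeric(length(t)))
  if (!is.matrix(tau)) tau <- matrix(tau, nrow = length(t),
                                     dimnames = list(NULL, names(per)))
  structure(
    list(time = t, samples = samples, tau = tau,
         resultant = data.frame(time = t, tau_sum = rowSums(tau))),
    class = "torque_result")
}

#' Simulate the classic two-muscle baseline model
#'
#' Runs the same pipeline as [simulate_elbow_torque()] on the traditional
#' double-muscle elbow model, in which both the lumped biceps and the
#' lumped triceps act along straight tension lines (triangular geometry).
#' The straight triceps line is the baseline's known departure from the
#' olecranon-trochlea anatomy and is what the improved six-muscle model
#' corrects.
#'
#' @param trajectory A [joint_trajectory()].
#' @param activations An [activation_set()] with one column per baseline
#'   muscle (see [baseline_activations()] for lumping six-muscle traces).
#' @param muscles Two-muscle parameter list; default [baseline_muscles()].
#' @param fp Shared [formula_params()].
#' @return A `torque_result`, as for [simulate_elbow_torque()].
#' @export
simulate_double_muscle <- function(trajectory, activations,
                                   muscles = baseline_muscles(),
                                   fp = formula_params()) {
  if (length(muscles) != 2L) {
    stop("the baseline model has exactly two muscles", call. = FALSE)
  }
  if (any(vapply(muscles, `[[`, character(1), "path") != "line")) {
    stop("baseline muscles must all use straight-line paths", call. = FALSE)
  }
  simulate_elbow_torque(trajectory, activations, muscles, fp)
}

#' @export
print.torque_result <- function(x, ...) {
  n <- length(x$time)
  peak <- which.max(x$resultant$tau_sum)
  cat(sprintf("<torque_result> %d muscles, %d samples over %.3g s\n",
              ncol(x$tau), n, x$time[n] - x$time[1]))
  cat(sprintf("  peak resultant torque %.3f N m at t = %.3g s\n",
              x$resultant$tau_sum[peak], x$time[peak]))
  cat("  muscles:", paste(colnames(x$tau), collapse = ", "), "\n")
  invisible(x)
}
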