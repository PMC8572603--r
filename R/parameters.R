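#' Shared Hill-curve and geometry constants
#'
#' Container for the formula parameters shared by every muscle in the model:
#' the shape constants of the active force--length, force--velocity and
#' passive-force curves, the velocity normalisation, the extensor moment-arm
#' slope, the EMG-to-activation nonlinearity and the tendon length scale.
#' Defaults are the standard adult-arm values used throughout the package.
#'
#' @param gamma Shape coefficient of the active force--length curve
#'   (dimensionless, > 0). Default 0.5.
#' @param A_s Force--velocity curve parameter (dimensionless, > 0).
#'   Default 0.25.
#' @param f_M Maximum normalised force during fiber lengthening
#'   (dimensionless, > 1). Default 1.8.
#' @param v_max_factor Maximum contraction speed, in optimal fiber lengths
#'   per second (1/s, > 0). Default 8, i.e. \eqn{v_{max} = 8\,l_m^{opt}}.
#' @param k_PE Passive force curve shape parameter (dimensionless, > 0).
#'   Default 4.
#' @param eps0_M Maximum passive muscle tension strain (dimensionless, > 0).
#'   Default 0.5: passive force reaches the maximum isometric force at a
#'   fiber strain of 50 percent.
#' @param k_s Extensor moment-arm shape parameter (m per 90 degrees of
#'   flexion). Default 0.004.
#' @param A_nl EMG-to-activation nonlinearity (dimensionless, nonzero;
#'   negative values give the physiological concave shape). Default -1.
#' @param tendon_scale Real-time tendon length as a multiple of the resting
#'   tendon length (dimensionless, >= 1). Default 1.02.
#'
#' @return An object of class `formula_params` (a named list).
#' @seealso [muscle_params()], [arm_muscles()]
#' @examples
#' fp <- formula_params()
#' fp$gamma
#' @export
formula_params <- function(gamma = 0.5, A_s = 0.25, f_M = 1.8,
                           v_max_factor = 8, k_PE = 4, eps0_M = 0.5,
                           k_s = 0.004, A_nl = -1, tendon_scale = 1.02) {
  check_scalar(gamma, "gamma", lower = 0)
  check_scalar(A_s, "A_s", lower = 0)
  check_scalar(f_M, "f_M", lower = 1)
  check_scalar(v_max_factor, "v_max_factor", lower = 0)
  check_scalar(k_PE, "k_PE", lower = 0)
  check_scalar(eps0_M, "eps0_M", lower = 0)
  check_scalar(k_s, "k_s")
  check_scalar(A_nl, "A_nl")
  check_scalar(tendon_scale, "tendon_scale")
  if (A_nl == 0) {
    stop("`A_nl` must be nonzero; the A_nl -> 0 limit is the linear map ",
         "a = u, which you can get with a small value such as A_nl = -1e-8",
         call. = FALSE)
  }
  if (tendon_scale < 1) {
    stop("`tendon_scale` must be >= 1 (the tendon does not shorten below ",
         "its resting length)", call. = FALSE)
  }
  structure(
    list(gamma = gamma, A_s = A_s, f_M = f_M, v_max_factor = v_max_factor,
         k_PE = k_PE, eps0_M = eps0_M, k_s = k_s, A_nl = A_nl,
         tendon_scale = tendon_scale),
    class = "formula_params")
}

#' @export
print.formula_params <- function(x, ...) {
  cat("Hill-model formula parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-13s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Per-muscle physiological parameters
#'
#' One muscle of the planar elbow model. Flexors follow a straight-line
#' (triangular) path from an origin fixed on the upper arm to an insertion
#' that rotates with the forearm; any path length outside that triangle
#' (e.g. the shoulder-crossing segment of a biarticular head) is carried in
#' `l_0`. Extensors insert on the olecranon and wrap the humeral trochlea,
#' so their path is described by the moment arm at full extension `r_0`
#' rather than by points.
#'
#' @param name Muscle identifier, e.g. `"biceps_long"`.
#' @param group `"flexor"` or `"extensor"`; fixes the torque sign
#'   (flexion positive).
#' @param l_mopt Optimal (resting) fiber length in metres.
#' @param l_topt Resting tendon length in metres.
#' @param F_0 Maximum isometric force in Newtons.
#' @param phi0_deg Pennation angle at the optimal fiber length, degrees.
#' @param origin Numeric length-3 origin point (m) in the elbow-centred
#'   frame (straight-line path muscles only).
#' @param insertion Numeric length-3 insertion point (m) at full extension
#'   (straight-line path muscles only).
#' @param l_0 Path length outside the triangular relation, metres
#'   (straight-line path muscles only; 0 for a purely mono-articular path).
#' @param r_0 Moment arm at full extension, metres (trochlea-arc extensors
#'   only).
#'
#' @details Exactly one path description must be given: either
#'   `origin` + `insertion` + `l_0` (straight line) or `r_0` (trochlea arc).
#'   The elbow-centred frame is right-handed with x anterior, y medial and
#'   z superior; the forearm points along -z at 0 degrees of flexion.
#'
#' @return An object of class `muscle_params`.
#' @seealso [arm_muscles()], [baseline_muscles()], [formula_params()]
#' @export
muscle_params <- function(name, group = c("flexor", "extensor"),
                          l_mopt, l_topt, F_0, phi0_deg = 0,
                          origin = NULL, insertion = NULL, l_0 = NULL,
                          r_0 = NULL) {
  group <- match.arg(group)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a nonempty string", call. = FALSE)
  }
  check_scalar(l_mopt, "l_mopt", lower = 0)
  check_scalar(l_topt, "l_topt", lower = -1e-300) # zero tendon allowed
  if (l_topt < 0) stop("`l_topt` must be >= 0", call. = FALSE)
  check_scalar(F_0, "F_0", lower = 0)
  check_scalar(phi0_deg, "phi0_deg")
  if (phi0_deg < 0 || phi0_deg >= 90) {
    stop("`phi0_deg` must lie in [0, 90)", call. = FALSE)
  }
  has_line <- !is.null(origin) || !is.null(insertion) || !is.null(l_0)
  has_arc <- !is.null(r_0)
  if (has_line == has_arc) {
    stop("muscle '", name, "': give exactly one path description, either ",
         "origin + insertion (+ l_0) for a straight-line path or r_0 for ",
         "a trochlea-arc path", call. = FALSE)
  }
  if (has_line) {
    if (is.null(origin) || is.null(insertion)) {
      stop("muscle '", name, "': a straight-line path needs both `origin` ",
           "and `insertion`", call. = FALSE)
    }
    if (is.null(l_0)) l_0 <- 0
    origin <- as.numeric(origin)
    insertion <- as.numeric(insertion)
    if (length(origin) != 3L || length(insertion) != 3L ||
        any(!is.finite(origin)) || any(!is.finite(insertion))) {
      stop("muscle '", name, "': `origin` and `insertion` must be finite ",
           "length-3 numeric vectors", call. = FALSE)
    }
    check_scalar(l_0, "l_0")
    if (l_0 < 0) stop("`l_0` must be >= 0", call. = FALSE)
  } else {
    check_scalar(r_0, "r_0", lower = 0)
  }
  structure(
    list(name = name, group = group, path = if (has_line) "line" else "arc",
         l_mopt = l_mopt, l_topt = l_topt, F_0 = F_0,
         phi0 = phi0_deg * pi / 180,
         origin = origin, insertion = insertion, l_0 = l_0, r_0 = r_0),
    class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf("<muscle_params> %s (%s, %s path)\n", x$name, x$group, x$path))
  cat(sprintf("  l_mopt %.4g m, l_topt %.4g m, F_0 %.5g N, phi0 %.3g deg\n",
              x$l_mopt, x$l_topt, x$F_0, x$phi0 * 180 / pi))
  if (x$path == "line") {
    cat(sprintf("  origin (%s) m, insertion (%s) m, l_0 %.4g m\n",
                paste(format(x$origin), collapse = ", "),
                paste(format(x$insertion), collapse = ", "), x$l_0))
  } else {
    cat(sprintf("  r_0 %.4g m (moment arm at full extension)\n", x$r_0))
  }
  invisible(x)
}

#' Default six-muscle elbow parameter set
#'
#' Physiological parameters of the improved planar elbow model: long and
#' short heads of biceps brachii, brachialis (straight-line flexor paths),
#' and the long, lateral and medial heads of triceps brachii (shared
#' trochlea-arc extensor path). Fiber/tendon lengths, maximum isometric
#' forces, pennation angles and flexor path points are standard adult-arm
#' anatomical values; coordinates are in the elbow-centred frame (m).
#'
#' @param r0_extensor Extensor moment arm at full extension (m), shared by
#'   the three triceps heads, whose insertions converge on the olecranon
#'   tendon. This arm is not part of the anatomical tables the rest of the
#'   set comes from; the default 0.022 m is a representative adult value
#'   chosen for the demo fixture.
#' @param length_scale Uniform length scale for other subjects (scales all
#'   fiber/tendon lengths, path coordinates, `l_0` and `r_0`; maximum
#'   forces are left unscaled and should be measured per subject).
#'
#' @return Named list of [muscle_params()] objects.
#' @examples
#' ms <- arm_muscles()
#' names(ms)
#' @export
arm_muscles <- function(r0_extensor = 0.022, length_scale = 1) {
  bic_origin <- c(0.023, 0, 0.115)
  bic_insert <- c(0.007, 0, -0.047)
  ms <- list(
    muscle_params("biceps_long", "flexor", 0.116, 0.272, 624.3, 0,
                  origin = bic_origin, insertion = bic_insert, l_0 = 0.263),
    muscle_params("biceps_short", "flexor", 0.132, 0.192, 435.6, 0,
                  origin = bic_origin, insertion = bic_insert, l_0 = 0.178),
    muscle_params("brachialis", "flexor", 0.086, 0.054, 987.3, 0,
                  origin = c(0.008, 0, 0.115),
                  insertion = c(0.007, 0, -0.023), l_0 = 0.010),
    muscle_params("triceps_long", "extensor", 0.134, 0.143, 798.5, 12,
                  r_0 = r0_extensor),
    muscle_params("triceps_lateral", "extensor", 0.114, 0.091, 624.3, 9,
                  r_0 = r0_extensor),
    muscle_params("triceps_medial", "extensor", 0.114, 0.098, 624.3, 9,
                  r_0 = r0_extensor))
  names(ms) <- vapply(ms, `[[`, character(1), "name")
  if (length_scale != 1) ms <- scale_muscles(ms, length_scale)
  ms
}

#' Classic two-muscle baseline parameter set
#'
#' The traditional planar elbow model with a single lumped biceps tension
#' line and a single lumped triceps tension line, both on straight-line
#' (triangular) paths -- including the triceps, whose straight path is the
#' baseline model's known deviation from the olecranon-trochlea anatomy.
#' The lumped parameters are a synthetic fixture: biceps sums the two
#' biceps-head forces and uses the long-head path and lengths; triceps sums
#' the three triceps-head forces on a posterior straight line to the
#' olecranon, with `l_0` chosen so the lumped fiber is at its resting
#' length at full extension.
#'
#' @param length_scale Uniform length scale, as in [arm_muscles()].
#' @return Named list of two [muscle_params()] objects (`biceps`,
#'   `triceps`).
#' @seealso [simulate_double_muscle()]
#' @export
baseline_muscles <- function(length_scale = 1) {
  ms <- list(
    muscle_params("biceps", "flexor", 0.116, 0.272, 624.3 + 435.6, 0,
                  origin = c(0.023, 0, 0.115),
                  insertion = c(0.007, 0, -0.047), l_0 = 0.263),
    muscle_params("triceps", "extensor", 0.134, 0.143,
                  798.5 + 624.3 + 624.3, 12,
                  origin = c(-0.020, 0, 0.115),
                  insertion = c(-0.022, 0, 0.010), l_0 = 0.175))
  names(ms) <- vapply(ms, `[[`, character(1), "name")
  if (length_scale != 1) ms <- scale_muscles(ms, length_scale)
  ms
}

#' Scale a muscle set for a different subject height
#'
#' Applies one uniform length scale to every stored length: optimal fiber
#' length, resting tendon length, path coordinates, extra-triangle length
#' `l_0` and extensor arm `r_0`. Maximum isometric forces are not scaled.
#'
#' @param muscles List of [muscle_params()] objects.
#' @param factor Positive scale factor (1 = reference subject).
#' @return The scaled muscle list.
#' @export
scale_muscles <- function(muscles, factor) {
  check_scalar(factor, "factor", lower = 0)
  lapply(muscles, function(m) {
    m$l_mopt <- m$l_mopt * factor
    m$l_topt <- m$l_topt * factor
    if (m$path == "line") {
      m$origin <- m$origin * factor
      m$insertion <- m$insertion * factor
      m$l_0 <- m$l_0 * factor
    } else {
      m$r_0 <- m$r_0 * factor
    }
    m
  })
}

#' Read a model configuration file
#'
#' Reads a YAML (or JSON) configuration with a `formula:` block of shared
#' constants and a `muscles:` list of per-muscle entries, mirroring the
#' arguments of [formula_params()] and [muscle_params()]. The packaged
#' examples are `system.file("extdata", "arm_default.yaml", package =
#' "elbownms")` and `baseline_double_synthetic.yaml`.
#'
#' @param path Path to the configuration file.
#' @return List with elements `formula` ([formula_params()]) and `muscles`
#'   (named list of [muscle_params()]), plus `options` (any
#'   `options:` block, e.g. `extensor_baseline`, `literal_extensor_arc`).
#' @export
read_muscle_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  fp <- do.call(formula_params, as.list(cfg$formula %||% list()))
  if (is.null(cfg$muscles) || !length(cfg$muscles)) {
    stop("config has no `muscles:` block", call. = FALSE)
  }
  ms <- lapply(cfg$muscles, function(m) {
    do.call(muscle_params, m[!vapply(m, is.null, logical(1))])
  })
  names(ms) <- vapply(ms, `[[`, character(1), "name")
  list(formula = fp, muscles = ms, options = cfg$options %||% list())
}

# internal helpers ----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar <- function(x, nm, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (x <= lower) {
    stop("`", nm, "` must be > ", lower, call. = FALSE)
  }
  invisible(x)
}
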