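# Constant-curvature catheter pivoting at a fossa ovalis point.
#
# The inserted segment is a circular arc launched tangent to the pivot axis
# (the inward FO normal).  Controls u = (phi, theta, s): bending-plane angle,
# total bend angle theta = kappa * ell, and dimensionless insertion
# s = ell / ell_max.  Angles in radians, insertion scaled so all three
# Jacobian columns carry mm per unit control, which a singular-value ratio
# requires to be meaningful.

#' Kinematic limits of the catheter
#'
#' Encodes the "simple configuration" constraint: no looping (bend at most
#' `theta_max`), bounded insertion, and a minimum bend radius
#' `1 / kappa_max`.
#'
#' @param theta_max maximum total bend angle (rad), in (0, pi]; default pi.
#' @param ell_min,ell_max insertion arc-length range (mm); default 5-100.
#' @param kappa_max maximum curvature (1/mm); default 0.1 (10 mm minimum bend
#'   radius, typical of a steerable ablation catheter).
#' @return Object of class `kinematic_limits`.
#' @export
kinematic_limits <- function(theta_max = pi, ell_min = 5, ell_max = 100,
                             kappa_max = 0.1) {
  if (!(theta_max > 0 && theta_max <= pi))
    fg_validation_error("theta_max must be in (0, pi]")
  if (!(ell_min > 0 && ell_min < ell_max))
    fg_validation_error("need 0 < ell_min < ell_max")
  if (!(kappa_max > 0)) fg_validation_error("kappa_max must be > 0")
  structure(list(theta_max = theta_max, ell_min = ell_min, ell_max = ell_max,
                 kappa_max = kappa_max),
            class = "kinematic_limits")
}

#' Pivot frame at a puncture site
#'
#' Local frame of the catheter at the transseptal crossing: origin at the FO
#' point, z-axis along the inward (right-to-left) FO normal, x-axis along an
#' in-plane reference from which the bending-plane angle `phi` is measured.
#'
#' @param origin FO point (mm).
#' @param axis unit insertion direction (inward FO normal).
#' @param ref optional unit in-plane reference orthogonal to `axis`; a
#'   deterministic default is derived from `axis` when omitted.
#' @return Object of class `pivot_frame` with `origin`, `axis`, `ref` and the
#'   3x3 rotation `basis` whose columns are (ref, axis x ref, axis).
#' @export
pivot_frame <- function(origin, axis, ref = NULL) {
  origin <- assert_point3(origin, "origin")
  axis <- unitize(assert_point3(axis, "axis"), "axis")
  ref <- if (is.null(ref)) orthonormal_ref(axis) else {
    r <- assert_point3(ref, "ref")
    if (abs(vnorm(r) - 1) > 1e-9 || abs(sum(r * axis)) > 1e-9)
      fg_validation_error("ref must be unit length and orthogonal to axis (1e-9)")
    r
  }
  structure(list(origin = origin, axis = axis, ref = ref,
                 basis = cbind(ref, cross3(axis, ref), axis, deparse.level = 0)),
            class = "pivot_frame")
}

#' Catheter configuration
#'
#' @param phi bending-plane angle (rad), in `[-pi, pi]`.
#' @param theta total bend angle kappa * ell (rad), >= 0.
#' @param ell insertion arc length (mm), > 0.
#' @return Object of class `catheter_config`.
#' @export
catheter_config <- function(phi, theta, ell) {
  if (!is.finite(phi) || !is.finite(theta) || !is.finite(ell))
    fg_validation_error("configuration components must be finite")
  if (theta < 0) fg_validation_error("theta must be >= 0")
  if (ell <= 0) fg_validation_error("ell must be > 0")
  structure(list(phi = phi, theta = theta, ell = ell), class = "catheter_config")
}

#' Is a configuration within the kinematic limits?
#' @param config a [catheter_config()].
#' @param limits a [kinematic_limits()].
#' @param kappa_tol slack on the curvature bound (1/mm); default 1e-9.
#' @return logical flag.
#' @export
config_within_limits <- function(config, limits, kappa_tol = 1e-9) {
  config$theta <= limits$theta_max &&
    config$ell >= limits$ell_min && config$ell <= limits$ell_max &&
    config$theta / config$ell <= limits$kappa_max + kappa_tol
}

# Arc shape functions a = (1 - cos t)/t, b = sin t / t and derivatives,
# vectorized; Taylor series below the switch point keeps them smooth and
# accurate through the straight-catheter limit t -> 0.
arc_coeffs <- function(theta, eps = 1e-6) {
  t <- theta
  small <- t < eps
  a <- ifelse(small, t / 2 - t^3 / 24, 2 * sin(t / 2)^2 / t)
  b <- ifelse(small, 1 - t^2 / 6 + t^4 / 120, sin(t) / t)
  da <- ifelse(small, 0.5 - t^2 / 8, (t * sin(t) - 2 * sin(t / 2)^2) / t^2)
  db <- ifelse(small, -t / 3 + t^3 / 30, (t * cos(t) - sin(t)) / t^2)
  list(a = a, b = b, da = da, db = db)
}

#' Forward kinematics: catheter tip position
#'
#' In frame coordinates (x along `ref` rotated by `phi`, z along `axis`) the
#' tip of a constant-curvature arc of bend `theta` and length `ell` sits at
#' `ell * ((1 - cos theta)/theta, 0, sin theta / theta)` in the bending
#' plane, with the continuous limit `(0, 0, ell)` as theta -> 0.
#'
#' @param frame a [pivot_frame()].
#' @param config a [catheter_config()].
#' @return 3D tip position in world coordinates (mm).
#' @export
forward_kinematics <- function(frame, config) {
  stopifnot(inherits(frame, "pivot_frame"), inherits(config, "catheter_config"))
  ac <- arc_coeffs(config$theta)
  inplane <- config$ell * ac$a
  local <- c(cos(config$phi) * inplane, sin(config$phi) * inplane,
             config$ell * ac$b)
  as.numeric(frame$origin + frame$basis %*% local)
}

#' Inverse kinematics: configuration reaching a target point
#'
#' Closed-form inversion of the constant-curvature model.  With frame
#' coordinates `(x, y, z)` and in-plane radius `r = sqrt(x^2 + y^2)`:
#' `phi = atan2(y, x)`, curvature `kappa = 2 r / (r^2 + z^2)` (the circle
#' through the origin tangent to the axis), bend
#' `theta = atan2(z kappa, 1 - r kappa)` and `ell = theta / kappa`;
#' an on-axis target gives the straight solution `(phi = 0, theta = 0,
#' ell = z)` for `z > 0`.
#'
#' @param frame a [pivot_frame()].
#' @param target 3D point (mm); must differ from the frame origin.
#' @param limits a [kinematic_limits()], or `NULL` to return the geometric
#'   solution regardless of limits.
#' @param kappa_tol curvature tolerance (1/mm) below which the target counts
#'   as on-axis; default 1e-9.
#' @return A [catheter_config()], or `NULL` when no admissible solution
#'   exists (target behind the pivot on-axis, or limits violated).
#' @export
inverse_kinematics <- function(frame, target, limits = kinematic_limits(),
                               kappa_tol = 1e-9) {
  stopifnot(inherits(frame, "pivot_frame"))
  target <- assert_point3(target, "target")
  local <- as.numeric(crossprod(frame$basis, target - frame$origin))
  x <- local[1L]; y <- local[2L]; z <- local[3L]
  r <- sqrt(x^2 + y^2)
  if (r == 0 && z == 0) fg_domain_error("target coincides with the pivot origin")
  kappa <- 2 * r / (r^2 + z^2)
  if (kappa < kappa_tol) {           # straight catheter
    if (z <= 0) return(NULL)
    cfg <- catheter_config(0, 0, z)
  } else {
    theta <- atan2(z * kappa, 1 - r * kappa)
    if (theta <= 0) theta <- theta + 2 * pi
    cfg <- catheter_config(atan2(y, x), theta, theta / kappa)
  }
  if (!is.null(limits) && !config_within_limits(cfg, limits, kappa_tol))
    return(NULL)
  cfg
}

#' Catheter Jacobian at a configuration
#'
#' The 3x3 matrix of tip-position sensitivities to the controls.  Default
#' parameterization `u = (phi, theta, s)` with `s = ell / ell_max`
#' dimensionless, so every column is in mm per unit control; the alternative
#' `(phi, kappa, ell)` is provided for sensitivity checks.
#'
#' @param frame a [pivot_frame()].
#' @param config a [catheter_config()].
#' @param limits a [kinematic_limits()]; supplies `ell_max` for the scaled
#'   insertion control.
#' @param parameterization `"phi-theta-s"` (default) or `"phi-kappa-ell"`.
#' @return 3x3 numeric matrix in world coordinates.
#' @export
catheter_jacobian <- function(frame, config, limits = kinematic_limits(),
                              parameterization = c("phi-theta-s", "phi-kappa-ell")) {
  stopifnot(inherits(frame, "pivot_frame"), inherits(config, "catheter_config"))
  parameterization <- match.arg(parameterization)
  phi <- config$phi; theta <- config$theta; ell <- config$ell
  cp <- cos(phi); sp <- sin(phi)
  ac <- arc_coeffs(theta)
  col_phi <- ell * ac$a * c(-sp, cp, 0)
  if (parameterization == "phi-theta-s") {
    col2 <- ell * c(cp * ac$da, sp * ac$da, ac$db)
    col3 <- limits$ell_max * c(cp * ac$a, sp * ac$a, ac$b)
  } else {
    # u = (phi, kappa, ell): d theta/d kappa = ell, d/d ell at fixed kappa
    # gives the arc tangent direction (cos/sin identities of a + theta*da).
    col2 <- ell^2 * c(cp * ac$da, sp * ac$da, ac$db)
    col3 <- c(cp * sin(theta), sp * sin(theta), cos(theta))
  }
  frame$basis %*% cbind(col_phi, col2, col3, deparse.level = 0)
}
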