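# Reachable / unreachable left-atrial regions from a pivot site.

#' Classify one target as reachable from a pivot
#'
#' A target is reachable when a configuration inside the limits places the
#' catheter tip within `tol` of it: the closed-form inverse-kinematics
#' solution when that lies inside the limits, otherwise its projection onto
#' the limit box (which admits targets within `tol` of the reachable-set
#' boundary, matching an exhaustive configuration search).  Tip-only
#' criterion: shaft-wall collision is not modelled.
#'
#' @param frame a [pivot_frame()].
#' @param target 3D point (mm).
#' @param limits a [kinematic_limits()].
#' @param tol placement tolerance in mm (> 0); default 1 (order of
#'   electromagnetic-tracking precision).
#' @return List with `reachable` (flag) and `config` (a [catheter_config()]
#'   or `NULL`).
#' @export
classify_point <- function(frame, target, limits = kinematic_limits(), tol = 1) {
  if (!(tol > 0)) fg_validation_error("tol must be > 0")
  target <- assert_point3(target, "target")
  if (all(target == frame$origin))
    fg_domain_error("target coincides with the pivot origin")
  rb <- reach_batch(frame, matrix(target, 1L, 3L), limits, tol)
  if (!rb$ok) return(list(reachable = FALSE, config = NULL))
  cfg <- if (rb$theta > 0) catheter_config(rb$phi, rb$theta, rb$ell)
         else catheter_config(0, 0, rb$ell)
  list(reachable = TRUE, config = cfg)
}

#' Map catheter reachability over the left-atrial samples
#'
#' @param frame a [pivot_frame()] (typically at the maximum-GII site).
#' @param la an `la_samples` object.
#' @param limits a [kinematic_limits()].
#' @param tol placement tolerance (mm).
#' @return Object of class `reachability_map`: `points`, `reachable`
#'   (logical), `config` (n x 3 matrix phi/theta/ell, `NA` where
#'   unreachable), `tol`, `fraction_reachable`.
#' @export
map_reachability <- function(frame, la, limits = kinematic_limits(), tol = 1) {
  stopifnot(inherits(frame, "pivot_frame"), inherits(la, "la_samples"))
  if (nrow(la$points) == 0L) fg_validation_error("la samples are empty")
  rb <- reach_batch(frame, la$points, limits, tol)
  cfg <- cbind(phi = rb$phi, theta = rb$theta, ell = rb$ell)
  cfg[!rb$ok, ] <- NA_real_
  structure(list(points = la$points, reachable = rb$ok, config = cfg,
                 tol = tol, fraction_reachable = mean(rb$ok),
                 pivot = frame),
            class = "reachability_map")
}

#' @export
print.reachability_map <- function(x, ...) {
  cat(sprintf("reachability_map: %d LA samples, %.1f%% reachable (tol %.2f mm)\n",
              length(x$reachable), 100 * x$fraction_reachable, x$tol))
  invisible(x)
}

#' @export
summary.reachability_map <- function(object, ...) {
  list(n = length(object$reachable),
       n_reachable = sum(object$reachable),
       fraction_reachable = object$fraction_reachable,
       tol = object$tol)
}

#' @export
plot.reachability_map <- function(x, dims = c(2L, 3L), ...) {
  p <- x$points
  graphics::plot(p[, dims[1]], p[, dims[2]],
                 col = ifelse(x$reachable, "forestgreen", "red2"),
                 pch = 16, cex = 0.5, asp = 1,
                 xlab = c("x", "y", "z")[dims[1]],
                 ylab = c("x", "y", "z")[dims[2]],
                 main = "LA reachability (green = reachable)", ...)
  invisible(x)
}

#' Write a reachability map as CSV (x, y, z, reachable, phi, theta, ell)
#' @param map a `reachability_map`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_reachability_csv <- function(map, path) {
  stopifnot(inherits(map, "reachability_map"))
  df <- data.frame(x = map$points[, 1], y = map$points[, 2], z = map$points[, 3],
                   reachable = map$reachable,
                   phi = map$config[, "phi"], theta = map$config[, "theta"],
                   ell = map$config[, "ell"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
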