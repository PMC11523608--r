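# Global isotropy index scoring of fossa ovalis candidate sites.
#
# GII = sigma_min / sigma_max of the catheter Jacobian.  In global mode the
# ratio is aggregated over the whole reachable LA workspace of a pivot
# (min over configurations of sigma_min divided by max of sigma_max); local
# mode applies the ratio to the single Jacobian at the configuration
# reaching the LA centroid.

#' Isotropy index of a single Jacobian
#'
#' Ratio of the smallest to the largest singular value; 1 means uniform
#' tip mobility in all directions, 0 a lost direction of motion.
#'
#' @param J 3x3 numeric matrix with finite entries.
#' @return Value in `[0, 1]`; 0 when the matrix is identically zero.
#' @examples
#' gii_of_matrix(diag(3))        # 1
#' gii_of_matrix(diag(c(2, 1, 1)))  # 0.5
#' @export
gii_of_matrix <- function(J) {
  J <- as.matrix(J)
  if (!all(dim(J) == c(3L, 3L)) || !all(is.finite(J)))
    fg_domain_error("J must be a finite 3x3 matrix")
  s <- svd(J, nu = 0, nv = 0)$d
  if (max(s) == 0) return(0)
  min(s) / max(s)
}

# --- vectorized internals -------------------------------------------------
#
# All LA sample points are inverted at once.  Because the two non-bending
# Jacobian columns lie in the bending plane and the phi-column is orthogonal
# to it, J^T J is block diagonal (1x1 + 2x2) and its eigenvalues -- hence
# the singular values of J -- are available in closed form without per-point
# SVDs.  Frame rotation drops out of J^T J entirely.

ik_local_batch <- function(local, kappa_tol = 1e-9) {
  x <- local[, 1L]; y <- local[, 2L]; z <- local[, 3L]
  r <- sqrt(x * x + y * y)
  d2 <- r * r + z * z
  kappa <- ifelse(d2 > 0, 2 * r / d2, Inf)
  straight <- kappa < kappa_tol
  theta <- atan2(z * kappa, 1 - r * kappa)
  theta <- ifelse(theta <= 0, theta + 2 * pi, theta)
  theta[straight] <- 0
  ell <- ifelse(straight, z, theta / kappa)
  phi <- atan2(y, x)
  phi[straight] <- 0
  ok <- d2 > 0 & (!straight | z > 0)
  list(phi = phi, theta = theta, ell = ell, ok = ok)
}

within_limits_batch <- function(theta, ell, limits, kappa_tol = 1e-9) {
  theta <= limits$theta_max & ell >= limits$ell_min & ell <= limits$ell_max &
    theta <= ell * (limits$kappa_max + kappa_tol)
}

# Extreme singular values of the (phi, theta, s) Jacobian for vectors of
# configurations.  lam1 = (ell * a)^2 is the phi-block; the bending-plane
# 2x2 block has entries A, B, C.
sigma_extremes_batch <- function(theta, ell, ell_max) {
  ac <- arc_coeffs(theta)
  lam1 <- (ell * ac$a)^2
  A <- ell^2 * (ac$da^2 + ac$db^2)
  B <- ell_max^2 * (ac$a^2 + ac$b^2)
  C <- ell * ell_max * (ac$a * ac$da + ac$b * ac$db)
  h <- (A + B) / 2
  disc <- sqrt(pmax(((A - B) / 2)^2 + C^2, 0))
  lam_hi <- h + disc
  lam_lo <- pmax(h - disc, 0)
  list(smin = sqrt(pmin(lam1, lam_lo)), smax = sqrt(pmax(lam1, lam_hi)))
}

tip_error_local <- function(phi, theta, ell, local) {
  ac <- arc_coeffs(theta)
  rr <- ell * ac$a
  sqrt((cos(phi) * rr - local[, 1L])^2 + (sin(phi) * rr - local[, 2L])^2 +
       (ell * ac$b - local[, 3L])^2)
}

# Reachability + configs of many targets from one pivot, local frame math.
# When the exact inverse-kinematics solution falls outside the limits, the
# configuration projected onto the limit box is tried as well, so targets
# within `tol` of the reachable-set boundary classify as reachable -- the
# same answer an exhaustive configuration-grid search gives.
reach_batch <- function(frame, targets, limits, tol, kappa_tol = 1e-9) {
  local <- (targets - matrix(frame$origin, nrow(targets), 3L, byrow = TRUE)) %*%
    frame$basis
  ik <- ik_local_batch(local, kappa_tol)
  phi <- ik$phi; theta <- ik$theta; ell <- ik$ell
  ok <- ik$ok & within_limits_batch(theta, ell, limits, kappa_tol)
  err <- tip_error_local(phi, theta, ell, local)
  ok <- ok & err <= tol
  # clamp the out-of-limit solutions onto the limit box and retest
  cl <- !ok
  if (any(cl)) {
    th_c <- pmin(pmax(theta[cl], 0), limits$theta_max)
    el_c <- pmin(pmax(ell[cl], limits$ell_min), limits$ell_max)
    over <- th_c > el_c * (limits$kappa_max + kappa_tol)
    el_c[over] <- pmin(th_c[over] / limits$kappa_max, limits$ell_max)
    th_c[over] <- pmin(th_c[over], el_c[over] * limits$kappa_max)
    err_c <- tip_error_local(phi[cl], th_c, el_c, local[cl, , drop = FALSE])
    take <- err_c <= tol
    idx <- which(cl)[take]
    ok[idx] <- TRUE
    theta[idx] <- th_c[take]
    ell[idx] <- el_c[take]
    err[idx] <- err_c[take]
  }
  list(ok = ok, phi = phi, theta = theta, ell = ell, err = err)
}

#' Score one fossa ovalis candidate site
#'
#' @param pivot a [pivot_frame()] at the candidate site (axis = inward FO
#'   normal).
#' @param la an [sample_la_interior()] result (`la_samples`).
#' @param limits a [kinematic_limits()].
#' @param mode `"global"` (default): aggregate the singular-value ratio over
#'   every reachable LA sample; `"local"`: single Jacobian at the
#'   configuration reaching the LA centroid.
#' @param tol reachability tolerance in mm (default 1).
#' @return GII value in `[0, 1]`; 0 when nothing is reachable.
#' @export
score_fo_point <- function(pivot, la, limits = kinematic_limits(),
                           mode = c("global", "local"), tol = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(pivot, "pivot_frame"), inherits(la, "la_samples"))
  if (nrow(la$points) == 0L) fg_validation_error("la samples are empty")
  if (mode == "local") {
    ctr <- colMeans(la$points)
    cfg <- tryCatch(inverse_kinematics(pivot, ctr, limits),
                    fossagii_domain_error = function(e) NULL)
    if (is.null(cfg)) return(0)
    return(gii_of_matrix(catheter_jacobian(pivot, cfg, limits)))
  }
  rb <- reach_batch(pivot, la$points, limits, tol)
  if (!any(rb$ok)) return(0)
  sig <- sigma_extremes_batch(rb$theta[rb$ok], rb$ell[rb$ok], limits$ell_max)
  smax <- max(sig$smax)
  if (smax == 0) return(0)
  min(sig$smin) / smax
}

#' Score every candidate on a fossa ovalis patch
#'
#' Evaluates [score_fo_point()] exhaustively at each candidate (every FO
#' mesh vertex is a potential puncture site), locates the maximizer and
#' builds the score histogram.
#'
#' @param patch an [extract_fo_candidates()] result (`fo_patch`).
#' @param la an `la_samples` object.
#' @param limits a [kinematic_limits()].
#' @param bin_width histogram bin width on `[0, 1]`; default 0.01.
#' @param mode `"global"` or `"local"`, see [score_fo_point()].
#' @param tol reachability tolerance (mm).
#' @return Object of class `gii_field`: `fo_points`, `scores`,
#'   `argmax_index`, `argmax_point`, `argmax_score`, `histogram`
#'   (`bin_left_edges`, `counts`, `bin_width`), `mode`.
#' @export
score_field <- function(patch, la, limits = kinematic_limits(),
                        bin_width = 0.01, mode = c("global", "local"),
                        tol = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(patch, "fo_patch"))
  n <- nrow(patch$points)
  if (n == 0L) fg_validation_error("fo_patch has no candidates")
  if (!(bin_width > 0 && bin_width <= 1))
    fg_validation_error("bin_width must be in (0, 1]")
  scores <- vapply(seq_len(n), function(i) {
    pf <- pivot_frame(patch$points[i, ], patch$normals[i, ])
    score_fo_point(pf, la, limits, mode = mode, tol = tol)
  }, numeric(1))
  am <- which.max(scores)  # ties resolve to the lowest candidate index
  structure(list(fo_points = patch$points, scores = scores,
                 argmax_index = am, argmax_point = patch$points[am, ],
                 argmax_score = scores[am],
                 histogram = gii_histogram(scores, bin_width),
                 mode = mode),
            class = "gii_field")
}

# Fixed-width histogram over [0, 1]; left-closed bins, scores of exactly 1
# fall into the last bin so counts always sum to the candidate count.
gii_histogram <- function(scores, bin_width) {
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  nb <- length(edges) - 1L
  idx <- pmin(pmax(findInterval(scores, edges, rightmost.closed = TRUE), 1L), nb)
  list(bin_left_edges = edges[-length(edges)], counts = tabulate(idx, nbins = nb),
       bin_width = bin_width)
}

#' Modal histogram bin of a GII field
#'
#' The most common score band across the fossa; ties resolve to the lowest
#' bin.
#'
#' @param field a `gii_field`.
#' @return List with `bin_center`, `bin_left`, `count`.
#' @export
mode_score <- function(field) {
  stopifnot(inherits(field, "gii_field"))
  h <- field$histogram
  i <- which.max(h$counts)
  list(bin_center = h$bin_left_edges[i] + h$bin_width / 2,
       bin_left = h$bin_left_edges[i], count = h$counts[i])
}

#' @export
print.gii_field <- function(x, ...) {
  cat(sprintf("gii_field (%s mode): %d candidates\n", x$mode, length(x$scores)))
  cat(sprintf("  scores: min %.4f, median %.4f, max %.4f\n",
              min(x$scores), stats::median(x$scores), max(x$scores)))
  cat(sprintf("  argmax %.4f at (%.2f, %.2f, %.2f) mm [candidate %d]\n",
              x$argmax_score, x$argmax_point[1], x$argmax_point[2],
              x$argmax_point[3], x$argmax_index))
  ms <- mode_score(x)
  cat(sprintf("  modal bin: %.3f (count %d, width %.2g)\n",
              ms$bin_center, ms$count, x$histogram$bin_width))
  invisible(x)
}

#' @export
summary.gii_field <- function(object, ...) {
  ms <- mode_score(object)
  out <- list(n = length(object$scores),
              mode = object$mode,
              quartiles = stats::quantile(object$scores),
              argmax_point = object$argmax_point,
              argmax_score = object$argmax_score,
              modal_bin_center = ms$bin_center,
              modal_bin_count = ms$count)
  class(out) <- "summary.gii_field"
  out
}

#' @export
print.summary.gii_field <- function(x, ...) {
  cat(sprintf("GII field summary (%s mode, n = %d candidates)\n", x$mode, x$n))
  print(round(x$quartiles, 4))
  cat(sprintf("argmax %.4f at (%.2f, %.2f, %.2f) mm; modal bin %.3f (n = %d)\n",
              x$argmax_score, x$argmax_point[1], x$argmax_point[2],
              x$argmax_point[3], x$modal_bin_center, x$modal_bin_count))
  invisible(x)
}

#' @export
plot.gii_field <- function(x, ...) {
  h <- x$histogram
  graphics::barplot(h$counts, names.arg = NULL, space = 0, col = "steelblue",
                    border = NA, xlab = "GII", ylab = "candidate count",
                    main = sprintf("GII score distribution (%s mode)", x$mode),
                    ...)
  at <- pretty(c(0, 1))
  graphics::axis(1, at = at / h$bin_width, labels = at)
  invisible(x)
}

#' Write a GII field as CSV (fo_x, fo_y, fo_z, gii)
#' @param field a `gii_field`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_gii_csv <- function(field, path) {
  stopifnot(inherits(field, "gii_field"))
  df <- data.frame(fo_x = field$fo_points[, 1], fo_y = field$fo_points[, 2],
                   fo_z = field$fo_points[, 3], gii = field$scores)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
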