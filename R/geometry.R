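# FO candidate extraction, anatomical quadrants, LA interior sampling.

#' Fossa ovalis candidate patch
#'
#' Candidate transseptal-puncture sites with oriented normals, per-point
#' septal thickness and the anatomical centroid, which by convention is the
#' thinnest point of the fossa.
#'
#' @param fo_mesh [tri_mesh()] of the fossa ovalis.
#' @param thickness numeric vector of per-vertex thickness (mm), strictly
#'   positive, one value per mesh vertex.
#' @param la_reference optional 3D point on the left-atrial side (e.g. the LA
#'   cavity centroid); vertex normals are flipped so they point towards it
#'   (the right-to-left puncture direction).  `NULL` keeps the mesh's own
#'   consistent orientation.
#' @param frame optional list with unit vectors `superior` and `posterior`
#'   spanning the FO plane; when supplied, every candidate is labelled with
#'   its anatomical quadrant (SP/IP/SA/IA) relative to the centroid.
#' @return An object of class `fo_patch`: `points` (n x 3 mm), `normals`
#'   (n x 3, unit), `thickness`, `centroid` (3-vector), `centroid_index`,
#'   `quadrant` (factor or `NA`), `mesh`.
#' @export
extract_fo_candidates <- function(fo_mesh, thickness, la_reference = NULL,
                                  frame = NULL) {
  stopifnot(inherits(fo_mesh, "tri_mesh"))
  thickness <- as.numeric(thickness)
  if (length(thickness) != nrow(fo_mesh$vertices))
    fg_validation_error("thickness length must equal FO vertex count")
  if (any(!is.finite(thickness)) || any(thickness <= 0))
    fg_validation_error("thickness values must be finite and strictly positive")
  normals <- vertex_normals(fo_mesh)
  ci <- which.min(thickness)  # ties resolve to the lowest vertex index
  centroid <- fo_mesh$vertices[ci, ]
  if (!is.null(la_reference)) {
    la_reference <- assert_point3(la_reference, "la_reference")
    inward <- la_reference - centroid
    s <- sign(normals %*% inward)
    s[s == 0] <- 1
    normals <- normals * as.numeric(s)
  }
  quadrant <- rep(NA_character_, nrow(fo_mesh$vertices))
  if (!is.null(frame)) {
    quadrant <- vapply(seq_len(nrow(fo_mesh$vertices)), function(i)
      assign_quadrant(fo_mesh$vertices[i, ], frame, centroid), character(1))
  }
  structure(list(points = fo_mesh$vertices, normals = normals,
                 thickness = thickness, centroid = centroid,
                 centroid_index = ci,
                 quadrant = factor(quadrant, levels = c("SP", "IP", "SA", "IA")),
                 mesh = fo_mesh),
            class = "fo_patch")
}

#' @export
print.fo_patch <- function(x, ...) {
  cat(sprintf("fo_patch: %d candidate sites\n", nrow(x$points)))
  cat(sprintf("  thickness [mm]: %.3f .. %.3f (centroid = thinnest, vertex %d)\n",
              min(x$thickness), max(x$thickness), x$centroid_index))
  if (!all(is.na(x$quadrant))) print(table(x$quadrant))
  invisible(x)
}

#' Anatomical quadrant of a point on the fossa ovalis
#'
#' Labels a point superior/inferior and posterior/anterior relative to the
#' FO centroid, using an explicit orthonormal in-plane frame.  Zero offsets
#' resolve towards superior and posterior.
#'
#' @param point 3D point (mm).
#' @param frame list with unit 3-vectors `superior` and `posterior`,
#'   orthonormal within 1e-9.
#' @param centroid FO centroid (mm).
#' @return One of `"SP"`, `"IP"`, `"SA"`, `"IA"`.
#' @export
assign_quadrant <- function(point, frame, centroid) {
  point <- assert_point3(point)
  centroid <- assert_point3(centroid, "centroid")
  s_ax <- assert_point3(frame$superior, "frame$superior")
  p_ax <- assert_point3(frame$posterior, "frame$posterior")
  if (abs(vnorm(s_ax) - 1) > 1e-9 || abs(vnorm(p_ax) - 1) > 1e-9 ||
      abs(sum(s_ax * p_ax)) > 1e-9)
    fg_validation_error("frame axes must be orthonormal within 1e-9")
  off <- point - centroid
  s_off <- sum(off * s_ax)
  p_off <- sum(off * p_ax)
  paste0(if (s_off >= 0) "S" else "I", if (p_off >= 0) "P" else "A")
}

#' Which points lie strictly inside a closed mesh?
#'
#' Ray-parity test: counts triangle crossings along a fixed oblique ray
#' direction (chosen away from mesh axes so grid points never graze edges).
#'
#' @param points `n x 3` matrix of query points (mm).
#' @param mesh a watertight [tri_mesh()].
#' @return Logical vector of length `n`.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) fg_validation_error("points must be n x 3")
  d <- unitize(c(0.2393716, 0.4683218, 0.8519728))  # generic direction
  v <- mesh$vertices
  f <- mesh$faces
  crossings <- integer(nrow(points))
  # Moller-Trumbore, vectorized over query points one triangle at a time.
  for (i in seq_len(nrow(f))) {
    p0 <- v[f[i, 1], ]
    e1 <- v[f[i, 2], ] - p0
    e2 <- v[f[i, 3], ] - p0
    pv <- cross3(d, e2)
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- points - matrix(p0, nrow(points), 3L, byrow = TRUE)
    u <- (tv %*% pv) / det
    qv <- cbind(tv[, 2] * e1[3] - tv[, 3] * e1[2],
                tv[, 3] * e1[1] - tv[, 1] * e1[3],
                tv[, 1] * e1[2] - tv[, 2] * e1[1])
    w <- (qv %*% d) / det
    t <- (qv %*% e2) / det
    hit <- u >= 0 & w >= 0 & (u + w) <= 1 & t > 1e-9
    crossings <- crossings + as.integer(hit)
  }
  crossings %% 2L == 1L
}

#' Sample the left-atrial cavity on a regular grid
#'
#' Represents the LA by discrete interior points: an axis-aligned grid at the
#' requested spacing, kept where the ray-parity test reports strictly inside.
#'
#' @param la_mesh watertight [tri_mesh()] of the LA cavity.
#' @param spacing grid resolution in mm (> 0); default 2.5.
#' @return An object of class `la_samples`: `points` (n x 3), `spacing`.
#' @export
sample_la_interior <- function(la_mesh, spacing = 2.5) {
  stopifnot(inherits(la_mesh, "tri_mesh"))
  if (!is.numeric(spacing) || spacing <= 0)
    fg_validation_error("spacing must be > 0")
  if (!is_watertight(la_mesh))
    fg_validation_error(sprintf("mesh '%s' is not watertight", la_mesh$name))
  bb <- apply(la_mesh$vertices, 2L, range)
  ax <- lapply(1:3, function(j) {
    n <- floor((bb[2, j] - bb[1, j]) / spacing)
    if (n < 0) numeric(0) else bb[1, j] + spacing / 2 + spacing * (0:n)
  })
  if (any(lengths(ax) == 0L))
    fg_resolution_error("spacing larger than the mesh extent: no grid points")
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  inside <- points_in_mesh(grid, la_mesh)
  if (!any(inside))
    fg_resolution_error("no grid point falls inside the mesh; reduce spacing")
  structure(list(points = grid[inside, , drop = FALSE], spacing = spacing),
            class = "la_samples")
}

#' @export
print.la_samples <- function(x, ...) {
  cat(sprintf("la_samples: %d interior points at %.2f mm grid spacing\n",
              nrow(x$points), x$spacing))
  invisible(x)
}
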