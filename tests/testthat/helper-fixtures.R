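# Fixtures and independent oracles shared across the suite.

# Canonical ASCII STL of the unit cube (12 facets), written to a temp file.
write_cube_stl <- function(path = tempfile(fileext = ".stl")) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  quads <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  lines <- "solid cube"
  for (q in quads) for (tri in list(q[c(1, 2, 3)], q[c(1, 3, 4)])) {
    lines <- c(lines, "  facet normal 0 0 0", "    outer loop",
               sprintf("      vertex %g %g %g",
                       v[tri, 1], v[tri, 2], v[tri, 3]),
               "    endloop", "  endfacet")
  }
  writeLines(c(lines, "endsolid cube"), path)
  path
}

# Generalized winding number of a point w.r.t. a closed mesh: sum of signed
# solid angles of the faces (van Oosterom & Strackee) over 4*pi.  Fully
# independent of the ray-parity implementation under test.
winding_inside <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  apply(points, 1L, function(p) {
    a <- v[f[, 1], , drop = FALSE] - matrix(p, nrow(f), 3L, byrow = TRUE)
    b <- v[f[, 2], , drop = FALSE] - matrix(p, nrow(f), 3L, byrow = TRUE)
    cc <- v[f[, 3], , drop = FALSE] - matrix(p, nrow(f), 3L, byrow = TRUE)
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(cc^2))
    num <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
           a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * cc) * lb +
           rowSums(b * cc) * la
    w <- sum(2 * atan2(num, den)) / (4 * pi)
    abs(w) > 0.5
  })
}

unitize_test <- function(v) v / sqrt(sum(v^2))

# Deterministic random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3L))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rotate_mesh <- function(mesh, R, shift = c(0, 0, 0)) {
  tri_mesh(mesh$vertices %*% t(R) + matrix(shift, nrow(mesh$vertices), 3L,
                                           byrow = TRUE),
           mesh$faces, name = mesh$name)
}

make_la_samples <- function(points, spacing) {
  structure(list(points = as.matrix(points), spacing = spacing),
            class = "la_samples")
}

# Default synthetic scene, built once per test run.
.scene_cache <- new.env(parent = emptyenv())
default_scene <- function() {
  if (is.null(.scene_cache$scene)) {
    cfg <- synth_config(seed = 1)
    geo <- make_geometry(cfg)
    patch <- extract_fo_candidates(geo$fo, geo$thickness,
                                   la_reference = geo$la_centroid,
                                   frame = geo$fo_frame)
    samp <- sample_la_interior(geo$la, 2.5)
    field <- score_field(patch, samp)
    .scene_cache$scene <- list(cfg = cfg, geo = geo, patch = patch,
                               samp = samp, field = field)
  }
  .scene_cache$scene
}

# Exhaustive configuration-grid search: distance from each local-frame
# target to the nearest grid-configuration tip.  For fixed (theta, ell) the
# tip-to-target distance is monotone in the bending-plane mismatch, so the
# nearest grid phi minimizes exactly; the remaining search runs over the
# (theta, ell) grid.  Independent of the closed-form inverse kinematics.
grid_reach_oracle <- function(local_targets, limits,
                              dphi = pi / 180, dtheta = pi / 180, dell = 0.5) {
  th <- seq(0, limits$theta_max, by = dtheta)
  el <- seq(limits$ell_min, limits$ell_max, by = dell)
  g <- expand.grid(theta = th, ell = el)
  g <- g[g$theta / g$ell <= limits$kappa_max, ]
  ac <- fossagii:::arc_coeffs(g$theta)
  rg <- g$ell * ac$a
  zg <- g$ell * ac$b
  apply(local_targets, 1L, function(p) {
    rt <- sqrt(p[1]^2 + p[2]^2)
    phit <- atan2(p[2], p[1])
    dphi_near <- abs(phit - round(phit / dphi) * dphi)
    d2 <- rg^2 + rt^2 - 2 * rg * rt * cos(dphi_near) + (zg - p[3])^2
    sqrt(min(d2))
  })
}

# Ball of grid points with 90-degree rotational symmetry about the x axis:
# grid centred on the axis in y and z.
symmetric_ball_samples <- function(radius, spacing) {
  ax <- spacing * seq(-floor(radius / spacing), floor(radius / spacing))
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE))
  make_la_samples(g[sqrt(rowSums(g^2)) <= radius - spacing / 2, , drop = FALSE],
                  spacing)
}
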