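# Synthetic study generator: parametric biatrial geometry, operator
# puncture cohorts, caliper/STL measurement pairs and Likert tables, all
# with known ground truth for parameter-recovery testing.
#
# Each output table draws from its own sub-stream of the master seed, so
# generating one table never perturbs another.

#' Configuration of the synthetic study
#'
#' Defaults encode the study conditions: a circular fossa ovalis insert of
#' 18.46 mm diameter (circularity 1.0) with a radially parabolic thickness
#' profile from 0.65 mm (centre, the thinnest point) to 1.75 mm (rim); four
#' cardiologists with 10, 10, 14 and 25 years of experience plus one
#' trainee, each contributing 4 recorded punctures (middle of the stated
#' 3-5); procedural times positively correlated with the puncture's GII
#' (target Pearson r 0.656) and its centroid distance (target 0.566); and
#' 3 researchers x 50 paired measurements with a +0.03 mm systematic
#' STL-minus-physical bias.
#'
#' @param seed master integer seed.
#' @param la_semi_axes LA ellipsoid semi-axes (mm); default c(30, 25, 22), a
#'   dilated atrium at atrial-fibrillation scale.
#' @param fo_diameter FO diameter (mm); default 18.46.
#' @param fo_thickness_range c(min, max) thickness (mm); default
#'   c(0.65, 1.75).
#' @param fo_rings,fo_sectors FO disc mesh resolution; defaults 7 rings x
#'   28 sectors (197 candidate vertices).
#' @param la_subdivisions icosphere subdivision level of the LA mesh;
#'   default 3 (1280 faces).
#' @param operators data frame with `id`, `experience_years` (trainee coded
#'   0), `dispersion_mm` (in-plane puncture scatter SD) and `n_trials`.
#' @param time_model list: `intercept_s`, `noise_sd` (s), `target_r_gii`,
#'   `target_r_dist` (population Pearson correlations of time with GII and
#'   centroid distance, used to calibrate the linear coefficients), and
#'   optional explicit `gii_coeff` / `dist_coeff` which bypass calibration.
#' @param measurement_model list: `bias_mm`, `sd_mm`, `n_per_researcher`,
#'   `n_researchers`, `feature_range_mm`.
#' @param likert_means named per-question target means in `[1, 5]`.
#' @param n_respondents questionnaire panel size; default 5.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         la_semi_axes = c(30, 25, 22),
                         fo_diameter = 18.46,
                         fo_thickness_range = c(0.65, 1.75),
                         fo_rings = 7L, fo_sectors = 28L,
                         la_subdivisions = 3L,
                         operators = data.frame(
                           id = c("Trainee", "Card10a", "Card10b", "Card14", "Card25"),
                           experience_years = c(0, 10, 10, 14, 25),
                           dispersion_mm = c(6, 2.5, 2.5, 2, 1.5),
                           n_trials = rep(4L, 5L)),
                         time_model = list(intercept_s = 180, noise_sd = 30,
                                           target_r_gii = 0.656,
                                           target_r_dist = 0.566,
                                           gii_coeff = NULL, dist_coeff = NULL),
                         measurement_model = list(bias_mm = 0.03, sd_mm = 0.2,
                                                  n_per_researcher = 50L,
                                                  n_researchers = 3L,
                                                  feature_range_mm = c(2, 80)),
                         likert_means = c(Q1 = 4.15, Q2 = 4.50, Q3 = 3.75,
                                          Q4 = 4.00, Q5 = 4.00, Q6 = 4.60),
                         n_respondents = 5L) {
  if (!(fo_diameter > 0)) fg_validation_error("fo_diameter must be > 0")
  if (!(length(fo_thickness_range) == 2L &&
        fo_thickness_range[1] > 0 &&
        fo_thickness_range[1] < fo_thickness_range[2]))
    fg_validation_error("fo_thickness_range must satisfy 0 < min < max")
  if (any(operators$dispersion_mm <= 0))
    fg_validation_error("operator dispersions must be > 0")
  if (any(operators$n_trials < 1L))
    fg_validation_error("each operator needs >= 1 trial")
  if (any(likert_means < 1 | likert_means > 5))
    fg_validation_error("likert_means must lie in [1, 5]")
  structure(list(seed = as.integer(seed), la_semi_axes = la_semi_axes,
                 fo_diameter = fo_diameter,
                 fo_thickness_range = fo_thickness_range,
                 fo_rings = as.integer(fo_rings),
                 fo_sectors = as.integer(fo_sectors),
                 la_subdivisions = as.integer(la_subdivisions),
                 operators = operators, time_model = time_model,
                 measurement_model = measurement_model,
                 likert_means = likert_means,
                 n_respondents = as.integer(n_respondents)),
            class = "synth_config")
}

# --- geometry -------------------------------------------------------------

# Unit icosphere: icosahedron refined by edge-midpoint subdivision, vertices
# renormalized to the unit sphere each level.
icosphere <- function(subdivisions = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- 1L + rbind(c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
                  c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
                  c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
                  c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  for (s in seq_len(subdivisions)) {
    mid <- new.env(hash = TRUE)
    vlist <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      k <- mid[[key]]
      if (!is.null(k)) return(k)
      m <- unitize(vlist[i, ] + vlist[j, ])
      vlist <<- rbind(vlist, m)
      k <- nrow(vlist)
      mid[[key]] <- k
      k
    }
    nf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- vlist
    f <- nf
  }
  list(vertices = v, faces = f)
}

# Planar disc of `rings` concentric rings x `sectors`, radius R, embedded at
# `center` in the plane spanned by (u, v); faces oriented with normal u x v.
disc_mesh <- function(center, u, v, R, rings, sectors, name = "FO") {
  ang <- 2 * pi * (seq_len(sectors) - 1L) / sectors
  verts <- matrix(center, 1L, 3L, byrow = TRUE)
  for (k in seq_len(rings)) {
    r <- R * k / rings
    ring <- matrix(center, sectors, 3L, byrow = TRUE) +
      outer(r * cos(ang), u) + outer(r * sin(ang), v)
    verts <- rbind(verts, ring)
  }
  ring_idx <- function(k, j) 1L + (k - 1L) * sectors + ((j - 1L) %% sectors) + 1L
  faces <- matrix(0L, 0L, 3L)
  for (j in seq_len(sectors))
    faces <- rbind(faces, c(1L, ring_idx(1L, j), ring_idx(1L, j + 1L)))
  if (rings > 1L) for (k in seq_len(rings - 1L)) for (j in seq_len(sectors)) {
    a <- ring_idx(k, j); b <- ring_idx(k, j + 1L)
    c_ <- ring_idx(k + 1L, j + 1L); d <- ring_idx(k + 1L, j)
    faces <- rbind(faces, c(a, d, c_), c(a, c_, b))
  }
  tri_mesh(verts, faces, name = name)
}

#' Generate the synthetic biatrial geometry
#'
#' Closed LA ellipsoid (icosphere scaled by the semi-axes) with a circular
#' FO disc tangent to its wall: the disc sits at the +x apex of the
#' ellipsoid with its plane spanned by the posterior (+y) and superior (+z)
#' axes, a radially parabolic thickness profile thinnest at the centre, and
#' inward normals pointing into the LA cavity.
#'
#' @param cfg a [synth_config()].
#' @return List: `la` and `fo` ([tri_mesh()]), `thickness` (per FO vertex,
#'   mm), `fo_frame` (superior/posterior unit axes), `la_centroid`,
#'   `fo_center`.
#' @export
make_geometry <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  ax <- cfg$la_semi_axes
  R <- cfg$fo_diameter / 2
  if (R >= 0.8 * min(ax))
    fg_validation_error("FO larger than the LA wall patch it must sit on")
  ico <- icosphere(cfg$la_subdivisions)
  la_verts <- ico$vertices * matrix(ax, nrow(ico$vertices), 3L, byrow = TRUE)
  la <- tri_mesh(la_verts, ico$faces, name = "LA")
  if (mesh_volume(la) < 0) la$faces <- la$faces[, c(1L, 3L, 2L)]
  fo_center <- c(ax[1], 0, 0)
  posterior <- c(0, 1, 0)
  superior <- c(0, 0, 1)
  fo <- disc_mesh(fo_center, posterior, superior, R,
                  cfg$fo_rings, cfg$fo_sectors, name = "FO")
  rho <- sqrt(rowSums((fo$vertices -
                         matrix(fo_center, nrow(fo$vertices), 3L, byrow = TRUE))^2))
  tr <- cfg$fo_thickness_range
  thickness <- tr[1] + (tr[2] - tr[1]) * (rho / R)^2
  list(la = la, fo = fo, thickness = thickness,
       fo_frame = list(superior = superior, posterior = posterior),
       la_centroid = c(0, 0, 0), fo_center = fo_center)
}

# --- cohort ---------------------------------------------------------------

# Orthonormal in-plane axes + normal of the best-fit plane through the FO
# candidates (principal components; signs fixed for determinism).
fo_plane <- function(fo_points) {
  ctr <- colMeans(fo_points)
  sv <- svd(sweep(fo_points, 2L, ctr))
  axes <- sv$v
  for (j in 1:3) if (axes[which.max(abs(axes[, j])), j] < 0) axes[, j] <- -axes[, j]
  list(center = ctr, u = axes[, 1], v = axes[, 2], normal = axes[, 3])
}

# Isotropic 2D normal scatter about `center2`, rejected outside radius R
# (punctures stay on the fossa).
draw_scatter2 <- function(n, sigma, center2, R) {
  out <- matrix(NA_real_, 0L, 2L)
  guard <- 0L
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 8L)
    cand <- cbind(center2[1] + stats::rnorm(m, 0, sigma),
                  center2[2] + stats::rnorm(m, 0, sigma))
    keep <- sqrt(rowSums(cand^2)) <= R
    out <- rbind(out, cand[keep, , drop = FALSE])
    guard <- guard + 1L
    if (guard > 10000L) fg_validation_error("scatter rejection failed to converge")
  }
  out[seq_len(n), , drop = FALSE]
}

# Scatter geometry shared by the cohort generator and the calibration:
# puncture centres halfway between FO centroid and max-GII site, in the FO
# plane.
scatter_geometry <- function(field, centroid) {
  pl <- fo_plane(field$fo_points)
  to2 <- function(p) c(sum((p - pl$center) * pl$u), sum((p - pl$center) * pl$v))
  R_eff <- max(sqrt(rowSums((sweep(field$fo_points, 2L, pl$center))^2)))
  mid3 <- (centroid + field$argmax_point) / 2
  list(plane = pl, center2 = to2(mid3), centroid2 = to2(centroid), R = R_eff)
}

nearest_candidate_gii <- function(pts2, field, pl) {
  cand2 <- cbind(as.numeric(sweep(field$fo_points, 2L, pl$center) %*% pl$u),
                 as.numeric(sweep(field$fo_points, 2L, pl$center) %*% pl$v))
  d2 <- outer(rowSums(pts2^2), rowSums(cand2^2), "+") - 2 * pts2 %*% t(cand2)
  field$scores[max.col(-d2, ties.method = "first")]
}

#' Calibrate the procedural-time model
#'
#' Solves the linear coefficients of
#' `time = intercept + beta_g * GII + beta_d * dist + noise` so that the
#' population Pearson correlations of time with GII and with centroid
#' distance equal the configured targets, given the operator scatter mix and
#' the noise SD.  Moments of (GII, dist) under the scatter distribution are
#' estimated once by Monte Carlo on a fixed internal stream (independent of
#' `cfg$seed`), so the calibrated model is a reusable population property.
#'
#' @param cfg a [synth_config()].
#' @param field a `gii_field` scored on the FO candidates.
#' @param centroid FO centroid (mm).
#' @param n_mc Monte-Carlo draws for the moment estimate; default 4000.
#' @return List: `beta_gii`, `beta_dist` (s per unit), `g_mean`, `d_mean`,
#'   `sigma_time` (total time SD, s), `rho_gd` (scatter-induced GII-distance
#'   correlation).
#' @export
calibrate_time_model <- function(cfg, field, centroid, n_mc = 4000L) {
  tm <- cfg$time_model
  if (!(tm$noise_sd > 0))
    fg_config_error("time-model calibration needs noise_sd > 0")
  geo <- scatter_geometry(field, centroid)
  w <- cfg$operators$n_trials / sum(cfg$operators$n_trials)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(20240901L)
  pts <- do.call(rbind, lapply(seq_len(nrow(cfg$operators)), function(i)
    draw_scatter2(max(2L, round(n_mc * w[i])), cfg$operators$dispersion_mm[i],
                  geo$center2, geo$R)))
  g <- nearest_candidate_gii(pts, field, geo$plane)
  d <- sqrt(rowSums(sweep(pts, 2L, geo$centroid2)^2))
  S <- stats::cov(cbind(g, d))
  v <- c(tm$target_r_gii * sqrt(S[1, 1]), tm$target_r_dist * sqrt(S[2, 2]))
  q <- as.numeric(crossprod(v, solve(S, v)))
  if (q >= 1)
    fg_config_error("target correlations infeasible for this scatter geometry")
  sigma_time <- tm$noise_sd / sqrt(1 - q)
  beta <- unname(sigma_time * solve(S, v))
  list(beta_gii = beta[1], beta_dist = beta[2],
       g_mean = mean(g), d_mean = mean(d), sigma_time = sigma_time,
       rho_gd = stats::cov2cor(S)[1, 2])
}

#' Generate an operator puncture cohort
#'
#' Puncture points are isotropic in-plane Gaussian scatter on the fossa,
#' centred between the FO centroid and the maximum-GII site, with the
#' per-operator dispersion (decreasing with experience under the defaults)
#' and rejected outside the fossa rim.  Procedural times follow the linear
#' time model on (GII at the nearest candidate, centroid distance) plus
#' Gaussian noise.
#'
#' @param cfg a [synth_config()].
#' @param field a `gii_field` on the FO candidates.
#' @param centroid FO centroid (mm).
#' @param time_coef optional precomputed [calibrate_time_model()] result
#'   (recomputed when `NULL` and no explicit coefficients are configured).
#' @return Data frame of puncture records: `participant`,
#'   `experience_years`, `trial`, `x`, `y`, `z`, `time_s`.
#' @export
make_cohort <- function(cfg, field, centroid, time_coef = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(field, "gii_field"))
  centroid <- assert_point3(centroid, "centroid")
  tm <- cfg$time_model
  explicit <- !is.null(tm$gii_coeff) && !is.null(tm$dist_coeff)
  if (!explicit && is.null(time_coef))
    time_coef <- calibrate_time_model(cfg, field, centroid)
  geo <- scatter_geometry(field, centroid)
  set.seed(fg_stream_seed(cfg$seed, 2L))
  ops <- cfg$operators
  rows <- lapply(seq_len(nrow(ops)), function(i) {
    n <- ops$n_trials[i]
    p2 <- draw_scatter2(n, ops$dispersion_mm[i], geo$center2, geo$R)
    p3 <- matrix(geo$plane$center, n, 3L, byrow = TRUE) +
      outer(p2[, 1], geo$plane$u) + outer(p2[, 2], geo$plane$v)
    g <- nearest_candidate_gii(p2, field, geo$plane)
    d <- sqrt(rowSums((p3 - matrix(centroid, n, 3L, byrow = TRUE))^2))
    noise <- stats::rnorm(n, 0, tm$noise_sd)
    t_s <- if (explicit) tm$intercept_s + tm$gii_coeff * g + tm$dist_coeff * d + noise
           else tm$intercept_s + time_coef$beta_gii * (g - time_coef$g_mean) +
                time_coef$beta_dist * (d - time_coef$d_mean) + noise
    data.frame(participant = ops$id[i], experience_years = ops$experience_years[i],
               trial = seq_len(n), x = p3[, 1], y = p3[, 2], z = p3[, 3],
               time_s = pmax(t_s, 1))
  })
  do.call(rbind, rows)
}

# --- measurements and questionnaire --------------------------------------

#' Generate paired STL/physical measurements
#'
#' Each of `n_researchers` measures the same `n_per_researcher` features.
#' True (STL) values are uniform over the feature range; physical values are
#' truth minus the systematic bias plus Gaussian noise, so the STL-minus-
#' physical difference recovers the configured bias.
#'
#' @param cfg a [synth_config()].
#' @return Data frame: `feature`, `researcher`, `stl_mm`, `physical_mm`.
#' @export
make_measurements <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  mm <- cfg$measurement_model
  if (mm$n_per_researcher < 2L) fg_validation_error("need n_per_researcher >= 2")
  set.seed(fg_stream_seed(cfg$seed, 3L))
  truth <- stats::runif(mm$n_per_researcher, mm$feature_range_mm[1],
                        mm$feature_range_mm[2])
  rows <- lapply(seq_len(mm$n_researchers), function(r)
    data.frame(feature = sprintf("f%02d", seq_len(mm$n_per_researcher)),
               researcher = sprintf("R%d", r),
               stl_mm = truth,
               physical_mm = truth - mm$bias_mm +
                 stats::rnorm(mm$n_per_researcher, 0, mm$sd_mm)))
  do.call(rbind, rows)
}

#' Generate Likert questionnaire responses
#'
#' Integer 1-5 scores from the two-point distribution on the floor and
#' ceiling of each target mean, with the ceiling probability equal to the
#' fractional part -- so every question matches its target mean in
#' expectation.
#'
#' @param cfg a [synth_config()].
#' @param question_means named target means in `[1, 5]`; defaults to the
#'   configured ones.
#' @param n_respondents panel size; defaults to the configured one.
#' @return Data frame: `participant`, `question`, `score`.
#' @export
make_likert <- function(cfg, question_means = cfg$likert_means,
                        n_respondents = cfg$n_respondents) {
  stopifnot(inherits(cfg, "synth_config"))
  if (any(question_means < 1 | question_means > 5))
    fg_validation_error("target means must lie in [1, 5]")
  set.seed(fg_stream_seed(cfg$seed, 4L))
  qs <- names(question_means) %||% sprintf("Q%d", seq_along(question_means))
  rows <- lapply(seq_along(question_means), function(j) {
    m <- question_means[j]
    base <- floor(m)
    sc <- base + as.integer(stats::runif(n_respondents) < (m - base))
    data.frame(participant = sprintf("P%d", seq_len(n_respondents)),
               question = qs[j], score = pmin(pmax(sc, 1L), 5L))
  })
  do.call(rbind, rows)
}
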