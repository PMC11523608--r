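# Synthetic generator: geometry dimensions, cohort ground truth,
# measurement and questionnaire models, determinism.

test_that("synthetic geometry matches the configured fossa dimensions", {
  sc <- default_scene()
  geo <- sc$geo
  expect_true(is_watertight(geo$la))
  expect_gt(mesh_volume(geo$la), 0)
  d <- as.matrix(dist(geo$fo$vertices))
  expect_lt(abs(max(d) - 18.46), 0.1)          # max chord = FO diameter
  expect_equal(min(geo$thickness), 0.65)
  expect_equal(max(geo$thickness), 1.75)
  # circularity 1.0: all rim vertices equidistant from the disc centre
  rim <- sqrt(rowSums(sweep(geo$fo$vertices, 2, geo$fo_center)^2))
  expect_equal(max(rim), 18.46 / 2, tolerance = 1e-9)
  expect_error(make_geometry(synth_config(fo_diameter = 0)),
               class = "fossagii_validation_error")
  expect_error(make_geometry(synth_config(fo_diameter = 60)),
               class = "fossagii_validation_error")
})

test_that("geometry generation is deterministic", {
  g1 <- make_geometry(synth_config(seed = 7))
  g2 <- make_geometry(synth_config(seed = 7))
  expect_identical(g1$la$vertices, g2$la$vertices)
  expect_identical(g1$thickness, g2$thickness)
})

test_that("a spherical LA yields a GII field symmetric about the FO axis", {
  cfg <- synth_config(la_semi_axes = c(25, 25, 25), fo_rings = 3L,
                      fo_sectors = 8L)
  geo <- make_geometry(cfg)
  patch <- extract_fo_candidates(geo$fo, geo$thickness, geo$la_centroid)
  samp <- symmetric_ball_samples(25, 5)
  field <- score_field(patch, samp)
  # ring vertices 90 degrees apart about the x axis are equivalent pivots
  ring1 <- 2:9  # first ring, 8 sectors
  s <- field$scores[ring1]
  expect_lt(max(abs(s - s[c(3:8, 1:2)])), 1e-6)
})

test_that("explicit time coefficients give the exact deterministic limits", {
  sc <- default_scene()
  cfg <- synth_config(seed = 5)
  cfg$time_model$gii_coeff <- 400
  cfg$time_model$dist_coeff <- 0
  cfg$time_model$noise_sd <- 0
  coh <- make_cohort(cfg, sc$field, sc$patch$centroid)
  g <- (coh$time_s - cfg$time_model$intercept_s) / 400
  expect_equal(correlate(g, coh$time_s)$r, 1)
  expect_true(all(coh$time_s > 0))
  expect_equal(nrow(coh), sum(cfg$operators$n_trials))
})

test_that("vanishing dispersion pins punctures at the scatter centre", {
  sc <- default_scene()
  cfg <- synth_config(seed = 5)
  cfg$operators$dispersion_mm <- rep(1e-9, 5)
  cfg$time_model$gii_coeff <- 0; cfg$time_model$dist_coeff <- 1
  cfg$time_model$noise_sd <- 0
  coh <- make_cohort(cfg, sc$field, sc$patch$centroid)
  d <- sqrt(rowSums(sweep(as.matrix(coh[, c("x", "y", "z")]), 2,
                          sc$patch$centroid)^2))
  offset <- sqrt(sum(((sc$patch$centroid + sc$field$argmax_point) / 2 -
                        sc$patch$centroid)^2))
  expect_lt(max(abs(d - offset)), 1e-6)
})

test_that("puncture scatter stays on the fossa plane and disc", {
  sc <- default_scene()
  coh <- make_cohort(sc$cfg, sc$field, sc$patch$centroid)
  pl <- fossagii:::fo_plane(sc$field$fo_points)
  pts <- as.matrix(coh[, c("x", "y", "z")])
  plane_dist <- abs(sweep(pts, 2, pl$center) %*% pl$normal)
  expect_lt(max(plane_dist), 1e-6)
  radial <- sqrt(rowSums(sweep(pts, 2, pl$center)^2))
  expect_lte(max(radial), 18.46 / 2 + 1e-9)
  expect_true(all(coh$time_s > 0))
})

test_that("mean distances order by experience in a dispersion-graded cohort", {
  sc <- default_scene()
  cfg <- synth_config(seed = 9,
                      operators = data.frame(
                        id = c("T", "C5", "C14", "C25"),
                        experience_years = c(0, 5, 14, 25),
                        dispersion_mm = c(6, 3, 2, 1.2),
                        n_trials = rep(200L, 4)))
  coh <- make_cohort(cfg, sc$field, sc$patch$centroid)
  tab <- distance_metrics(coh, sc$field$argmax_point, sc$patch$centroid)
  ord <- order(tab$experience_years)
  expect_true(all(diff(tab$mean_dist_centroid[ord]) < 0))
  expect_true(all(diff(tab$mean_dist_gii[ord]) < 0))
})

test_that("calibrated cohorts recover the target time correlations", {
  sc <- default_scene()
  tc <- calibrate_time_model(sc$cfg, sc$field, sc$patch$centroid)
  expect_gt(tc$sigma_time, sc$cfg$time_model$noise_sd)
  rs_g <- numeric(300); rs_d <- numeric(300)
  for (i in seq_len(300)) {
    cfg_i <- synth_config(seed = 10000 + i)
    coh <- make_cohort(cfg_i, sc$field, sc$patch$centroid, time_coef = tc)
    pl <- fossagii:::fo_plane(sc$field$fo_points)
    pts <- as.matrix(coh[, c("x", "y", "z")])
    p2 <- cbind(as.numeric(sweep(pts, 2, pl$center) %*% pl$u),
                as.numeric(sweep(pts, 2, pl$center) %*% pl$v))
    g <- fossagii:::nearest_candidate_gii(p2, sc$field, pl)
    d <- sqrt(rowSums(sweep(pts, 2, sc$patch$centroid)^2))
    rs_g[i] <- correlate(g, coh$time_s)$r
    rs_d[i] <- correlate(d, coh$time_s)$r
  }
  expect_lt(abs(mean(rs_g) - 0.656), 0.05)
  expect_lt(abs(mean(rs_d) - 0.566), 0.05)
})

test_that("measurement pairs recover the configured bias", {
  cfg0 <- synth_config(seed = 3)
  cfg0$measurement_model$sd_mm <- 0
  m0 <- make_measurements(cfg0)
  ba0 <- bland_altman(m0$stl_mm, m0$physical_mm)
  expect_equal(ba0$bias, 0.03)
  expect_equal(ba0$sd_diff, 0)
  biases <- vapply(1:30, function(s) {
    m <- make_measurements(synth_config(seed = 200 + s))
    bland_altman(m$stl_mm, m$physical_mm)$bias
  }, numeric(1))
  expect_true(mean(biases) >= 0 && mean(biases) <= 0.06)
})

test_that("identical researcher distributions give a uniform KW null", {
  ps <- vapply(1:400, function(s) {
    m <- make_measurements(synth_config(seed = 3000 + s))
    kruskal_wallis(split(m$stl_mm - m$physical_mm, m$researcher))$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("likert generation matches targets exactly at the extremes", {
  cfg <- synth_config(seed = 4, likert_means = c(Q1 = 5, Q2 = 1, Q3 = 4))
  lk <- make_likert(cfg)
  expect_true(all(lk$score[lk$question == "Q1"] == 5L))
  expect_true(all(lk$score[lk$question == "Q2"] == 1L))
  big <- make_likert(synth_config(seed = 4, likert_means = c(Q = 4.0)),
                     n_respondents = 5000L)
  expect_lt(abs(mean(big$score) - 4.0), 0.05)
  expect_error(make_likert(synth_config(), question_means = c(Q = 0.5)),
               class = "fossagii_validation_error")
})

test_that("every generated table is bitwise reproducible under a seed", {
  sc <- default_scene()
  tc <- calibrate_time_model(sc$cfg, sc$field, sc$patch$centroid)
  c1 <- make_cohort(sc$cfg, sc$field, sc$patch$centroid, tc)
  c2 <- make_cohort(sc$cfg, sc$field, sc$patch$centroid, tc)
  expect_identical(c1, c2)
  expect_identical(make_measurements(sc$cfg), make_measurements(sc$cfg))
  expect_identical(make_likert(sc$cfg), make_likert(sc$cfg))
})
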