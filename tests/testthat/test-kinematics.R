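# Constant-curvature forward/inverse kinematics and the catheter Jacobian.

frame0 <- function() pivot_frame(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))

test_that("forward kinematics reproduces the closed-form arc cases", {
  f <- frame0()
  # straight-catheter limit
  expect_equal(forward_kinematics(f, catheter_config(0, 0, 50)), c(0, 0, 50))
  # quarter-circle arc of radius 20 (kappa = 0.05 /mm)
  expect_equal(forward_kinematics(f, catheter_config(0, pi / 2, 10 * pi)),
               c(20, 0, 20), tolerance = 1e-12)
  # rotating the bending plane about the insertion axis
  expect_equal(forward_kinematics(f, catheter_config(pi / 2, pi / 2, 10 * pi)),
               c(0, 20, 20), tolerance = 1e-12)
  # semicircle: tip at diameter height zero forward offset
  expect_equal(forward_kinematics(f, catheter_config(0, pi, 10 * pi)),
               c(20, 0, 0), tolerance = 1e-12)
})

test_that("forward kinematics is continuous across the straight limit", {
  f <- frame0()
  below <- forward_kinematics(f, catheter_config(0.3, 1e-6 * (1 - 1e-9), 80))
  above <- forward_kinematics(f, catheter_config(0.3, 1e-6 * (1 + 1e-9), 80))
  expect_lt(sqrt(sum((below - above)^2)), 1e-9)
  # series and exact branch of the arc coefficients agree at the switch
  ser <- fossagii:::arc_coeffs(1e-6, eps = 1e-3)   # forces the series branch
  exact <- fossagii:::arc_coeffs(1e-6, eps = 1e-9) # forces the exact branch
  for (nm in c("a", "b", "da", "db"))
    expect_lt(abs(ser[[nm]] - exact[[nm]]), 1e-9)
})

test_that("inverse kinematics inverts the arc and flags no-solution cases", {
  f <- frame0()
  cfg <- inverse_kinematics(f, c(0, 0, 30))
  expect_equal(c(cfg$phi, cfg$theta, cfg$ell), c(0, 0, 30))
  cfg <- inverse_kinematics(f, c(20, 0, 20))
  expect_equal(cfg$theta, pi / 2, tolerance = 1e-12)
  expect_equal(cfg$ell, 10 * pi, tolerance = 1e-12)
  expect_equal(cfg$theta / cfg$ell, 0.05, tolerance = 1e-12)
  # behind the pivot on-axis: no solution
  expect_null(inverse_kinematics(f, c(0, 0, -10), NULL))
  # within geometric reach but outside the insertion limit
  expect_null(inverse_kinematics(f, c(0, 0, 150)))
  expect_error(inverse_kinematics(f, c(0, 0, 0)),
               class = "fossagii_domain_error")
})

test_that("FK/IK round-trips close on random in-limit configurations", {
  f <- pivot_frame(c(3, -2, 7), unitize_test(c(1, 2, -1)))
  lim <- kinematic_limits()
  set.seed(42)
  n <- 0
  while (n < 200) {
    cfg <- catheter_config(runif(1, -pi, pi), runif(1, 1e-3, pi),
                           runif(1, lim$ell_min, lim$ell_max))
    if (cfg$theta / cfg$ell > lim$kappa_max) next
    n <- n + 1
    tip <- forward_kinematics(f, cfg)
    cfg2 <- inverse_kinematics(f, tip, lim)
    expect_false(is.null(cfg2))
    tip2 <- forward_kinematics(f, cfg2)
    expect_lt(sqrt(sum((tip - tip2)^2)), 1e-6)
    # config-space identity away from the straight singular direction
    expect_equal(cfg2$theta, cfg$theta, tolerance = 1e-9)
    expect_equal(cfg2$ell, cfg$ell, tolerance = 1e-6)
  }
})

test_that("tip distance from the pivot never exceeds the arc length", {
  f <- frame0()
  set.seed(8)
  for (k in 1:100) {
    cfg <- catheter_config(runif(1, -pi, pi), runif(1, 0, pi), runif(1, 1, 100))
    expect_lte(sqrt(sum(forward_kinematics(f, cfg)^2)), cfg$ell + 1e-9)
  }
})

test_that("analytic Jacobian matches central finite differences", {
  f <- pivot_frame(c(1, 1, 1), unitize_test(c(-1, 1, 2)))
  lim <- kinematic_limits()
  h <- 1e-5
  set.seed(5)
  n <- 0
  while (n < 100) {
    phi <- runif(1, -pi, pi); theta <- runif(1, 0.05, pi)
    ell <- runif(1, lim$ell_min + 1, lim$ell_max - 1)
    if (theta / ell > lim$kappa_max) next
    n <- n + 1
    J <- catheter_jacobian(f, catheter_config(phi, theta, ell), lim)
    fd <- vapply(1:3, function(k) {
      d <- numeric(3); d[k] <- h
      u <- c(phi, theta, ell / lim$ell_max)
      fk <- function(u) forward_kinematics(
        f, catheter_config(u[1], u[2], u[3] * lim$ell_max))
      (fk(u + d) - fk(u - d)) / (2 * h)
    }, numeric(3))
    expect_lt(max(abs(J - fd)) / max(abs(J)), 1e-5)
  }
})

test_that("Jacobian columns have the stated closed-form magnitudes", {
  f <- frame0()
  lim <- kinematic_limits()
  # straight limit: insertion column is ell_max times the axis
  J <- catheter_jacobian(f, catheter_config(0, 1e-12, 50), lim)
  expect_equal(J[, 3], lim$ell_max * c(0, 0, 1), tolerance = 1e-9)
  # phi column magnitude equals the in-plane radius (20 mm) on the quarter arc
  J <- catheter_jacobian(f, catheter_config(0, pi / 2, 10 * pi), lim)
  expect_equal(sqrt(sum(J[, 1]^2)), 20, tolerance = 1e-12)
})

test_that("alternative (phi, kappa, ell) parameterization matches differences", {
  f <- frame0()
  lim <- kinematic_limits()
  phi <- 0.4; theta <- 1.1; ell <- 40
  kappa <- theta / ell
  J <- catheter_jacobian(f, catheter_config(phi, theta, ell), lim,
                         parameterization = "phi-kappa-ell")
  h <- 1e-6
  fk <- function(u) forward_kinematics(
    f, catheter_config(u[1], u[2] * u[3], u[3]))
  fd <- vapply(1:3, function(k) {
    d <- numeric(3); d[k] <- h
    u <- c(phi, kappa, ell)
    (fk(u + d) - fk(u - d)) / (2 * h)
  }, numeric(3))
  expect_lt(max(abs(J - fd)) / max(abs(J)), 1e-4)
})

test_that("Jacobian rotates with the frame, singular values invariant", {
  lim <- kinematic_limits()
  cfg <- catheter_config(0.7, 1.3, 35)
  f <- frame0()
  J <- catheter_jacobian(f, cfg, lim)
  for (k in 1:5) {
    R <- random_rotation(300 + k)
    fr <- pivot_frame(as.numeric(R %*% f$origin), as.numeric(R %*% f$axis),
                      as.numeric(R %*% f$ref))
    Jr <- catheter_jacobian(fr, cfg, lim)
    expect_equal(Jr, R %*% J, tolerance = 1e-12)
    expect_equal(svd(Jr)$d, svd(J)$d, tolerance = 1e-9)
  }
})

test_that("configuration and frame validation reject bad inputs", {
  expect_error(catheter_config(0, -1, 10), class = "fossagii_validation_error")
  expect_error(catheter_config(0, 1, 0), class = "fossagii_validation_error")
  expect_error(kinematic_limits(theta_max = 4), class = "fossagii_validation_error")
  expect_error(kinematic_limits(ell_min = 10, ell_max = 5),
               class = "fossagii_validation_error")
  expect_error(pivot_frame(c(0, 0, 0), c(0, 0, 1), ref = c(0, 0, 1)),
               class = "fossagii_validation_error")
})
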