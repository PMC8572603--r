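test_that("forearm rotation is the identity at 0 and preserves norms", {
  p <- c(0.007, 0, -0.047)
  expect_equal(rotate_insertion(p, 0), p)
  expect_equal(rotate_insertion(p, 90), c(0.047, 0, 0.007),
               tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:25) {
      q <- runif(3, -0.2, 0.2)
      th <- runif(1, -180, 360)
      expect_equal(sqrt(sum(rotate_insertion(q, th)^2)), sqrt(sum(q^2)),
                   tolerance = 1e-12)
    }
  })
  m <- rotate_insertion(p, c(0, 45, 90))
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m[1, ], c(x = p[1], y = p[2], z = p[3]))
})

test_that("flexor musculotendon length matches the hand-computed fixture", {
  bl <- arm_muscles()$biceps_long
  # at full extension: dist((0.023,0,0.115),(0.007,0,-0.047)) + 0.263
  want <- sqrt(0.016^2 + 0.162^2) + 0.263
  expect_equal(flexor_mt_length(bl$origin, bl$insertion, bl$l_0), want,
               tolerance = 1e-12)
  expect_equal(flexor_mt_length(c(0.1, 0, 0), c(0.3, 0, 0), 0), 0.2)
  # biceps path shortens monotonically from extension to 90 deg flexion
  th <- seq(0, 90, by = 1)
  lmt <- flexor_mt_length(bl$origin, rotate_insertion(bl$insertion, th),
                          bl$l_0)
  expect_true(all(diff(lmt) < 0))
  expect_error(flexor_mt_length(c(0, 0, 0.1), c(0, 0, 0.1), 0),
               "degenerate")
})

test_that("fiber length splits off the fixed-scale tendon", {
  got <- fiber_length(0.4257882, 0.272)
  expect_equal(got$l_t, 0.27744)
  expect_equal(got$l_m, 0.4257882 - 0.27744, tolerance = 1e-12)
  expect_equal(fiber_length(0.3, 0, tendon_scale = 1)$l_m, 0.3)
  expect_error(fiber_length(1.02 * 0.272, 0.272, muscle = "biceps_long",
                            theta_deg = 15),
               "biceps_long.*15")
})

test_that("flexor moment arm equals the point-line distance oracle", {
  # vertical and horizontal lines of action
  expect_equal(flexor_moment_arm(c(1, 0, 0), c(1, 0, 1)), 1)
  expect_equal(flexor_moment_arm(c(0, 0, 1), c(1, 0, 1)), 1)
  ms <- arm_muscles()
  for (nm in c("biceps_long", "biceps_short", "brachialis")) {
    m <- ms[[nm]]
    for (th in c(seq(0, 120, by = 2.5), 45)) {
      ins <- rotate_insertion(m$insertion, th)
      expect_equal(flexor_moment_arm(m$origin, ins),
                   point_line_distance_xz(m$origin, ins),
                   tolerance = 1e-12, info = paste(nm, th))
    }
  }
  withr::with_seed(9, {
    for (i in 1:50) {
      a <- c(runif(1, -0.1, 0.1), 0, runif(1, -0.1, 0.1))
      c_ <- c(runif(1, -0.1, 0.1), 0, runif(1, -0.1, 0.1))
      expect_equal(flexor_moment_arm(a, c_), point_line_distance_xz(a, c_),
                   tolerance = 1e-12)
    }
  })
})

test_that("virtual work: |d l_mt / d theta_rad| equals the moment arm", {
  ms <- arm_muscles()
  h <- 1e-3  # degrees
  for (nm in c("biceps_long", "biceps_short", "brachialis")) {
    m <- ms[[nm]]
    for (th in seq(0, 120, by = 5)) {
      lp <- flexor_mt_length(m$origin, rotate_insertion(m$insertion, th + h),
                             m$l_0)
      lm <- flexor_mt_length(m$origin, rotate_insertion(m$insertion, th - h),
                             m$l_0)
      dl_dth <- (lp - lm) / (2 * h * pi / 180)
      r <- flexor_moment_arm(m$origin, rotate_insertion(m$insertion, th))
      expect_equal(abs(dl_dth), r, tolerance = 1e-6, info = paste(nm, th))
    }
  }
})

test_that("extensor arm is linear in angle and shared across heads", {
  expect_equal(extensor_moment_arm(0, 0.022), 0.022)
  expect_equal(extensor_moment_arm(90, 0.022, k_s = 0.004), 0.022 - 0.004)
  expect_equal(extensor_moment_arm(45, 0.022),
               (extensor_moment_arm(0, 0.022) +
                  extensor_moment_arm(90, 0.022)) / 2)
  ms <- arm_muscles()
  th <- seq(0, 150, by = 10)
  arms <- sapply(c("triceps_long", "triceps_lateral", "triceps_medial"),
                 function(nm) extensor_moment_arm(th, ms[[nm]]$r_0))
  expect_true(all(arms[, 1] == arms[, 2] & arms[, 2] == arms[, 3]))
  expect_error(extensor_moment_arm(90, r_0 = 0.003), "nonpositive")
})

test_that("extensor path lengthens by the swept arc", {
  expect_equal(extensor_mt_length(0, 0.02, 0.134), 0.134)
  expect_equal(extensor_mt_length(90, 0.02, 0.134),
               0.134 + pi / 2 * 0.02, tolerance = 1e-12)
  # degree-literal variant drops pi
  expect_equal(extensor_mt_length(90, 0.02, 0.134, literal = TRUE),
               0.134 + 90 * 0.02 / 180)
  # arc-length derivative at fixed r
  r <- 0.021
  th <- c(30, 30 + 1e-3)
  dl <- diff(extensor_mt_length(th, r, 0.2)) / (1e-3 * pi / 180)
  expect_equal(dl, r, tolerance = 1e-9)
})

test_that("fiber velocity differentiates length series correctly", {
  t <- seq(0, 2, by = 0.01)
  expect_equal(fiber_velocity(rep(0.1, length(t)), t, 0.1),
               rep(0, length(t)))
  # linear ramp l_m = l_mopt (1 + 0.1 t) with v_max_factor 8
  expect_equal(fiber_velocity(0.1 * (1 + 0.1 * t), t, 0.1),
               rep(0.1 / 8, length(t)), tolerance = 1e-12)
  # sinusoid against the analytic derivative, O(dt^2) interior accuracy
  lm <- 0.1 * (1 + 0.05 * sin(2 * pi * t))
  vn <- fiber_velocity(lm, t, 0.1)
  analytic <- 0.1 * 0.05 * 2 * pi * cos(2 * pi * t) / (8 * 0.1)
  expect_equal(vn[2:200], analytic[2:200], tolerance = 1e-3)
  expect_error(fiber_velocity(c(1, 2), c(0, 1), 0.1), ">= 3")
  expect_error(fiber_velocity(1:4, c(0, 1, 3, 7), 0.1), "uniform")
})
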