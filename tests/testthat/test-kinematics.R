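test_that("spline upsampling is exact on the input samples and on lines", {
  tr <- helix_trajectory()
  expect_identical(interpolate_trajectory(tr, 1L), tr)
  expect_error(interpolate_trajectory(tr, 0L), "factor")

  tt <- seq(0, 1, by = 0.01)
  line <- wm_trajectory(cbind(2 * tt, -tt, 3 * tt + 1), rate = 100)
  up <- interpolate_trajectory(line, 5L)
  tn <- seq(0, 1, by = 1 / 500)
  expect_lt(max(abs(up$coords - cbind(2 * tn, -tn, 3 * tn + 1))), 1e-9)
  # original samples reproduced exactly
  expect_equal(up$coords[seq(1, nrow(up$coords), by = 5), ], line$coords,
               tolerance = 1e-12)
})

test_that("spline upsampling recovers a sine to high accuracy", {
  tt <- seq(0, 0.99, by = 0.01)
  tr <- wm_trajectory(cbind(sin(2 * pi * tt), 0 * tt, 0 * tt), rate = 100)
  up <- interpolate_trajectory(tr, 5L)
  tn <- seq(0, 0.99, by = 1 / 500)
  # interior accuracy (natural-spline end conditions are only O(h^2) at the
  # boundary); the 1e-4 bound is checked away from the two ends
  interior <- tn > 0.02 & tn < 0.97
  expect_lt(max(abs(up$coords[interior, 1] - sin(2 * pi * tn[interior]))),
            1e-4)
})

test_that("speed is the forward-difference magnitude times the rate", {
  const <- wm_trajectory(matrix(1, 50, 3), rate = 100)
  expect_equal(compute_speed(const), rep(0, 49))

  tt <- 0:99
  step <- wm_trajectory(cbind(0.01 * tt, 0 * tt, 0 * tt), rate = 100)
  expect_equal(compute_speed(step), rep(1, 99), tolerance = 1e-12)

  # helix vs dense finite-difference oracle
  h <- helix_trajectory(rate = 100)
  dense <- helix_trajectory(rate = 1e4)
  analytic <- sqrt(4 * pi^2 + 1)
  expect_lt(max(abs(compute_speed(dense) - analytic)), 1e-2)
  expect_lt(max(abs(compute_speed(h) - analytic)), 0.25)
})

test_that("acceleration is the second-difference magnitude times rate^2", {
  tt <- 0:99
  line <- wm_trajectory(cbind(0.02 * tt, -0.01 * tt, 0.005 * tt), rate = 100)
  expect_equal(compute_acceleration(line), rep(0, 98), tolerance = 1e-9)

  a <- 3.7
  quad <- wm_trajectory(cbind(0.5 * a * (tt / 100)^2, 0 * tt, 0 * tt),
                        rate = 100)
  expect_equal(compute_acceleration(quad), rep(a, 98), tolerance = 1e-8)

  h <- helix_trajectory(rate = 1000)
  expect_lt(max(abs(compute_acceleration(h) - 4 * pi^2)), 0.01)
})

test_that("planar angles use the vertex convention with a pi fallback", {
  tt <- 0:9
  line <- wm_trajectory(cbind(tt, 2 * tt, -tt), rate = 1)
  expect_equal(unname(compute_planar_angles(line)),
               matrix(pi, 3, 8), tolerance = 1e-7)

  turn <- wm_trajectory(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), rate = 1)
  expect_equal(unname(compute_planar_angles(turn)["angle_xy", 1]), pi / 2,
               tolerance = 1e-12)

  still <- wm_trajectory(matrix(0, 5, 3), rate = 1)
  expect_true(all(compute_planar_angles(still) == pi))
})

test_that("planar angles agree with an independent atan2 oracle", {
  set.seed(31)
  for (r in 1:500) {
    p <- matrix(rnorm(9), 3, 3)
    tr <- wm_trajectory(p, rate = 1)
    ang <- compute_planar_angles(tr)
    for (pl in list(c("angle_xy", 1, 2), c("angle_xz", 1, 3),
                    c("angle_yz", 2, 3))) {
      ix <- as.integer(pl[2:3])
      expect_equal(unname(ang[pl[1], 1]),
                   angle_atan2_oracle(p[1, ix], p[2, ix], p[3, ix]),
                   tolerance = 1e-10)
    }
  }
})

test_that("the feature series stacks the three operations at length T-2", {
  set.seed(5)
  tr <- wm_trajectory(matrix(rnorm(300), 100, 3), rate = 100)
  fs <- build_feature_series(tr)
  expect_equal(dim(fs$values), c(5, 98))
  expect_identical(rownames(fs$values), feature_channels())
  expect_equal(fs$values["speed", ], compute_speed(tr)[-1])
  expect_equal(fs$values["accel", ], compute_acceleration(tr))
  expect_equal(fs$values[3:5, ], compute_planar_angles(tr))

  const <- wm_trajectory(matrix(2, 60, 3), rate = 100)
  fc <- build_feature_series(const)
  expect_true(all(fc$values[c("speed", "accel"), ] == 0))
  expect_true(all(fc$values[3:5, ] == pi))
})

test_that("speed and acceleration are rigid-motion invariant, angles are not", {
  set.seed(6)
  tr <- wm_trajectory(matrix(rnorm(300), 100, 3), rate = 100)
  R <- rigid_rotation()
  moved <- wm_trajectory(tr$coords %*% t(R) +
                           matrix(c(5, -3, 2), 100, 3, byrow = TRUE),
                         rate = 100)
  expect_equal(compute_speed(moved), compute_speed(tr), tolerance = 1e-9)
  expect_equal(compute_acceleration(moved), compute_acceleration(tr),
               tolerance = 1e-9)
  expect_gt(max(abs(compute_planar_angles(moved) -
                      compute_planar_angles(tr))), 1e-3)
})

test_that("time reversal reverses the speed series", {
  set.seed(7)
  tr <- wm_trajectory(matrix(rnorm(150), 50, 3), rate = 100)
  rev_tr <- wm_trajectory(tr$coords[50:1, ], rate = 100)
  expect_equal(compute_speed(rev_tr), rev(compute_speed(tr)),
               tolerance = 1e-12)
})

test_that("coordinate scaling scales speed/acceleration and fixes angles", {
  set.seed(8)
  tr <- wm_trajectory(matrix(rnorm(150), 50, 3), rate = 100)
  sc <- wm_trajectory(2.5 * tr$coords, rate = 100)
  expect_equal(compute_speed(sc), 2.5 * compute_speed(tr), tolerance = 1e-9)
  expect_equal(compute_acceleration(sc), 2.5 * compute_acceleration(tr),
               tolerance = 1e-9)
  expect_equal(compute_planar_angles(sc), compute_planar_angles(tr),
               tolerance = 1e-9)
})
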