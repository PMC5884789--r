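test_that("gimbal composition matches identity and full-turn cases", {
  id <- orientation_from_gimbal(0, 0)
  expect_equal(gravity_in_sample_frame(id), c(0, 0, -1), tolerance = 1e-12)

  full <- orientation_from_gimbal(2 * pi, 2 * pi)
  expect_lt(max(abs(gravity_in_sample_frame(full) - c(0, 0, -1))), 1e-9)

  flipped <- orientation_from_gimbal(pi, 0)
  expect_lt(max(abs(gravity_in_sample_frame(flipped) - c(0, 0, 1))), 1e-9)

  expect_error(orientation_from_gimbal(NaN, 0), "finite")
  expect_error(orientation_from_gimbal(0, Inf), "finite")
})

test_that("gimbal composition agrees with a rotation-matrix oracle on 1000 random pairs", {
  set.seed(101)
  for (i in 1:1000) {
    ang <- stats::runif(2, -2 * pi, 2 * pi)
    o <- orientation_from_gimbal(ang[1], ang[2])
    R <- rpmsim:::quat_to_matrix(o)
    expect_lt(max(abs(R - gimbal_matrix_oracle(ang[1], ang[2]))), 1e-9)
  }
})

test_that("orientations preserve norms and invert cleanly", {
  set.seed(7)
  for (i in 1:50) {
    o <- orientation_from_gimbal(stats::runif(1, -10, 10), stats::runif(1, -10, 10))
    expect_lt(abs(sum(unclass(o)^2) - 1), 1e-9)
    u <- gravity_in_sample_frame(o)
    expect_lt(abs(sum(u^2) - 1), 1e-9)
    # composing with the conjugate gives the identity action
    back <- rpmsim:::quat_rotate(o, u)
    expect_lt(max(abs(back - c(0, 0, -1))), 1e-9)
  }
  expect_error(gravity_in_sample_frame(c(1, 0, 0, 0)), "rpm_orientation")
})

test_that("trajectory integration handles constants, full revolutions and bad input", {
  still <- integrate_gimbal_trajectory(function(t) c(0, 0), duration = 10, dt = 0.5)
  expect_equal(nrow(still), 21)
  expect_true(all(abs(still$uz + 1) < 1e-12))

  # one full outer revolution at 60 deg/s returns to the start
  rev <- integrate_gimbal_trajectory(function(t) c(pi / 3, 0), duration = 6, dt = 0.01)
  last <- as.numeric(rev[nrow(rev), c("ux", "uy", "uz")])
  expect_lt(max(abs(last - c(0, 0, -1))), 1e-6)

  expect_error(integrate_gimbal_trajectory(function(t) c(0, 0), duration = 0, dt = 0.1), "duration")
  expect_error(integrate_gimbal_trajectory(function(t) c(0, 0), duration = 10, dt = 0), "dt")
})

test_that("uniform rotation about a horizontal axis time-averages to zero in the rotation plane", {
  # constant outer-rate rotation about lab X: u sweeps the y-z great
  # circle; over whole revolutions the trapezoidal mean vanishes
  tr <- integrate_gimbal_trajectory(function(t) c(pi / 3, 0), duration = 12, dt = 0.05)
  avg <- time_averaged_gravity(tr)
  expect_lt(abs(avg$mean_vector[2]), 1e-6)
  expect_lt(abs(avg$mean_vector[3]), 1e-6)
  expect_lt(abs(avg$mean_vector[1]), 1e-12)
})

test_that("rates beyond max_rate are clipped and flagged", {
  fast <- integrate_gimbal_trajectory(function(t) c(10, 0), duration = 3, dt = 0.1,
                                      max_rate = pi / 3)
  capped <- integrate_gimbal_trajectory(function(t) c(pi / 3, 0), duration = 3, dt = 0.1,
                                        max_rate = pi / 3)
  expect_true(attr(fast, "meta")$clipped)
  expect_false(attr(capped, "meta")$clipped)
  expect_equal(fast$uz, capped$uz, tolerance = 1e-12)
  # consecutive gravity directions never move faster than both gimbals
  # combined allow
  u <- as.matrix(fast[, c("ux", "uy", "uz")])
  steps <- acos(pmin(1, rowSums(u[-nrow(u), ] * u[-1, ])))
  expect_lt(max(steps), sqrt(2) * pi / 3 * 0.1 + 1e-9)
})

test_that("time-averaged gravity is trapezoidal and linear over concatenation", {
  expect_error(time_averaged_gravity(tibble::tibble()), "gravity trace|empty")

  const <- gravity_trace(0:10, cbind(0, 0, rep(-1, 11)))
  expect_equal(time_averaged_gravity(const)$magnitude, 1, tolerance = 1e-12)

  # two-state trace with q = 0.69: mean magnitude (p + 1)/2 relation
  tq <- gravity_trace(c(0, 69, 69 + 1e-9, 100),
                      rbind(c(0, 0, -1), c(0, 0, -1), c(0, 0, 1), c(0, 0, 1)))
  expect_equal(time_averaged_gravity(tq)$magnitude, 0.38, tolerance = 1e-8)

  # concatenation: duration-weighted average of the parts
  set.seed(3)
  th <- stats::runif(21, 0, pi)
  u <- cbind(sin(th), 0, -cos(th))
  tA <- gravity_trace(seq(0, 10, by = 0.5), u)
  tB <- gravity_trace(seq(10, 16, by = 0.3), rbind(u[21, ], u[1:20, ]))
  whole <- gravity_trace(c(tA$t, tB$t[-1]),
                         rbind(as.matrix(tA[, 2:4]), as.matrix(tB[-1, 2:4])))
  vA <- time_averaged_gravity(tA)$mean_vector
  vB <- time_averaged_gravity(tB)$mean_vector
  vW <- time_averaged_gravity(whole)$mean_vector
  expect_lt(max(abs(vW - (10 * vA + 6 * vB) / 16)), 1e-12)
})

test_that("classic real-random mode averages gravity out over two hours", {
  set.seed(4)
  prof <- random_rate_profile(max_rate = pi / 3, interval = c(1, 10), horizon = 7300)
  tr <- integrate_gimbal_trajectory(prof, duration = 7200, dt = 0.1)
  expect_lt(time_averaged_gravity(tr)$magnitude, 0.05)
  expect_unit_rows(as.matrix(tr[, c("ux", "uy", "uz")]))
})

test_that("traces round-trip through CSV", {
  tr <- integrate_gimbal_trajectory(function(t) c(0.3, -0.2), duration = 5, dt = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  expect_identical(readLines(path, n = 1), "t,ux,uy,uz,m")
  back <- read_trace_csv(path)
  expect_equal(as.matrix(back), as.matrix(tr[names(back)]), tolerance = 1e-12,
               ignore_attr = TRUE)
})
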