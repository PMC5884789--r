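tab1 <- tibble::tribble(
  ~condition,       ~g, ~rpm, ~radius,
  "Moon",           0.17, 36, 0.12,
  "Mars",           0.38, 53, 0.12,
  "1/2 g-Earth",    0.50, 53, 0.16,
  "3/4 g-Earth",    0.75, 75, 0.12,
  "1 g HW control", 1.00, 75, 0.16
)

test_that("centripetal g reproduces the reference centrifuge settings", {
  partial <- tab1[tab1$g < 1, ]
  achieved <- centripetal_g(partial$rpm, partial$radius, "rpm")
  expect_equal(round(achieved, 2), partial$g)
  # the 1 g control at integer rpm lands within the rpm-rounding
  # quantisation of the printed level
  expect_lt(abs(centripetal_g(75, 0.16, "rpm") - 1.00), 0.01)

  expect_equal(centripetal_g(0, 0.12, "rpm"), 0)
  expect_equal(round(centripetal_g(60, 0.20, "deg_s"), 2), 0.02)
  expect_error(centripetal_g(36, 0.12), "unit")
  expect_error(centripetal_g(36, 0.12, "furlongs"), "unit")
  expect_error(centripetal_g(36, -1, "rpm"), "radius")
})

test_that("integer-rpm solver inverts every reference row exactly", {
  expect_equal(solve_rpm(tab1$g, tab1$radius), as.integer(tab1$rpm))
  expect_identical(solve_rpm(0, 0.12), 0L)
  expect_error(solve_rpm(0.38, 0), "radius")
})

test_that("centripetal g scales quadratically in speed and linearly in radius", {
  set.seed(14)
  w <- stats::runif(50, 1, 100)
  r <- stats::runif(50, 0.01, 0.5)
  k <- stats::runif(50, 0.1, 5)
  expect_equal(centripetal_g(2 * w, r, "rpm"), 4 * centripetal_g(w, r, "rpm"), tolerance = 1e-12)
  expect_equal(centripetal_g(w, k * r, "rpm"), k * centripetal_g(w, r, "rpm"), tolerance = 1e-12)
})

test_that("residual g follows the quadratic scaling law", {
  expect_equal(residual_g(60, 0.20), 0.0224, tolerance = 0.01)
  expect_equal(residual_g(0, 0.20), 0)
  expect_equal(residual_g(30, 0.20), residual_g(60, 0.20) / 4, tolerance = 1e-12)
})

test_that("relative residual error matches the Mars-run figures", {
  expect_equal(relative_residual_error(0.02, 0.38), 5.26, tolerance = 0.001)
  expect_equal(relative_residual_error(0, 0.38), 0)
  expect_equal(relative_residual_error(residual_g(60, 0.20), 0.38), 5.88, tolerance = 0.001)
  expect_error(relative_residual_error(0.02, 0), "> 0")
})

test_that("combined g intervals contain the nominal level", {
  res <- residual_g(60, 0.20)
  iv <- combined_g(0.38, res)
  expect_equal(iv$rule, "interval")
  expect_true(iv$low <= iv$nominal && iv$nominal <= iv$high)
  expect_equal(iv$high - iv$low, 2 * res, tolerance = 1e-12)
  expect_equal(combined_g(0.38, 0.02)[, c("low", "high")],
               tibble::tibble(low = 0.36, high = 0.40), tolerance = 1e-12)

  zero <- combined_g(0.5, 0)
  expect_equal(zero$low, zero$high)
  expect_equal(zero$low, 0.5)

  rss <- combined_g(0.38, 0.02, "rss")
  expect_equal(rss$low, sqrt(0.38^2 + 0.02^2), tolerance = 1e-12)
})

test_that("g-gradient is linear in the sample extent", {
  none <- g_gradient(53, 0.12, 0)
  expect_equal(none$delta_g, 0)

  g1 <- g_gradient(53, 0.12, 0.02)
  expect_equal(g1$rel_gradient, 0.02 / 0.12, tolerance = 1e-12)
  g2 <- g_gradient(53, 0.12, 0.04)
  expect_equal(g2$delta_g, 2 * g1$delta_g, tolerance = 1e-12)

  expect_error(g_gradient(53, 0.01, 0.04), "positive")
})

test_that("equi-gravity placement keeps every position at constant g inside the dish", {
  pl <- equigravity_positions(0.12, 0.09, 0.12, n = 25)
  expect_equal(nrow(pl), 25)
  r <- sqrt(pl$x^2 + pl$y^2)
  expect_lt(max(abs(r - 0.12)), 1e-9)
  # all inside the dish (centre at (0.12, 0))
  expect_true(all(sqrt((pl$x - 0.12)^2 + pl$y^2) < 0.045))
  # constant g across positions, analytically zero spread
  g <- centripetal_g(53, r, "rpm")
  expect_equal(max(g) - min(g), 0, tolerance = 1e-12)

  single <- equigravity_positions(0.16, 0.09, 0.16, n = 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$y, 0, tolerance = 1e-12)

  expect_error(equigravity_positions(0.12, 0.09, 0.20, n = 5), "feasible range")
})

test_that("hardware planner assembles the full settings block", {
  plan <- plan_hw(1.00, 0.16)
  expect_equal(plan$rpm, 75L)
  plan_mars <- plan_hw(0.38, 0.12)
  expect_equal(plan_mars$rpm, 53L)
  expect_equal(plan_mars$relative_error_pct, 5.88, tolerance = 0.001)
  expect_equal(plan_mars$rel_gradient, 0.02 / 0.12, tolerance = 1e-6)

  tab <- reference_settings()
  expect_equal(tab$rpm, tab1$rpm)
  expect_equal(tab$eccentricity[1:4], c(0.25, 0.53, 0.66, 0.87))
  expect_true(is.na(tab$eccentricity[5]))
})
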