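test_that("equal-area partitions conserve and equalise solid angle", {
  one <- equal_area_partition(1, 1)
  expect_equal(one$area, 4 * pi, tolerance = 1e-12)

  part <- equal_area_partition(10)
  expect_equal(nrow(part), 100)
  expect_lt(abs(sum(part$area) - 4 * pi), 1e-9)
  expect_lt(max(part$area) / min(part$area), 1 + 1e-9)

  odd <- equal_area_partition(7, 3)
  expect_lt(abs(sum(odd$area) - 4 * pi), 1e-9)
  expect_lt(max(odd$area) / min(odd$area), 1 + 1e-9)

  expect_error(equal_area_partition(0), ">= 1")
})

test_that("residence density conserves time and normalises to uniform = 1", {
  part <- equal_area_partition(10)
  tr <- generate_sw_trajectory(spheroid_spec(0.53), duration = 600, dt = 0.1, seed = 3)
  dens <- residence_density(tr, part)
  # cell residence times sum to the trace duration
  times <- dens$density * attr(dens, "total_time") * dens$area / (4 * pi)
  expect_lt(abs(sum(times) - attr(dens, "total_time")), 1e-9)
  # area-weighted mean density is 1
  expect_lt(abs(sum(dens$density * dens$area) / (4 * pi) - 1), 1e-9)

  const <- gravity_trace(0:10, cbind(0, 0, rep(-1, 11)))
  cd <- residence_density(const, part)
  expect_equal(sort(unique(cd$density)), c(0, 100))
  expect_equal(sum(cd$density > 0), 1)

  expect_error(residence_density(tibble::tibble(), part), "gravity trace|empty")
})

test_that("uniform draws fill every cell at density close to 1", {
  part <- equal_area_partition(10)
  set.seed(8)
  u <- sample_spheroid_directions(spheroid_spec(0), 2e5)
  dens <- sample_density(u, part)
  expect_true(all(dens$density > 0.85 & dens$density < 1.15))
})

test_that("analytic spheroid density is exact for the sphere and matches the sampler", {
  part <- equal_area_partition(10)
  em0 <- expected_spheroid_density(spheroid_spec(0), part)
  expect_lt(max(abs(em0$density - 1)), 1e-9)

  em <- expected_spheroid_density(spheroid_spec(0.53), part)
  expect_lt(abs(sum(em$density * em$area / (4 * pi)) - 1), 1e-9)

  u <- sample_spheroid_directions(spheroid_spec(0.53), 2e5, seed = 31)
  cmp <- compare_density_maps(sample_density(u, part), em, n_obs = 2e5)
  expect_gt(cmp$p_value, 0.001)

  # residence mode sits in the polar band containing the mean-g direction
  # (the symmetry axis, (0, 0, -1))
  tr_dens <- sample_density(u, part)
  top <- which.max(tr_dens$density)
  expect_lte(tr_dens$cos_hi[top], -0.8 + 1e-9)
})

test_that("uniformity metrics have their closed-form extremes", {
  part <- equal_area_partition(10)
  flat <- rpmsim:::new_density_map(part, rep(1, 100), 3600)
  m <- uniformity_metrics(flat)
  expect_equal(m$cv, 0)
  expect_equal(m$chisq, 0)

  conc <- rpmsim:::new_density_map(part, c(100, rep(0, 99)), 3600)
  expect_equal(uniformity_metrics(conc)$cv, sqrt(99), tolerance = 1e-12)

  # CV invariant to total-time scaling
  short <- rpmsim:::new_density_map(part, c(100, rep(0, 99)), 10)
  expect_equal(uniformity_metrics(short)$cv, uniformity_metrics(conc)$cv)
})

test_that("density maps serialise to the band/sector CSV layout", {
  part <- equal_area_partition(5, 4)
  em <- expected_spheroid_density(spheroid_spec(0.25), part)
  path <- withr::local_tempfile(fileext = ".csv")
  write_density_csv(em, path)
  expect_identical(readLines(path, n = 1), "band_lo,band_hi,az_lo,az_hi,density")
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 20)
  expect_true(all(df$band_lo < df$band_hi))
  expect_equal(df$density, em$density, tolerance = 1e-6)
})
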