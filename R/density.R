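#' Equal-area partition of the unit sphere
#'
#' Band-and-sector scheme: polar bands with equally spaced `cos(theta)`
#' boundaries (each band then has equal area) and the same number of
#' azimuthal sectors per band, so every cell subtends the same solid angle
#' `4*pi / (n_bands * cells_per_band)`.
#'
#' @param n_bands Number of polar bands (>= 1).
#' @param cells_per_band Azimuthal sectors per band (>= 1); default
#'   `n_bands`, giving the 100-cell map used for density diagnostics when
#'   `n_bands = 10`.
#' @return A tibble of class `sphere_partition` with columns `cell`,
#'   `cos_lo`, `cos_hi` (band limits in `cos(theta)`, theta from +z),
#'   `az_lo`, `az_hi` (radians) and `area` (steradians).
#' @examples
#' equal_area_partition(10)
#' @export
equal_area_partition <- function(n_bands, cells_per_band = n_bands) {
  if (!is.numeric(n_bands) || n_bands < 1) stop("`n_bands` must be >= 1", call. = FALSE)
  if (!is.numeric(cells_per_band) || cells_per_band < 1) {
    stop("`cells_per_band` must be >= 1", call. = FALSE)
  }
  n_bands <- as.integer(n_bands)
  cells_per_band <- as.integer(cells_per_band)
  cos_breaks <- seq(-1, 1, length.out = n_bands + 1)
  az_breaks <- seq(0, 2 * pi, length.out = cells_per_band + 1)
  grid <- tidyr::expand_grid(band = seq_len(n_bands), sector = seq_len(cells_per_band))
  out <- tibble::tibble(
    cell = seq_len(nrow(grid)),
    cos_lo = cos_breaks[grid$band],
    cos_hi = cos_breaks[grid$band + 1],
    az_lo = az_breaks[grid$sector],
    az_hi = az_breaks[grid$sector + 1],
    area = (cos_breaks[grid$band + 1] - cos_breaks[grid$band]) *
      (az_breaks[grid$sector + 1] - az_breaks[grid$sector])
  )
  class(out) <- c("sphere_partition", class(out))
  out
}

partition_cell_of <- function(partition, u) {
  n_bands <- length(unique(partition$cos_lo))
  cells_per_band <- nrow(partition) / n_bands
  cosz <- pmin(pmax(u[, 3], -1), 1)
  az <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  band <- pmin(pmax(ceiling((cosz + 1) / 2 * n_bands), 1), n_bands)
  sector <- pmin(pmax(ceiling(az / (2 * pi) * cells_per_band), 1), cells_per_band)
  (band - 1) * cells_per_band + sector
}

new_density_map <- function(partition, density, total_time) {
  out <- tibble::tibble(
    cell = partition$cell,
    cos_lo = partition$cos_lo, cos_hi = partition$cos_hi,
    az_lo = partition$az_lo, az_hi = partition$az_hi,
    area = partition$area,
    density = density
  )
  class(out) <- c("density_map", class(out))
  attr(out, "total_time") <- total_time
  out
}

#' Residence-time density of a gravity trace on the sphere
#'
#' Bins the gravity directions of a trace into an equal-area partition,
#' weighting each sample by its trapezoidal share of the total time, and
#' normalises residence time per unit solid angle so that 1 is the uniform
#' density (the convention of the orientation-distribution plots: a cell
#' at density 1 is visited exactly as much as under perfect randomisation).
#'
#' @param trace A [gravity_trace()].
#' @param partition An [equal_area_partition()].
#' @return A `density_map` tibble (columns of the partition plus
#'   `density`), with total trace duration in attribute `"total_time"`.
#'   The area-weighted mean density is 1.
#' @export
residence_density <- function(trace, partition) {
  assert_trace(trace)
  u <- as.matrix(trace[, c("ux", "uy", "uz")])
  w <- if (nrow(trace) == 1) 1 else trapezoid_weights(trace$t)
  total <- sum(w)
  cells <- partition_cell_of(partition, u)
  time_in <- vapply(partition$cell, function(cl) sum(w[cells == cl]), numeric(1))
  density <- (time_in / total) / (partition$area / (4 * pi))
  new_density_map(partition, density, total)
}

#' Density of point samples on the sphere
#'
#' Like [residence_density()] but for i.i.d. direction draws (equal
#' weights), e.g. the output of [sample_spheroid_directions()].
#'
#' @param u An `n` x 3 matrix of unit vectors.
#' @param partition An [equal_area_partition()].
#' @return A `density_map` tibble.
#' @export
sample_density <- function(u, partition) {
  u <- matrix(u, ncol = 3)
  cells <- partition_cell_of(partition, u)
  counts <- tabulate(cells, nbins = nrow(partition))
  density <- (counts / nrow(u)) / (partition$area / (4 * pi))
  new_density_map(partition, density, nrow(u))
}

#' Analytic spheroid residence density per partition cell
#'
#' Expected residence density of the spheroid target distribution in each
#' cell, computed in closed form from the same axial density the sampler
#' uses: the cell mass is the z-measure of the band (via the antiderivative
#' of `sqrt(1 - e^2 z^2)`) times the azimuth fraction, mapped through the
#' focus projection. Masses sum to 1; the area-weighted mean density is 1.
#'
#' Assumes the partition's polar axis (+z) is aligned with
#' `-symmetry_axis` of the spec, the default geometry (symmetry axis
#' `(0, 0, -1)`).
#'
#' @param spec A [spheroid_spec()].
#' @param partition An [equal_area_partition()].
#' @return A `density_map` tibble.
#' @export
expected_spheroid_density <- function(spec, partition) {
  if (!inherits(spec, "spheroid_spec")) stop("`spec` must be a spheroid_spec", call. = FALSE)
  e <- spec$eccentricity
  total_z <- spheroid_area_cdf_raw(e, 1) - spheroid_area_cdf_raw(e, -1)
  # with symmetry axis (0,0,-1) the sampler's global z component equals the
  # focus-frame axial component a(z) = (z-e)/(1-ez), increasing in z, so
  # cos(theta) in [lo, hi] maps to z in [z(lo), z(hi)]
  z_of_u <- function(u) (u + e) / (1 + e * u)
  band_mass <- function(lo, hi) {
    (spheroid_area_cdf_raw(e, z_of_u(hi)) -
       spheroid_area_cdf_raw(e, z_of_u(lo))) / total_z
  }
  mass <- mapply(band_mass, partition$cos_lo, partition$cos_hi) *
    (partition$az_hi - partition$az_lo) / (2 * pi)
  density <- mass / (partition$area / (4 * pi))
  new_density_map(partition, density, NA_real_)
}

#' Uniformity metrics of a density map
#'
#' Descriptive statistics quantifying how close a residence distribution
#' is to uniform: the coefficient of variation of the (equal-area) cell
#' densities, their range, and a chi-square statistic of the cell masses
#' against the uniform expectation with its tail probability.
#'
#' @param map A `density_map`.
#' @return A one-row tibble: `cv`, `min`, `max`, `chisq`, `p_value`,
#'   `n_cells`.
#' @examples
#' part <- equal_area_partition(10)
#' uniformity_metrics(expected_spheroid_density(spheroid_spec(0), part))
#' @export
uniformity_metrics <- function(map) {
  if (!inherits(map, "density_map")) stop("`map` must be a density_map", call. = FALSE)
  d <- map$density
  n <- length(d)
  # equal-area cells: mass fraction per cell is density / sum(density)
  frac <- d / sum(d)
  total <- attr(map, "total_time")
  # Pearson statistic on residence "counts" (time units or draws)
  scale <- if (is.finite(total %||% NA_real_)) total else 1
  chisq_stat <- scale * sum((frac - 1 / n)^2) * n
  tibble::tibble(
    cv = sqrt(mean((d - mean(d))^2)) / mean(d),
    min = min(d),
    max = max(d),
    chisq = chisq_stat,
    p_value = stats::pchisq(chisq_stat, df = n - 1, lower.tail = FALSE),
    n_cells = n
  )
}

#' Chi-square comparison of an observed map against an expected map
#'
#' Compares per-cell observed masses (from residence times or sample
#' counts) with expected masses from an analytic target, using the usual
#' Pearson statistic on counts.
#'
#' @param observed A `density_map` built from `n` samples
#'   ([sample_density()]) or a timed trace ([residence_density()]).
#' @param expected A `density_map` of expected densities (e.g.
#'   [expected_spheroid_density()]).
#' @param n_obs Number of independent observations behind `observed`
#'   (defaults to the map's `total_time` attribute).
#' @return A one-row tibble: `chisq`, `df`, `p_value`.
#' @export
compare_density_maps <- function(observed, expected, n_obs = attr(observed, "total_time")) {
  stopifnot(nrow(observed) == nrow(expected))
  obs_frac <- observed$density * observed$area / (4 * pi)
  exp_frac <- expected$density * expected$area / (4 * pi)
  keep <- exp_frac > 0
  obs_counts <- obs_frac[keep] * n_obs
  exp_counts <- exp_frac[keep] * n_obs
  chisq <- sum((obs_counts - exp_counts)^2 / exp_counts)
  df <- sum(keep) - 1
  tibble::tibble(chisq = chisq, df = df,
                 p_value = stats::pchisq(chisq, df = df, lower.tail = FALSE))
}

#' Write a density map as CSV
#'
#' Header `band_lo,band_hi,az_lo,az_hi,density`: band limits as polar
#' angles in radians (from +z), azimuth limits in radians, density
#' dimensionless (1 = uniform).
#'
#' @param map A `density_map`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(map, path) {
  df <- data.frame(
    band_lo = acos(pmin(pmax(map$cos_hi, -1), 1)),
    band_hi = acos(pmin(pmax(map$cos_lo, -1), 1)),
    az_lo = map$az_lo,
    az_hi = map$az_hi,
    density = map$density
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
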