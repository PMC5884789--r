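#' Prolate-spheroid specification for the software partial-gravity paradigm
#'
#' The software paradigm steers the RPM so that the gravity direction, seen
#' from the sample, spends equal time per unit area on the surface of a
#' prolate spheroid with one focal point at the rotation centre
#' (semi-major axis normalised to 1, so the focal distance equals the
#' eccentricity). Viewed from that focus, residence time per solid angle is
#' larger on the near-vertex side, so the time-averaged gravity vector is
#' non-zero; its magnitude grows monotonically with eccentricity from 0
#' (sphere, simulated microgravity) towards 1.
#'
#' @param eccentricity Dimensionless, in `[0, 1)`. 0 is a sphere.
#' @param symmetry_axis Unit 3-vector, the direction in the sample frame
#'   along which the mean gravity vector is delivered (default sample
#'   "down", `c(0, 0, -1)`).
#' @return A `spheroid_spec` list with fields `eccentricity`, `semi_major`
#'   (1), `semi_minor`, `focal_distance`, `symmetry_axis`.
#' @examples
#' spheroid_spec(0.53)
#' @export
spheroid_spec <- function(eccentricity, symmetry_axis = c(0, 0, -1)) {
  if (!is.numeric(eccentricity) || length(eccentricity) != 1 ||
      !is.finite(eccentricity) || eccentricity < 0 || eccentricity >= 1) {
    stop("`eccentricity` must be a single number in [0, 1)", call. = FALSE)
  }
  if (length(symmetry_axis) != 3 || any(!is.finite(symmetry_axis)) ||
      sum(symmetry_axis^2) == 0) {
    stop("`symmetry_axis` must be a finite non-zero 3-vector", call. = FALSE)
  }
  symmetry_axis <- symmetry_axis / sqrt(sum(symmetry_axis^2))
  structure(list(
    eccentricity = eccentricity,
    semi_major = 1,
    semi_minor = sqrt(1 - eccentricity^2),
    focal_distance = eccentricity,
    symmetry_axis = symmetry_axis
  ), class = "spheroid_spec")
}

#' @export
print.spheroid_spec <- function(x, ...) {
  cat(sprintf("<spheroid_spec> e = %.4f (b = %.4f, c = %.4f), axis = (%g, %g, %g)\n",
              x$eccentricity, x$semi_minor, x$focal_distance,
              x$symmetry_axis[1], x$symmetry_axis[2], x$symmetry_axis[3]))
  cat(sprintf("  mean gravity factor p = %.4f g\n", mean_g_from_eccentricity(x$eccentricity)))
  invisible(x)
}

# Surface geometry, parametrised by the axial coordinate z in [-1, 1]
# (semi-major = 1, focus at +e on the axis):
#   area element      dA            proportional to sqrt(1 - e^2 z^2) dz
#   focus-point range d(z)        = 1 - e z
#   direction from focus: axial component a(z) = (z - e) / (1 - e z),
#                         transverse          = sqrt(1-e^2) sqrt(1-z^2) / (1 - e z)
# and a^2 + transverse^2 = 1 identically.
spheroid_axial_component <- function(e, z) (z - e) / (1 - e * z)

spheroid_transverse_component <- function(e, z) {
  sqrt(1 - e^2) * sqrt(pmax(1 - z^2, 0)) / (1 - e * z)
}

spheroid_area_density <- function(e, z) sqrt(1 - e^2 * z^2)

# Antiderivative of sqrt(1 - e^2 z^2); used for analytic cell masses.
spheroid_area_cdf_raw <- function(e, z) {
  if (e == 0) return(z)
  (z * sqrt(1 - e^2 * z^2) + asin(e * z) / e) / 2
}

#' Mean gravity factor of a spheroid residence distribution
#'
#' For a gravity direction distributed uniformly per unit area over a
#' prolate spheroid of eccentricity `e` viewed from a focus, returns the
#' magnitude `p` of the time-averaged gravity vector (in g units):
#' \deqn{p(e) = \left|\int_{-1}^{1} (e - z)\sqrt{\frac{1+ez}{1-ez}}\,dz\right|
#'       \Big/ \int_{-1}^{1} \sqrt{1 - e^2 z^2}\,dz}
#' evaluated by adaptive quadrature (absolute tolerance 1e-8 per
#' integral; both integrands are finite at the endpoints). `p` is strictly
#' increasing in `e`, with `p(0) = 0` and `p -> 1` as `e -> 1`.
#'
#' @param e Eccentricity, in `[0, 1)`. Vectorised.
#' @return Mean gravity factor(s) in g units.
#' @examples
#' mean_g_from_eccentricity(c(0, 0.25, 0.53, 0.87))
#' @export
mean_g_from_eccentricity <- function(e) {
  if (!is.numeric(e) || any(!is.finite(e)) || any(e < 0) || any(e >= 1)) {
    stop("`e` must be in [0, 1)", call. = FALSE)
  }
  vapply(e, function(ei) {
    if (ei == 0) return(0)
    num <- stats::integrate(function(z) (ei - z) * sqrt((1 + ei * z) / (1 - ei * z)),
                            -1, 1, abs.tol = 1e-8, rel.tol = 1e-10)$value
    den <- stats::integrate(function(z) spheroid_area_density(ei, z),
                            -1, 1, abs.tol = 1e-8, rel.tol = 1e-10)$value
    abs(num) / den
  }, numeric(1))
}

#' Eccentricity required for a target mean gravity factor
#'
#' Inverts [mean_g_from_eccentricity()] by bracketed bisection on
#' `[0, 1 - 1e-9]` (tolerance 1e-6); strict monotonicity of `p(e)`
#' guarantees a unique root. This is the map that turns a desired partial
#' gravity level (e.g. 0.17 g Moon, 0.38 g Mars) into the machine setting.
#'
#' @param p Target mean gravity factor in g units, in `[0, 1)`. Vectorised.
#' @return Eccentricity value(s) in `[0, 1)`.
#' @examples
#' eccentricity_for_mean_g(c(0.17, 0.38, 0.50, 0.75))
#' @export
eccentricity_for_mean_g <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("`p` must be in [0, 1)", call. = FALSE)
  }
  vapply(p, function(pi_) {
    if (pi_ == 0) return(0)
    stats::uniroot(function(e) mean_g_from_eccentricity(e) - pi_,
                   lower = 0, upper = 1 - 1e-9, tol = 1e-6)$root
  }, numeric(1))
}

#' Sample gravity directions from the spheroid residence distribution
#'
#' Draws i.i.d. unit vectors distributed as the stationary gravity
#' direction of the software paradigm: the axial surface coordinate `z` is
#' drawn with density proportional to `sqrt(1 - e^2 z^2)` on `[-1, 1]`
#' (rejection sampling under a uniform envelope), azimuth uniform on
#' `[0, 2*pi)`; each vector is the unit direction from the focus to the
#' surface point, oriented so the distribution mean lies along the spec's
#' `symmetry_axis`.
#'
#' @param spec A [spheroid_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sample_spheroid_directions <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "spheroid_spec")) stop("`spec` must be a spheroid_spec", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  e <- spec$eccentricity
  z <- numeric(0)
  while (length(z) < n) {
    m <- max(1000L, as.integer(ceiling((n - length(z)) * 1.3)))
    cand <- stats::runif(m, -1, 1)
    z <- c(z, cand[stats::runif(m) < spheroid_area_density(e, cand)])
  }
  z <- z[seq_len(n)]
  phi <- stats::runif(n, 0, 2 * pi)
  # the uniform-surface mean of a(z) is negative (near-vertex side); flip
  # the axial unit so the mean gravity vector is delivered along the
  # symmetry axis (sample "down")
  axial <- -spheroid_axial_component(e, z)
  trans <- spheroid_transverse_component(e, z)
  basis <- axis_basis(spec$symmetry_axis)
  u <- outer(axial, basis$axis) +
    outer(trans * cos(phi), basis$e1) +
    outer(trans * sin(phi), basis$e2)
  u / sqrt(rowSums(u^2))
}

# Orthonormal basis with the given axis as third direction.
axis_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  helper <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- helper - sum(helper * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(axis = axis, e1 = e1, e2 = e2)
}
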