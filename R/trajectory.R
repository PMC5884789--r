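#' Gravity traces
#'
#' A gravity trace is a tibble of class `gravity_trace` with columns
#' `t` (seconds, strictly increasing), `ux`, `uy`, `uz` (unit direction of
#' lab gravity expressed in the sample frame) and `m` (gravity magnitude in
#' g units, 1 for a trace recorded on an RPM under Earth gravity).
#' Trace-level metadata (seed, waypoint count, rate clipping) is kept in
#' attributes and carried into reports.
#'
#' @param t Numeric vector of sample times in seconds.
#' @param u Numeric matrix (n x 3) of unit gravity directions.
#' @param m Gravity magnitudes in g units (scalar or length n).
#' @param meta Named list of metadata stored as attribute `"meta"`.
#' @return A `gravity_trace` tibble.
#' @export
gravity_trace <- function(t, u, m = 1, meta = list()) {
  u <- matrix(u, ncol = 3)
  if (length(t) != nrow(u)) stop("`t` and `u` lengths differ", call. = FALSE)
  if (length(t) == 0) stop("a gravity trace needs at least one sample", call. = FALSE)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  norms <- sqrt(rowSums(u^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop("every gravity direction must be unit norm (within 1e-9)", call. = FALSE)
  }
  m <- rep_len(m, length(t))
  if (any(m < 0)) stop("gravity magnitude must be non-negative", call. = FALSE)
  out <- tibble::tibble(t = as.numeric(t), ux = u[, 1], uy = u[, 2], uz = u[, 3], m = m)
  class(out) <- c("gravity_trace", class(out))
  attr(out, "meta") <- meta
  out
}

trace_meta <- function(trace) attr(trace, "meta") %||% list()

assert_trace <- function(trace) {
  if (!is.data.frame(trace) || !all(c("t", "ux", "uy", "uz", "m") %in% names(trace))) {
    stop("expected a gravity trace with columns t, ux, uy, uz, m", call. = FALSE)
  }
  if (nrow(trace) == 0) stop("gravity trace is empty", call. = FALSE)
  invisible(trace)
}

#' Integrate a gimbal rate profile into a gravity trace
#'
#' Advances the outer and inner gimbal angles by explicit fixed-step
#' integration of a rate profile and records the gravity direction seen by
#' the sample at every step. Rates are piecewise-constant per step (exact
#' for the piecewise-constant drivers used throughout), and are clipped to
#' `max_rate`; any clipping is flagged in the trace metadata. Internal
#' angles are left unwrapped to preserve continuity.
#'
#' @param rate_profile Function `t -> c(outer_rate, inner_rate)` in rad/s.
#' @param duration Total simulated time, seconds (> 0).
#' @param dt Integration step, seconds (0 < dt <= duration).
#' @param max_rate Maximum angular speed per frame, rad/s. Default is the
#'   RPM standard maximum of 60 deg/s.
#' @param initial Initial `c(outer_angle, inner_angle)` in radians.
#' @return A [gravity_trace()] with `ceiling(duration/dt) + 1` samples and
#'   metadata fields `clipped`, `final_angles` (wrapped to `[0, 2*pi)`).
#' @examples
#' tr <- integrate_gimbal_trajectory(function(t) c(pi / 3, 0), duration = 6, dt = 0.1)
#' time_averaged_gravity(tr)
#' @export
integrate_gimbal_trajectory <- function(rate_profile, duration, dt,
                                        max_rate = pi / 3, initial = c(0, 0)) {
  if (!is.function(rate_profile)) stop("`rate_profile` must be a function", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0 || dt > duration) {
    stop("`dt` must satisfy 0 < dt <= duration", call. = FALSE)
  }
  n_steps <- ceiling(duration / dt)
  times <- c(seq(0, by = dt, length.out = n_steps), duration)
  # guard against a duplicated endpoint when duration is a multiple of dt
  if (times[n_steps + 1] - times[n_steps] < dt * 1e-9) times <- times[-(n_steps + 1)]
  n <- length(times)
  angles <- matrix(0, nrow = n, ncol = 2)
  angles[1, ] <- initial
  clipped <- FALSE
  for (i in seq_len(n - 1)) {
    rates <- rate_profile(times[i])
    if (any(abs(rates) > max_rate)) {
      clipped <- TRUE
      rates <- pmin(pmax(rates, -max_rate), max_rate)
    }
    angles[i + 1, ] <- angles[i, ] + rates * (times[i + 1] - times[i])
  }
  u <- t(vapply(seq_len(n), function(i) {
    gravity_in_sample_frame(orientation_from_gimbal(angles[i, 1], angles[i, 2]))
  }, numeric(3)))
  gravity_trace(times, u, m = 1, meta = list(
    clipped = clipped,
    final_angles = wrap_angle(angles[n, ]),
    max_rate = max_rate
  ))
}

#' Random gimbal rate profile ("real random mode")
#'
#' Piecewise-constant rate profile emulating an RPM's real random mode:
#' each frame independently redraws its rate (random direction, uniform
#' magnitude up to `max_rate`) after a random holding interval.
#'
#' @param max_rate Maximum angular speed per frame, rad/s.
#' @param interval Range (seconds) from which holding intervals are drawn
#'   uniformly.
#' @param horizon Total time covered by the pre-drawn schedule, seconds.
#' @return A function `t -> c(outer_rate, inner_rate)` suitable for
#'   [integrate_gimbal_trajectory()]. Uses the current RNG state when
#'   constructed; seed the session (or pass through the simulate drivers)
#'   for reproducibility.
#' @export
random_rate_profile <- function(max_rate = pi / 3, interval = c(1, 10), horizon = 7200) {
  draw_schedule <- function() {
    n_max <- ceiling(horizon / interval[1]) + 1
    holds <- stats::runif(n_max, interval[1], interval[2])
    breaks <- c(0, cumsum(holds))
    rates <- stats::runif(n_max, -max_rate, max_rate)
    list(breaks = breaks, rates = rates)
  }
  outer <- draw_schedule()
  inner <- draw_schedule()
  function(t) {
    c(outer$rates[findInterval(t, outer$breaks)],
      inner$rates[findInterval(t, inner$breaks)])
  }
}

#' Time-averaged gravity of a trace
#'
#' Computes the time-weighted mean of the gravity vector `m * u` using
#' trapezoidal weights over `t`, and the magnitude of that mean vector —
#' the actual partial gravity factor realised by a trajectory, to be
#' compared with the desired one.
#'
#' @param trace A [gravity_trace()].
#' @return A list with `mean_vector` (3-vector, g units) and `magnitude`
#'   (its Euclidean norm, g units).
#' @export
time_averaged_gravity <- function(trace) {
  assert_trace(trace)
  g <- as.matrix(trace[, c("ux", "uy", "uz")]) * trace$m
  if (nrow(trace) == 1) {
    v <- as.numeric(g[1, ])
    return(list(mean_vector = v, magnitude = sqrt(sum(v^2))))
  }
  w <- trapezoid_weights(trace$t)
  v <- as.numeric(colSums(g * w) / sum(w))
  list(mean_vector = v, magnitude = sqrt(sum(v^2)))
}

trapezoid_weights <- function(t) {
  n <- length(t)
  dt <- diff(t)
  c(dt[1] / 2, (dt[-(n - 1)] + dt[-1]) / 2, dt[n - 1] / 2)
}

# Running trapezoidal mean of m*u at every sample time (first sample: the
# instantaneous vector). Used by convergence reports.
running_mean_gravity <- function(trace) {
  g <- as.matrix(trace[, c("ux", "uy", "uz")]) * trace$m
  n <- nrow(g)
  if (n == 1) return(g)
  dt <- diff(trace$t)
  seg <- (g[-n, , drop = FALSE] + g[-1, , drop = FALSE]) / 2 * dt
  cum <- apply(seg, 2, cumsum)
  out <- rbind(g[1, ], cum / (trace$t[-1] - trace$t[1]))
  unname(out)
}

#' Write or read a gravity trace as CSV
#'
#' Plain UTF-8 CSV with header `t,ux,uy,uz,m` ('.' decimal separator):
#' seconds, dimensionless unit-vector components, g units.
#'
#' @param trace A [gravity_trace()].
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a [gravity_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  assert_trace(trace)
  utils::write.csv(as.data.frame(trace)[, c("t", "ux", "uy", "uz", "m")],
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  gravity_trace(df$t, as.matrix(df[, c("ux", "uy", "uz")]), m = df$m)
}
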