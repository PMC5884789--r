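#' Generate a software-paradigm partial-gravity trajectory
#'
#' Simulates the spheroid-based software paradigm: waypoint directions are
#' drawn i.i.d. from the spheroid residence distribution
#' ([sample_spheroid_directions()]) and the gravity direction moves from
#' one waypoint to the next along the shortest great-circle arc at the
#' maximum frame rate. The empirical residence distribution converges to
#' the spheroid target, and the time-averaged gravity magnitude converges
#' to [mean_g_from_eccentricity()] of the spec. With eccentricity 0 this is
#' a classic-RPM randomisation whose time-averaged gravity converges to 0.
#'
#' One admissible traversal of the target distribution; convergence speed
#' (not the stationary distribution) depends on this choice.
#'
#' @param spec A [spheroid_spec()].
#' @param duration Simulated time, seconds (> 0).
#' @param dt Sampling step, seconds (> 0).
#' @param max_rate Angular speed along the arc, rad/s (> 0); default the
#'   RPM standard maximum of 60 deg/s.
#' @param seed Integer seed recorded in the trace metadata.
#' @return A [gravity_trace()] with metadata `seed`, `n_waypoints`,
#'   `eccentricity`, `target_p`.
#' @examples
#' tr <- generate_sw_trajectory(spheroid_spec(0.53), duration = 600, dt = 0.1, seed = 1)
#' time_averaged_gravity(tr)$magnitude
#' @export
generate_sw_trajectory <- function(spec, duration, dt, max_rate = pi / 3, seed = 1) {
  if (!inherits(spec, "spheroid_spec")) stop("`spec` must be a spheroid_spec", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (!is.numeric(max_rate) || max_rate <= 0) stop("`max_rate` must be > 0", call. = FALSE)
  set.seed(seed)

  n <- ceiling(duration / dt) + 1
  times <- seq(0, by = dt, length.out = n)
  # waypoint pool, replenished on demand; expected arc ~ pi/2 radians
  pool <- sample_spheroid_directions(spec, max(64L, ceiling(duration * max_rate / (pi / 2)) + 16L))
  next_wp <- 1L
  take_waypoint <- function() {
    if (next_wp > nrow(pool)) {
      pool <<- sample_spheroid_directions(spec, nrow(pool))
      next_wp <<- 1L
    }
    w <- pool[next_wp, ]
    next_wp <<- next_wp + 1L
    w
  }

  u <- matrix(0, nrow = n, ncol = 3)
  u[1, ] <- pool[1, ]
  next_wp <- 2L
  cur <- u[1, ]
  target <- take_waypoint()
  n_waypoints <- 2L
  for (i in seq_len(n - 1)) {
    budget <- max_rate * dt
    # rotate toward successive waypoints until the step's angular budget
    # is spent, so motion continues seamlessly across waypoints
    repeat {
      ang <- angle_between(cur, target)
      if (ang > budget + 1e-12) {
        cur <- rotate_towards(cur, target, budget)
        break
      }
      budget <- budget - ang
      cur <- target
      target <- take_waypoint()
      n_waypoints <- n_waypoints + 1L
      if (budget <= 1e-12) break
    }
    u[i + 1, ] <- cur
  }
  gravity_trace(times, u, m = 1, meta = list(
    seed = seed,
    n_waypoints = n_waypoints,
    eccentricity = spec$eccentricity,
    target_p = mean_g_from_eccentricity(spec$eccentricity),
    max_rate = max_rate
  ))
}

angle_between <- function(a, b) {
  acos(min(1, max(-1, sum(a * b))))
}

# Rotate unit vector a towards unit vector b by `ang` radians along the
# great circle through both (slerp step).
rotate_towards <- function(a, b, ang) {
  total <- angle_between(a, b)
  if (total < 1e-12) return(a)
  if (abs(total - pi) < 1e-9) {
    # antipodal: pick any perpendicular direction deterministically
    perp <- axis_basis(a)$e1
    b <- cos(1e-6) * -a + sin(1e-6) * perp
    total <- angle_between(a, b)
  }
  out <- (sin(total - ang) * a + sin(ang) * b) / sin(total)
  out / sqrt(sum(out^2))
}

#' Two-state baseline partial-gravity trajectory
#'
#' The simplest partial-gravity scheme: point the sample along gravity for
#' a fraction `q = (p + 1) / 2` of the time and against gravity for the
#' remaining `1 - q`, giving a time-averaged gravity factor of exactly `p`
#' (up to `dt` discretisation of the switch time). Useful as a deterministic
#' baseline; unlike the spheroid paradigm it concentrates residence on two
#' orientations instead of spreading it over a surface.
#'
#' @param p Target mean gravity factor, g units, in `[0, 1]`.
#' @param duration Total time, seconds (> 0).
#' @param dt Sampling step, seconds (> 0).
#' @return A [gravity_trace()] with metadata `target_p`, `q`.
#' @examples
#' tr <- two_state_trajectory(0.38, duration = 3600, dt = 1)
#' time_averaged_gravity(tr)$magnitude
#' @export
two_state_trajectory <- function(p, duration, dt) {
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p < 0 || p > 1) {
    stop("`p` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  q <- (p + 1) / 2
  n <- ceiling(duration / dt) + 1
  times <- seq(0, by = dt, length.out = n)
  down <- times <= q * duration
  u <- cbind(0, 0, ifelse(down, -1, 1))
  gravity_trace(times, u, m = 1, meta = list(target_p = p, q = q))
}

#' Convergence of the realised mean gravity towards the target
#'
#' Tracks `| ||running time-averaged gravity up to t|| - p |` — the error
#' between the actual and the desired partial gravity factor — at every
#' sample time of a trace.
#'
#' @param trace A [gravity_trace()].
#' @param desired_p Desired mean gravity factor, g units.
#' @return A tibble of class `convergence_report` with columns `t`
#'   (seconds), `mean_g` (running time-averaged gravity magnitude, g) and
#'   `error` (g units, >= 0).
#' @examples
#' tr <- two_state_trajectory(0.38, duration = 3600, dt = 1)
#' tail(convergence_report(tr, 0.38))
#' @export
convergence_report <- function(trace, desired_p) {
  assert_trace(trace)
  if (!is.numeric(desired_p) || length(desired_p) != 1 || desired_p < 0) {
    stop("`desired_p` must be a single non-negative number", call. = FALSE)
  }
  run <- running_mean_gravity(trace)
  mag <- sqrt(rowSums(run^2))
  out <- tibble::tibble(t = trace$t, mean_g = mag, error = abs(mag - desired_p))
  class(out) <- c("convergence_report", class(out))
  attr(out, "desired_p") <- desired_p
  out
}
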