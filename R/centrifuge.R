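#' @importFrom rlang %||%
NULL

G0 <- 9.81  # m/s^2; the value used for all g conversions in this package

to_rad_s <- function(speed, unit) {
  if (missing(unit) || is.null(unit) || !unit %in% c("rpm", "deg_s", "rad_s")) {
    stop('`unit` must be one of "rpm", "deg_s", "rad_s"', call. = FALSE)
  }
  switch(unit,
    rpm = speed * 2 * pi / 60,
    deg_s = speed * pi / 180,
    rad_s = speed
  )
}

#' Centripetal g-level of a centrifuge setting
#'
#' `g = omega^2 r / g0` with `g0 = 9.81 m/s^2`, `omega` converted from the
#' tagged unit. This is the net gravity level a sample at radius `r`
#' experiences on a centrifuge riding an RPM, since the RPM nulls the
#' static component.
#'
#' @param speed Angular speed (>= 0), in the unit given by `unit`.
#' @param radius Distance from the rotation axis, metres (> 0). Vectorised
#'   with `speed`.
#' @param unit One of `"rpm"`, `"deg_s"`, `"rad_s"`. No default: the unit
#'   tag is required.
#' @return g-level(s) in g units.
#' @examples
#' centripetal_g(53, 0.12, "rpm")   # Mars setting
#' centripetal_g(60, 0.20, "deg_s") # residual g at the platter edge
#' @export
centripetal_g <- function(speed, radius, unit) {
  if (any(!is.finite(speed)) || any(speed < 0)) stop("`speed` must be >= 0", call. = FALSE)
  if (any(!is.finite(radius)) || any(radius <= 0)) stop("`radius` must be > 0", call. = FALSE)
  to_rad_s(speed, unit)^2 * radius / G0
}

#' Integer rpm needed for a target g-level
#'
#' Inverts [centripetal_g()] and rounds to the nearest integer rpm (ties to
#' even), the granularity at which the centrifuge controller is set.
#'
#' @param target_g Target g-level (>= 0), g units.
#' @param radius Sample radius, metres (> 0).
#' @return Integer rpm.
#' @examples
#' solve_rpm(0.38, 0.12) # 53 rpm
#' @export
solve_rpm <- function(target_g, radius) {
  if (any(!is.finite(target_g)) || any(target_g < 0)) stop("`target_g` must be >= 0", call. = FALSE)
  if (any(!is.finite(radius)) || any(radius <= 0)) stop("`radius` must be > 0", call. = FALSE)
  as.integer(round(60 / (2 * pi) * sqrt(target_g * G0 / radius)))
}

#' Residual g from RPM frame rotation
#'
#' A sample displaced from the RPM rotation centre feels a parasitic
#' centripetal acceleration from the frame rotation itself. At the RPM
#' standard maximum rotation speed of 60 deg/s and a 0.20 m platter radius
#' this residual is about 0.02 g, superimposed onto whatever partial
#' gravity level the centrifuge generates.
#'
#' @param frame_rate RPM frame rotation speed, deg/s (>= 0).
#' @param platter_radius Worst-case sample displacement from the rotation
#'   centre, metres (> 0).
#' @return Residual g-level, g units.
#' @examples
#' residual_g(60, 0.20)
#' @export
residual_g <- function(frame_rate, platter_radius) {
  centripetal_g(frame_rate, platter_radius, unit = "deg_s")
}

#' Relative error of the residual g against a target level
#'
#' @param residual Residual g, g units (>= 0).
#' @param target Target partial gravity level, g units (> 0).
#' @return Percentage `100 * residual / target`.
#' @examples
#' relative_residual_error(residual_g(60, 0.20), 0.38) # ~5% for a Mars run
#' @export
relative_residual_error <- function(residual, target) {
  if (any(!is.finite(residual)) || any(residual < 0)) stop("`residual` must be >= 0", call. = FALSE)
  if (any(!is.finite(target)) || any(target <= 0)) stop("`target` must be > 0", call. = FALSE)
  100 * residual / target
}

#' Combine a centrifuge g-level with the RPM residual g
#'
#' The direction of the residual relative to the centrifuge vector is
#' time-varying, so three combination rules are offered: `"interval"`
#' (default; the bound `[g - res, g + res]`), `"scalar_add"` (same
#' interval, reported with the worst-case high end as nominal pessimum),
#' and `"rss"` (root-sum-square single value, appropriate if the residual
#' averages out in direction).
#'
#' @param g_level Centrifuge g-level, g units.
#' @param residual Residual g, g units.
#' @param rule One of `"interval"`, `"scalar_add"`, `"rss"`.
#' @return A tibble with columns `nominal`, `low`, `high`, `rule`.
#' @examples
#' combined_g(0.38, residual_g(60, 0.20))
#' @export
combined_g <- function(g_level, residual, rule = c("interval", "scalar_add", "rss")) {
  rule <- match.arg(rule)
  if (any(!is.finite(g_level)) || any(g_level < 0)) stop("`g_level` must be >= 0", call. = FALSE)
  if (any(!is.finite(residual)) || any(residual < 0)) stop("`residual` must be >= 0", call. = FALSE)
  bounds <- switch(rule,
    interval = ,
    scalar_add = list(low = pmax(g_level - residual, 0), high = g_level + residual),
    rss = {
      v <- sqrt(g_level^2 + residual^2)
      list(low = v, high = v)
    }
  )
  tibble::tibble(nominal = g_level, low = bounds$low, high = bounds$high, rule = rule)
}

#' g-gradient across a sample's radial extent
#'
#' At fixed angular speed the centrifugal g-level is linear in radius, so a
#' sample of finite radial extent sees a gradient `delta_g` proportional to
#' its extent — the reason large-platter centrifuges are preferred.
#'
#' @param rpm Angular speed, rpm.
#' @param r_center Sample centre radius, metres.
#' @param sample_extent Radial extent of the sample, metres (>= 0;
#'   `r_center - sample_extent/2` must stay positive).
#' @return A tibble with `g_min`, `g_max`, `g_center`, `delta_g`, and
#'   `rel_gradient` (`delta_g / g_center`).
#' @examples
#' g_gradient(53, 0.12, 0.02)
#' @export
g_gradient <- function(rpm, r_center, sample_extent) {
  if (any(sample_extent < 0)) stop("`sample_extent` must be >= 0", call. = FALSE)
  r_in <- r_center - sample_extent / 2
  if (any(r_in <= 0)) stop("inner radius must be positive", call. = FALSE)
  g_in <- centripetal_g(rpm, r_in, "rpm")
  g_out <- centripetal_g(rpm, r_center + sample_extent / 2, "rpm")
  g_c <- centripetal_g(rpm, r_center, "rpm")
  tibble::tibble(g_min = g_in, g_max = g_out, g_center = g_c,
                 delta_g = g_out - g_in, rel_gradient = (g_out - g_in) / g_c)
}

#' Equi-gravity sample positions on the centrifuge platter
#'
#' Places `n` points evenly along the arc of constant radius
#' `target_radius` (hence constant centrifugal g) clipped to the interior
#' of a circular dish whose centre sits at `dish_center_radius` from the
#' rotation axis (dish centre on the +x axis).
#'
#' @param dish_center_radius Dish centre distance from the rotation axis, m.
#' @param dish_diameter Dish diameter, m (default 0.09, a 9 cm Petri dish).
#' @param target_radius Equi-gravity radius, m; the arc must intersect the
#'   dish.
#' @param n Number of positions (>= 1).
#' @return A tibble with columns `x`, `y` (metres, platter coordinates) and
#'   `radius` (all equal to `target_radius`).
#' @examples
#' equigravity_positions(0.12, 0.09, 0.12, n = 25)
#' @export
equigravity_positions <- function(dish_center_radius, dish_diameter = 0.09,
                                  target_radius, n) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  r_dish <- dish_diameter / 2
  lo <- dish_center_radius - r_dish
  hi <- dish_center_radius + r_dish
  if (target_radius <= max(lo, 0) || target_radius >= hi) {
    stop(sprintf(
      "the equi-gravity arc at radius %.4f m misses the dish; feasible range is (%.4f, %.4f) m",
      target_radius, max(lo, 0), hi), call. = FALSE)
  }
  # half-angle (about the rotation axis) of the arc inside the dish:
  # law of cosines in the triangle (axis, dish centre, arc point)
  cos_half <- (target_radius^2 + dish_center_radius^2 - r_dish^2) /
    (2 * target_radius * dish_center_radius)
  half <- acos(min(1, max(-1, cos_half)))
  # keep positions strictly inside the dish rim
  half <- half * 0.98
  theta <- if (n == 1) 0 else seq(-half, half, length.out = n)
  tibble::tibble(
    x = target_radius * cos(theta),
    y = target_radius * sin(theta),
    radius = target_radius
  )
}

#' Plan a hardware partial-gravity run
#'
#' Turns a target g-level and sample radius into a centrifuge settings
#' block: the integer rpm, the realised g at that rpm, the residual g from
#' the RPM frame rotation, its relative error against the target, and the
#' g-gradient over the sample extent.
#'
#' @param target_g Target g-level, g units.
#' @param radius Sample radius, metres.
#' @param frame_rate RPM frame rotation speed used for the residual, deg/s.
#' @param platter_radius Platter radius for the worst-case residual, m.
#' @param sample_extent Sample radial extent for the gradient, m.
#' @return A one-row tibble: `target_g`, `radius_cm`, `rpm`, `achieved_g`,
#'   `residual_g`, `relative_error_pct`, `delta_g`, `rel_gradient`.
#' @examples
#' plan_hw(0.38, 0.12)
#' @export
plan_hw <- function(target_g, radius, frame_rate = 60, platter_radius = 0.20,
                    sample_extent = 0.02) {
  rpm <- solve_rpm(target_g, radius)
  achieved <- centripetal_g(rpm, radius, "rpm")
  res <- residual_g(frame_rate, platter_radius)
  grad <- g_gradient(max(rpm, 1e-9), radius, sample_extent)
  tibble::tibble(
    target_g = target_g,
    radius_cm = radius * 100,
    rpm = rpm,
    achieved_g = achieved,
    residual_g = res,
    relative_error_pct = if (target_g > 0) relative_residual_error(res, target_g) else NA_real_,
    delta_g = if (rpm > 0) grad$delta_g else 0,
    rel_gradient = if (rpm > 0) grad$rel_gradient else NA_real_
  )
}

#' Reference settings table for both partial-gravity paradigms
#'
#' Recomputes, from first principles, the settings used to simulate the
#' five standard conditions (Moon, Mars, 1/2 g, 3/4 g and the 1 g hardware
#' control): centrifuge rpm at the given radius for the hardware paradigm
#' and spheroid eccentricity for the software paradigm.
#'
#' @return A tibble with columns `condition`, `g_level`, `rpm`,
#'   `radius_cm`, `eccentricity` (NA where the software paradigm is not
#'   used).
#' @examples
#' reference_settings()
#' @export
reference_settings <- function() {
  rows <- tibble::tribble(
    ~condition,       ~g_level, ~radius_cm,
    "Moon",           0.17,     12,
    "Mars",           0.38,     12,
    "1/2 g-Earth",    0.50,     16,
    "3/4 g-Earth",    0.75,     12,
    "1 g HW control", 1.00,     16
  )
  rows |>
    dplyr::mutate(
      rpm = solve_rpm(.data$g_level, .data$radius_cm / 100),
      eccentricity = vapply(.data$g_level, function(g) {
        if (g >= 1) NA_real_ else round(eccentricity_for_mean_g(g), 2)
      }, numeric(1))
    ) |>
    dplyr::select("condition", "g_level", "rpm", "radius_cm", "eccentricity")
}
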