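#' Unit-quaternion orientations
#'
#' An orientation is stored as a unit quaternion `c(w, x, y, z)` of class
#' `rpm_orientation`, representing the active rotation of the machine frames
#' relative to the lab. The sample rides the inner gimbal frame, so the
#' gravity vector "seen" by the sample is the lab gravity direction pushed
#' through the inverse rotation.
#'
#' @param w,x,y,z quaternion components.
#' @return An `rpm_orientation` (unit-norm numeric of length 4).
#' @keywords internal
new_orientation <- function(w, x, y, z) {
  q <- c(w, x, y, z)
  n <- sqrt(sum(q^2))
  if (!all(is.finite(q)) || n == 0) {
    stop("orientation components must be finite and not all zero", call. = FALSE)
  }
  structure(q / n, class = "rpm_orientation")
}

#' @export
print.rpm_orientation <- function(x, ...) {
  cat(sprintf("<orientation> quaternion (w, x, y, z) = (%.6f, %.6f, %.6f, %.6f)\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

quat_identity <- function() new_orientation(1, 0, 0, 0)

# Hamilton product; composition q1 * q2 applies q2 first, then q1.
quat_mul <- function(q1, q2) {
  w1 <- q1[1]; x1 <- q1[2]; y1 <- q1[3]; z1 <- q1[4]
  w2 <- q2[1]; x2 <- q2[2]; y2 <- q2[3]; z2 <- q2[4]
  new_orientation(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
}

quat_conjugate <- function(q) new_orientation(q[1], -q[2], -q[3], -q[4])

quat_from_axis_angle <- function(axis, angle) {
  if (!is.finite(angle)) stop("rotation angle must be finite", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  s <- sin(angle / 2)
  new_orientation(cos(angle / 2), s * axis[1], s * axis[2], s * axis[3])
}

# Rotate a 3-vector by quaternion q (active rotation).
quat_rotate <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  2 * sum(u * v) * u + (w^2 - sum(u^2)) * v + 2 * w * c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Orientation of the two-gimbal RPM
#'
#' Composes the rotation of the two independently driven perpendicular
#' frames of a Random Positioning Machine. The outer gimbal rotates about
#' the fixed lab X axis; the inner gimbal rotates about the outer frame's
#' (already rotated) Y axis. Lab gravity points along -Z. Any fixed
#' perpendicular axis pair is physically equivalent; this convention is
#' used throughout the package.
#'
#' @param outer_angle,inner_angle Gimbal angles in radians (finite; any
#'   real value, full turns wrap to the identity).
#' @return An `rpm_orientation` mapping lab-frame vectors to the inner
#'   (sample) frame.
#' @examples
#' orientation_from_gimbal(0, 0)
#' gravity_in_sample_frame(orientation_from_gimbal(pi, 0))
#' @export
orientation_from_gimbal <- function(outer_angle, inner_angle) {
  if (!is.numeric(outer_angle) || !is.numeric(inner_angle) ||
      length(outer_angle) != 1 || length(inner_angle) != 1 ||
      !is.finite(outer_angle) || !is.finite(inner_angle)) {
    stop("gimbal angles must be single finite numbers", call. = FALSE)
  }
  q_outer <- quat_from_axis_angle(c(1, 0, 0), outer_angle)
  inner_axis <- quat_rotate(q_outer, c(0, 1, 0))
  q_inner <- quat_from_axis_angle(inner_axis, inner_angle)
  quat_mul(q_inner, q_outer)
}

#' Gravity direction in the sample frame
#'
#' Applies the inverse of an orientation to the lab gravity direction
#' (0, 0, -1), giving the unit vector along which the sample feels gravity.
#'
#' @param o An `rpm_orientation`.
#' @return A unit 3-vector.
#' @export
gravity_in_sample_frame <- function(o) {
  if (!inherits(o, "rpm_orientation")) {
    stop("`o` must be an rpm_orientation", call. = FALSE)
  }
  quat_rotate(quat_conjugate(o), c(0, 0, -1))
}

wrap_angle <- function(a) a %% (2 * pi)
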