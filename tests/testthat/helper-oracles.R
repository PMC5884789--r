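# Independent oracles used across the suite.

# Brute-force rotation matrices (Rodrigues), independent of the quaternion
# implementation under test.
rot_x <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), nrow = 3, byrow = TRUE)
}

rot_axis <- function(axis, a) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), nrow = 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Matrix-product oracle for the two-gimbal composition: outer rotation
# about lab X, then inner rotation about the rotated Y axis.
gimbal_matrix_oracle <- function(outer, inner) {
  Ro <- rot_x(outer)
  rot_axis(as.numeric(Ro %*% c(0, 1, 0)), inner) %*% Ro
}

# Monte-Carlo oracle for the spheroid mean gravity factor: uniform-area
# surface draws (axial density proportional to sqrt(1 - e^2 z^2)), mean of
# the focus-frame axial direction component. Returns the estimate and its
# standard error.
mc_mean_g <- function(e, n) {
  z <- numeric(0)
  while (length(z) < n) {
    m <- ceiling((n - length(z)) * 1.4) + 1000
    cand <- stats::runif(m, -1, 1)
    z <- c(z, cand[stats::runif(m) < sqrt(1 - e^2 * cand^2)])
  }
  z <- z[seq_len(n)]
  a <- (z - e) / (1 - e * z)
  list(estimate = abs(mean(a)), se = stats::sd(a) / sqrt(n))
}

expect_unit_rows <- function(u, tol = 1e-9) {
  expect_lt(max(abs(sqrt(rowSums(u^2)) - 1)), tol)
}
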