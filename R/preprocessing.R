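# Raw ADC counts -> physical units, and body-frame -> world-frame rotation
# through the fused orientation quaternion.

STANDARD_GRAVITY <- 9.807  # m/s^2 per g, the conversion factor used throughout

#' Sensor scaling specification
#'
#' Holds the configured full-scale range and ADC resolution that drive the
#' linear count-to-unit scaling: `a = raw * range_a / 2^bits_a * 9.807`
#' (m/s^2) and `omega = raw * range_w / 2^bits_w` (deg/s). Whether a
#' manufacturer's "+/-8 g" maps to range 8 or 16 is sensor-dialect
#' dependent; the presets take the stated sensitivity value literally and
#' are editable.
#'
#' @param accel_range_g accelerometer full-scale parameter, in g.
#' @param accel_bits accelerometer ADC resolution (8..32 bits).
#' @param gyro_range_dps gyroscope full-scale parameter, in deg/s.
#' @param gyro_bits gyroscope ADC resolution (8..32 bits).
#' @return an object of class `sensor_spec`.
#' @export
sensor_spec <- function(accel_range_g, accel_bits, gyro_range_dps, gyro_bits) {
  stopifnot(accel_range_g > 0, gyro_range_dps > 0,
            accel_bits %in% 8:32, gyro_bits %in% 8:32)
  structure(list(accel_range_g = accel_range_g, accel_bits = as.integer(accel_bits),
                 gyro_range_dps = gyro_range_dps, gyro_bits = as.integer(gyro_bits),
                 gravity = STANDARD_GRAVITY),
            class = "sensor_spec")
}

#' Shipped sensor presets
#'
#' `bno055`: +/-8 g / 14-bit accelerometer, +/-2000 deg/s / 16-bit gyro.
#' `mpu9250`: +/-16 g / 16-bit accelerometer, +/-2000 deg/s / 16-bit gyro.
#'
#' @param name `"bno055"` or `"mpu9250"`.
#' @return a [sensor_spec()].
#' @export
sensor_preset <- function(name = c("bno055", "mpu9250")) {
  switch(match.arg(name),
         bno055  = sensor_spec(8, 14, 2000, 16),
         mpu9250 = sensor_spec(16, 16, 2000, 16))
}

#' Convert raw accelerometer counts to m/s^2
#'
#' @param raw integer count(s); must satisfy `|raw| < 2^accel_bits`.
#' @param spec a [sensor_spec()].
#' @return acceleration in m/s^2.
#' @export
raw_to_accel <- function(raw, spec) {
  stopifnot(inherits(spec, "sensor_spec"))
  if (any(abs(raw) >= 2^spec$accel_bits)) {
    stop("raw accelerometer count out of ADC range (|raw| < 2^",
         spec$accel_bits, " required)")
  }
  raw * spec$accel_range_g / 2^spec$accel_bits * spec$gravity
}

#' Convert raw gyroscope counts to deg/s
#'
#' @inheritParams raw_to_accel
#' @return angular rate in deg/s.
#' @export
raw_to_gyro <- function(raw, spec) {
  stopifnot(inherits(spec, "sensor_spec"))
  if (any(abs(raw) >= 2^spec$gyro_bits)) {
    stop("raw gyroscope count out of ADC range (|raw| < 2^",
         spec$gyro_bits, " required)")
  }
  raw * spec$gyro_range_dps / 2^spec$gyro_bits
}

#' Normalize a quaternion
#'
#' Scalar-first `(w, x, y, z)`, right-handed, Hamilton convention.
#'
#' @param q numeric length-4 vector.
#' @return unit quaternion.
#' @export
quat_normalize <- function(q) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("degenerate input: zero quaternion has no orientation")
  q / n
}

#' Hamilton product of two quaternions
#'
#' @param p,q scalar-first quaternions.
#' @return the product `p * q`.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' Rotation matrix from a unit quaternion
#'
#' Standard scalar-first mapping; the result rotates body-frame vectors
#' into the world frame. The input is normalized internally.
#'
#' @param q scalar-first quaternion `(w, x, y, z)`.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
quat_to_rotation <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate body-frame samples into the world frame
#'
#' Applies `a_world = R(q) %*% a_body`. The rotated quantity is specific
#' force: gravity is retained, so a stationary collar shows ~9.807 m/s^2
#' on the world z axis regardless of collar orientation. Gyroscope and
#' magnetometer channels are never rotated by the pipeline; only
#' accelerations exist in both frames.
#'
#' @param a_body length-3 vector, or an n x 3 matrix of samples.
#' @param q a single quaternion, or an n x 4 matrix (one per sample).
#' @return rotated vector/matrix of the same shape.
#' @export
rotate_to_world <- function(a_body, q) {
  if (is.null(dim(a_body))) {
    stopifnot(length(a_body) == 3)
    return(drop(quat_to_rotation(q) %*% a_body))
  }
  a_body <- as.matrix(a_body)
  stopifnot(ncol(a_body) == 3)
  if (is.null(dim(q))) {
    return(a_body %*% t(quat_to_rotation(q)))
  }
  q <- as.matrix(q)
  stopifnot(nrow(q) == nrow(a_body), ncol(q) == 4)
  out <- a_body
  for (i in seq_len(nrow(a_body))) {
    out[i, ] <- quat_to_rotation(q[i, ]) %*% a_body[i, ]
  }
  out
}
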