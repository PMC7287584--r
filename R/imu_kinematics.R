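## Orientation fusion and derived acceleration series for the waist unit.

#' Madgwick gradient-descent orientation estimate
#'
#' Fuses gyroscope and accelerometer streams into a per-sample unit
#' quaternion mapping sensor-frame vectors to the earth frame (Hamilton
#' convention, scalar first). The IMU variant is used: the gradient step of
#' magnitude `beta` pulls the predicted gravity direction toward the
#' measured specific force; the magnetometer is ignored. A zero-norm
#' accelerometer sample propagates that step gyro-only. With `beta = 0` the
#' filter reduces to pure gyroscope integration.
#'
#' @param imu An [imu_recording()] (gyroscope in degrees/s, converted to
#'   rad/s internally).
#' @param beta Gradient step magnitude in rad/s (default 0.1).
#' @param init Initial quaternion (scalar first), or `"acc"` (default) to
#'   align the initial orientation with gravity as measured by the first
#'   accelerometer samples, avoiding a convergence transient.
#' @return A list of class `orientation_series` with `q` (n-by-4 matrix of
#'   unit quaternions) and `sample_rate`.
#' @export
madgwick_orientation <- function(imu, beta = 0.1, init = "acc") {
  if (identical(init, "acc")) {
    n0 <- min(20L, nrow(imu$acc))
    a <- colMeans(imu$acc[seq_len(n0), , drop = FALSE])
    init <- quat_from_gravity(a)
  }
  gyr_rad <- imu$gyr * pi / 180
  q <- madgwick_filter(gyr_rad, imu$acc, imu$sample_rate, beta,
                       as.numeric(init))
  structure(list(q = q, sample_rate = imu$sample_rate),
            class = "orientation_series")
}

## Quaternion rotating the measured gravity direction `a` (sensor frame)
## onto earth +z: the shortest arc. Falls back to identity for a zero
## vector and to a 180-degree roll when `a` points straight down.
quat_from_gravity <- function(a) {
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) return(c(1, 0, 0, 0))
  a <- a / nrm
  d <- a[3]  # dot with z-hat
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) return(c(0, 1, 0, 0))
  axis <- c(a[2], -a[1], 0)  # a x z-hat
  axis <- axis / sqrt(sum(axis^2))
  half <- acos(d) / 2
  c(cos(half), sin(half) * axis)
}

## Rotate row-wise sensor-frame vectors v (n x 3) into the earth frame by
## quaternions q (n x 4): v_e = q (x) v (x) q*.
quat_rotate_rows <- function(q, v) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # R(q) %*% v per row, expanded
  cbind(
    (1 - 2 * (y^2 + z^2)) * vx + 2 * (x * y - w * z) * vy + 2 * (x * z + w * y) * vz,
    2 * (x * y + w * z) * vx + (1 - 2 * (x^2 + z^2)) * vy + 2 * (y * z - w * x) * vz,
    2 * (x * z - w * y) * vx + 2 * (y * z + w * x) * vy + (1 - 2 * (x^2 + y^2)) * vz)
}

#' Earth-frame vertical acceleration from a waist IMU
#'
#' Rotates each accelerometer sample into the earth frame using the fused
#' orientation and removes the 1 g gravity component from the vertical axis.
#'
#' @param imu An [imu_recording()].
#' @param orientation An `orientation_series` from [madgwick_orientation()]
#'   aligned sample-by-sample with `imu`.
#' @return A list of class `scalar_series` with `values` (g),
#'   `sample_rate`, `kind = "vertical_acc_g"`.
#' @export
vertical_acceleration <- function(imu, orientation) {
  if (nrow(orientation$q) != nrow(imu$acc))
    stop("orientation and IMU recording differ in length", call. = FALSE)
  ve <- quat_rotate_rows(orientation$q, imu$acc)
  scalar_series(ve[, 3] - 1, imu$sample_rate, "vertical_acc_g")
}

#' Resultant (vector-norm) acceleration
#'
#' Per-sample Euclidean norm of the raw three-axis accelerometer signal,
#' gravity included — invariant to how the sensor was mounted. This is the
#' series the entropy analyses and the entropy tolerance are computed from.
#'
#' @param imu An [imu_recording()].
#' @return A `scalar_series` in g with `kind = "resultant_acc_g"`.
#' @export
resultant_acceleration <- function(imu) {
  scalar_series(sqrt(rowSums(imu$acc^2)), imu$sample_rate, "resultant_acc_g")
}

#' Scalar time series container
#'
#' @param values Numeric values.
#' @param sample_rate Sampling rate in Hz.
#' @param kind Label for the quantity carried.
#' @return A list of class `scalar_series`.
#' @export
scalar_series <- function(values, sample_rate,
                          kind = c("vertical_acc_g", "resultant_acc_g",
                                   "sagittal_gyro_dps", "convolved",
                                   "filtered_convolved", "generic")) {
  kind <- match.arg(kind)
  stopifnot(sample_rate > 0)
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 kind = kind),
            class = "scalar_series")
}
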