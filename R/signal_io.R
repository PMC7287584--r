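## CSV reading/writing for the two device types, and sync-pulse alignment.
## Column layouts:
##   force plate: t, fx, fy, fz [, aux]      (seconds, newtons, volts)
##   IMU:         t, ax, ay, az, gx, gy, gz [, mx, my, mz] [, aux]
##                (seconds, g, degrees/s, microtesla, volts)

check_monotonic <- function(t, path) {
  if (length(t) > 1 && any(diff(t) <= 0))
    stop(sprintf("non-monotonic time column in '%s'", path), call. = FALSE)
  if (length(t) > 2) {
    dt <- diff(t)
    period <- median(dt)
    if (max(abs(dt - period)) > period / 2)
      stop(sprintf("non-uniform sampling in '%s' (timestamp jitter exceeds half a sample period)",
                   path), call. = FALSE)
  }
}

require_columns <- function(d, cols, path) {
  missing <- setdiff(cols, names(d))
  if (length(missing))
    stop(sprintf("file '%s' lacks required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read a force-plate recording from CSV
#'
#' Expects columns `t,fx,fy,fz` with an optional `aux` sync channel. Body
#' weight is derived from body mass using standard gravity (9.81 m/s^2).
#'
#' @param path Path to the CSV file.
#' @param body_mass Participant body mass in kg (> 0).
#' @return A [forceplate_recording()].
#' @export
read_forceplate <- function(path, body_mass) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("`body_mass` must be a positive number (kg)", call. = FALSE)
  d <- read.csv(path)
  require_columns(d, c("t", "fx", "fy", "fz"), path)
  check_monotonic(d$t, path)
  forceplate_recording(t = d$t, fx = d$fx, fy = d$fy, fz = d$fz,
                       body_weight = body_mass * GRAVITY,
                       aux = if ("aux" %in% names(d)) d$aux else NULL)
}

#' Write a force-plate recording to CSV
#'
#' @param rec A [forceplate_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forceplate <- function(rec, path) {
  d <- data.frame(t = rec$t, fx = rec$fx, fy = rec$fy, fz = rec$fz)
  if (!is.null(rec$aux)) d$aux <- rec$aux
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' Expects columns `t,ax,ay,az,gx,gy,gz`, with optional `mx,my,mz`
#' (magnetometer) and `aux` (sync). Units are preserved as documented:
#' accelerometer in g, gyroscope in degrees/s, magnetometer in microtesla.
#'
#' @param path Path to the CSV file.
#' @param placement `"waist"` or `"ankle"`.
#' @return An [imu_recording()].
#' @export
read_imu <- function(path, placement = c("waist", "ankle")) {
  placement <- match.arg(placement)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  d <- read.csv(path)
  require_columns(d, c("t", "ax", "ay", "az", "gx", "gy", "gz"), path)
  check_monotonic(d$t, path)
  has_mag <- all(c("mx", "my", "mz") %in% names(d))
  imu_recording(
    t = d$t,
    acc = cbind(d$ax, d$ay, d$az),
    gyr = cbind(d$gx, d$gy, d$gz),
    mag = if (has_mag) cbind(d$mx, d$my, d$mz) else NULL,
    aux = if ("aux" %in% names(d)) d$aux else NULL,
    placement = placement)
}

#' Write an IMU recording to CSV
#'
#' @param rec An [imu_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu <- function(rec, path) {
  d <- data.frame(t = rec$t,
                  ax = rec$acc[, 1], ay = rec$acc[, 2], az = rec$acc[, 3],
                  gx = rec$gyr[, 1], gy = rec$gyr[, 2], gz = rec$gyr[, 3])
  if (!is.null(rec$mag)) {
    d$mx <- rec$mag[, 1]; d$my <- rec$mag[, 2]; d$mz <- rec$mag[, 3]
  }
  if (!is.null(rec$aux)) d$aux <- rec$aux
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

sync_edge_time <- function(rec, threshold) {
  if (is.null(rec$aux))
    stop("recording has no auxiliary sync channel", call. = FALSE)
  a <- rec$aux
  rising <- which(a[-1] > threshold & a[-length(a)] <= threshold)
  if (length(rising) == 0L)
    stop("no rising sync edge found in auxiliary channel", call. = FALSE)
  if (length(rising) > 1L)
    stop(sprintf("expected exactly one rising sync edge, found %d",
                 length(rising)), call. = FALSE)
  rec$t[rising + 1L]
}

#' Align two recordings by their square sync pulse
#'
#' Both devices record a shared square pulse on their auxiliary channel; the
#' first upward threshold crossing marks the edge. The returned offset is the
#' number of seconds to add to recording `b`'s time base so the edges
#' coincide.
#'
#' @param a,b Recordings (force plate or IMU) with `aux` channels containing
#'   exactly one rising edge each.
#' @param threshold Crossing threshold in volts (default 0.75, half the
#'   nominal 1.5 V pulse).
#' @return A list of class `sync_alignment` with element `offset` (seconds).
#' @export
align_by_sync_pulse <- function(a, b, threshold = 0.75) {
  ta <- sync_edge_time(a, threshold)
  tb <- sync_edge_time(b, threshold)
  structure(list(offset = ta - tb), class = "sync_alignment")
}
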