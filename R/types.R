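## Core containers. Lightweight S3: plain lists with validation at
## construction, the style used throughout base-R biomechanics code.

#' Force-plate recording
#'
#' Container for a summed 3-D ground reaction force time series with the
#' participant's body weight. Forces are the sum over all plates of the array,
#' so both feet contribute during double support.
#'
#' @param t Numeric vector of sample times in seconds (uniformly spaced).
#' @param fx,fy,fz Numeric vectors, horizontal (anteroposterior,
#'   mediolateral) and vertical force in newtons; equal length to `t`.
#' @param body_weight Body weight in newtons (> 0).
#' @param sample_rate Sampling rate in Hz; defaults to the inverse median
#'   time step.
#' @param aux Optional auxiliary (synchronization) channel in volts.
#' @return An object of class `forceplate_recording`.
#' @export
forceplate_recording <- function(t, fx, fy, fz, body_weight,
                                 sample_rate = NULL, aux = NULL) {
  n <- length(t)
  if (length(fx) != n || length(fy) != n || length(fz) != n)
    stop("force channels must have the same length as `t`", call. = FALSE)
  if (!is.null(aux) && length(aux) != n)
    stop("`aux` must have the same length as `t`", call. = FALSE)
  if (!is.numeric(body_weight) || length(body_weight) != 1L || body_weight <= 0)
    stop("`body_weight` must be a single positive number", call. = FALSE)
  if (is.null(sample_rate)) {
    if (n < 2L) stop("cannot infer sample rate from fewer than 2 samples",
                     call. = FALSE)
    sample_rate <- 1 / median(diff(t))
  }
  if (sample_rate <= 0) stop("`sample_rate` must be positive", call. = FALSE)
  structure(
    list(t = as.numeric(t), fx = as.numeric(fx), fy = as.numeric(fy),
         fz = as.numeric(fz), body_weight = body_weight,
         sample_rate = sample_rate, aux = if (is.null(aux)) NULL else as.numeric(aux)),
    class = "forceplate_recording")
}

#' @export
print.forceplate_recording <- function(x, ...) {
  cat(sprintf("<forceplate_recording> %d samples @ %.6g Hz, BW = %.1f N%s\n",
              length(x$t), x$sample_rate, x$body_weight,
              if (is.null(x$aux)) "" else ", aux present"))
  invisible(x)
}

#' Inertial measurement unit recording
#'
#' Tri-axial accelerometer (g) and gyroscope (degrees/s) streams from one
#' body-worn unit, with an optional magnetometer stream and auxiliary
#' synchronization channel.
#'
#' @param t Sample times in seconds.
#' @param acc n-by-3 matrix of specific force in g.
#' @param gyr n-by-3 matrix of angular velocity in degrees/s.
#' @param placement `"waist"` or `"ankle"`.
#' @param sample_rate Sampling rate in Hz; inferred from `t` when `NULL`.
#' @param mag Optional n-by-3 magnetometer matrix in microtesla.
#' @param aux Optional auxiliary channel in volts.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(t, acc, gyr, placement = c("waist", "ankle"),
                          sample_rate = NULL, mag = NULL, aux = NULL) {
  placement <- match.arg(placement)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  n <- length(t)
  if (nrow(acc) != n || ncol(acc) != 3L)
    stop("`acc` must be an n-by-3 matrix", call. = FALSE)
  if (nrow(gyr) != n || ncol(gyr) != 3L)
    stop("`gyr` must be an n-by-3 matrix", call. = FALSE)
  if (!is.null(mag)) {
    mag <- as.matrix(mag)
    if (ncol(mag) != 3L) stop("`mag` must have 3 columns", call. = FALSE)
  }
  if (!is.null(aux) && length(aux) != n)
    stop("`aux` must match `t` in length", call. = FALSE)
  if (is.null(sample_rate)) {
    if (n < 2L) stop("cannot infer sample rate from fewer than 2 samples",
                     call. = FALSE)
    sample_rate <- 1 / median(diff(t))
  }
  structure(
    list(t = as.numeric(t), acc = acc, gyr = gyr, mag = mag,
         aux = if (is.null(aux)) NULL else as.numeric(aux),
         placement = placement, sample_rate = sample_rate),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording:%s> %d samples @ %.6g Hz%s%s\n",
              x$placement, length(x$t), x$sample_rate,
              if (is.null(x$mag)) "" else ", mag present",
              if (is.null(x$aux)) "" else ", aux present"))
  invisible(x)
}

#' Gait event series
#'
#' Sorted, labeled gait events (heel-strikes and toe-offs) with foot side and
#' detection source.
#'
#' @param times Event times in seconds (sorted ascending).
#' @param labels Character vector, `"HS"` or `"TO"` per event.
#' @param foot `"right"`, `"left"` or `"unknown"` per event (recycled).
#' @param source `"force"`, `"waist"` or `"ankle"` (recycled).
#' @return An object of class `event_series`, a data frame with columns
#'   `time`, `label`, `foot`, `source`.
#' @export
event_series <- function(times = numeric(), labels = character(),
                         foot = "unknown", source = "force") {
  n <- length(times)
  if (length(labels) == 1L) labels <- rep(labels, n)
  if (n > 0 && length(labels) != n)
    stop("`labels` must match `times`", call. = FALSE)
  stopifnot(all(labels %in% c("HS", "TO")))
  foot <- rep_len(as.character(foot), n)
  source <- rep_len(as.character(source), n)
  stopifnot(all(foot %in% c("right", "left", "unknown")),
            all(source %in% c("force", "waist", "ankle")))
  if (n > 1 && any(diff(times) <= 0)) {
    o <- order(times)
    times <- times[o]; labels <- labels[o]; foot <- foot[o]; source <- source[o]
    if (any(diff(times) <= 0))
      stop("event times must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = as.numeric(times), label = labels,
                       foot = foot, source = source,
                       stringsAsFactors = FALSE),
            class = c("event_series", "data.frame"))
}

#' Stride series
#'
#' Stride start times and durations, as produced from a heel-strike sequence
#' and carried through the median-ratio filter.
#'
#' @param start_times Stride start times in seconds (sorted).
#' @param durations_ms Stride durations in milliseconds (> 0).
#' @param source Detection source label.
#' @return An object of class `stride_series`, a data frame with columns
#'   `start_time`, `duration_ms`, `source`.
#' @export
stride_series <- function(start_times = numeric(), durations_ms = numeric(),
                          source = "force") {
  if (length(start_times) != length(durations_ms))
    stop("`start_times` and `durations_ms` must have equal length",
         call. = FALSE)
  if (any(durations_ms <= 0))
    stop("stride durations must be positive", call. = FALSE)
  structure(data.frame(start_time = as.numeric(start_times),
                       duration_ms = as.numeric(durations_ms),
                       source = rep_len(as.character(source),
                                        length(start_times)),
                       stringsAsFactors = FALSE),
            class = c("stride_series", "data.frame"))
}

#' Per-scale entropy profile
#'
#' Holds one entropy value per coarseness scale for either refined composite
#' multiscale sample entropy (RCME) or refined multiscale permutation entropy
#' (RMPE). Scales where the estimate is undefined (no template matches) carry
#' `NA`.
#'
#' @param scales Integer coarseness scales.
#' @param values Entropy in nats per scale (`NA` allowed).
#' @param kind `"RCME"` or `"RMPE"`.
#' @param n_epochs_averaged Number of epochs averaged into `values`.
#' @return An object of class `entropy_profile`.
#' @export
entropy_profile <- function(scales, values, kind = c("RCME", "RMPE"),
                            n_epochs_averaged = 1L) {
  kind <- match.arg(kind)
  if (length(scales) != length(values))
    stop("`scales` and `values` must have equal length", call. = FALSE)
  structure(list(scales = as.integer(scales), values = as.numeric(values),
                 kind = kind, n_epochs_averaged = as.integer(n_epochs_averaged)),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy_profile:%s> %d scales (%d NA), %d epoch(s) averaged\n",
              x$kind, length(x$scales), sum(is.na(x$values)),
              x$n_epochs_averaged))
  invisible(x)
}
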