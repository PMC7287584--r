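## Event detection from body-worn IMUs: waist heel-strikes via Ricker
## matched filtering of vertical acceleration; ankle heel-strike/toe-off
## from sagittal angular velocity troughs around the mid-swing peak.

#' Ricker ("Mexican hat") wavelet kernel
#'
#' `psi(t) = (1 - (t/sigma)^2) exp(-t^2 / (2 sigma^2))` with
#' `sigma = 1 / (pi f_p sqrt(2))`, which places the spectral peak of the
#' kernel at `peak_frequency`. Sampled symmetrically on +/- 4 sigma.
#'
#' @param peak_frequency Spectral peak frequency in Hz (default 16; must be
#'   below the Nyquist rate).
#' @param sample_rate Sampling rate in Hz (default 400).
#' @return A list of class `wavelet_kernel` with `samples` (odd length,
#'   symmetric), `peak_frequency`, `sample_rate`.
#' @export
ricker_kernel <- function(peak_frequency = 16, sample_rate = 400) {
  if (peak_frequency <= 0 || peak_frequency >= sample_rate / 2)
    stop("`peak_frequency` must lie in (0, sample_rate/2)", call. = FALSE)
  sigma <- 1 / (pi * peak_frequency * sqrt(2))
  half <- ceiling(4 * sigma * sample_rate)
  tt <- (-half:half) / sample_rate
  psi <- (1 - (tt / sigma)^2) * exp(-tt^2 / (2 * sigma^2))
  # remove the residual DC of the sampled, truncated kernel so the discrete
  # wavelet is exactly admissible (zero sum)
  psi <- psi - mean(psi)
  structure(list(samples = psi, peak_frequency = peak_frequency,
                 sample_rate = sample_rate),
            class = "wavelet_kernel")
}

## Same-length convolution with a centered symmetric kernel.
convolve_same <- function(x, k) {
  n <- length(x); m <- length(k)
  full <- convolve(x, rev(k), type = "open")
  start <- (m + 1L) %/% 2L
  full[start:(start + n - 1L)]
}

## Indices of strict interior local maxima.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

#' Topographic prominence of local maxima
#'
#' For each peak, the drop from the peak height to the higher of the two
#' lowest points separating it from higher terrain (or the signal edge) on
#' either side.
#'
#' @param x Numeric signal.
#' @param peaks Indices of local maxima in `x`.
#' @return Numeric vector of prominences, parallel to `peaks`.
#' @export
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher_l <- which(left >= h)
    lmin <- min(x[(if (length(higher_l)) max(higher_l) else 1):p])
    right <- x[p:length(x)]
    higher_r <- which(right[-1] >= h)
    rend <- if (length(higher_r)) p + min(higher_r) else length(x)
    rmin <- min(x[p:rend])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect heel-strikes from waist vertical acceleration
#'
#' Convolves the vertical acceleration with a Ricker wavelet matched to the
#' heel-strike transient, low-pass filters the convolved signal with a
#' zero-lag 4th-order Butterworth filter (a 2nd-order filter run forward and
#' backward), and keeps local maxima whose prominence exceeds `prom_frac`
#' times the `prom_pct`-th percentile of all local-maxima prominences.
#' Since the threshold is relative, the detector is invariant to overall
#' amplitude scaling.
#'
#' @param vacc A `scalar_series` of vertical acceleration (g).
#' @param kernel A [ricker_kernel()] at the same sample rate.
#' @param lp_cutoff Low-pass cutoff in Hz (default 6).
#' @param prom_frac Fraction of the percentile defining the threshold
#'   (default 0.5).
#' @param prom_pct Percentile of the local-maxima statistics (default 80).
#' @param threshold_on `"prominence"` (default) thresholds on peak
#'   prominences; `"height"` uses peak heights instead.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An [event_series()] of heel-strikes, foot `"unknown"`, source
#'   `"waist"`.
#' @export
detect_waist_heelstrikes <- function(vacc, kernel = ricker_kernel(
                                       sample_rate = vacc$sample_rate),
                                     lp_cutoff = 6, prom_frac = 0.5,
                                     prom_pct = 80,
                                     threshold_on = c("prominence", "height"),
                                     t0 = 0) {
  threshold_on <- match.arg(threshold_on)
  x <- vacc$values
  if (length(x) <= length(kernel$samples))
    stop("signal shorter than the wavelet kernel", call. = FALSE)
  if (abs(kernel$sample_rate - vacc$sample_rate) > 1e-9)
    stop("kernel and signal sample rates differ", call. = FALSE)
  if (diff(range(x)) == 0) return(event_series(source = "waist"))
  conv <- convolve_same(x, kernel$samples)
  bf <- signal::butter(2, lp_cutoff / (vacc$sample_rate / 2), type = "low")
  filt <- signal::filtfilt(bf, conv)
  pk <- local_maxima(filt)
  if (length(pk) == 0) return(event_series(source = "waist"))
  stat <- if (threshold_on == "prominence") peak_prominences(filt, pk)
          else filt[pk]
  thr <- prom_frac * quantile(stat, prom_pct / 100, names = FALSE)
  keep <- if (threshold_on == "prominence") stat > thr else stat > thr
  pk <- pk[keep]
  if (length(pk) == 0) return(event_series(source = "waist"))
  event_series(times = t0 + (pk - 1L) / vacc$sample_rate, labels = "HS",
               foot = "unknown", source = "waist")
}

## Least-squares parabola through 2*halfwidth+1 samples around index i;
## returns the vertex position in samples relative to i, clamped to
## +/- halfwidth.
parabola_vertex <- function(x, i, halfwidth) {
  idx <- (i - halfwidth):(i + halfwidth)
  idx <- idx[idx >= 1 & idx <= length(x)]
  if (length(idx) < 3) return(0)
  u <- idx - i
  y <- x[idx]
  fit <- stats::lm.fit(cbind(1, u, u^2), y)
  a <- fit$coefficients[3]; b <- fit$coefficients[2]
  if (!is.finite(a) || a == 0) return(0)
  max(-halfwidth, min(halfwidth, -b / (2 * a)))
}

#' Detect heel-strike and toe-off from ankle sagittal angular velocity
#'
#' Finds positive mid-swing peaks (above `min_swing_dps`, separated by at
#' least `min_sep_s`); for each, the heel-strike is the deepest local
#' minimum within `search_s` after the peak and the toe-off the deepest
#' local minimum within `search_s` before it. Event times are refined by
#' the vertex of a parabola fit to `2 * parabola_halfwidth + 1` samples
#' around each minimum (the refinement never moves an event by more than
#' `parabola_halfwidth` samples).
#'
#' @param gyro_sag A `scalar_series` of sagittal angular velocity
#'   (degrees/s), positive in swing.
#' @param min_swing_dps Swing-peak threshold in degrees/s (default 100).
#' @param parabola_halfwidth Half-width of the refinement fit in samples
#'   (default 2).
#' @param min_sep_s Minimum separation between swing peaks in s
#'   (default 0.5).
#' @param search_s Search extent on either side of a swing peak in s
#'   (default 0.4).
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An [event_series()] of HS and TO events, foot `"right"`,
#'   source `"ankle"`.
#' @export
detect_ankle_events <- function(gyro_sag, min_swing_dps = 100,
                                parabola_halfwidth = 2, min_sep_s = 0.5,
                                search_s = 0.4, t0 = 0) {
  x <- gyro_sag$values
  fs <- gyro_sag$sample_rate
  pk <- local_maxima(x)
  pk <- pk[x[pk] >= min_swing_dps]
  if (length(pk) == 0) return(event_series(source = "ankle"))
  # enforce minimum separation, keeping the taller peak
  o <- pk[order(x[pk], decreasing = TRUE)]
  accepted <- integer()
  for (p in o)
    if (!length(accepted) || all(abs(accepted - p) >= min_sep_s * fs))
      accepted <- c(accepted, p)
  pk <- sort(accepted)

  w <- as.integer(round(search_s * fs))
  times <- numeric(); labels <- character()
  for (p in pk) {
    after <- (p + 1L):min(length(x), p + w)
    if (length(after) > 2) {
      seg_min <- local_minima(x[after])
      mins_a <- after[seg_min]
    } else mins_a <- integer()
    if (length(mins_a)) {
      i <- mins_a[which.min(x[mins_a])]
      times <- c(times, t0 + (i - 1L + parabola_vertex(x, i, parabola_halfwidth)) / fs)
      labels <- c(labels, "HS")
    }
    before <- max(1L, p - w):(p - 1L)
    if (length(before) > 2) {
      seg_min <- local_minima(x[before])
      mins_b <- before[seg_min]
    } else mins_b <- integer()
    if (length(mins_b)) {
      i <- mins_b[which.min(x[mins_b])]
      times <- c(times, t0 + (i - 1L + parabola_vertex(x, i, parabola_halfwidth)) / fs)
      labels <- c(labels, "TO")
    }
  }
  o <- order(times)
  event_series(times = times[o], labels = labels[o], foot = "right",
               source = "ankle")
}

#' Enforce alternation of heel-strikes and toe-offs
#'
#' Merges a sorted HS/TO sequence down to strictly alternating labels: any
#' heel-strike not followed by a toe-off, or toe-off not followed by a
#' heel-strike, is filtered out, keeping the earliest event of each
#' same-label run.
#'
#' @param events An [event_series()] with HS/TO labels, sorted.
#' @return The reduced [event_series()].
#' @export
pair_ankle_events <- function(events) {
  if (nrow(events) == 0) return(events)
  keep <- c(TRUE, events$label[-1] != events$label[-nrow(events)])
  structure(events[keep, , drop = FALSE],
            class = class(events))
}
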