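## Stride construction, outlier filtering, cross-instrument matching, and
## stride-duration outcomes.

#' Build strides from a heel-strike sequence
#'
#' Stride `k` spans heel-strike `k` to heel-strike `k + step`. Use
#' `step = 1` for a single-foot series (force plate right foot, ankle unit)
#' and `step = 2` when the series mixes both feet (waist unit), where a
#' stride is the current to current-plus-two heel-strike.
#'
#' @param hs Heel-strike times in seconds (sorted), or an [event_series()]
#'   from which HS times are taken.
#' @param step 1 or 2.
#' @param source Source label for the result.
#' @return A [stride_series()]; empty when fewer than `step + 1`
#'   heel-strikes are available.
#' @export
build_strides <- function(hs, step = 1, source = "force") {
  if (inherits(hs, "event_series")) hs <- hs$time[hs$label == "HS"]
  stopifnot(step %in% c(1, 2))
  n <- length(hs)
  if (n < step + 1) return(stride_series(source = source))
  starts <- hs[seq_len(n - step)]
  durs <- (hs[seq_len(n - step) + step] - starts) * 1000
  stride_series(starts, durs, source)
}

#' Median-ratio stride filter
#'
#' Keeps strides whose duration lies within a multiplicative band of the
#' median of all candidate durations: `median / ratio <= d <= median * ratio`.
#' The median is computed once from the input and not re-estimated.
#'
#' @param s A [stride_series()].
#' @param ratio Band ratio (default 1.25).
#' @return The filtered [stride_series()].
#' @export
median_ratio_filter <- function(s, ratio = 1.25) {
  if (nrow(s) == 0) return(s)
  med <- median(s$duration_ms)
  keep <- s$duration_ms >= med / ratio & s$duration_ms <= med * ratio
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(s))
}

#' Match events across instruments within a time tolerance
#'
#' One-to-one matching of two sorted event-time sequences by a single
#' forward pass: pointers advance through both sequences in time order, a
#' pair is accepted whenever the current reference and candidate lie within
#' `tol_s`, and otherwise the earlier of the two is skipped. For
#' one-dimensional times this yields a maximum-cardinality matching.
#'
#' @param reference,candidate Sorted event times (seconds), or
#'   [event_series()] objects (all event times are used).
#' @param tol_s Matching tolerance in seconds (default 0.2).
#' @return A data frame with columns `ref_time`, `cand_time`.
#' @export
match_events <- function(reference, candidate, tol_s = 0.2) {
  if (inherits(reference, "event_series")) reference <- reference$time
  if (inherits(candidate, "event_series")) candidate <- candidate$time
  i <- 1L; j <- 1L
  ref_m <- numeric(); cand_m <- numeric()
  while (i <= length(reference) && j <= length(candidate)) {
    d <- reference[i] - candidate[j]
    if (abs(d) <= tol_s) {
      ref_m <- c(ref_m, reference[i]); cand_m <- c(cand_m, candidate[j])
      i <- i + 1L; j <- j + 1L
    } else if (d > 0) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(ref_time = ref_m, cand_time = cand_m)
}

#' Stride-duration outcomes
#'
#' Mean, sample standard deviation (n - 1 denominator) and percent
#' coefficient of variation (SD / mean x 100) of the stride durations.
#'
#' @param s A [stride_series()] with at least 2 strides.
#' @return A list of class `gait_outcomes` with `n_strides`, `mean_ms`,
#'   `sd_ms`, `cv_pct`.
#' @export
gait_outcomes <- function(s) {
  n <- nrow(s)
  if (n < 2)
    stop("at least 2 strides are required for outcome statistics",
         call. = FALSE)
  m <- mean(s$duration_ms)
  sdv <- sd(s$duration_ms)
  structure(list(n_strides = n, mean_ms = m, sd_ms = sdv,
                 cv_pct = sdv / m * 100),
            class = "gait_outcomes")
}

#' @export
print.gait_outcomes <- function(x, ...) {
  cat(sprintf("strides: %d  mean: %.1f ms  SD: %.2f ms  CV: %.2f%%\n",
              x$n_strides, x$mean_ms, x$sd_ms, x$cv_pct))
  invisible(x)
}
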