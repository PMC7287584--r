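## Heel-strike detection from the summed vertical ground reaction force:
## supra-body-weight force peaks -> backward jerk search -> false-candidate
## removal -> foot assignment from horizontal force -> right strides.

#' Find sustained supra-threshold vertical force peaks
#'
#' Identifies maximal runs of samples where the vertical force exceeds
#' `bw_factor` times body weight for at least `min_above_ms`, returning each
#' run together with the time of its maximum force.
#'
#' @param rec A [forceplate_recording()].
#' @param min_above_ms Minimum run duration in ms (default 2.5).
#' @param bw_factor Body-weight multiple defining the threshold (default 1.1).
#' @return A data frame with columns `start`, `end`, `peak_time` (seconds);
#'   zero rows when nothing crosses.
#' @export
detect_force_peaks <- function(rec, min_above_ms = 2.5, bw_factor = 1.1) {
  thr <- bw_factor * rec$body_weight
  above <- rec$fz > thr
  empty <- data.frame(start = numeric(), end = numeric(),
                      peak_time = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= min_above_ms / 1000 * rec$sample_rate)
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  peak_idx <- mapply(function(s, e) s + which.max(rec$fz[s:e]) - 1L,
                     starts, ends)
  data.frame(start = rec$t[starts], end = rec$t[ends],
             peak_time = rec$t[peak_idx])
}

## Central-difference first derivative of fz, N/s; endpoints one-sided.
force_jerk <- function(rec) {
  fz <- rec$fz; n <- length(fz); fs <- rec$sample_rate
  if (n < 2) return(numeric(n))
  j <- numeric(n)
  j[2:(n - 1)] <- (fz[3:n] - fz[1:(n - 2)]) * fs / 2
  j[1] <- (fz[2] - fz[1]) * fs
  j[n] <- (fz[n] - fz[n - 1]) * fs
  j
}

#' Heel-strike candidates from peak force jerk
#'
#' For each sustained force peak, searches a window extending backwards from
#' the peak-force instant and takes the time of maximum positive jerk (first
#' time derivative of vertical force, central difference) as a heel-strike
#' candidate. Windows reaching before the recording start are truncated.
#' Candidates from different peaks that land closer together than
#' `dedup_ms` are merged, keeping the higher jerk (both force peaks of one
#' stance must not produce two heel-strikes).
#'
#' @param rec A [forceplate_recording()].
#' @param peaks Output of [detect_force_peaks()].
#' @param window_ms Backward search window length in ms (default 50).
#' @param dedup_ms Minimum separation between distinct candidates in ms
#'   (default 250, below any physiological step time).
#' @return A data frame with columns `time`, `jerk` (N/s),
#'   `source_peak_time`, sorted by time.
#' @export
jerk_candidates <- function(rec, peaks, window_ms = 50, dedup_ms = 250) {
  empty <- data.frame(time = numeric(), jerk = numeric(),
                      source_peak_time = numeric())
  if (nrow(peaks) == 0) return(empty)
  j <- force_jerk(rec)
  fs <- rec$sample_rate
  t0 <- rec$t[1]
  out <- lapply(seq_len(nrow(peaks)), function(k) {
    pk <- peaks$peak_time[k]
    i1 <- round((pk - t0) * fs) + 1L
    i0 <- max(1L, i1 - as.integer(round(window_ms / 1000 * fs)))
    w <- i0:i1
    im <- w[which.max(j[w])]
    data.frame(time = rec$t[im], jerk = j[im], source_peak_time = pk)
  })
  cand <- do.call(rbind, out)
  cand <- cand[order(cand$time), , drop = FALSE]
  # de-duplicate: among candidates within dedup_ms keep the highest jerk
  keep <- logical(nrow(cand))
  last <- 0L
  for (k in seq_len(nrow(cand))) {
    if (last == 0L || (cand$time[k] - cand$time[last]) * 1000 >= dedup_ms) {
      keep[k] <- TRUE; last <- k
    } else if (cand$jerk[k] > cand$jerk[last]) {
      keep[last] <- FALSE; keep[k] <- TRUE; last <- k
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove low-jerk false heel-strike candidates
#'
#' The threshold is `frac` times the mean jerk of the `top_n` highest-jerk
#' candidates (all candidates when fewer exist); candidates below it are
#' dropped. Set `method = "rank"` to use the `top_n`-th highest jerk itself
#' as the reference instead of the mean.
#'
#' @param cands Candidate data frame from [jerk_candidates()].
#' @param frac Fraction of the reference jerk (default 0.3).
#' @param top_n Number of highest candidates defining the reference
#'   (default 50).
#' @param method `"mean"` (default) or `"rank"`.
#' @return The filtered candidate data frame.
#' @export
filter_false_candidates <- function(cands, frac = 0.3, top_n = 50,
                                    method = c("mean", "rank")) {
  method <- match.arg(method)
  if (nrow(cands) == 0) return(cands)
  top <- sort(cands$jerk, decreasing = TRUE)[seq_len(min(top_n, nrow(cands)))]
  ref <- if (method == "mean") mean(top) else top[length(top)]
  out <- cands[cands$jerk >= frac * ref, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign foot side from the horizontal force after each heel-strike
#'
#' Averages the mediolateral force `fy` over a window following each
#' candidate; a mean with the configured right-foot sign labels the event
#' right, otherwise left (an exact zero ties to left). A warning is emitted
#' when the resulting labels do not strictly alternate.
#'
#' @param rec A [forceplate_recording()].
#' @param cands Candidate data frame (filtered).
#' @param window_ms Averaging window after the event in ms (default 150).
#' @param right_sign +1 (default) if right-foot stance gives positive `fy`.
#' @return An [event_series()] of heel-strikes with foot labels,
#'   source `"force"`.
#' @export
assign_foot <- function(rec, cands, window_ms = 150, right_sign = 1) {
  if (nrow(cands) == 0)
    return(event_series(source = "force"))
  fs <- rec$sample_rate
  t0 <- rec$t[1]
  n <- length(rec$t)
  wlen <- as.integer(round(window_ms / 1000 * fs))
  foot <- vapply(cands$time, function(tt) {
    i0 <- round((tt - t0) * fs) + 1L
    i1 <- min(n, i0 + wlen)
    m <- mean(rec$fy[i0:i1])
    if (m * right_sign > 0) "right" else "left"
  }, character(1))
  if (length(foot) > 1 && any(foot[-1] == foot[-length(foot)]))
    warning("heel-strike foot labels do not strictly alternate")
  event_series(times = cands$time, labels = "HS", foot = foot,
               source = "force")
}

#' Extract right strides from a labeled heel-strike series
#'
#' Each consecutive pair of right-foot heel-strikes is one stride. The
#' result should be passed through [median_ratio_filter()] before outcomes
#' are computed.
#'
#' @param events An [event_series()] with foot labels.
#' @return A [stride_series()] (empty when fewer than two right
#'   heel-strikes are present).
#' @export
right_strides <- function(events) {
  rhs <- events$time[events$label == "HS" & events$foot == "right"]
  build_strides(rhs, step = 1, source = "force")
}

#' Full force-plate heel-strike detection chain
#'
#' Convenience wrapper: sustained force peaks, backward jerk candidates,
#' false-candidate removal and foot assignment, with the defaults of each
#' stage.
#'
#' @param rec A [forceplate_recording()].
#' @inheritParams detect_force_peaks
#' @inheritParams jerk_candidates
#' @inheritParams filter_false_candidates
#' @inheritParams assign_foot
#' @return An [event_series()] of labeled heel-strikes.
#' @export
detect_force_heelstrikes <- function(rec, min_above_ms = 2.5,
                                     bw_factor = 1.1, window_ms = 50,
                                     frac = 0.3, top_n = 50,
                                     right_sign = 1) {
  peaks <- detect_force_peaks(rec, min_above_ms, bw_factor)
  cands <- jerk_candidates(rec, peaks, window_ms)
  cands <- filter_false_candidates(cands, frac, top_n)
  assign_foot(rec, cands, right_sign = right_sign)
}
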