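## End-to-end orchestration: one session (three detection chains + outcomes
## + entropy), and two-session cohort reliability.

#' Run the full measurement chain on one session
#'
#' Takes a simulated or loaded session and runs: force-plate heel-strike
#' detection to right strides (step 1); ankle event detection, alternation
#' pairing, strides (step 1) matched to force-plate stride initiations;
#' waist heel-strike detection, matching to force-plate heel-strikes,
#' strides (step 2); the median-ratio filter on every stride set; stride
#' outcomes; and RCME/RMPE of the resultant waist acceleration over 1-min
#' epochs. Any stage yielding nothing leaves its downstream fields `NULL`
#' and the run continues.
#'
#' @param session A `gait_session` list (from [simulate_session()]) or a
#'   list with elements `force`, `waist`, `ankle` (any may be `NULL`).
#' @param entropy Compute the entropy profiles (default `TRUE`).
#' @param taus Entropy coarseness scales (default `1:80`).
#' @param epoch_s Entropy epoch length in seconds (default 60).
#' @param match_tol_s Cross-instrument matching tolerance (default 0.2).
#' @param wavelet_hz Ricker peak frequency for the waist detector
#'   (default 16; 8 accommodates atypical gait styles).
#' @param matched Restrict IMU strides to force-plate-matched events
#'   (default `TRUE`, the laboratory protocol); `FALSE` gives standalone
#'   IMU outcomes for field use.
#' @return A list of class `session_result` with per-source `outcomes`
#'   and `strides`, `entropy` (RCME and RMPE profiles), and a `log` of
#'   per-stage event counts.
#' @export
run_session <- function(session, entropy = TRUE, taus = 1:80, epoch_s = 60,
                        match_tol_s = 0.2, wavelet_hz = 16, matched = TRUE) {
  log <- list()
  res <- list(outcomes = list(), strides = list(), entropy = NULL, log = NULL)

  force_hs <- NULL
  if (!is.null(session$force)) {
    ev <- detect_force_heelstrikes(session$force)
    force_hs <- ev
    log$force_hs <- nrow(ev)
    fstr <- median_ratio_filter(right_strides(ev))
    log$force_strides <- nrow(fstr)
    res$strides$force <- fstr
    if (nrow(fstr) >= 2) res$outcomes$force <- gait_outcomes(fstr)
  }

  if (!is.null(session$ankle)) {
    sag <- scalar_series(session$ankle$gyr[, 3], session$ankle$sample_rate,
                         "sagittal_gyro_dps")
    ev <- pair_ankle_events(detect_ankle_events(sag))
    log$ankle_events <- nrow(ev)
    hs <- ev$time[ev$label == "HS"]
    if (matched && !is.null(force_hs) && nrow(force_hs) > 0) {
      rhs <- force_hs$time[force_hs$foot == "right"]
      hs <- match_events(rhs, hs, match_tol_s)$cand_time
    }
    log$ankle_hs_matched <- length(hs)
    astr <- median_ratio_filter(build_strides(hs, step = 1, source = "ankle"))
    log$ankle_strides <- nrow(astr)
    res$strides$ankle <- astr
    if (nrow(astr) >= 2) res$outcomes$ankle <- gait_outcomes(astr)
  }

  if (!is.null(session$waist)) {
    orient <- madgwick_orientation(session$waist)
    vacc <- vertical_acceleration(session$waist, orient)
    kern <- ricker_kernel(wavelet_hz, session$waist$sample_rate)
    ev <- detect_waist_heelstrikes(vacc, kern)
    log$waist_hs <- nrow(ev)
    hs <- ev$time
    if (matched && !is.null(force_hs) && nrow(force_hs) > 0)
      hs <- match_events(force_hs$time, hs, match_tol_s)$cand_time
    log$waist_hs_matched <- length(hs)
    wstr <- median_ratio_filter(build_strides(hs, step = 2, source = "waist"))
    log$waist_strides <- nrow(wstr)
    res$strides$waist <- wstr
    if (nrow(wstr) >= 2) res$outcomes$waist <- gait_outcomes(wstr)

    if (entropy) {
      resultant <- resultant_acceleration(session$waist)
      eps <- suppressWarnings(split_epochs(resultant, epoch_s))
      log$n_epochs <- length(eps$epochs)
      if (length(eps$epochs) > 0)
        res$entropy <- list(
          rcme = session_entropy(eps, "RCME", taus = taus),
          rmpe = session_entropy(eps, "RMPE", taus = taus))
    }
  }

  res$log <- log
  structure(res, class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  for (src in names(x$outcomes)) {
    cat(sprintf("%-6s ", src)); print(x$outcomes[[src]])
  }
  if (!is.null(x$entropy))
    cat(sprintf("entropy: %d scales over %d epoch(s)\n",
                length(x$entropy$rcme$scales),
                x$entropy$rcme$n_epochs_averaged))
  invisible(x)
}

#' Simulate a two-session cohort and evaluate test-retest reliability
#'
#' Each subject gets its own gait parameters (mean stride duration and
#' stride-duration SD drawn from between-subject distributions); both
#' sessions of a subject share those parameters and differ only in the
#' random stride realization — unless `exchangeable = TRUE`, where the
#' second session gets freshly drawn subject parameters (no subject effect,
#' so the expected ICC is zero).
#'
#' @param n_subjects Number of subjects (default 27).
#' @param seed Integer seed.
#' @param mean_stride_ms,between_mean_sd Population mean and
#'   between-subject SD of subject mean stride duration, ms (1040, 100).
#' @param stride_sd_ms,between_sd_sd Population mean and between-subject SD
#'   of subject stride-duration SD, ms (19.6, 7.5).
#' @param duration_s Walk duration per session (default 180).
#' @param exchangeable Break the subject link between sessions
#'   (default `FALSE`).
#' @param chain `"force"` runs the full force-plate detection chain on
#'   synthesized signals; `"plan"` computes outcomes directly from the
#'   ground-truth stride plan (fast, for Monte-Carlo work).
#' @return A list with data frames `session1` and `session2` (columns
#'   `subject`, `mean_ms`, `sd_ms`, `cv_pct`).
#' @export
simulate_cohort <- function(n_subjects = 27, seed = 1,
                            mean_stride_ms = 1040, between_mean_sd = 100,
                            stride_sd_ms = 19.6, between_sd_sd = 7.5,
                            duration_s = 180, exchangeable = FALSE,
                            chain = c("force", "plan")) {
  chain <- match.arg(chain)
  set.seed(seed)
  draw_subject <- function() list(
    mu = rnorm(1, mean_stride_ms, between_mean_sd),
    sdv = max(2, rnorm(1, stride_sd_ms, between_sd_sd)))
  subj_seeds <- sample.int(2^30, 2 * n_subjects)

  one_session <- function(pars, s_seed) {
    p <- gait_sim_params(mean_stride_ms = pars$mu, stride_sd_ms = pars$sdv,
                         duration_s = duration_s, seed = s_seed)
    if (chain == "plan") {
      truth <- generate_stride_plan(p)
      s <- stride_series(truth$right_hs[-length(truth$right_hs)],
                         truth$stride_durations_ms)
    } else {
      truth <- generate_stride_plan(p)
      rec <- synthesize_forceplate(truth, p)
      s <- median_ratio_filter(right_strides(detect_force_heelstrikes(rec)))
    }
    out <- gait_outcomes(s)
    data.frame(mean_ms = out$mean_ms, sd_ms = out$sd_ms, cv_pct = out$cv_pct)
  }

  rows1 <- list(); rows2 <- list()
  for (i in seq_len(n_subjects)) {
    pars1 <- draw_subject()
    pars2 <- if (exchangeable) draw_subject() else pars1
    rows1[[i]] <- cbind(subject = i,
                        one_session(pars1, subj_seeds[2 * i - 1]))
    rows2[[i]] <- cbind(subject = i,
                        one_session(pars2, subj_seeds[2 * i]))
  }
  list(session1 = do.call(rbind, rows1), session2 = do.call(rbind, rows2))
}

#' Reliability / agreement report across two sessions
#'
#' Runs the full agreement battery per outcome column shared by the two
#' session tables.
#'
#' @param session1,session2 Data frames with a `subject` column and one
#'   column per outcome, as from [simulate_cohort()].
#' @return A named list of [agreement_summary()] results, one per outcome.
#' @export
run_reliability <- function(session1, session2) {
  if (!identical(session1$subject, session2$subject))
    stop("sessions cover different subject lists", call. = FALSE)
  outcomes <- setdiff(intersect(names(session1), names(session2)), "subject")
  res <- lapply(outcomes, function(v)
    agreement_summary(session1[[v]], session2[[v]]))
  names(res) <- outcomes
  res
}

#' Serialize a session result to stable JSON
#'
#' Deterministic textual form of a [run_session()] result (used for report
#' files and byte-identity checks).
#'
#' @param result A `session_result`.
#' @return A JSON string.
#' @export
session_report_json <- function(result) {
  strip <- function(x) {
    if (inherits(x, "entropy_profile"))
      return(list(kind = x$kind, scales = x$scales, values = x$values,
                  n_epochs_averaged = x$n_epochs_averaged))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::toJSON(strip(unclass(result)), digits = NA, auto_unbox = TRUE,
                   na = "null")
}
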