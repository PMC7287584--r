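mk_force <- function(fz, fs = 1000, bw = 700, fy = NULL) {
  n <- length(fz)
  forceplate_recording(t = (0:(n - 1)) / fs, fx = numeric(n),
                       fy = if (is.null(fy)) numeric(n) else fy,
                       fz = fz, body_weight = bw, sample_rate = fs)
}

test_that("force peak gate: constant body weight yields nothing; short excursions rejected", {
  rec <- mk_force(rep(700, 1000))
  expect_equal(nrow(detect_force_peaks(rec)), 0)
  # 2 ms above 1.1 BW at 1000 Hz -> only 2 samples, below the 2.5 ms gate
  fz <- rep(700, 1000); fz[500:501] <- 800
  expect_equal(nrow(detect_force_peaks(mk_force(fz))), 0)
  # 4 ms excursion passes
  fz[500:503] <- 800
  pk <- detect_force_peaks(mk_force(fz))
  expect_equal(nrow(pk), 1)
})

test_that("jerk candidate of a linear ramp equals the ramp slope", {
  # fz ramps from 600 to 900 N over 100 ms then stays: slope 3000 N/s
  fz <- c(rep(600, 200), seq(600, 900, length.out = 101), rep(900, 200))
  rec <- mk_force(fz)
  pk <- detect_force_peaks(rec)
  cand <- jerk_candidates(rec, pk)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$jerk, 3000, tolerance = 1e-6)
})

test_that("backward window truncates at the recording start", {
  # peak 40 ms in; 50 ms window must clip to [0, 0.04]
  fz <- c(seq(600, 900, length.out = 41), rep(900, 100))
  rec <- mk_force(fz)
  pk <- detect_force_peaks(rec)
  cand <- jerk_candidates(rec, pk, window_ms = 50)
  expect_equal(nrow(cand), 1)
  expect_gte(cand$time, 0)
})

test_that("false-candidate filter implements the 0.3 x top-50 rule", {
  cands <- data.frame(time = seq(0, 25, by = 0.5)[1:51],
                      jerk = c(rep(10, 50), 2),
                      source_peak_time = seq(0, 25, by = 0.5)[1:51])
  out <- filter_false_candidates(cands)
  # threshold = 0.3 * mean(top 50) = 3: the jerk-2 candidate is removed
  expect_equal(nrow(out), 50)
  expect_false(2 %in% out$jerk)
  # all-equal jerks are all retained
  cands$jerk <- 7
  expect_equal(nrow(filter_false_candidates(cands)), 51)
  # empty input passes through
  expect_equal(nrow(filter_false_candidates(cands[0, ])), 0)
})

test_that("foot assignment follows the fy sign convention and warns on ties", {
  n <- 2000
  fy <- c(rep(50, 1000), rep(-50, 1000))
  rec <- mk_force(rep(700, n), fy = fy)
  cands <- data.frame(time = c(0.2, 1.2), jerk = c(1, 1),
                      source_peak_time = c(0.2, 1.2))
  ev <- assign_foot(rec, cands)
  expect_equal(ev$foot, c("right", "left"))
  # all-zero fy: tie-break to left, alternation warning
  rec0 <- mk_force(rep(700, n))
  expect_warning(ev0 <- assign_foot(rec0, cands), "alternate")
  expect_equal(ev0$foot, c("left", "left"))
})

test_that("right strides come from consecutive right heel-strikes only", {
  ev <- event_series(times = c(0, 0.52, 1.04, 1.56, 2.08),
                     labels = "HS",
                     foot = c("right", "left", "right", "left", "right"),
                     source = "force")
  s <- right_strides(ev)
  expect_equal(s$duration_ms, c(1040, 1040))
  # single right HS -> empty
  ev1 <- event_series(times = 0.1, labels = "HS", foot = "right")
  expect_equal(nrow(right_strides(ev1)), 0)
})

test_that("noiseless synthetic walk is recovered perfectly with correct foot labels", {
  p <- gait_sim_params(seed = 8, noise_force_N = 0, noise_acc_g = 0,
                       duration_s = 60)
  sess <- simulate_session(p)
  ev <- detect_force_heelstrikes(sess$force)
  truth_all <- sort(c(sess$truth$right_hs, sess$truth$left_hs))
  expect_equal(nrow(ev), length(truth_all))
  expect_lt(max(abs(ev$time - truth_all)), 0.005)
  # foot labels match the truth exactly
  rhs <- ev$time[ev$foot == "right"]
  expect_equal(length(rhs), length(sess$truth$right_hs))
  expect_lt(max(abs(rhs - sess$truth$right_hs)), 0.005)
  # stride durations match the plan within 5 ms each
  s <- right_strides(ev)
  expect_equal(s$duration_ms, sess$truth$stride_durations_ms, tolerance = 0.005)
})

test_that("detection is translation-equivariant and BW-scale invariant", {
  p <- gait_sim_params(seed = 12, noise_force_N = 0, duration_s = 20)
  sess <- simulate_session(p)
  rec <- sess$force
  ev <- detect_force_heelstrikes(rec)
  # shift time base by 3.5 s
  rec_shift <- forceplate_recording(rec$t + 3.5, rec$fx, rec$fy, rec$fz,
                                    rec$body_weight, rec$sample_rate)
  ev_shift <- detect_force_heelstrikes(rec_shift)
  expect_equal(ev_shift$time, ev$time + 3.5, tolerance = 1e-9)
  # scale force and body weight together
  rec_scaled <- forceplate_recording(rec$t, 2.7 * rec$fx, 2.7 * rec$fy,
                                     2.7 * rec$fz, 2.7 * rec$body_weight,
                                     rec$sample_rate)
  ev_scaled <- detect_force_heelstrikes(rec_scaled)
  expect_equal(ev_scaled$time, ev$time, tolerance = 1e-9)
  expect_equal(ev_scaled$foot, ev$foot)
})
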