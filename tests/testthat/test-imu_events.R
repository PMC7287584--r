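test_that("Ricker kernel has the closed-form shape and near-zero sum", {
  k <- ricker_kernel(16, 400)
  s <- k$samples
  mid <- (length(s) + 1) / 2
  expect_equal(which.max(s), mid)        # psi(0) is the global maximum
  expect_equal(s[mid], max(s))
  # the continuous wavelet crosses zero at +/- sigma: on the sample grid the
  # sign change happens between the samples bracketing sigma
  sigma <- 1 / (pi * 16 * sqrt(2))
  i_lo <- mid + floor(sigma * 400); i_hi <- mid + ceiling(sigma * 400)
  expect_lt(s[i_lo] * s[i_hi], 0)
  expect_lt(abs(sum(s)), 1e-9 * max(abs(s)))  # discrete admissibility
  expect_equal(s, rev(s))  # symmetric
  expect_error(ricker_kernel(300, 400), "peak_frequency")
})

test_that("Ricker kernel spectral peak sits at the requested frequency", {
  k <- ricker_kernel(16, 400)
  n <- 4096
  padded <- c(k$samples, rep(0, n - length(k$samples)))
  spec <- Mod(fft(padded))[1:(n / 2)]
  f <- (0:(n / 2 - 1)) * 400 / n
  expect_lt(abs(f[which.max(spec)] - 16), 1)
})

test_that("waist detector: one event per cycle of a pure sinusoid, none on flat input", {
  fs <- 400
  t <- (0:(20 * fs - 1)) / fs
  x <- scalar_series(sin(2 * pi * 1 * t), fs, "vertical_acc_g")
  ev <- detect_waist_heelstrikes(x)
  # interior maxima: ~1 per second
  expect_gte(nrow(ev), 18)
  expect_lte(nrow(ev), 20)
  dt <- diff(ev$time)
  expect_lt(max(abs(dt - 1)), 0.02)

  flat <- scalar_series(rep(0.5, 8000), fs, "vertical_acc_g")
  expect_equal(nrow(detect_waist_heelstrikes(flat)), 0)
})

test_that("waist detector is invariant to amplitude scaling", {
  sess <- short_session(seed = 14, duration_s = 30)
  o <- madgwick_orientation(sess$waist)
  v <- vertical_acceleration(sess$waist, o)
  ev1 <- detect_waist_heelstrikes(v)
  v2 <- scalar_series(17.3 * v$values, v$sample_rate, "vertical_acc_g")
  ev2 <- detect_waist_heelstrikes(v2)
  expect_equal(ev1$time, ev2$time)
})

test_that("zero-lag filtering introduces less than one sample of group delay at 2 Hz", {
  fs <- 400
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 2 * t)
  bf <- signal::butter(2, 6 / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  # cross-correlation peak within +/- 1 sample of zero lag
  mid <- 2001:3000
  lags <- -3:3
  cc <- vapply(lags, function(l) cor(x[mid], y[mid + l]), numeric(1))
  expect_lte(abs(lags[which.max(cc)]), 1)
})

test_that("ankle detector recovers noiseless events within 5 ms and refinement is bounded", {
  p <- gait_sim_params(seed = 15, noise_acc_g = 0, duration_s = 30)
  sess <- simulate_session(p)
  sag <- scalar_series(sess$ankle$gyr[, 3], 400, "sagittal_gyro_dps")
  ev <- detect_ankle_events(sag)
  hs <- ev$time[ev$label == "HS"]
  to <- ev$time[ev$label == "TO"]
  tr <- sess$truth
  m_hs <- match_events(tr$right_hs, hs, 0.05)
  expect_equal(nrow(m_hs), length(tr$right_hs))
  expect_lt(max(abs(m_hs$ref_time - m_hs$cand_time)), 0.005)
  # a swing-anchored method can only see toe-offs followed by a completed
  # swing: the final toe-off of the window has none
  detectable_to <- tr$right_to[tr$right_to < max(tr$right_hs)]
  m_to <- match_events(detectable_to, to, 0.05)
  expect_equal(nrow(m_to), length(detectable_to))
  expect_lt(max(abs(m_to$ref_time - m_to$cand_time)), 0.005)
  # refinement never moves an event by more than halfwidth samples:
  # unrefined minima are on the sample grid, so |refined - grid| <= 2/fs
  off <- (hs * 400) %% 1
  expect_true(all(pmin(off, 1 - off) <= 2 + 1e-9))
  # constant signal: nothing detected
  flat <- scalar_series(rep(0, 4000), 400, "sagittal_gyro_dps")
  expect_equal(nrow(detect_ankle_events(flat)), 0)
})

test_that("parabola vertex of a symmetric triple is the center sample", {
  x <- c(10, 4, 0, 4, 10)
  expect_equal(gaitvar:::parabola_vertex(x, 3L, 1L), 0)
  expect_equal(gaitvar:::parabola_vertex(x, 3L, 2L), 0)
})

test_that("alternation pairing keeps the earliest of each same-label run", {
  ev <- event_series(times = c(1, 2, 3, 4), labels = c("HS", "TO", "HS", "TO"),
                     foot = "right", source = "ankle")
  expect_equal(pair_ankle_events(ev)$time, c(1, 2, 3, 4))
  ev2 <- event_series(times = c(1, 1.5, 2), labels = c("HS", "HS", "TO"),
                      foot = "right", source = "ankle")
  out <- pair_ankle_events(ev2)
  expect_equal(out$time, c(1, 2))
  expect_equal(out$label, c("HS", "TO"))
})

test_that("alternation pairing always alternates under random duplications", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(3:20, 1)
    times <- sort(runif(n, 0, 10))
    labels <- sample(c("HS", "TO"), n, replace = TRUE)
    ev <- event_series(times = times, labels = labels, foot = "right",
                       source = "ankle")
    out <- pair_ankle_events(ev)
    if (nrow(out) > 1)
      expect_true(all(out$label[-1] != out$label[-nrow(out)]))
  }
})
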