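## Synthetic 3-min walk generator: a stride plan with ground-truth events,
## rendered into a summed force-plate signal and waist/ankle IMU streams that
## the detection chains can be validated against.

#' Simulation parameters for a synthetic walking trial
#'
#' Defaults emulate the laboratory conditions the package targets: 3-minute
#' continuous walks by healthy older adults with mean stride duration 1040 ms
#' and stride-duration SD 19.6 ms, force plate at 1000 Hz, IMUs at 400 Hz.
#'
#' @param mean_stride_ms Mean right-stride duration in ms.
#' @param stride_sd_ms Stationary SD of stride durations in ms.
#' @param ar1_phi Lag-1 autocorrelation of the stride-duration AR(1) process
#'   (0 = white, the default: no temporal structure is imposed).
#' @param duration_s Walk duration in seconds.
#' @param body_mass_kg Body mass in kg (body weight = mass x 9.81 N).
#' @param duty_factor Fraction of the stride spent in stance per foot
#'   (must lie in (0.5, 0.75); overlapping stances create double support).
#' @param transient_amp Heel-strike transient amplitude in N; a short
#'   (12 ms) impact spike whose rising edge carries the peak jerk.
#' @param noise_force_N White-noise SD added to each force channel, N.
#' @param noise_acc_g White-noise SD added to each accelerometer axis, g.
#' @param waist_tilt_deg Static tilt of the waist sensor about its x axis,
#'   degrees (a small sinusoidal sway is superimposed).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `gait_sim_params`.
#' @export
gait_sim_params <- function(mean_stride_ms = 1040, stride_sd_ms = 19.6,
                            ar1_phi = 0, duration_s = 180,
                            body_mass_kg = 75, duty_factor = 0.62,
                            transient_amp = 400, noise_force_N = 5,
                            noise_acc_g = 0.02, waist_tilt_deg = 8,
                            seed = 1L) {
  stopifnot(mean_stride_ms > 0, stride_sd_ms >= 0,
            ar1_phi > -1, ar1_phi < 1,
            duration_s >= 0, body_mass_kg > 0,
            duty_factor > 0.5, duty_factor < 0.75,
            transient_amp >= 0, noise_force_N >= 0, noise_acc_g >= 0)
  structure(list(mean_stride_ms = mean_stride_ms, stride_sd_ms = stride_sd_ms,
                 ar1_phi = ar1_phi, duration_s = duration_s,
                 body_mass_kg = body_mass_kg, duty_factor = duty_factor,
                 transient_amp = transient_amp, noise_force_N = noise_force_N,
                 noise_acc_g = noise_acc_g, waist_tilt_deg = waist_tilt_deg,
                 seed = as.integer(seed)),
            class = "gait_sim_params")
}

## Force-plate and IMU sampling rates of the emulated setup
FORCE_FS <- 1000
IMU_FS <- 400
## Margin kept free of events at the end of the walk so the last stance and
## the sync pulse fit inside the recording
END_MARGIN_S <- 1.0

#' Draw the ground-truth stride plan
#'
#' Right-stride durations follow a stationary AR(1) process
#' `d_k = mu + phi (d_{k-1} - mu) + e_k`, `e_k ~ N(0, sigma^2 (1 - phi^2))`,
#' so the stationary SD equals `stride_sd_ms` for any `phi`. Left
#' heel-strikes sit half a stride after the right ones (plus a small jitter
#' proportional to the stride SD); toe-offs follow each same-foot
#' heel-strike by `duty_factor` strides.
#'
#' @param params A [gait_sim_params()] list.
#' @return A list of class `gait_truth` with sorted event vectors
#'   `right_hs`, `left_hs`, `right_to`, `left_to` (seconds) and
#'   `stride_durations_ms` (= `diff(right_hs)` in ms).
#' @export
generate_stride_plan <- function(params) {
  mu <- params$mean_stride_ms
  sdv <- params$stride_sd_ms
  phi <- params$ar1_phi
  dur <- params$duration_s
  set.seed(params$seed)

  t0 <- 0.6  # first right heel-strike
  t_max <- dur - END_MARGIN_S
  empty <- structure(list(right_hs = numeric(), left_hs = numeric(),
                          right_to = numeric(), left_to = numeric(),
                          stride_durations_ms = numeric()),
                     class = "gait_truth")
  if (t_max <= t0) return(empty)

  n <- ceiling((t_max - t0) * 1000 / mu) + 4L
  d <- numeric(n)
  if (sdv == 0) {
    d[] <- mu
  } else {
    d[1] <- mu + rnorm(1, 0, sdv)
    eps <- rnorm(n - 1, 0, sdv * sqrt(1 - phi^2))
    for (k in 2:n) d[k] <- mu + phi * (d[k - 1] - mu) + eps[k - 1]
    d <- pmax(d, 0.4 * mu)  # guard against non-physiological draws
  }
  right_hs <- t0 + c(0, cumsum(d[-n])) / 1000
  keep <- right_hs <= t_max
  right_hs <- right_hs[keep]
  d <- d[keep]
  if (length(right_hs) < 2) return(empty)

  m <- length(right_hs)
  jitter_sd <- sdv / 4
  jit <- if (jitter_sd > 0) rnorm(m, 0, jitter_sd) else numeric(m)
  left_hs <- right_hs + (0.5 * d + jit) / 1000
  right_to <- right_hs + params$duty_factor * d / 1000
  left_stride <- c(diff(left_hs) * 1000, mu)
  left_to <- left_hs + params$duty_factor * left_stride / 1000

  clip <- function(x) x[x > 0 & x <= dur - 0.2]
  structure(list(right_hs = right_hs, left_hs = clip(left_hs),
                 right_to = clip(right_to), left_to = clip(left_to),
                 stride_durations_ms = diff(right_hs) * 1000),
            class = "gait_truth")
}

## Cosine interpolation through knots (u in [0,1] of stance); smooth
## M-shaped vertical GRF with a steep initial rise, peaks of 1.20 and 1.15
## body weights and a mid-stance valley of 0.72. The knot set keeps the
## walk-averaged vertical force close to body weight.
STANCE_KNOT_U <- c(0, 0.055, 0.45, 0.75, 1)
STANCE_KNOT_V <- c(0, 1.20, 0.72, 1.15, 0)

cos_interp <- function(u, ku, kv) {
  v <- numeric(length(u))
  for (s in seq_len(length(ku) - 1)) {
    in_seg <- u >= ku[s] & u <= ku[s + 1]
    if (!any(in_seg)) next
    f <- (u[in_seg] - ku[s]) / (ku[s + 1] - ku[s])
    v[in_seg] <- kv[s] + (kv[s + 1] - kv[s]) * 0.5 * (1 - cos(pi * f))
  }
  v
}

## Add a raised-cosine pulse of amplitude `amp`, centered at `center`, with
## half-width `hw` seconds into signal `x` sampled on grid `t`.
add_pulse <- function(x, t, center, hw, amp, fs) {
  i0 <- max(1L, floor((center - hw) * fs) + 1L)
  i1 <- min(length(x), ceiling((center + hw) * fs) + 1L)
  if (i1 < i0) return(x)
  idx <- i0:i1
  u <- (t[idx] - center) / hw
  w <- abs(u) <= 1
  x[idx[w]] <- x[idx[w]] + amp * 0.5 * (1 + cos(pi * u[w]))
  x
}

#' Render the summed force-plate signal for a stride plan
#'
#' Each stance contributes a double-bump vertical profile (peaks ~1.2 and
#' ~1.15 body weights, mid-stance valley ~0.72) plus a 12 ms heel-strike
#' impact transient whose rising edge starts exactly at the true heel-strike,
#' so the peak force jerk marks the event. The mediolateral force `fy` is
#' positive during right-foot stance and negative during left-foot stance.
#'
#' @param truth A `gait_truth` plan from [generate_stride_plan()].
#' @param params The matching [gait_sim_params()].
#' @return A [forceplate_recording()] at 1000 Hz with a 1.5 V sync pulse on
#'   the aux channel over the last half second.
#' @export
synthesize_forceplate <- function(truth, params) {
  set.seed(params$seed + 1L)
  fs <- FORCE_FS
  dur <- params$duration_s
  bw <- params$body_mass_kg * GRAVITY
  n <- max(0L, as.integer(round(dur * fs)))
  t <- seq_len(n) / fs - 1 / fs
  fz <- numeric(n); fy <- numeric(n); fx <- numeric(n)

  add_foot <- function(hs, side_sign) {
    if (length(hs) == 0) return(invisible())
    strides <- c(diff(hs), params$mean_stride_ms / 1000)
    for (k in seq_along(hs)) {
      stance <- params$duty_factor * strides[k]
      i0 <- max(1L, floor(hs[k] * fs) + 1L)
      i1 <- min(n, ceiling((hs[k] + stance) * fs) + 1L)
      if (i1 <= i0) next
      idx <- i0:i1
      u <- (t[idx] - hs[k]) / stance
      u <- pmin(pmax(u, 0), 1)
      prof <- cos_interp(u, STANCE_KNOT_U, STANCE_KNOT_V)
      fz[idx] <<- fz[idx] + bw * prof
      # mediolateral force: loading-response pulse over the first half of
      # stance only, signed by foot side -- late stance contributes nothing,
      # so the window after a heel-strike sees the striking foot alone
      ml <- ifelse(abs(u - 0.25) <= 0.25,
                   0.5 * (1 + cos(pi * (u - 0.25) / 0.25)), 0)
      fy[idx] <<- fy[idx] + side_sign * 0.10 * bw * ml
      fx[idx] <<- fx[idx] + 0.03 * bw * sin(2 * pi * u)
      # impact transient: raised cosine centered 6 ms after heel-strike,
      # half-width 6 ms; max positive jerk lands ~3 ms after the event
      fz <<- add_pulse(fz, t, hs[k] + 0.006, 0.006, params$transient_amp, fs)
    }
  }
  add_foot(truth$right_hs, +1)
  add_foot(truth$left_hs, -1)

  if (params$noise_force_N > 0 && n > 0) {
    fz <- fz + rnorm(n, 0, params$noise_force_N)
    fy <- fy + rnorm(n, 0, params$noise_force_N)
    fx <- fx + rnorm(n, 0, params$noise_force_N)
  }
  aux <- numeric(n)
  if (n > 0) aux[t >= dur - 0.5] <- 1.5
  forceplate_recording(t = t, fx = fx, fy = fy, fz = fz, body_weight = bw,
                       sample_rate = fs, aux = aux)
}

## Earth-frame waist acceleration components shared by the waist synthesizer
## and its validation: smooth step-frequency oscillation plus a sharp
## positive pulse centered at every heel-strike (both feet).
waist_vertical_earth <- function(t, truth, params) {
  all_hs <- sort(c(truth$right_hs, truth$left_hs))
  v <- numeric(length(t))
  if (length(all_hs) >= 2) {
    f_step <- 1 / mean(diff(all_hs))
    v <- 0.12 * sin(2 * pi * f_step * (t - all_hs[1]))
    fs <- 1 / (t[2] - t[1])
    # heel-strike impact: raised cosine, 30 ms half-width -- wide enough
    # that its energy sits inside the detector's 6 Hz low-pass band
    for (h in all_hs) v <- add_pulse(v, t, h, 0.030, 0.5, fs)
  }
  v
}

rot_x <- function(theta_rad) {
  ct <- cos(theta_rad); st <- sin(theta_rad)
  matrix(c(1, 0, 0, 0, ct, -st, 0, st, ct), 3, 3, byrow = TRUE)
}

#' Render the waist-worn IMU streams for a stride plan
#'
#' The earth-frame vertical acceleration is a smooth step-frequency
#' oscillation with a sharp positive pulse at every heel-strike. The sensor
#' is tilted about its x axis by `waist_tilt_deg` with a slow sinusoidal
#' sway; the gyroscope carries the exact angular rate of that orientation,
#' and the accelerometer reports specific force (movement + 1 g gravity) in
#' the sensor frame.
#'
#' @param truth A `gait_truth` plan.
#' @param params The matching [gait_sim_params()].
#' @return An [imu_recording()] at 400 Hz, placement `"waist"`, with the
#'   noiseless earth-frame vertical acceleration attached as attribute
#'   `earth_vacc` for validation.
#' @export
synthesize_waist_imu <- function(truth, params) {
  set.seed(params$seed + 2L)
  fs <- IMU_FS
  dur <- params$duration_s
  n <- max(0L, as.integer(round(dur * fs)))
  t <- seq_len(n) / fs - 1 / fs

  a_vert <- waist_vertical_earth(t, truth, params)
  all_hs <- sort(c(truth$right_hs, truth$left_hs))
  if (length(all_hs) >= 2) {
    f_stride <- 1 / (2 * mean(diff(all_hs)))
    a_ml <- 0.05 * sin(2 * pi * f_stride * t)
    a_ap <- 0.04 * sin(2 * pi * 2 * f_stride * t + 0.5)
  } else {
    a_ml <- numeric(n); a_ap <- numeric(n)
  }

  sway_amp <- 2; sway_f <- 0.25  # degrees, Hz
  theta_deg <- params$waist_tilt_deg + sway_amp * sin(2 * pi * sway_f * t)
  theta_dot_dps <- sway_amp * 2 * pi * sway_f * cos(2 * pi * sway_f * t)

  acc <- matrix(0, n, 3); gyr <- matrix(0, n, 3)
  th <- theta_deg * pi / 180
  # specific force in sensor frame: Rx(theta)^T (a_earth + z_hat)
  fe_x <- a_ap; fe_y <- a_ml; fe_z <- a_vert + 1
  ct <- cos(th); st <- sin(th)
  acc[, 1] <- fe_x
  acc[, 2] <- ct * fe_y + st * fe_z
  acc[, 3] <- -st * fe_y + ct * fe_z
  gyr[, 1] <- theta_dot_dps

  if (params$noise_acc_g > 0 && n > 0) {
    acc <- acc + matrix(rnorm(3 * n, 0, params$noise_acc_g), n, 3)
    gyr <- gyr + matrix(rnorm(3 * n, 0, 0.2), n, 3)
  }
  aux <- numeric(n)
  if (n > 0) aux[t >= dur - 0.5] <- 1.5
  rec <- imu_recording(t = t, acc = acc, gyr = gyr, placement = "waist",
                       sample_rate = fs, aux = aux)
  attr(rec, "earth_vacc") <- a_vert
  rec
}

#' Render the ankle-worn (right shank) IMU streams for a stride plan
#'
#' The sagittal gyroscope channel (`gz`) carries, per right stride, a large
#' positive mid-swing lobe flanked by sharp negative troughs centered exactly
#' at the true toe-off and heel-strike instants; the accelerometer is
#' quiescent gravity plus noise.
#'
#' @param truth A `gait_truth` plan.
#' @param params The matching [gait_sim_params()].
#' @return An [imu_recording()] at 400 Hz, placement `"ankle"`.
#' @export
synthesize_ankle_imu <- function(truth, params) {
  set.seed(params$seed + 3L)
  fs <- IMU_FS
  dur <- params$duration_s
  n <- max(0L, as.integer(round(dur * fs)))
  t <- seq_len(n) / fs - 1 / fs

  gz <- numeric(n)
  hs <- truth$right_hs; to <- truth$right_to
  for (h in hs) gz <- add_pulse(gz, t, h, 0.025, -120, fs)
  for (x in to) gz <- add_pulse(gz, t, x, 0.025, -120, fs)
  # walking was ongoing before the window: render the swing (and its
  # toe-off) that precedes the first recorded heel-strike, so that event is
  # detectable like every other
  if (length(hs) >= 1) {
    stride1 <- if (length(hs) >= 2) hs[2] - hs[1]
               else params$mean_stride_ms / 1000
    to0 <- hs[1] - (1 - params$duty_factor) * stride1
    if (to0 > 0.05) {
      gz <- add_pulse(gz, t, to0, 0.025, -120, fs)
      swing0 <- to0 + 0.04; swing1 <- hs[1] - 0.04
      if (swing1 > swing0)
        gz <- add_pulse(gz, t, (swing0 + swing1) / 2,
                        (swing1 - swing0) / 2, 280, fs)
    }
  }
  if (length(hs) >= 2) {
    for (k in seq_len(length(hs) - 1)) {
      to_k <- to[to > hs[k] & to < hs[k + 1]]
      if (length(to_k) != 1) next
      swing0 <- to_k + 0.04; swing1 <- hs[k + 1] - 0.04
      if (swing1 <= swing0) next
      mid <- (swing0 + swing1) / 2
      gz <- add_pulse(gz, t, mid, (swing1 - swing0) / 2, 280, fs)
    }
  }

  acc <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  gyr <- cbind(numeric(n), numeric(n), gz)
  if (params$noise_acc_g > 0 && n > 0) {
    acc <- acc + matrix(rnorm(3 * n, 0, params$noise_acc_g), n, 3)
    gyr <- gyr + matrix(rnorm(3 * n, 0, 25 * params$noise_acc_g), n, 3)
  }
  aux <- numeric(n)
  if (n > 0) aux[t >= dur - 0.5] <- 1.5
  imu_recording(t = t, acc = acc, gyr = gyr, placement = "ankle",
                sample_rate = fs, aux = aux)
}

#' Simulate one complete measurement session
#'
#' Draws a stride plan and renders the three synchronized recordings on a
#' shared time base.
#'
#' @param params A [gait_sim_params()] list.
#' @return A list of class `gait_session` with elements `truth`, `force`,
#'   `waist`, `ankle` and `params`.
#' @export
simulate_session <- function(params = gait_sim_params()) {
  truth <- generate_stride_plan(params)
  structure(list(truth = truth,
                 force = synthesize_forceplate(truth, params),
                 waist = synthesize_waist_imu(truth, params),
                 ankle = synthesize_ankle_imu(truth, params),
                 params = params),
            class = "gait_session")
}
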