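## Synthetic observers: the generative model for every data stream the
## analysis consumes.
##
## A synthetic observer carries (i) a ground-truth 1-D perceptual scale
## over the stimuli, (ii) a triplet decision model (distance comparison
## corrupted by logistic noise and lapses), (iii) a head-movement
## strategy (continuous pitch nodding, continuous yaw shaking, or
## static), and (iv) a gaze distribution of controllable spread.  All
## three simulators are fully deterministic given their seeds.

#' Default ground-truth scale parameters
#'
#' Parameters of the generating scale `s(Sph) = a + b * c^Sph`, one
#' `(a, b)` pair per addition power and a shared base `c`.  The defaults
#' reproduce the qualitative structure of measured distortion scales:
#' zero at the undistorted reference, negative values for minus lenses,
#' steeper growth for plus lenses, and partial compensation of perceived
#' distortion by addition power at negative Sph.
#'
#' The defaults place all eleven stimuli at distinct scale values:
#' higher addition power lifts the whole curve (`a3 > a1`) and
#' steepens the plus-lens branch (`b3 > b1`), so Add compensates
#' perceived distortion at negative Sph but amplifies it at positive
#' Sph, with the Sph 5 / Add 3 lens the most distorted condition.
#'
#' @param a1,b1 Offset and slope for Add = 1 dpt.
#' @param a3,b3 Offset and slope for Add = 3 dpt.
#' @param c Shared exponential base (> 0).
#' @return A list of class `scale_params`.
#' @export
scale_params <- function(a1 = -0.55, b1 = 0.35, a3 = -0.3, b3 = 0.4,
                         c = 1.4) {
  if (c <= 0) stopf("exponential base `c` must be positive")
  structure(list(a1 = a1, b1 = b1, a3 = a3, b3 = b3, c = c),
            class = "scale_params")
}

#' Materialize a ground-truth scale over a stimulus set
#'
#' Evaluates the exponential generating model at every stimulus:
#' non-reference lenses get `s = a_add + b_add * c^sph`, the undistorted
#' reference gets exactly 0.
#'
#' @param params A [scale_params()].
#' @param stimuli A stimulus table with columns `sph`, `add`,
#'   `is_reference` (e.g. [build_stimulus_set()] output, or the
#'   augmented table attached to a trial list, in which case the catch
#'   lens is scored with the Add-3 parameters).
#' @return Numeric vector of ground-truth scale values, one per row of
#'   `stimuli`.
#' @examples
#' materialize_scale(scale_params(), build_stimulus_set())
#' @export
materialize_scale <- function(params, stimuli) {
  stopifnot(inherits(params, "scale_params"))
  vapply(seq_len(nrow(stimuli)), function(i) {
    if (isTRUE(stimuli$is_reference[i])) return(0)
    ab <- switch(as.character(stimuli$add[i]),
                 "1" = c(params$a1, params$b1),
                 "3" = c(params$a3, params$b3),
                 stopf("no scale parameters for add = %g (stimulus row %d)",
                       stimuli$add[i], i))
    ab[1] + ab[2] * params$c^stimuli$sph[i]
  }, numeric(1))
}

#' Describe a synthetic observer
#'
#' @param sigma Decision noise in scale units (>= 0; 0 means a
#'   deterministic observer).
#' @param lapse Lapse rate in `[0, 0.5)`: probability of a stimulus-
#'   independent random answer.
#' @param strategy Head-movement strategy: `"dynamic-pitch"` (nodding),
#'   `"dynamic-yaw"` (shaking) or `"static"`.
#' @param gaze_sd Gaze spread in degrees (> 0).
#' @param gaze_center Gaze centroid `(lon, lat)` in degrees.
#' @param amplitude,frequency Oscillation amplitude (deg) and frequency
#'   (Hz) of the dynamic head movement.
#' @param seed Integer seed for all of this observer's randomness.
#' @return A list of class `observer_profile`.
#' @export
observer_profile <- function(sigma = 0.05, lapse = 0,
                             strategy = c("dynamic-pitch", "dynamic-yaw",
                                          "static"),
                             gaze_sd = 5, gaze_center = c(0, -5),
                             amplitude = 15, frequency = 0.5,
                             seed = 1L) {
  strategy <- match.arg(strategy)
  if (sigma < 0) stopf("`sigma` must be non-negative")
  if (lapse < 0 || lapse >= 0.5) stopf("`lapse` must lie in [0, 0.5)")
  if (gaze_sd <= 0) stopf("`gaze_sd` must be positive")
  structure(list(sigma = sigma, lapse = lapse, strategy = strategy,
                 gaze_sd = gaze_sd, gaze_center = gaze_center,
                 amplitude = amplitude, frequency = frequency,
                 seed = as.integer(seed)),
            class = "observer_profile")
}

#' Simulate triplet responses
#'
#' For a trial with anchor `a` and choices `1`, `2`, the observer
#' compares scale distances `d1 = |s1 - sa|` and `d2 = |s2 - sa|` and
#' answers choice 1 with probability
#' `lapse/2 + (1 - lapse) * plogis((d2 - d1) / sigma)`.
#' A noiseless observer (`sigma = 0`, `lapse = 0`) answers by exact
#' argmin, with ties broken by a fair seeded coin.
#'
#' @param trials A [build_trial_list()] result.
#' @param scale_values Ground-truth scale values indexed like the trial
#'   list's stimulus table (see [materialize_scale()]).
#' @param profile An [observer_profile()].
#' @return A data frame of class `triplet_responses`: columns
#'   `trial_index`, `pair_id`, `answer` (1 or 2), `is_catch`,
#'   `n_repeats` (always 1 for simulated observers).
#' @export
answer_trials <- function(trials, scale_values, profile) {
  stopifnot(inherits(trials, "data.frame"), inherits(profile, "observer_profile"))
  idx <- c(trials$choice1, trials$anchor, trials$choice2)
  if (any(idx < 1L | idx > length(scale_values))) {
    stopf("trial references a stimulus with no scale value")
  }
  d1 <- abs(scale_values[trials$choice1] - scale_values[trials$anchor])
  d2 <- abs(scale_values[trials$choice2] - scale_values[trials$anchor])
  p1 <- if (profile$sigma > 0) {
    plogis((d2 - d1) / profile$sigma)
  } else {
    ifelse(d1 < d2, 1, ifelse(d1 > d2, 0, 0.5))
  }
  p1 <- profile$lapse / 2 + (1 - profile$lapse) * p1
  ans <- with_seed(profile$seed,
                   ifelse(runif(nrow(trials)) < p1, 1L, 2L))
  structure(data.frame(trial_index = trials$trial_index,
                       pair_id = trials$pair_id,
                       answer = ans,
                       is_catch = trials$is_catch,
                       n_repeats = 1L),
            class = c("triplet_responses", "data.frame"))
}

# Smooth small-amplitude jitter: two seeded low-frequency sinusoids with
# total sd `sd_deg`.  Smoothness keeps the static strategy's mean
# absolute angular velocity far below the 10 deg/s dynamic threshold
# (white noise resampled at 90 Hz would not).
smooth_jitter <- function(t, sd_deg = 0.5) {
  f <- runif(2, 0.1, 0.3)
  phi <- runif(2, 0, 2 * pi)
  amp <- sd_deg                  # two components, each variance amp^2/2
  amp * sin(2 * pi * f[1] * t + phi[1]) +
    amp * sin(2 * pi * f[2] * t + phi[2])
}

#' Simulate a head-orientation trace
#'
#' Dynamic observers oscillate sinusoidally on their primary axis
#' (`pitch(t) = A sin(2 pi f t)` for nodding, the analogue on yaw for
#' shaking) with small smooth jitter (sd 0.5 deg) on the other axes;
#' static observers show jitter only.  Yaw/pitch/roll are composed in
#' the intrinsic y-x-z order into orientation quaternions sampled at
#' `rate`.
#'
#' @param profile An [observer_profile()].
#' @param duration Trace duration in seconds.
#' @param rate Sampling rate in Hz.
#' @return A data frame of class `head_trace` with columns `t`, `qw`,
#'   `qx`, `qy`, `qz` (unit quaternions).
#' @export
simulate_head_trace <- function(profile, duration = 10, rate = 90) {
  stopifnot(inherits(profile, "observer_profile"))
  if (duration <= 0 || rate <= 0) stopf("duration and rate must be positive")
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  ang <- with_seed(profile$seed + 1L, {
    yaw <- smooth_jitter(t)
    pitch <- smooth_jitter(t)
    roll <- smooth_jitter(t)
    main <- profile$amplitude * sin(2 * pi * profile$frequency * t)
    # the oscillation replaces (not adds to) jitter on the primary axis,
    # so its mean absolute velocity is exactly 4 * A * f
    if (profile$strategy == "dynamic-pitch") pitch <- main
    if (profile$strategy == "dynamic-yaw") yaw <- main
    cbind(yaw, pitch, roll)
  })
  q <- tait_bryan_to_quaternion(ang[, 1], ang[, 2], ang[, 3])
  structure(data.frame(t = t, qw = q[, 1], qx = q[, 2], qy = q[, 3],
                       qz = q[, 4]),
            class = c("head_trace", "data.frame"))
}

# Direction vector for (lon, lat) in degrees; head frame is
# right-handed, x right, y up, z backward (straight ahead = -z).
lonlat_to_vec <- function(lon, lat) {
  lon <- deg2rad(lon); lat <- deg2rad(lat)
  cbind(x = cos(lat) * sin(lon), y = sin(lat), z = -cos(lat) * cos(lon))
}

vec_to_lonlat <- function(v) {
  cbind(lon = rad2deg(atan2(v[, 1], -v[, 3])),
        lat = rad2deg(asin(pmin(1, pmax(-1, v[, 2])))))
}

#' Simulate binocular gaze samples
#'
#' Draws the binocular gaze direction with longitude and latitude
#' independently Gaussian around the observer's gaze center (sd
#' `gaze_sd`), then constructs left- and right-eye unit vectors
#' symmetrically offset in longitude so that their normalized average
#' equals the binocular direction exactly.
#'
#' @param profile An [observer_profile()].
#' @param n Number of gaze samples.
#' @param eye_offset Horizontal half-angle between the eyes' directions
#'   in degrees (vergence stand-in).
#' @param rate Nominal sampling rate (Hz) used for the timestamps.
#' @return A data frame of class `gaze_samples` with columns `t`,
#'   `lx, ly, lz`, `rx, ry, rz` (per-eye unit vectors).
#' @export
simulate_gaze <- function(profile, n = 1000, eye_offset = 1, rate = 120) {
  stopifnot(inherits(profile, "observer_profile"))
  if (n <= 0) stopf("`n` must be positive")
  ll <- with_seed(profile$seed + 2L, {
    cbind(rnorm(n, profile$gaze_center[1], profile$gaze_sd),
          rnorm(n, profile$gaze_center[2], profile$gaze_sd))
  })
  d <- lonlat_to_vec(ll[, 1], ll[, 2])
  # rotate the binocular direction by +/- eye_offset about the local
  # vertical axis (orthogonal to d): the two eye vectors then average
  # to cos(offset) * d, whose normalization is d exactly
  up <- cbind(0, 1, 0) [rep(1, n), , drop = FALSE]
  proj <- rowSums(up * d)
  axis <- up - proj * d
  axis <- axis / sqrt(rowSums(axis^2))
  horiz <- cbind(axis[, 2] * d[, 3] - axis[, 3] * d[, 2],
                 axis[, 3] * d[, 1] - axis[, 1] * d[, 3],
                 axis[, 1] * d[, 2] - axis[, 2] * d[, 1])
  co <- cos(deg2rad(eye_offset)); si <- sin(deg2rad(eye_offset))
  left <- co * d - si * horiz
  right <- co * d + si * horiz
  structure(data.frame(t = (seq_len(n) - 1L) / rate,
                       lx = left[, 1], ly = left[, 2], lz = left[, 3],
                       rx = right[, 1], ry = right[, 2], rz = right[, 3]),
            class = c("gaze_samples", "data.frame"))
}

#' Generate a full synthetic cohort
#'
#' Builds per-subject ground-truth scales (the shared exponential scale
#' plus independent per-stimulus Gaussian perturbations of sd
#' `subject_sd`, reference pinned at 0) and observer profiles.  By
#' default 7 subjects are dynamic movers (4 pitch, 3 yaw) and 6 are
#' static, matching the grouping observed in distortion-scaling cohorts.
#' Behavior parameters are drawn independently of the scale values, so
#' cohorts generated here embody the null hypothesis of no
#' behavior-perception link.
#'
#' @param n_subjects Number of observers.
#' @param stimuli Stimulus table (with catch lens appended if responses
#'   to a trial list with catch trials will be simulated).
#' @param params A [scale_params()].
#' @param subject_sd Per-subject, per-stimulus scale perturbation sd.
#' @param sigma,lapse Decision-model parameters shared by all subjects.
#' @param seed Master seed.
#' @return A list of class `cohort`: `profiles` (list of
#'   [observer_profile()]), `true_scales` (matrix, stimuli x subjects),
#'   `params`, `seed`.
#' @export
make_cohort <- function(n_subjects = 13, stimuli, params = scale_params(),
                        subject_sd = 0.05, sigma = 0.05, lapse = 0,
                        seed = 1L) {
  if (n_subjects < 1) stopf("`n_subjects` must be at least 1")
  base <- materialize_scale(params, stimuli)
  n_dyn <- round(n_subjects * 7 / 13)
  strategies <- rep("static", n_subjects)
  if (n_dyn > 0) {
    strategies[seq_len(n_dyn)] <- rep(c("dynamic-pitch", "dynamic-yaw"),
                                      length.out = n_dyn)
  }
  seeds <- derive_seeds(seed, 2L * n_subjects)
  true_scales <- matrix(NA_real_, nrow = length(base), ncol = n_subjects)
  profiles <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    pert <- with_seed(seeds[j], rnorm(length(base), 0, subject_sd))
    pert[which(stimuli$is_reference)] <- 0
    true_scales[, j] <- base + pert
    gaze <- with_seed(seeds[n_subjects + j],
                      c(runif(1, 2, 8), runif(1, -15, 5)))
    profiles[[j]] <- observer_profile(
      sigma = sigma, lapse = lapse, strategy = strategies[j],
      gaze_sd = gaze[1], gaze_center = c(0, gaze[2]),
      seed = seeds[n_subjects + j]
    )
  }
  structure(list(profiles = profiles, true_scales = true_scales,
                 params = params, seed = as.integer(seed)),
            class = "cohort")
}

#' Write or read simulated responses as CSV
#'
#' @param responses A `triplet_responses` data frame.
#' @param path CSV path.
#' @param subject_id Identifier stored in the `subject_id` column.
#' @export
write_responses_csv <- function(responses, path, subject_id = 1L) {
  out <- data.frame(subject_id = subject_id,
                    trial_index = responses$trial_index,
                    pair_id = responses$pair_id,
                    answer = responses$answer,
                    is_catch = responses$is_catch,
                    n_repeats = responses$n_repeats)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a head trace or gaze samples as CSV
#'
#' @param x A `head_trace` or `gaze_samples` data frame.
#' @param path CSV path.
#' @export
write_trace_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
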