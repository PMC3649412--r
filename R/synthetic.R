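#' Cued acquisition protocol
#'
#' Timing of one cued movement animation and of a session. Each animation
#' lasts 8.3 s: 0.4 s initial rest, 2.9 s forward movement, 1.25 s hold,
#' 2.9 s backward movement, 0.8 s final rest; subjects rest 3 s between
#' movements. A session presents 5 repetitions of each of the 7 movements in
#' random order; a test comprises 5 sessions.
#'
#' @param initial_rest,forward,hold,backward,final_rest animation phase
#'   durations in seconds.
#' @param inter_movement_rest rest between movements, seconds.
#' @param reps_per_movement repetitions of each movement per session.
#' @param sessions sessions per subject test.
#' @param sample_rate sampling rate in Hz.
#' @return list of class `protocol`.
#' @export
protocol <- function(initial_rest = 0.4, forward = 2.9, hold = 1.25,
                     backward = 2.9, final_rest = 0.8,
                     inter_movement_rest = 3, reps_per_movement = 5,
                     sessions = 5, sample_rate = 1000) {
  stopifnot(initial_rest > 0, forward > 0, hold > 0, backward > 0,
            final_rest > 0, inter_movement_rest > 0, reps_per_movement >= 1,
            sessions >= 1, sample_rate > 0)
  structure(list(initial_rest = initial_rest, forward = forward, hold = hold,
                 backward = backward, final_rest = final_rest,
                 inter_movement_rest = inter_movement_rest,
                 reps_per_movement = as.integer(reps_per_movement),
                 sessions = as.integer(sessions), sample_rate = sample_rate),
            class = "protocol")
}

#' Duration of one animation (seconds)
#' @param p a [protocol()].
#' @return animation duration (8.3 s at defaults).
#' @export
animation_duration <- function(p) {
  p$initial_rest + p$forward + p$hold + p$backward + p$final_rest
}

#' Duration of a full session (seconds)
#'
#' A session is 35 cued animations (7 movements x 5 reps at defaults), each
#' preceded by the inter-movement rest, plus a trailing rest.
#'
#' @param p a [protocol()].
#' @return session duration in seconds.
#' @export
session_duration <- function(p) {
  n <- 7L * p$reps_per_movement
  n * (p$inter_movement_rest + animation_duration(p)) + p$inter_movement_rest
}

#' Muscle activation envelope of one animation
#'
#' Trapezoidal activation: 0 during the initial rest, a linear ramp to 1 over
#' the forward movement, 1 through the hold, a linear ramp back to 0 over the
#' backward movement, 0 through the final rest and beyond.
#'
#' @param t time in seconds since the cue (vectorized, `t >= 0`).
#' @param p a [protocol()].
#' @return activation in [0, 1].
#' @export
activation_profile <- function(t, p = protocol()) {
  t1 <- p$initial_rest
  t2 <- t1 + p$forward
  t3 <- t2 + p$hold
  t4 <- t3 + p$backward
  a <- numeric(length(t))
  up <- t >= t1 & t < t2
  a[up] <- (t[up] - t1) / p$forward
  a[t >= t2 & t < t3] <- 1
  dn <- t >= t3 & t < t4
  a[dn] <- 1 - (t[dn] - t3) / p$backward
  a
}

#' Movement-to-channel activation map
#'
#' A 7 x 8 gain matrix (movements M0-M6 by channels C0-C7) describing how
#' strongly each muscle/channel activates during each movement. Each
#' movement's primary channel (biceps for forearm flexion, pronator teres for
#' forearm rotation, extensor digitorum for hand contraction, etc.) has gain
#' 1; physiologically coupled channels carry a crosstalk gain — forearm
#' flexion and rotation share the biceps and brachioradialis, which is why
#' those two classes are the hardest to separate — and all remaining channels
#' sit at a small baseline.
#'
#' @param crosstalk gain on shared-muscle channels (default 0.4).
#' @param baseline gain on uninvolved channels (default 0.05).
#' @return 7 x 8 numeric matrix, rownames M0-M6, colnames C0-C7; each row has
#'   exactly one gain of 1.
#' @export
activation_map <- function(crosstalk = 0.4, baseline = 0.05) {
  stopifnot(crosstalk >= 0, crosstalk <= 1, baseline >= 0, baseline < 1)
  ch <- paste0("C", 0:7)
  mv <- paste0("M", 0:6)
  g <- matrix(baseline, 7, 8, dimnames = list(mv, ch))
  # primary channels: C0 biceps -> M3, C1 flexor carpi ulnaris -> M5,
  # C2 flexor carpi radialis -> M6, C3 extensor digitorum -> M0,
  # C4 pronator teres -> M4, C6 palmaris longus -> M2,
  # C7 extensor carpi ulnaris -> M1
  g["M0", "C3"] <- 1
  g["M1", "C7"] <- 1
  g["M2", "C6"] <- 1
  g["M3", "C0"] <- 1
  g["M4", "C4"] <- 1
  g["M5", "C1"] <- 1
  g["M6", "C2"] <- 1
  # shared muscles: biceps and brachioradialis (C5, itself a forearm-rotation
  # muscle) participate in both forearm flexion (M3) and rotation (M4)
  g["M3", "C4"] <- crosstalk
  g["M3", "C5"] <- crosstalk
  g["M4", "C0"] <- crosstalk
  g["M4", "C5"] <- crosstalk
  g
}

#' Synthetic-EMG noise model
#'
#' The surrogate signal on each channel is amplitude-modulated band-limited
#' Gaussian noise (the standard interference-pattern model of surface EMG)
#' plus 60 Hz mains interference and a per-channel DC offset. The band-limited
#' carrier has unit RMS; its instantaneous amplitude is
#' `rest_noise_rms + gain * activation`, so the rest-level RMS and the active
#' amplitude are set directly in signal units.
#'
#' @param rest_noise_rms baseline (rest) noise RMS, default 0.05.
#' @param mains_amplitude amplitude of the 60 Hz interference, default 0.1.
#' @param mains_hz interference frequency, default 60.
#' @param dc_offset per-channel DC offsets (recycled), default 0.2.
#' @param emg_band band limits (Hz) of the noise carrier, default c(20, 450).
#' @param rep_jitter per-repetition amplitude jitter fraction: each repetition
#'   scales its activation by a factor uniform in `1 +/- rep_jitter`. Default
#'   0 (off): the protocol places no constraint on exerted force, and by
#'   default repetitions are equally strong.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(rest_noise_rms = 0.05, mains_amplitude = 0.1,
                        mains_hz = 60, dc_offset = 0.2,
                        emg_band = c(20, 450), rep_jitter = 0) {
  stopifnot(rest_noise_rms >= 0, mains_amplitude >= 0, mains_hz > 0,
            length(emg_band) == 2, emg_band[1] > 0, emg_band[2] > emg_band[1],
            rep_jitter >= 0, rep_jitter < 1)
  structure(list(rest_noise_rms = rest_noise_rms,
                 mains_amplitude = mains_amplitude, mains_hz = mains_hz,
                 dc_offset = dc_offset, emg_band = emg_band,
                 rep_jitter = rep_jitter),
            class = "noise_model")
}

# Unit-RMS band-limited Gaussian carrier of length n. Zero noise settings are
# handled by the caller (envelope of zeros).
band_limited_noise <- function(n, sample_rate, band) {
  x <- stats::rnorm(n)
  x <- bandpass(x, sample_rate, band[1], band[2])
  s <- sqrt(mean(x^2))
  if (s > 0) x / s else x
}

# Synthesize channels for a given envelope matrix (n x nch) of instantaneous
# noise amplitudes; adds mains and DC. Assumes the RNG state is already set.
synth_channels <- function(env, nm, sample_rate) {
  n <- nrow(env); nch <- ncol(env)
  tt <- (seq_len(n) - 1L) / sample_rate
  dc <- rep_len(nm$dc_offset, nch)
  out <- matrix(0, n, nch)
  for (c in seq_len(nch)) {
    carrier <- band_limited_noise(n, sample_rate, nm$emg_band)
    phase <- stats::runif(1, 0, 2 * pi)
    out[, c] <- dc[c] +
      nm$mains_amplitude * sin(2 * pi * nm$mains_hz * tt + phase) +
      carrier * env[, c]
  }
  out
}

#' Generate one cued movement trial
#'
#' Produces a recording of one animation (optionally padded with rest) on all
#' 8 channels: each channel's noise amplitude follows
#' `rest_noise_rms + gain[movement, channel] * activation_profile(t)`, plus
#' mains interference and DC offset. Deterministic given the seed.
#'
#' @param movement movement label or abbreviation (M0-M6).
#' @param p a [protocol()].
#' @param amap an [activation_map()].
#' @param nm a [noise_model()].
#' @param seed integer RNG seed.
#' @param lead_rest,trail_rest rest padding before/after the animation,
#'   seconds (defaults: the protocol's inter-movement rest on both sides).
#' @return list with `recording` (a [recording()]) and `cues` (one-row cue
#'   schedule; the cue onset is at `lead_rest`).
#' @export
generate_movement <- function(movement, p = protocol(),
                              amap = activation_map(), nm = noise_model(),
                              seed = 1L,
                              lead_rest = p$inter_movement_rest,
                              trail_rest = p$inter_movement_rest) {
  mc <- movement_codes()
  mi <- match(movement, mc$abbreviation)
  if (is.na(mi)) mi <- match(movement, mc$label)
  if (is.na(mi)) stop("unknown movement: ", movement)
  abbr <- mc$abbreviation[mi]
  sr <- p$sample_rate
  dur <- lead_rest + animation_duration(p) + trail_rest
  n <- round(dur * sr)
  tt <- (seq_len(n) - 1L) / sr
  act <- activation_profile(tt - lead_rest, p)
  act[tt < lead_rest] <- 0
  set.seed(seed)
  jit <- if (nm$rep_jitter > 0)
    stats::runif(1, 1 - nm$rep_jitter, 1 + nm$rep_jitter) else 1
  env <- nm$rest_noise_rms + outer(act, jit * amap[abbr, ])
  rec <- recording(synth_channels(env, nm, sr), sr, colnames(amap))
  list(recording = rec,
       cues = data.frame(onset_s = lead_rest, movement_label = mc$label[mi],
                         stringsAsFactors = FALSE))
}

#' Generate one full synthetic session
#'
#' A session presents every movement `reps_per_movement` times in
#' seeded-random order, each animation preceded by the inter-movement rest,
#' with a trailing rest at the end. Returns the concatenated recording and
#' the cue schedule (one onset + label per execution).
#'
#' @param p a [protocol()].
#' @param amap an [activation_map()].
#' @param nm a [noise_model()].
#' @param seed integer RNG seed.
#' @param subject_id optional subject label stamped on the recording.
#' @return list with `recording`, `cues` (data.frame `onset_s`,
#'   `movement_label`) and `labels` (the movement order).
#' @export
generate_session <- function(p = protocol(), amap = activation_map(),
                             nm = noise_model(), seed = 1L,
                             subject_id = NA_character_) {
  mc <- movement_codes()
  set.seed(seed)
  order_lab <- sample(rep(mc$label, p$reps_per_movement))
  jit <- if (nm$rep_jitter > 0) {
    stats::runif(length(order_lab), 1 - nm$rep_jitter, 1 + nm$rep_jitter)
  } else rep(1, length(order_lab))
  sr <- p$sample_rate
  anim <- animation_duration(p)
  step <- p$inter_movement_rest + anim
  dur <- session_duration(p)
  n <- round(dur * sr)
  tt <- (seq_len(n) - 1L) / sr
  onsets <- p$inter_movement_rest + (seq_along(order_lab) - 1L) * step
  env <- matrix(nm$rest_noise_rms, n, ncol(amap))
  for (i in seq_along(order_lab)) {
    abbr <- mc$abbreviation[match(order_lab[i], mc$label)]
    idx <- which(tt >= onsets[i] & tt < onsets[i] + anim)
    act <- activation_profile(tt[idx] - onsets[i], p)
    env[idx, ] <- env[idx, ] + outer(act, jit[i] * amap[abbr, ])
  }
  rec <- recording(synth_channels(env, nm, sr), sr, colnames(amap),
                   subject_id)
  list(recording = rec,
       cues = data.frame(onset_s = onsets, movement_label = order_lab,
                         stringsAsFactors = FALSE),
       labels = order_lab)
}

#' Generate a full subject test (5 sessions)
#'
#' Applies [generate_session()] with per-session sub-seeds derived from the
#' master seed by fixed offsets. By convention the first session is the
#' training session: its feature vectors and target codes seed and train the
#' classifier, and the remaining sessions are held out for evaluation.
#'
#' @param p a [protocol()].
#' @param amap an [activation_map()].
#' @param nm a [noise_model()].
#' @param seed integer master seed.
#' @param subject_id optional subject label.
#' @return list of `p$sessions` session objects (see [generate_session()]).
#' @export
generate_subject <- function(p = protocol(), amap = activation_map(),
                             nm = noise_model(), seed = 1L,
                             subject_id = NA_character_) {
  lapply(seq_len(p$sessions), function(s) {
    generate_session(p, amap, nm, seed = session_seed(seed, s),
                     subject_id = subject_id)
  })
}

# Derived per-session seed, kept within 32-bit integer range.
session_seed <- function(seed, session) {
  as.integer((as.numeric(seed) + 9973 * session) %% .Machine$integer.max)
}
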