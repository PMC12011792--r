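#' @useDynLib ecgid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois lowess sd pt qt cor
#' @importFrom utils write.csv read.csv
NULL

# canonical 12-lead order used throughout the package
LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")

# Canonical normal-sinus beat: Gaussian-sum PQRST. Amplitudes in mV, widths in
# s, wave centers as phase offsets (rad) within one cardiac cycle (R at 0).
CANONICAL_BEAT <- list(
  amp   = c(P = 0.15, Q = -0.12, R = 1.10, S = -0.25, T = 0.35),
  width = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.012, T = 0.045),
  phase = c(P = -pi / 3, Q = -pi / 16, R = 0, S = pi / 16, T = pi / 2)
)

# Typical relative lead gains for a normal axis (lead II largest limb lead,
# precordial transition around V3/V4). Signs give aVR its inverted morphology.
CANONICAL_LEAD_GAIN <- c(
  I = 0.60, II = 1.00, III = 0.45, aVR = -0.65, aVL = 0.30, aVF = 0.75,
  V1 = -0.40, V2 = 0.65, V3 = 0.90, V4 = 1.10, V5 = 0.95, V6 = 0.70
)

#' Noise specification for the ECG simulator
#'
#' Describes the four classical ECG contaminants: mains powerline
#' interference, baseline wander, muscle (EMG) noise, and electrode/motion
#' artifacts. A spec with all amplitudes zero is the identity noise model.
#'
#' @param powerline_amp Powerline sinusoid amplitude, mV.
#' @param powerline_freq Mains frequency, Hz (50 in Europe/Russia).
#' @param baseline_amp Baseline-wander amplitude, mV.
#' @param baseline_freq Baseline-wander frequency, Hz (respiratory rate).
#' @param emg_amp Muscle-noise level (SD of the band-limited process), mV.
#' @param motion_spike_rate Electrode/motion artifact events per second.
#' @param motion_amp Scale of motion random-walk excursions, mV.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(powerline_amp = 0.05, powerline_freq = 50,
                       baseline_amp = 0.10, baseline_freq = 0.25,
                       emg_amp = 0.03, motion_spike_rate = 0.1,
                       motion_amp = 0.10) {
  amps <- c(powerline_amp, baseline_amp, emg_amp, motion_amp)
  if (any(amps < 0) || motion_spike_rate < 0)
    stop("noise amplitudes and rates must be >= 0")
  structure(list(powerline_amp = as.numeric(powerline_amp),
                 powerline_freq = as.numeric(powerline_freq),
                 baseline_amp = as.numeric(baseline_amp),
                 baseline_freq = as.numeric(baseline_freq),
                 emg_amp = as.numeric(emg_amp),
                 motion_spike_rate = as.numeric(motion_spike_rate),
                 motion_amp = as.numeric(motion_amp)),
            class = "noise_spec")
}

#' Zero-noise specification (identity noise model)
#' @return A `noise_spec` with every amplitude zero.
#' @export
noise_none <- function() {
  noise_spec(powerline_amp = 0, baseline_amp = 0, emg_amp = 0,
             motion_spike_rate = 0, motion_amp = 0)
}

#' Draw a per-subject beat template
#'
#' Samples a subject-specific PQRST morphology around the canonical
#' normal-sinus beat: wave amplitudes and widths scaled by uniform factors,
#' wave phases jittered, a subject heart rate, and per-lead projection gains
#' and width modifiers. Deterministic for a given seed.
#'
#' @param seed Non-negative integer seed.
#' @param subject_id Subject identifier string.
#' @return An object of class `subject_template`.
#' @export
generate_subject_template <- function(seed, subject_id) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0,
            seed == floor(seed))
  rng <- local_rng(seed)
  on.exit(rng())
  amp   <- CANONICAL_BEAT$amp * runif(5, 0.8, 1.2)
  width <- CANONICAL_BEAT$width * runif(5, 0.8, 1.2)
  phase <- CANONICAL_BEAT$phase + runif(5, -0.1, 0.1)
  phase["R"] <- 0                      # R anchors the beat
  rr_mean <- runif(1, 0.7, 1.1)
  lead_gain <- CANONICAL_LEAD_GAIN * runif(12, 0.7, 1.3)
  lead_width <- runif(12, 0.9, 1.1)
  structure(list(subject_id = as.character(subject_id),
                 wave_params = list(amp = amp, width = width, phase = phase),
                 rr_mean = rr_mean, rr_jitter_sd = 0.005,
                 lead_projection = lead_gain, lead_width_mod = lead_width),
            class = "subject_template")
}

# one clean lead: Gaussian-sum waves at the given beat (R-peak) times
beat_train <- function(t, r_times, amp, width, phase, rr, gain, wmod) {
  y <- numeric(length(t))
  centers_off <- phase / (2 * pi) * rr
  for (r in r_times) {
    for (w in seq_along(amp)) {
      c_w <- r + centers_off[w]
      s_w <- width[w] * wmod
      y <- y + amp[w] * exp(-(t - c_w)^2 / (2 * s_w^2))
    }
  }
  gain * y
}

#' Synthesize one 12-lead recording
#'
#' Places Gaussian-sum beats at RR intervals with truncated Gaussian jitter,
#' projects the common cardiac source onto 12 leads through the template's
#' per-lead gains and width modifiers, then adds noise per `noise`.
#' Bit-reproducible for a given `(template, seed)`.
#'
#' @param template A `subject_template`.
#' @param duration Recording length, s.
#' @param fs Sampling rate, Hz.
#' @param noise A `noise_spec`.
#' @param seed Integer seed for RR jitter and noise realization.
#' @param record_id Record identifier.
#' @return An object of class `ecg_recording` with a 12 x T `signal` matrix
#'   (mV), `fs`, `lead_names`, `record_id` and `subject_id`.
#' @export
synthesize_recording <- function(template, duration = 10, fs = 257,
                                 noise = noise_spec(), seed = 0,
                                 record_id = template$subject_id) {
  if (!inherits(template, "subject_template")) stop("not a subject_template")
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  if (fs <= 2 * noise$powerline_freq && noise$powerline_amp > 0)
    stop("fs must exceed twice the powerline frequency")
  rng <- local_rng(seed)
  on.exit(rng())

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  wp <- template$wave_params
  rr <- template$rr_mean

  # jittered R-peak times; jitter truncated at +/- 3 SD to keep beats ordered
  n_beats <- ceiling(duration / rr) + 2
  jit <- rnorm(n_beats, 0, template$rr_jitter_sd)
  jit <- pmin(pmax(jit, -3 * template$rr_jitter_sd), 3 * template$rr_jitter_sd)
  r_times <- rr / 2 + (seq_len(n_beats) - 1) * rr + jit
  r_times <- r_times[r_times > -0.5 & r_times < duration + 0.5]

  signal <- matrix(0, nrow = 12, ncol = n,
                   dimnames = list(LEAD_NAMES, NULL))
  for (l in 1:12) {
    signal[l, ] <- beat_train(t, r_times, wp$amp, wp$width, wp$phase, rr,
                              template$lead_projection[l],
                              template$lead_width_mod[l])
  }
  signal <- signal + synth_noise(noise, n, fs, t)

  structure(list(record_id = as.character(record_id),
                 subject_id = template$subject_id,
                 fs = fs, signal = signal, lead_names = LEAD_NAMES),
            class = "ecg_recording")
}

# 12 x n additive noise matrix; consumes the active RNG stream
synth_noise <- function(noise, n, fs, t) {
  out <- matrix(0, nrow = 12, ncol = n)
  if (noise$powerline_amp > 0) {
    # mains pickup is common-mode: one phase, slightly different coupling/lead
    ph <- runif(1, 0, 2 * pi)
    coupling <- runif(12, 0.8, 1.2)
    pli <- noise$powerline_amp * sin(2 * pi * noise$powerline_freq * t + ph)
    out <- out + outer(coupling, pli)
  }
  if (noise$baseline_amp > 0) {
    for (l in 1:12) {
      ph <- runif(1, 0, 2 * pi)
      a <- noise$baseline_amp * runif(1, 0.7, 1.3)
      out[l, ] <- out[l, ] + a * sin(2 * pi * noise$baseline_freq * t + ph)
    }
  }
  if (noise$emg_amp > 0) {
    for (l in 1:12) {
      w <- rnorm(n)
      out[l, ] <- out[l, ] + noise$emg_amp * fft_bandpass(w, fs, 20,
                                                          min(120, fs / 2))
    }
  }
  if (noise$motion_spike_rate > 0 && noise$motion_amp > 0) {
    dur <- n / fs
    for (l in 1:12) {
      n_ev <- rpois(1, noise$motion_spike_rate * dur)
      if (n_ev > 0) {
        starts <- runif(n_ev, 0, dur)
        lens <- runif(n_ev, 0.3, 1.0)
        for (e in seq_len(n_ev)) {
          i0 <- max(1L, round(starts[e] * fs))
          i1 <- min(n, i0 + round(lens[e] * fs))
          m <- i1 - i0 + 1L
          if (m < 2) next
          walk <- cumsum(rnorm(m)) / sqrt(m)
          win <- sin(pi * (seq_len(m) - 1) / (m - 1))^2  # taper to 0 at ends
          out[l, i0:i1] <- out[l, i0:i1] + noise$motion_amp * walk * win
        }
      }
    }
  }
  out
}

# brick-wall FFT band-pass used only for noise shaping in the simulator
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  keep <- f >= lo & f <= hi
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_subjects` templates, then `recordings_per_subject` recordings per
#' subject. Recordings of one subject share the template but differ in RR
#' jitter and noise realization.
#'
#' @param n_subjects Number of subjects (>= 2; identification needs classes).
#' @param recordings_per_subject Recordings per subject (>= 1).
#' @param duration,fs Recording length (s) and sampling rate (Hz).
#' @param noise A `noise_spec` applied to every recording.
#' @param seed Master seed; subject templates and per-recording realizations
#'   derive deterministic sub-seeds from it.
#' @return List of `ecg_recording`, length `n_subjects *
#'   recordings_per_subject`.
#' @export
generate_cohort <- function(n_subjects = 20, recordings_per_subject = 6,
                            duration = 10, fs = 257, noise = noise_spec(),
                            seed = 42) {
  if (n_subjects < 2) stop("n_subjects must be >= 2: identification undefined")
  if (recordings_per_subject < 1) stop("recordings_per_subject must be >= 1")
  cohort <- vector("list", n_subjects * recordings_per_subject)
  k <- 0L
  seed <- as.numeric(seed)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    tmpl <- generate_subject_template(seed * 1000 + s, sid)
    for (r in seq_len(recordings_per_subject)) {
      k <- k + 1L
      rid <- sprintf("%s_r%02d", sid, r)
      cohort[[k]] <- synthesize_recording(
        tmpl, duration = duration, fs = fs, noise = noise,
        seed = (seed * 1000 + s) * 100 + r, record_id = rid)
    }
  }
  cohort
}

# Scoped RNG: seeds the global stream, returns a restorer for on.exit().
# Keeps package functions pure in (arguments, seed) without clobbering the
# caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording %s subject=%s %d leads x %d samples @ %g Hz>\n",
              x$record_id, x$subject_id, nrow(x$signal), ncol(x$signal),
              x$fs))
  invisible(x)
}
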