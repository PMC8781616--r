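#' Rhythm specification for the waveform fixture generator
#'
#' Parameter bundle describing one of the five rhythm classes for
#' [simulate_ecg()].  `default_rhythm_spec()` fills in class defaults
#' chosen to reproduce the defining clinical characteristics: NSR is a
#' regular 75 bpm train with P waves; APC inserts occasional early narrow
#' beats; AFib has irregular RR intervals with no repetitive pattern, no
#' P waves and a fibrillatory baseline; VPC inserts occasional early wide
#' large-amplitude beats; VT is a sustained wide-QRS run above 120 bpm.
#'
#' @param symptom Symptom ID 1--5.
#' @param heart_rate_bpm Base heart rate.
#' @param premature_fraction Probability that a beat is premature
#'   (APC/VPC).
#' @param rr_jitter_sd_s Relative RR-interval jitter (sd as a fraction of
#'   the base RR for regular rhythms; AFib instead draws RR uniformly over
#'   +/- 40% of the base).
#' @param qrs_width_scale Width multiplier of the QRS complex for
#'   ventricular (wide) beats.
#' @param fib_wave_amp Amplitude (mV) of the fibrillatory baseline waves.
#' @return List of class `"rhythm_spec"`.
#' @export
rhythm_spec <- function(symptom, heart_rate_bpm, premature_fraction = 0,
                        rr_jitter_sd_s = 0.02, qrs_width_scale = 1,
                        fib_wave_amp = 0) {
  symptom <- as.integer(symptom)
  if (!symptom %in% 1:5) stop("invalid symptom ID (must be 1..5)")
  stopifnot(heart_rate_bpm > 0, premature_fraction >= 0,
            premature_fraction <= 1, qrs_width_scale > 0)
  structure(list(symptom = symptom, heart_rate_bpm = heart_rate_bpm,
                 premature_fraction = premature_fraction,
                 rr_jitter_sd_s = rr_jitter_sd_s,
                 qrs_width_scale = qrs_width_scale,
                 fib_wave_amp = fib_wave_amp),
            class = "rhythm_spec")
}

#' @rdname rhythm_spec
#' @export
default_rhythm_spec <- function(symptom) {
  symptom <- as.integer(symptom)
  switch(symptom,
    rhythm_spec(1L, 75),                                      # NSR
    rhythm_spec(2L, 75, premature_fraction = 0.25),           # APC
    rhythm_spec(3L, 100, rr_jitter_sd_s = 0.25,
                fib_wave_amp = 0.1),                          # AFib
    rhythm_spec(4L, 75, premature_fraction = 0.25,
                qrs_width_scale = 2.5),                       # VPC
    rhythm_spec(5L, 160, rr_jitter_sd_s = 0.01,
                qrs_width_scale = 2.5),                       # VT
    stop("invalid symptom ID (must be 1..5)"))
}

gauss_bump <- function(t, centre, width, amp) {
  amp * exp(-0.5 * ((t - centre) / width)^2)
}

# One PQRST complex at R-peak time t0.  Wide (ventricular) beats lose the
# P wave, broaden Q/R/S by `width_scale`, gain R amplitude and invert T.
pqrst <- function(t, t0, width_scale = 1, p_amp = 0.15, wide = FALSE) {
  w <- if (wide) width_scale else 1
  y <- gauss_bump(t, t0 - 0.040 * w, 0.010 * w, -0.10) +
       gauss_bump(t, t0,             0.012 * w, if (wide) 1.4 else 1.0) +
       gauss_bump(t, t0 + 0.040 * w, 0.015 * w, -0.20)
  if (!wide) {
    y <- y + gauss_bump(t, t0 - 0.17, 0.025, p_amp) +
             gauss_bump(t, t0 + 0.22, 0.045, 0.30)
  } else {
    y <- y + gauss_bump(t, t0 + 0.22 * w, 0.050, -0.35)
  }
  y
}

#' Generate a synthetic single-lead ECG record for one rhythm class
#'
#' Template-based PQRST train with class-specific modifications (see
#' [rhythm_spec()]).  This generator is openly synthetic: it exists so the
#' full pipeline and the scanner can be exercised end-to-end with no
#' external database, and its contract is class separability of the
#' derived features, not clinical realism.  Annotations are placed at the
#' R-peak times of symptomatic beats (every beat for NSR/AFib/VT, the
#' premature beats for APC/VPC), labelled with the record's symptom ID.
#'
#' @param spec A [rhythm_spec()] or symptom ID 1--5 (class defaults).
#' @param duration_s Record length in seconds (>= 3).
#' @param fs Sampling rate in Hz (default 360).
#' @param seed Integer seed; identical seeds give identical records.
#' @return An [ecg_record()].  Attribute `"generator"` carries the beat
#'   times, RR intervals, P-wave amplitude and the spec, for fixture
#'   checks.
#' @export
simulate_ecg <- function(spec, duration_s = 30, fs = 360, seed = 1) {
  if (is.numeric(spec) && length(spec) == 1L)
    spec <- default_rhythm_spec(spec)
  if (!inherits(spec, "rhythm_spec")) stop("invalid symptom ID (must be 1..5)")
  if (duration_s < 3) stop("duration_s must be >= 3")
  set.seed(as.integer(seed))
  rr_base <- 60 / spec$heart_rate_bpm
  p_amp <- if (spec$symptom == 3L) 0 else 0.15

  beat_t <- 0.4; premature <- FALSE
  repeat {
    prem <- spec$symptom %in% c(2L, 4L) &&
      stats::runif(1) < spec$premature_fraction
    rr <- if (spec$symptom == 3L) {
      rr_base * stats::runif(1, 0.6, 1.4)        # no repetitive pattern
    } else if (prem) {
      rr_base * 0.6                              # the next beat arrives early
    } else {
      rr_base * (1 + stats::rnorm(1, 0, spec$rr_jitter_sd_s))
    }
    t_next <- beat_t[length(beat_t)] + max(rr, 0.25)
    if (t_next >= duration_s - 0.5) break
    beat_t <- c(beat_t, t_next)
    premature <- c(premature, prem)
  }
  # guarantee at least one premature beat away from the record edges
  if (spec$symptom %in% c(2L, 4L) && !any(premature) && length(beat_t) > 2L) {
    k <- max(2L, length(beat_t) %/% 2L)
    premature[k] <- TRUE
    beat_t[k] <- beat_t[k - 1L] + 0.6 * rr_base
  }

  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  y <- numeric(length(t))
  wide_all <- spec$symptom == 5L
  for (k in seq_along(beat_t)) {
    wide <- wide_all || (spec$symptom == 4L && premature[k])
    y <- y + pqrst(t, beat_t[k], spec$qrs_width_scale, p_amp, wide)
  }
  if (spec$fib_wave_amp > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    y <- y + spec$fib_wave_amp *
      (sin(2 * pi * 6.5 * t + ph[1]) + 0.6 * sin(2 * pi * 8.1 * t + ph[2]))
  }
  y <- y + stats::rnorm(length(t), 0, 0.02)      # measurement noise

  ann_t <- if (spec$symptom %in% c(2L, 4L)) beat_t[premature] else beat_t
  ann <- data.frame(time_s = ann_t, label = spec$symptom)
  rec <- ecg_record(y, fs = fs,
                    record_id = sprintf("sim_%s_seed%d",
                                        symptom_names[spec$symptom],
                                        as.integer(seed)),
                    annotations = ann)
  attr(rec, "generator") <- list(beat_times_s = beat_t,
                                 rr_s = diff(beat_t),
                                 p_amplitude = p_amp, spec = spec)
  rec
}
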