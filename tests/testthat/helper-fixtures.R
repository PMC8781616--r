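# Shared fixtures, all built in code.

FS <- 360

tone_frame <- function(f0, amp = 1, duration_s = 3, fs = FS, phase = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  ecg_frame(amp * sin(2 * pi * f0 * t + phase), fs)
}

frame_time <- function(duration_s = 3, fs = FS) {
  (seq_len(round(duration_s * fs)) - 1) / fs
}

# Two well-separated Gaussian classes in 6-D (class means 10 sd apart on
# every coordinate).
separable_features <- function(n_per_class = 100, delta = 10, seed = 42) {
  set.seed(seed)
  mk <- function(mu, lab) {
    m <- matrix(stats::rnorm(n_per_class * 6, mu, 1), ncol = 6)
    feature_table(as.data.frame(m), lab)
  }
  rbind(mk(0, 1L), mk(delta, 2L))
}

# Balanced k-class Gaussian features with given means per class.
gaussian_class_features <- function(means, n_per_class = 30, sd = 1,
                                    seed = 7) {
  set.seed(seed)
  out <- lapply(seq_along(means), function(i) {
    m <- matrix(stats::rnorm(n_per_class * 6, means[i], sd), ncol = 6)
    feature_table(as.data.frame(m), i)
  })
  do.call(rbind, out)
}

# Brute-force AUC: probability that a positive outscores a negative,
# ties counted one half.  Independent of the ROC implementation.
brute_force_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Dominant frequency of a series via the periodogram peak.
dominant_freq <- function(x, fs = FS) {
  n <- length(x)
  s <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]
  which.max(s) * fs / n
}

write_record_csv <- function(samples, path) {
  writeLines(c("mV", format(samples, digits = 17)), path)
  path
}
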