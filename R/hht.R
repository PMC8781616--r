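#' Zero-phase low-pass Butterworth filter for one frame
#'
#' Applies a forward-backward (zero-phase) digital Butterworth low-pass
#' filter.  Zero-phase filtering avoids shifting the PQRST morphology; the
#' effective magnitude response is the Butterworth response squared,
#' `|H(f)|^2 = (1 + (f/fc)^(2*order))^(-1)`, with unit DC gain.
#'
#' @param frame An [ecg_frame()] or numeric vector.
#' @param order Filter order (default 5).
#' @param cutoff_hz Cutoff frequency in Hz (default 16); must be below the
#'   Nyquist frequency.
#' @param fs Sampling rate, required when `frame` is a bare vector.
#' @return Same type as `frame`, filtered.
#' @export
lowpass_filter <- function(frame, order = 5, cutoff_hz = 16, fs = NULL) {
  x <- if (inherits(frame, "ecg_frame")) frame$samples else as.numeric(frame)
  fs <- if (inherits(frame, "ecg_frame")) frame$fs else fs
  if (is.null(fs)) stop("fs required for a bare numeric frame")
  if (cutoff_hz >= fs / 2) stop("cutoff_hz must be below the Nyquist frequency")
  if (length(x) <= 3 * order) stop("frame too short for the filter order")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding suppresses start/end transients of the
  # forward-backward pass (the zero-padding default sags at the edges)
  n <- length(x)
  pad <- min(n - 1L, 2000L)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))[(pad + 1):(pad + n)]
  if (inherits(frame, "ecg_frame")) {
    frame$samples <- y
    frame
  } else y
}

# Local extrema by sign changes of the first difference; plateaus are
# collapsed to their midpoint sample.
find_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(), minima = integer()))
  maxima <- integer(); minima <- integer()
  for (k in seq_len(length(nz) - 1L)) {
    i <- nz[k]; j <- nz[k + 1L]
    if (s[i] > 0 && s[j] < 0) maxima <- c(maxima, (i + j + 1L) %/% 2L)
    if (s[i] < 0 && s[j] > 0) minima <- c(minima, (i + j + 1L) %/% 2L)
  }
  list(maxima = maxima, minima = minima)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

# The defining IMF condition: extrema and zero-crossing counts differ by
# at most one.
is_imf <- function(x) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  abs(n_ext - count_zero_crossings(x)) <= 1L
}

# Spline envelope through extrema, with the two end extrema of each kind
# mirrored across the frame boundaries so the spline does not diverge at
# the edges.
spline_envelope <- function(x, idx) {
  n <- length(x)
  xs <- idx; ys <- x[idx]
  m <- length(idx)
  left <- 2L - rev(idx[seq_len(min(2L, m))])      # mirror about sample 1
  right <- 2L * n - rev(idx[(m - min(2L, m) + 1L):m])  # mirror about sample n
  xs <- c(left, xs, right)
  ys <- c(rev(ys[seq_len(min(2L, m))]), ys,
          rev(ys[(m - min(2L, m) + 1L):m]))
  keep <- !duplicated(xs)
  stats::splinefun(xs[keep], ys[keep], method = "natural")(seq_len(n))
}

#' One sifting step of empirical mode decomposition
#'
#' Subtracts the mean of the cubic-spline upper and lower envelopes (through
#' the local maxima and minima, with boundary extrema mirrored) from the
#' series.  A valid IMF has this envelope mean close to zero everywhere.
#'
#' @param series Numeric vector with at least two maxima and two minima.
#' @return List with `candidate` (series minus envelope mean) and
#'   `mean_envelope`.
#' @export
sift_once <- function(series) {
  x <- as.numeric(series)
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L)
    stop("residue reached: fewer than 2 maxima or 2 minima")
  upper <- spline_envelope(x, ex$maxima)
  lower <- spline_envelope(x, ex$minima)
  m <- (upper + lower) / 2
  list(candidate = x - m, mean_envelope = m)
}

#' Empirical mode decomposition of one frame
#'
#' Decomposes the frame into ordered intrinsic mode functions (IMFs) by
#' iterated sifting and a final residue.  Sifting of each mode stops when
#' the Cauchy criterion `sum((h_prev - h)^2) / sum(h_prev^2) < stop_sd`
#' is met and the candidate satisfies the IMF extrema/zero-crossing
#' condition, or after `max_sifts` iterations.  Decomposition stops when
#' the residue has fewer than two maxima or two minima (monotonic trend),
#' or after `max_imfs` modes.  By construction
#' `input == rowSums(imfs) + residue` exactly.
#'
#' @param frame An [ecg_frame()] or numeric vector.
#' @param stop_sd Cauchy sifting stop threshold (default 0.2, the classic
#'   Hilbert-Huang value).
#' @param max_imfs,max_sifts Iteration caps.
#' @return Object of class `"imf_set"`: list with `imfs` (list of numeric
#'   vectors, possibly empty), `residue`, `n_sifts`, `fs`.
#' @export
emd <- function(frame, stop_sd = 0.2, max_imfs = 10, max_sifts = 100) {
  x <- if (inherits(frame, "ecg_frame")) frame$samples else as.numeric(frame)
  fs <- if (inherits(frame, "ecg_frame")) frame$fs else NA_real_
  if (!all(is.finite(x))) stop("non-finite input")
  if (length(x) < 16L) stop("frame too short for EMD")
  imfs <- list(); n_sifts <- integer()
  residue <- x
  scale <- max(abs(x))
  while (length(imfs) < max_imfs) {
    ex <- find_extrema(residue)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
    h <- residue
    sifts <- 0L
    repeat {
      st <- tryCatch(sift_once(h), error = function(e) NULL)
      if (is.null(st)) break
      hnew <- st$candidate
      denom <- sum(h^2)
      sd_crit <- if (denom > 0) sum((h - hnew)^2) / denom else 0
      h <- hnew
      sifts <- sifts + 1L
      if ((sd_crit < stop_sd && is_imf(h)) || sifts >= max_sifts) break
    }
    if (sifts == 0L) break
    if (max(abs(h)) < 1e-12 * max(scale, 1e-300)) break  # numerically null mode
    imfs[[length(imfs) + 1L]] <- h
    n_sifts <- c(n_sifts, sifts)
    residue <- residue - h
  }
  structure(list(imfs = imfs, residue = residue, n_sifts = n_sifts, fs = fs),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("EMD: %d IMF(s) of %d samples, sift counts [%s]\n",
              length(x$imfs),
              length(x$residue), paste(x$n_sifts, collapse = ", ")))
  invisible(x)
}

# Analytic signal by the FFT method (positive-frequency doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert spectral analysis of an IMF set
#'
#' For each IMF, forms the analytic signal, takes the instantaneous
#' amplitude envelope and the instantaneous frequency as the central
#' difference of the unwrapped phase (Hz).  Negative instantaneous
#' frequencies are clipped to 0 and the first and last 2% of samples are
#' excluded from the spectrum entries to suppress boundary (Gibbs)
#' artefacts.
#'
#' @param imfs An [emd()] result, or a list of numeric IMF vectors.
#' @param fs Sampling rate in Hz (taken from `imfs` when available).
#' @return Object of class `"hilbert_spectrum"`: list with `per_imf` (one
#'   data frame `time_s,freq_hz,amp` per IMF), `fs`, `n`, `duration_s`.
#' @export
hilbert_analysis <- function(imfs, fs = NULL) {
  series <- if (inherits(imfs, "imf_set")) imfs$imfs else imfs
  if (is.null(fs)) fs <- if (inherits(imfs, "imf_set")) imfs$fs else NULL
  if (is.null(fs) || is.na(fs)) stop("fs required")
  if (length(series) == 0L) stop("empty IMF list")
  n <- length(series[[1]])
  drop <- floor(0.02 * n)
  keep <- (drop + 1):(n - drop)
  per_imf <- lapply(series, function(x) {
    z <- analytic_signal(x)
    a <- Mod(z)
    ph <- unwrap_phase(Arg(z))
    f <- numeric(n)
    f[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / 2
    f[1] <- ph[2] - ph[1]
    f[n] <- ph[n] - ph[n - 1]
    f <- f * fs / (2 * pi)
    f <- pmax(f, 0)
    data.frame(time_s = (keep - 1) / fs, freq_hz = f[keep], amp = a[keep])
  })
  structure(list(per_imf = per_imf, fs = fs, n = n, duration_s = n / fs),
            class = "hilbert_spectrum")
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Marginal Hilbert spectrum of one IMF
#'
#' Integrates the Hilbert spectrum along the time axis: each kept sample
#' contributes `amp * dt` (or `amp^2 * dt` with `energy = "squared"`) to
#' the frequency bin holding its instantaneous frequency.  Frequencies at
#' or above `fmax_hz` are accumulated in the top bin, so the bin sum equals
#' the time integral of the amplitude exactly (energy conservation).
#'
#' @param hs A [hilbert_analysis()] result.
#' @param imf_index Which IMF (1-based).
#' @param bin_hz Bin width in Hz (default 0.05).
#' @param fmax_hz Upper grid edge in Hz (default 20).
#' @param energy `"amplitude"` or `"squared"` integrand.
#' @return Object of class `"marginal_spectrum"`: list with `freq_hz` (bin
#'   centres), `energy`, `frame_duration_s`.
#' @export
marginal_spectrum <- function(hs, imf_index, bin_hz = 0.05, fmax_hz = 20,
                              energy = c("amplitude", "squared")) {
  energy <- match.arg(energy)
  if (bin_hz <= 0) stop("bin_hz must be > 0")
  if (imf_index < 1L || imf_index > length(hs$per_imf))
    stop("imf_index out of range")
  ent <- hs$per_imf[[imf_index]]
  nb <- ceiling(fmax_hz / bin_hz)
  bin <- pmin(floor(ent$freq_hz / bin_hz) + 1L, nb)
  amp <- if (energy == "squared") ent$amp^2 else ent$amp
  dt <- 1 / hs$fs
  e <- numeric(nb)
  acc <- tapply(amp * dt, bin, sum)
  e[as.integer(names(acc))] <- acc
  structure(list(freq_hz = (seq_len(nb) - 0.5) * bin_hz, energy = e,
                 frame_duration_s = hs$duration_s),
            class = "marginal_spectrum")
}

#' Area centroid of a marginal Hilbert spectrum
#'
#' The feature point of one IMF: mean frequency
#' `sum(freq * MHS) / sum(MHS)` (0 for an all-zero spectrum) and power
#' `sum(MHS) / T`, the spectral energy per second of the analysis frame.
#'
#' @param mhs A [marginal_spectrum()] result.
#' @return List of class `"mhs_centroid"` with `freq_hz` and `power`.
#' @export
mhs_centroid <- function(mhs) {
  if (mhs$frame_duration_s <= 0) stop("frame duration must be > 0")
  total <- sum(mhs$energy)
  freq <- if (total > 0) sum(mhs$freq_hz * mhs$energy) / total else 0
  structure(list(freq_hz = freq, power = total / mhs$frame_duration_s),
            class = "mhs_centroid")
}
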