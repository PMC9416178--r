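#' Remove the DC component of a signal
#'
#' The reader's receiver circuit adds a constant (zero-frequency) offset to
#' the phase series; by the Fourier identity the DC term equals the sample
#' mean, so it is removed by subtracting the mean.
#'
#' @param x Numeric vector.
#' @return `x - mean(x)`.
#' @export
remove_dc <- function(x) {
  if (!length(x)) stop("empty signal", call. = FALSE)
  x - mean(x)
}

#' Butterworth bandpass filter for the respiratory band
#'
#' Applies a digital Butterworth bandpass (default 2nd order, 0.1-1 Hz) to
#' isolate breathing: quiet adult respiration sits around 0.2-0.33 Hz and
#' essentially never exceeds 1 Hz, while low-frequency drift crowds the
#' region below 0.1 Hz. The Butterworth magnitude response is maximally flat
#' in the passband; order 2 already suppresses the drift, and much higher
#' orders distort the waveform. Filtering is zero-phase by default
#' (forward-backward), which keeps extremum timing intact for waveform
#' reconstruction; set `zero_phase = FALSE` for a causal single pass.
#'
#' @param x A `clean_stream`, or a numeric vector (then `Fs` is required).
#' @param order Filter order (>= 1), default 2.
#' @param band Passband `c(f_lo, f_hi)` in Hz.
#' @param Fs Sampling rate in Hz; taken from `x` when it is a `clean_stream`.
#' @param zero_phase Use forward-backward filtering (default `TRUE`).
#' @return Filtered numeric vector, same length as the input signal.
#' @examples
#' cs <- clean_stream(simulate_streams(breathing_scenario(1, seed = 3), 30)$streams[[1]])
#' y <- bandpass(cs)
#' @export
bandpass <- function(x, order = 2, band = c(0.1, 1.0), Fs = NULL,
                     zero_phase = TRUE) {
  if (inherits(x, "clean_stream")) {
    if (is.null(Fs)) Fs <- x$Fs
    x <- x$phase
  }
  if (is.null(Fs)) stop("`Fs` is required for a plain numeric signal", call. = FALSE)
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    stop("`band` must be c(f_lo, f_hi) with 0 < f_lo < f_hi", call. = FALSE)
  }
  if (Fs <= 2 * band[2]) {
    stop("sampling rate ", Fs, " Hz cannot carry the passband upper edge ",
         band[2], " Hz (need Fs > 2 * f_hi)", call. = FALSE)
  }
  bf <- signal::butter(order, band / (Fs / 2), type = "pass")
  if (zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Extract the respiratory rate as the dominant spectral peak
#'
#' Computes the FFT magnitude spectrum of the (filtered) phase series,
#' zero-padded so the frequency grid is no coarser than 0.01 Hz, and returns
#' the frequency of the largest magnitude within the respiratory band. Ties
#' go to the lower frequency.
#'
#' @param x Filtered numeric signal on a uniform grid.
#' @param Fs Sampling rate in Hz.
#' @param band Search band `c(f_lo, f_hi)` in Hz.
#' @param window `"rect"` (plain FFT, default) or `"hann"`.
#' @return An object of class `rate_estimate`: list with `rate` (Hz),
#'   `rate_bpm`, `peak_amplitude`, `freq` and `magnitude` (the in-band
#'   spectrum), and `band`.
#' @examples
#' t <- seq(0, 128, by = 1 / 16)
#' est <- extract_rate(sin(2 * pi * 0.25 * t), Fs = 16)
#' est$rate  # 0.25
#' @export
extract_rate <- function(x, Fs, band = c(0.1, 1.0), window = c("rect", "hann")) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 10 * Fs) {
    stop("signal too short for rate extraction (need >= 10 s, got ",
         round(n / Fs, 1), " s)", call. = FALSE)
  }
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
  }
  nfft <- 2^ceiling(log2(max(8 * n, Fs / 0.01)))
  spec <- Mod(stats::fft(c(x, numeric(nfft - n))))
  freq <- (seq_len(nfft) - 1) * Fs / nfft
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("no FFT bins inside the band", call. = FALSE)
  f_in <- freq[keep]
  m_in <- spec[keep]
  i <- which.max(m_in)  # first maximum = lowest-frequency tie
  structure(list(rate = f_in[i], rate_bpm = 60 * f_in[i],
                 peak_amplitude = m_in[i], freq = f_in, magnitude = m_in,
                 band = band),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Respiratory rate: %.4f Hz (%.2f bpm), band %.2f-%.2f Hz\n",
              x$rate, x$rate_bpm, x$band[1], x$band[2]))
  invisible(x)
}
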