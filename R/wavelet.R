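# Daubechies-2 decomposition lowpass filter (orthonormal, sum = sqrt(2)).
DB2_DEC_LO <- c((1 - sqrt(3)), (3 - sqrt(3)), (3 + sqrt(3)), (1 + sqrt(3))) / (4 * sqrt(2))

#' Choose the wavelet decomposition depth from the sampling rate
#'
#' The reader's sampling rate varies with distance, tag orientation and tag
#' type, so the decomposition depth must be chosen per recording. The
#' level-n approximation has effective rate `Fs / 2^n`; reconstruction works
#' best when that rate lies in `[lo, hi]` (default 0.6-2.0 Hz: twice the
#' 0.3 Hz reference breathing rate on the low side, twice the 1 Hz ceiling
#' of human breathing on the high side). Among admissible levels, the one
#' whose residual `f(n) = Fs / 2^n - 2 * Frr` is smallest while still
#' non-negative is chosen, i.e. the deepest level that keeps the
#' approximation rate at or above twice the reference rate. If no admissible
#' level has a non-negative residual, the level with the smallest `|f(n)|`
#' is used.
#'
#' @param Fs Sampling rate in Hz.
#' @param lo,hi Admissible approximation-rate bounds in Hz.
#' @param Frr Reference respiratory rate in Hz (default 0.3, i.e. 18 bpm).
#' @return An object of class `wavelet_plan`: list with `Fs`, `n` (chosen
#'   level), `omega` (admissible levels), `Frr`, `lo`, `hi`.
#' @examples
#' select_levels(23.1674)$n  # 5
#' @export
select_levels <- function(Fs, lo = 0.6, hi = 2.0, Frr = 0.3) {
  if (Fs <= lo) stop("sampling rate ", Fs, " Hz is below the admissible band",
                     call. = FALSE)
  eps <- 1e-9
  e_min <- max(0L, as.integer(ceiling(log2(Fs / hi) - eps)))
  e_max <- as.integer(floor(log2(Fs / lo) + eps))
  if (e_max < e_min) {
    stop("no integer level n keeps Fs/2^n within [", lo, ", ", hi, "] Hz for Fs = ",
         Fs, " Hz", call. = FALSE)
  }
  omega <- e_min:e_max
  f <- Fs / 2^omega - 2 * Frr
  ok <- f >= 0
  n <- if (any(ok)) omega[ok][which.min(f[ok])] else omega[which.min(abs(f))]
  structure(list(Fs = Fs, n = n, omega = omega, Frr = Frr, lo = lo, hi = hi),
            class = "wavelet_plan")
}

# One decimated db2 analysis step with symmetric boundary extension.
dwt_step_db2 <- function(x) {
  n <- length(x)
  fl <- length(DB2_DEC_LO)
  ext <- c(rev(x[seq_len(fl - 1L)]), x, rev(x[seq(n - fl + 2L, n)]))
  y <- stats::convolve(ext, rev(DB2_DEC_LO), type = "open")
  y[seq(2L * fl - 3L, by = 2L, length.out = (n + fl - 1L) %/% 2L)]
}

#' Level-n db2 wavelet approximation of a phase series
#'
#' Runs an n-level decimated discrete wavelet decomposition with the
#' Daubechies-2 wavelet (symmetric boundary extension) and keeps only the
#' level-n approximation coefficients, discarding all detail branches. At
#' the chosen level every high-frequency ripple of the respiratory waveform
#' has been removed and only the low-frequency contour - the breathing
#' envelope - remains. db2 is used because the Haar wavelet lacks symmetry
#' and distorts the waveform phase, while higher-order Daubechies wavelets
#' cost more for little gain.
#'
#' Coefficients are in the decimated (orthonormal) convention, so a
#' constant signal `c` comes back as `c * 2^(n/2)`.
#'
#' @param x Numeric signal on a uniform grid (typically [bandpass()] output).
#' @param plan A `wavelet_plan` from [select_levels()], or an integer level.
#' @param t0 Time of the first sample in seconds.
#' @param Fs Sampling rate in Hz; taken from the plan if missing.
#' @return A list with `coef` (approximation coefficients), `t` (coefficient
#'   times `t0 + k * 2^n / Fs`), `n`, and `Fs`.
#' @examples
#' ap <- approximation(rep(2, 64), select_levels(16))
#' head(ap$coef)
#' @export
approximation <- function(x, plan, t0 = 0, Fs = NULL) {
  if (inherits(plan, "wavelet_plan")) {
    n_lev <- plan$n
    if (is.null(Fs)) Fs <- plan$Fs
  } else {
    n_lev <- as.integer(plan)
    if (is.null(Fs)) stop("`Fs` is required when `plan` is a bare level", call. = FALSE)
  }
  if (n_lev < 0L) stop("decomposition level must be >= 0", call. = FALSE)
  a <- as.numeric(x)
  for (j in seq_len(n_lev)) {
    if (length(a) < length(DB2_DEC_LO)) {
      stop("signal too short for a ", n_lev, "-level decomposition", call. = FALSE)
    }
    a <- dwt_step_db2(a)
  }
  list(coef = a, t = t0 + (seq_along(a) - 1) * 2^n_lev / Fs, n = n_lev, Fs = Fs)
}
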