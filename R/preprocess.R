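#' Remove pi-radian ambiguity from a wrapped phase sequence
#'
#' The reader may report either the true phase or the true phase shifted by
#' pi (mod 2*pi). Scanning the sequence in time order, a sample is flagged
#' as ambiguous when its circular distance to the previous accepted value
#' falls within `delta` of pi; it is then corrected by +pi or -pi, whichever
#' lands closer to the previous accepted value. Corrections compare against
#' the running corrected reference, so a single flip does not cascade.
#'
#' @param phases Numeric vector of wrapped phases in `[0, 2*pi)`.
#' @param delta Detection half-width in radians, in `(0, pi)`. Default 1.8:
#'   a jump whose circular size lies in `[pi - 1.8, pi]` is treated as an
#'   ambiguity event.
#' @return Numeric vector of the same length with ambiguities removed.
#' @examples
#' disambiguate(c(1, 1 + pi, 1))  # the middle sample is pulled back to 1
#' @export
disambiguate <- function(phases, delta = 1.8) {
  if (delta <= 0 || delta >= pi) stop("`delta` must be in (0, pi)", call. = FALSE)
  n <- length(phases)
  if (n == 0L) return(numeric(0))
  out <- phases
  prev <- out[1L]
  if (n > 1L) for (i in 2:n) {
    d <- abs(out[i] - prev) %% (2 * pi)
    circ <- min(d, 2 * pi - d)
    if (circ >= pi - delta && circ <= pi + delta) {
      cand <- c(out[i] + pi, out[i] - pi)
      out[i] <- cand[which.min(abs(cand - prev))]
    }
    prev <- out[i]
  }
  out
}

#' Unwrap 2*pi jumps from a phase sequence
#'
#' The carrier phase wraps when it crosses a period boundary (2*pi -> 0 or
#' 0 -> 2*pi). Scanning in time order with an accumulated multiple-of-2*pi
#' offset, a sample whose distance to the previous accepted value is within
#' `delta` of 2*pi is shifted by +2*pi (if below the reference) or -2*pi (if
#' above). The output is continuous and may leave `[0, 2*pi)`.
#'
#' Breathing moves the phase by well under `delta` between consecutive
#' reads, so genuine motion is never mistaken for a wrap.
#'
#' @param phases Numeric vector of (disambiguated) wrapped phases.
#' @param delta Detection half-width in radians. Default 1.
#' @return Numeric vector of unwrapped phases, same length.
#' @examples
#' unwrap_phase(c(6.2, 0.05))  # second sample becomes 0.05 + 2*pi
#' @export
unwrap_phase <- function(phases, delta = 1) {
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  n <- length(phases)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  offset <- 0
  out[1L] <- phases[1L]
  if (n > 1L) for (i in 2:n) {
    cand <- phases[i] + offset
    if (abs(cand - out[i - 1L]) >= 2 * pi - delta &&
        abs(cand - out[i - 1L]) <= 2 * pi + delta) {
      offset <- offset + if (cand < out[i - 1L]) 2 * pi else -2 * pi
      cand <- phases[i] + offset
    }
    out[i] <- cand
  }
  out
}

#' Estimate the reader sampling rate from timestamps
#'
#' The reader does not interrogate at a constant rate, so the effective
#' sampling frequency is taken as the number of inter-sample intervals over
#' the spanned time: `Fs = (N - 1) / ((t_last - t_first) / 1000)`.
#'
#' @param t_ms Strictly increasing timestamps in milliseconds.
#' @return Estimated sampling frequency in Hz.
#' @examples
#' estimate_fs(c(0, 500, 1000))  # 2 Hz
#' @export
estimate_fs <- function(t_ms) {
  if (length(t_ms) < 2L) stop("need at least 2 samples to estimate Fs", call. = FALSE)
  if (any(diff(t_ms) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  (length(t_ms) - 1) / ((t_ms[length(t_ms)] - t_ms[1L]) / 1000)
}

#' Resample an unwrapped phase series onto a uniform grid
#'
#' Filters and the FFT need uniformly spaced samples, but the reader's
#' interrogations are irregular. Linear interpolation maps the unwrapped
#' series onto the grid `t[1] + k / Fs`, `k = 0..floor((t_last - t_first) * Fs)`.
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param phase Unwrapped phase values at `t`.
#' @param Fs Target sampling frequency in Hz (> 0); defaults to the rate
#'   estimated from `t`.
#' @return A list of class `clean_stream` with fields `t` (uniform grid, s),
#'   `phase` (radians), `Fs` (Hz) and `epc` (`NA` unless set by
#'   [clean_stream()]).
#' @export
resample_uniform <- function(t, phase, Fs = NULL) {
  if (length(t) != length(phase)) stop("`t` and `phase` lengths differ", call. = FALSE)
  if (length(t) < 2L) stop("need at least 2 samples to resample", call. = FALSE)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (is.null(Fs)) Fs <- estimate_fs(t * 1000)
  if (Fs <= 0) stop("`Fs` must be positive", call. = FALSE)
  grid <- t[1L] + seq(0, floor((t[length(t)] - t[1L]) * Fs)) / Fs
  y <- stats::approx(t, phase, xout = grid, method = "linear", rule = 2)$y
  structure(list(t = grid, phase = y, Fs = Fs, epc = NA_character_),
            class = "clean_stream")
}

#' Clean one raw tag stream
#'
#' Full pre-processing for a single tag: pi-radian disambiguation, 2*pi
#' unwrapping, sampling-rate estimation from the timestamps, and linear
#' resampling onto a uniform grid at that rate.
#'
#' @param stream A data.frame with columns `t_ms` and `phase` (and
#'   optionally `epc`), as produced by [simulate_streams()] or
#'   [read_phase_log()].
#' @param delta_ambiguity Threshold for [disambiguate()], radians.
#' @param delta_unwrap Threshold for [unwrap_phase()], radians.
#' @return A `clean_stream` (see [resample_uniform()]).
#' @examples
#' sim <- simulate_streams(breathing_scenario(1, seed = 2), 20)
#' cs <- clean_stream(sim$streams[[1]])
#' cs$Fs
#' @export
clean_stream <- function(stream, delta_ambiguity = 1.8, delta_unwrap = 1) {
  stopifnot(is.data.frame(stream), all(c("t_ms", "phase") %in% names(stream)))
  if (nrow(stream) < 2L) stop("stream too short to clean", call. = FALSE)
  ph <- disambiguate(stream$phase, delta_ambiguity)
  ph <- unwrap_phase(ph, delta_unwrap)
  Fs <- estimate_fs(stream$t_ms)
  cs <- resample_uniform(stream$t_ms / 1000, ph, Fs)
  cs$epc <- if ("epc" %in% names(stream)) stream$epc[1L] else NA_character_
  cs
}
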