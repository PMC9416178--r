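#' Detect local extrema of the wavelet approximation
#'
#' Interior samples strictly greater than both neighbours are maxima,
#' strictly smaller are minima. A flat run (plateau) contributes its first
#' sample. The extrema of the level-n approximation are read as the peaks
#' and troughs of the breathing waveform.
#'
#' @param coef Numeric sequence (approximation coefficients).
#' @param t Times of the coefficients in seconds.
#' @return A data.frame with columns `time`, `value`, `kind`
#'   (`"max"`/`"min"`) and `index`, in chronological order. Fewer than 3
#'   samples give an empty frame.
#' @examples
#' detect_extrema(c(0, 1, 0), 0:2)
#' @export
detect_extrema <- function(coef, t = seq_along(coef)) {
  stopifnot(length(coef) == length(t))
  empty <- data.frame(time = numeric(), value = numeric(),
                      kind = character(), index = integer(),
                      stringsAsFactors = FALSE)
  if (length(coef) < 3L) return(empty)
  # Collapse plateaus to their first sample, then compare run neighbours.
  r <- rle(coef)
  v <- r$values
  first_idx <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  if (length(v) < 3L) return(empty)
  inner <- 2:(length(v) - 1L)
  is_max <- v[inner] > v[inner - 1L] & v[inner] > v[inner + 1L]
  is_min <- v[inner] < v[inner - 1L] & v[inner] < v[inner + 1L]
  keep <- inner[is_max | is_min]
  if (!length(keep)) return(empty)
  idx <- first_idx[keep]
  data.frame(time = t[idx], value = coef[idx],
             kind = ifelse(is_max[keep - 1L], "max", "min"),
             index = idx, stringsAsFactors = FALSE)
}

#' Amplitude-filter an extremum sequence
#'
#' A genuine breath swings the phase by an amount comparable to the typical
#' peak-trough range; tiny wiggles are noise. With `emax` the mean of all
#' maxima and `emin` the mean of all minima (computed once, before any
#' rejection), an extremum is kept only if it differs from the last kept
#' extremum by at least `alpha * (emax - emin)`. The first extremum is
#' always kept.
#'
#' @param ex Extremum data.frame from [detect_extrema()].
#' @param alpha Proportionality constant in `(0, 1]`, default 0.5.
#' @return The surviving rows of `ex`.
#' @export
filter_extrema <- function(ex, alpha = 0.5) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  if (!nrow(ex)) return(ex)
  emax <- mean(ex$value[ex$kind == "max"])
  emin <- mean(ex$value[ex$kind == "min"])
  # A lone extremum has no peer of the other kind; nothing to filter.
  if (is.nan(emax) || is.nan(emin)) return(ex)
  thr <- alpha * (emax - emin)
  keep <- logical(nrow(ex))
  keep[1L] <- TRUE
  last <- ex$value[1L]
  if (nrow(ex) > 1L) for (i in 2:nrow(ex)) {
    if (abs(ex$value[i] - last) >= thr) {
      keep[i] <- TRUE
      last <- ex$value[i]
    }
  }
  ex[keep, , drop = FALSE]
}

#' Difference an extremum sequence
#'
#' Differencing the peaks and troughs removes the slowly drifting baseline
#' and highlights the breath-to-breath phase swing: `d_i = e_{i+1} - e_i`.
#'
#' @param ex Extremum data.frame (time order).
#' @return A list of class `diff_sequence`: `d` (differences), `t_left`,
#'   `t_right` (times of the flanking extrema), `L` (count), and `extrema`
#'   (the input rows).
#' @export
difference <- function(ex) {
  d <- if (nrow(ex) >= 2L) diff(ex$value) else numeric(0)
  structure(list(d = d,
                 t_left = if (length(d)) ex$time[seq_along(d)] else numeric(0),
                 t_right = if (length(d)) ex$time[seq_along(d) + 1L] else numeric(0),
                 L = length(d), extrema = ex),
            class = "diff_sequence")
}

#' Enforce sign alternation of the difference sequence
#'
#' Adjacent peaks and troughs of a breathing waveform must alternate: each
#' difference between consecutive extrema must flip sign
#' (`sign(d_i) * sign(d_{i-1}) = -1`). While some adjacent pair of
#' differences shares a sign, the shared middle extremum of the first
#' offending triple is removed (merging the two differences, i.e. keeping
#' the larger net swing) and the differences are recomputed.
#'
#' @param D A `diff_sequence` from [difference()].
#' @return A `diff_sequence` whose `d` alternates in sign.
#' @export
enforce_alternation <- function(D) {
  stopifnot(inherits(D, "diff_sequence"))
  ex <- D$extrema
  repeat {
    d <- if (nrow(ex) >= 2L) diff(ex$value) else numeric(0)
    if (length(d) < 2L) break
    s <- sign(d)
    bad <- which(s[-1L] * s[-length(s)] >= 0)
    if (!length(bad)) break
    ex <- ex[-(bad[1L] + 1L), , drop = FALSE]  # drop the shared middle extremum
  }
  difference(ex)
}

#' Reconstruct the breathing waveform through the surviving extrema
#'
#' Fits a natural cubic spline through the (time, value) points of the
#' filtered, alternating extrema and evaluates it on a uniform grid. The
#' spline passes through every knot exactly; with only two knots it
#' degenerates to the straight line between them.
#'
#' @param ex Extremum data.frame (the knots), at least 2 rows.
#' @param Fs_out Output grid rate in Hz.
#' @return A data.frame with columns `t` (s) and `y` (radians) spanning the
#'   first to last knot.
#' @export
spline_waveform <- function(ex, Fs_out = 10) {
  if (nrow(ex) < 2L) stop("need at least 2 extrema to reconstruct", call. = FALSE)
  f <- stats::splinefun(ex$time, ex$value, method = "natural")
  t <- seq(ex$time[1L], ex$time[nrow(ex)], by = 1 / Fs_out)
  data.frame(t = t, y = f(t))
}

#' Full waveform-reconstruction chain for one cleaned stream
#'
#' Composes the reconstruction steps: depth selection from the sampling
#' rate, db2 wavelet approximation, extremum detection, amplitude
#' filtering, differencing with sign-alternation enforcement, and (when at
#' least two extrema survive) cubic-spline interpolation.
#'
#' @param cs A `clean_stream` from [clean_stream()].
#' @param signal Optional pre-filtered signal to decompose instead of
#'   `cs$phase` (e.g. [bandpass()] output).
#' @param alpha Amplitude-filter constant, see [filter_extrema()].
#' @param Frr Reference rate for [select_levels()], Hz.
#' @param Fs_out Spline output rate, Hz.
#' @return A list of class `reconstruction`: `plan`, `approx`, `extrema`
#'   (surviving knots), `D` (alternating `diff_sequence`), `waveform`
#'   (data.frame or `NULL` when under 2 knots survive).
#' @examples
#' sim <- simulate_streams(breathing_scenario(1, seed = 4), 60)
#' cs <- clean_stream(sim$streams[[1]])
#' rec <- reconstruct_waveform(cs, signal = bandpass(cs))
#' rec$D$L
#' @export
reconstruct_waveform <- function(cs, signal = NULL, alpha = 0.5, Frr = 0.3,
                                 Fs_out = 10) {
  stopifnot(inherits(cs, "clean_stream"))
  x <- if (is.null(signal)) remove_dc(cs$phase) else signal
  plan <- select_levels(cs$Fs, Frr = Frr)
  ap <- approximation(x, plan, t0 = cs$t[1L])
  ex <- detect_extrema(ap$coef, ap$t)
  ex <- filter_extrema(ex, alpha)
  D <- enforce_alternation(difference(ex))
  wf <- if (nrow(D$extrema) >= 2L) spline_waveform(D$extrema, Fs_out) else NULL
  structure(list(plan = plan, approx = ap, extrema = D$extrema, D = D,
                 waveform = wf, epc = cs$epc),
            class = "reconstruction")
}
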