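#' Minimum expected extremum-difference count for a monitoring interval
#'
#' Over an interval of `dt` seconds a breathing person at the slowest
#' plausible rate `fmin` produces at least `2 * fmin * dt` extremum
#' differences (each breath contributes a peak and a trough).
#'
#' @param dt Monitoring time in seconds (> 0).
#' @param fmin Slowest plausible respiratory rate, Hz (default 0.05).
#' @return The threshold `2 * fmin * dt`.
#' @examples
#' length_threshold(16.5226)  # 1.65226
#' @export
length_threshold <- function(dt, fmin = 0.05) {
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  2 * fmin * dt
}

#' Length principle for tag selection
#'
#' A tag is monitoring breathing only if its difference sequence is long
#' enough for the time spanned: `2 * fmin * dt < L`. A tag that fails this
#' over an interval saw too few breath-like phase swings - either it is on
#' the wrong body part or the person is not breathing.
#'
#' @param L Number of extremum differences observed.
#' @param dt Monitoring time in seconds.
#' @param fmin Slowest plausible respiratory rate, Hz.
#' @return `TRUE` if the tag passes.
#' @examples
#' length_principle(1, 16.5226)  # FALSE: apnea indicator
#' @export
length_principle <- function(L, dt, fmin = 0.05) {
  stopifnot(L >= 0)
  length_threshold(dt, fmin) < L
}

#' Amplitude principle for tag selection
#'
#' The mean absolute extremum difference must exceed a threshold `Delta`,
#' otherwise the phase barely moved and the tag is not seeing respiration.
#' The default threshold is ten times the reader's phase quantization step
#' (10 * 2*pi/4096, about 0.015 rad), separating respiration-scale phase
#' swings from quantization noise.
#'
#' @param D A `diff_sequence` (see [difference()]) or a numeric vector of
#'   differences.
#' @param threshold Minimum mean `|d_i|` in radians (> 0).
#' @return `TRUE` if the tag passes; an empty difference sequence fails.
#' @export
amplitude_principle <- function(D, threshold = 10 * 2 * pi / 4096) {
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  d <- if (inherits(D, "diff_sequence")) D$d else D
  if (!length(d)) return(FALSE)
  mean(abs(d)) > threshold
}

#' Respiratory-rate accuracy against ground truth
#'
#' `100 * (1 - |est - truth| / truth)` percent. Can be negative when the
#' estimate is off by more than the true rate itself.
#'
#' @param rate_est Estimated rate, Hz.
#' @param rate_true True rate, Hz (> 0).
#' @return Accuracy in percent.
#' @examples
#' rate_accuracy(0.388803, 0.3889)  # 99.98
#' @export
rate_accuracy <- function(rate_est, rate_true) {
  if (any(rate_true <= 0)) stop("`rate_true` must be positive", call. = FALSE)
  100 * (1 - abs(rate_est - rate_true) / rate_true)
}

#' Select the informative tag for one subject
#'
#' Each subject wears a chest and an abdomen tag; breathing style decides
#' which one actually moves. Given each tag's verdicts on the two selection
#' principles, the chest tag is selected when both tags pass (chest motion
#' is the conventional reference); the passing tag is selected when only one
#' passes; and when neither passes the subject is flagged as experiencing
#' apnea.
#'
#' @param tags A data.frame with columns `epc`, `body_part`, and `passes`
#'   (logical: both principles hold), 1-2 rows.
#' @return A list with `selected` (EPC or `NA`) and `apnea` (logical).
#' @export
assess_subject <- function(tags) {
  stopifnot(is.data.frame(tags), nrow(tags) >= 1L, nrow(tags) <= 2L,
            all(c("epc", "body_part", "passes") %in% names(tags)))
  ok <- tags[tags$passes, , drop = FALSE]
  if (!nrow(ok)) return(list(selected = NA_character_, apnea = TRUE))
  pick <- if (any(ok$body_part == "chest")) {
    ok$epc[ok$body_part == "chest"][1L]
  } else ok$epc[1L]
  list(selected = pick, apnea = FALSE)
}

#' Monitor every subject in a set of phase streams
#'
#' The full pipeline: each tag's raw stream is cleaned (disambiguation,
#' unwrapping, resampling), bandpass-filtered, its respiratory rate is
#' extracted from the FFT peak, and its waveform is reconstructed through
#' the wavelet/extremum chain. The two selection principles are evaluated
#' per tag over the whole recording, and per subject the informative tag is
#' selected (or apnea flagged).
#'
#' @param streams Named list of raw tag data.frames (EPC -> stream), as from
#'   [simulate_streams()]`$streams` or [read_phase_log()].
#' @param subject_map A data.frame mapping `epc` to `subject_id` and
#'   `body_part` (see [read_subject_map()]); by default decoded from the
#'   EPCs themselves.
#' @param config A [pipeline_config()] list of tuning parameters.
#' @return An object of class `monitoring_report`: list with data.frames
#'   `tags` (per-tag rate, L, dt, mean |d|, principle verdicts) and
#'   `subjects` (selected tag, rate in Hz and bpm, apnea flag).
#' @examples
#' sim <- simulate_streams(breathing_scenario(2, seed = 5), 60)
#' rep <- monitor_streams(sim$streams)
#' rep$subjects
#' @export
monitor_streams <- function(streams, subject_map = NULL,
                            config = pipeline_config()) {
  stopifnot(length(streams) > 0)
  if (is.null(subject_map)) subject_map <- subject_map_from_epcs(names(streams))
  tag_rows <- lapply(names(streams), function(epc) {
    m <- subject_map[subject_map$epc == epc, , drop = FALSE]
    if (!nrow(m)) stop("unmapped tag: EPC ", epc,
                       " is absent from the subject map", call. = FALSE)
    analyze_tag(streams[[epc]], epc, m$subject_id[1L], m$body_part[1L], config)
  })
  tags <- do.call(rbind, tag_rows)
  subjects <- lapply(split(tags, tags$subject_id), function(tg) {
    verdict <- assess_subject(tg[, c("epc", "body_part", "passes")])
    rate <- if (!is.na(verdict$selected)) tg$rate[tg$epc == verdict$selected] else NA_real_
    data.frame(subject_id = tg$subject_id[1L], selected = verdict$selected,
               rate = rate, rate_bpm = 60 * rate, apnea = verdict$apnea,
               stringsAsFactors = FALSE)
  })
  structure(list(tags = tags, subjects = do.call(rbind, unname(subjects)),
                 config = config),
            class = "monitoring_report")
}

analyze_tag <- function(stream, epc, subject_id, body_part, config) {
  cs <- clean_stream(stream, config$delta_ambiguity, config$delta_unwrap)
  x <- remove_dc(cs$phase)
  filtered <- if (config$use_bandpass) {
    bandpass(x, order = config$order, band = config$band, Fs = cs$Fs,
             zero_phase = config$zero_phase)
  } else x
  rate <- tryCatch(extract_rate(filtered, cs$Fs, config$band)$rate,
                   error = function(e) NA_real_)
  rec <- reconstruct_waveform(cs, signal = filtered, alpha = config$alpha,
                              Frr = config$Frr)
  dt <- cs$t[length(cs$t)] - cs$t[1L]
  p_len <- length_principle(rec$D$L, dt, config$fmin)
  p_amp <- amplitude_principle(rec$D, config$amplitude_threshold)
  data.frame(epc = epc, subject_id = subject_id, body_part = body_part,
             Fs = cs$Fs, dt = dt, L = rec$D$L,
             mean_abs_d = if (rec$D$L) mean(abs(rec$D$d)) else 0,
             passes_length = p_len, passes_amplitude = p_amp,
             passes = p_len && p_amp, rate = rate,
             stringsAsFactors = FALSE)
}

#' Detect apnea with sliding windows
#'
#' Runs the reconstruction chain per tag with the bandpass filter disabled -
#' filtering smears an artificial waveform into the start of a breath-hold,
#' so apnea screening is more reliable on the unfiltered (DC-removed) phase.
#' The extremum differences are computed once over the whole recording (so
#' the amplitude filter's threshold reflects real breaths), then counted
#' within sliding windows. A tag fails a window when the length principle
#' (with `dt` = window length) or the amplitude principle fails there; a
#' subject is flagged apneic when, in some window, every one of their tags
#' fails.
#'
#' @param streams Named list of raw tag streams (EPC -> data.frame).
#' @param subject_map EPC -> subject mapping; decoded from EPCs by default.
#' @param config A [pipeline_config()]; `use_bandpass` is ignored (always
#'   off here).
#' @param window Window length in seconds.
#' @param step Window step in seconds.
#' @return A data.frame per subject: `subject_id`, `apnea` (logical),
#'   `t_flag` (start of the first flagged window, or `NA`).
#' @examples
#' s <- subject_spec(1, apnea_intervals = list(c(20, 40)))
#' sim <- simulate_streams(breathing_scenario(list(s), seed = 6), 60)
#' detect_apnea(sim$streams)
#' @export
detect_apnea <- function(streams, subject_map = NULL,
                         config = pipeline_config(), window = 20, step = 5) {
  stopifnot(length(streams) > 0, window > 0, step > 0)
  if (is.null(subject_map)) subject_map <- subject_map_from_epcs(names(streams))
  per_tag <- lapply(names(streams), function(epc) {
    m <- subject_map[subject_map$epc == epc, , drop = FALSE]
    if (!nrow(m)) stop("unmapped tag: EPC ", epc, call. = FALSE)
    cs <- clean_stream(streams[[epc]], config$delta_ambiguity, config$delta_unwrap)
    rec <- reconstruct_waveform(cs, signal = remove_dc(cs$phase),
                                alpha = config$alpha, Frr = config$Frr)
    list(subject_id = m$subject_id[1L], D = rec$D,
         t0 = cs$t[1L], t1 = cs$t[length(cs$t)])
  })
  subjects <- unique(vapply(per_tag, `[[`, numeric(1), "subject_id"))
  out <- lapply(subjects, function(sid) {
    tags <- Filter(function(p) p$subject_id == sid, per_tag)
    t0 <- min(vapply(tags, `[[`, numeric(1), "t0"))
    t1 <- max(vapply(tags, `[[`, numeric(1), "t1"))
    starts <- if (t1 - t0 <= window) t0 else seq(t0, t1 - window, by = step)
    flag_at <- NA_real_
    for (w0 in starts) {
      w1 <- w0 + window
      all_fail <- all(vapply(tags, function(p) {
        inside <- p$D$t_left >= w0 & p$D$t_right <= w1
        L <- sum(inside)
        !(length_principle(L, window, config$fmin) &&
            amplitude_principle(p$D$d[inside], config$amplitude_threshold))
      }, logical(1)))
      if (all_fail) { flag_at <- w0; break }
    }
    data.frame(subject_id = sid, apnea = !is.na(flag_at), t_flag = flag_at)
  })
  do.call(rbind, out)
}

#' @export
print.monitoring_report <- function(x, ...) {
  cat("Respiratory monitoring report\n")
  for (i in seq_len(nrow(x$subjects))) {
    s <- x$subjects[i, ]
    if (s$apnea) {
      cat(sprintf("  subject %d: APNEA ALARM (no informative tag)\n", s$subject_id))
    } else {
      cat(sprintf("  subject %d: %.4f Hz (%.1f bpm) via %s tag %s\n",
                  s$subject_id, s$rate, s$rate_bpm,
                  x$tags$body_part[x$tags$epc == s$selected], s$selected))
    }
  }
  invisible(x)
}
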