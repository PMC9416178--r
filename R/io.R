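#' Pipeline tuning parameters
#'
#' One place for every knob of the monitoring pipeline, with defaults at
#' the values the method was developed with: disambiguation threshold 1.8
#' rad, unwrapping threshold 1 rad, passband 0.1-1 Hz with a 2nd-order
#' zero-phase Butterworth filter, extremum-filter constant `alpha = 0.5`,
#' slowest plausible rate `fmin = 0.05` Hz, amplitude threshold ten
#' quantization steps, reference rate `Frr = 0.3` Hz, db2 wavelet, and a
#' 20 s apnea window.
#'
#' @param delta_ambiguity Disambiguation threshold, radians.
#' @param delta_unwrap Unwrapping threshold, radians.
#' @param band Bandpass `c(f_lo, f_hi)`, Hz.
#' @param order Butterworth order.
#' @param zero_phase Forward-backward filtering.
#' @param use_bandpass Apply the bandpass in [monitor_streams()].
#' @param alpha Extremum amplitude-filter constant.
#' @param fmin Slowest plausible respiratory rate, Hz.
#' @param amplitude_threshold Mean `|d|` threshold, radians.
#' @param Frr Reference respiratory rate, Hz.
#' @param wavelet Wavelet name (only `"db2"` is implemented).
#' @param apnea_window Apnea sliding-window length, seconds.
#' @param seed Seed recorded for provenance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(delta_ambiguity = 1.8, delta_unwrap = 1,
                            band = c(0.1, 1.0), order = 2, zero_phase = TRUE,
                            use_bandpass = TRUE, alpha = 0.5, fmin = 0.05,
                            amplitude_threshold = 10 * 2 * pi / 4096,
                            Frr = 0.3, wavelet = "db2", apnea_window = 20,
                            seed = 1L) {
  if (!identical(wavelet, "db2")) {
    stop("only the db2 wavelet is implemented", call. = FALSE)
  }
  structure(list(delta_ambiguity = delta_ambiguity, delta_unwrap = delta_unwrap,
                 band = band, order = order, zero_phase = zero_phase,
                 use_bandpass = use_bandpass, alpha = alpha, fmin = fmin,
                 amplitude_threshold = amplitude_threshold, Frr = Frr,
                 wavelet = wavelet, apnea_window = apnea_window,
                 seed = as.integer(seed)),
            class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

PHASE_LOG_HEADER <- c("epc", "t_ms", "phase_rad", "raw_code", "rssi_dbm")

#' Write phase streams to a delimited text log
#'
#' One CSV row per reader observation: `epc,t_ms,phase_rad,raw_code,rssi_dbm`.
#' Comment lines starting with `#` carry provenance (e.g. the scenario
#' seed). The ground truth of a simulation can be written alongside with
#' [write_truth()].
#'
#' @param streams Named list of tag data.frames (EPC -> stream) or a
#'   `phase_simulation`.
#' @param path Output file path.
#' @param provenance Optional named character vector written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_phase_log <- function(streams, path, provenance = NULL) {
  if (inherits(streams, "phase_simulation")) {
    provenance <- c(provenance, seed = streams$scenario$seed,
                    duration_s = streams$duration)
    streams <- streams$streams
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  writeLines(paste(PHASE_LOG_HEADER, collapse = ","), con)
  for (s in streams) {
    rssi <- if ("rssi" %in% names(s)) s$rssi else NA_real_
    writeLines(sprintf("%s,%d,%.10g,%d,%.1f", s$epc, s$t_ms, s$phase,
                       s$raw_code, rssi), con)
  }
  invisible(path)
}

#' Read a phase log into per-tag streams
#'
#' Parses the delimited format of [write_phase_log()], groups records by
#' EPC preserving file order, and validates timestamps. Malformed rows
#' raise an error naming the line; non-monotone timestamps within a tag
#' produce a warning and a stable sort.
#'
#' @param path Path to a phase log.
#' @return Named list EPC -> data.frame with columns `epc`, `t_ms`,
#'   `phase`, `raw_code`, `rssi`.
#' @export
read_phase_log <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  body <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body)) stop("phase log has no header line", call. = FALSE)
  header <- strsplit(lines[body[1L]], ",", fixed = TRUE)[[1L]]
  if (!all(PHASE_LOG_HEADER %in% trimws(header))) {
    stop("phase log is missing columns: ",
         paste(setdiff(PHASE_LOG_HEADER, trimws(header)), collapse = ", "),
         call. = FALSE)
  }
  data_lines <- body[-1L]
  if (!length(data_lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines[data_lines], ",", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad)) {
    stop("malformed phase-log row at line ", data_lines[bad[1L]], ": ",
         lines[data_lines[bad[1L]]], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  colnames(m) <- trimws(header)
  t_ms <- suppressWarnings(as.integer(m[, "t_ms"]))
  phase <- suppressWarnings(as.numeric(m[, "phase_rad"]))
  raw_code <- suppressWarnings(as.integer(m[, "raw_code"]))
  bad <- which(is.na(t_ms) | is.na(phase))
  if (length(bad)) {
    stop("non-numeric field in phase-log row at line ", data_lines[bad[1L]],
         call. = FALSE)
  }
  df <- data.frame(epc = m[, "epc"], t_ms = t_ms, phase = phase,
                   raw_code = raw_code,
                   rssi = suppressWarnings(as.numeric(m[, "rssi_dbm"])),
                   stringsAsFactors = FALSE)
  out <- split(df, df$epc)
  out <- lapply(out, function(s) {
    if (is.unsorted(s$t_ms)) {
      warning("timestamps for EPC ", s$epc[1L],
              " are not non-decreasing; applying a stable sort", call. = FALSE)
      s <- s[order(s$t_ms), , drop = FALSE]
    }
    rownames(s) <- NULL
    s
  })
  out[unique(df$epc)]
}

#' Write / read the simulation ground truth sidecar
#'
#' @param sim A `phase_simulation`.
#' @param path CSV path for the per-tag truth; apnea windows go to
#'   `<path>.apnea`.
#' @return `read_truth()` returns a list with `truth` and `apnea`
#'   data.frames.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "phase_simulation"))
  utils::write.csv(sim$truth, path, row.names = FALSE)
  utils::write.csv(sim$apnea, paste0(path, ".apnea"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  list(truth = utils::read.csv(path, stringsAsFactors = FALSE),
       apnea = utils::read.csv(paste0(path, ".apnea"), stringsAsFactors = FALSE))
}

#' Subject map: which tag sits on which person and body part
#'
#' `read_subject_map()` reads a CSV with columns `epc`, `subject_id`,
#' `body_part`; `write_subject_map()` writes one;
#' `subject_map_from_epcs()` decodes the mapping from the id word embedded
#' in each EPC (see [epc_encode()]), for tags whose EPC was pre-written.
#' A file-based map overrides the in-EPC encoding.
#'
#' @param path CSV path.
#' @param epcs Character vector of EPCs.
#' @param map A subject-map data.frame.
#' @return A data.frame with columns `epc`, `subject_id`, `body_part`.
#' @export
read_subject_map <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epc", "subject_id", "body_part")
  if (!all(need %in% names(m))) {
    stop("subject map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$epc)) stop("duplicate EPC in subject map", call. = FALSE)
  bad <- !m$body_part %in% c("chest", "abdomen")
  if (any(bad)) stop("unknown body_part: ", m$body_part[bad][1L], call. = FALSE)
  m[need]
}

#' @rdname read_subject_map
#' @export
write_subject_map <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_subject_map
#' @export
subject_map_from_epcs <- function(epcs) {
  rows <- lapply(epcs, function(e) {
    d <- epc_decode(e)
    data.frame(epc = e, subject_id = d$subject_id, body_part = d$body_part,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
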