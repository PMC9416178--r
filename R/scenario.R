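#' Encode / decode subject identity in a tag EPC
#'
#' The tag's Electronic Product Code is rewritable in 16-bit words; the last
#' word of the EPC is used here to carry the mapping to (subject, body part):
#' 12 bits of subject id followed by a 4-bit body-part code (1 = chest,
#' 2 = abdomen). `epc_encode()` appends that word (4 hex digits) to a prefix;
#' `epc_decode()` reads it back from the last 4 hex digits.
#'
#' @param subject_id Integer subject number, 0..4095.
#' @param body_part `"chest"` or `"abdomen"`.
#' @param prefix Hex string prefix for the remainder of the EPC.
#' @return `epc_encode()`: an EPC hex string. `epc_decode()`: a list with
#'   `subject_id` and `body_part`.
#' @examples
#' epc <- epc_encode(3, "chest")
#' epc_decode(epc)
#' @export
epc_encode <- function(subject_id, body_part = c("chest", "abdomen"),
                       prefix = "E2000000") {
  body_part <- match.arg(body_part)
  if (subject_id < 0 || subject_id > 4095) {
    stop("`subject_id` must fit in 12 bits (0..4095)", call. = FALSE)
  }
  bp_code <- if (body_part == "chest") 1L else 2L
  word <- bitwShiftL(as.integer(subject_id), 4L) + bp_code
  paste0(prefix, sprintf("%04X", word))
}

#' @rdname epc_encode
#' @param epc An EPC hex string produced by `epc_encode()`.
#' @export
epc_decode <- function(epc) {
  if (nchar(epc) < 4L) stop("EPC too short to carry an id word", call. = FALSE)
  word <- strtoi(substr(epc, nchar(epc) - 3L, nchar(epc)), base = 16L)
  if (is.na(word)) stop("EPC id word is not valid hex: ", epc, call. = FALSE)
  bp_code <- bitwAnd(word, 15L)
  bp <- switch(as.character(bp_code), "1" = "chest", "2" = "abdomen", NA_character_)
  if (is.na(bp)) stop("EPC body-part code ", bp_code, " is not 1 (chest) or 2 (abdomen)",
                      call. = FALSE)
  list(subject_id = bitwShiftR(word, 4L), body_part = bp)
}

#' Specify one monitored subject
#'
#' Each subject wears two tags, one on the chest and one on the abdomen,
#' because people breathe thoracically, abdominally, or with both. Each body
#' part moves sinusoidally: distance to the antenna is
#' `R(t) = R0 + A * sin(2*pi*rate*t + phase_offset)`. The chest wall excursion
#' during quiet breathing is about 0.5 cm peak to peak, i.e. `A = 2.5` mm;
#' a subject whose breathing is mostly thoracic gets a smaller abdominal
#' amplitude and vice versa. During apnea intervals the amplitude is forced
#' to zero.
#'
#' @param subject_id Integer id (0..4095).
#' @param chest,abdomen Lists with fields `R0` (baseline distance, m),
#'   `A` (motion amplitude, m), `rate` (breathing rate, Hz) and optionally
#'   `phase_offset` (radians, default 0).
#' @param apnea_intervals A list of `c(t_start, t_end)` pairs in seconds
#'   during which both body parts stop moving.
#' @return An object of class `subject_spec`.
#' @examples
#' subject_spec(1, chest = list(R0 = 1.2, A = 0.0025, rate = 0.25))
#' @export
subject_spec <- function(subject_id,
                         chest = list(R0 = 1.2, A = 0.0025, rate = 0.25),
                         abdomen = list(R0 = 1.25, A = 0.002, rate = NULL),
                         apnea_intervals = list()) {
  norm_part <- function(part, other) {
    if (is.null(part)) return(NULL)
    if (is.null(part$phase_offset)) part$phase_offset <- 0
    if (is.null(part$rate)) part$rate <- other$rate  # both parts share the breath
    stopifnot(part$R0 > 0, part$A >= 0, part$rate > 0)
    part
  }
  chest <- norm_part(chest, abdomen)
  abdomen <- norm_part(abdomen, chest)
  if (is.null(chest) && is.null(abdomen)) {
    stop("a subject needs at least one tagged body part", call. = FALSE)
  }
  for (iv in apnea_intervals) {
    if (length(iv) != 2L || iv[1] >= iv[2]) {
      stop("apnea intervals must be (t_start, t_end) with t_start < t_end",
           call. = FALSE)
    }
  }
  structure(list(subject_id = subject_id, chest = chest, abdomen = abdomen,
                 apnea_intervals = apnea_intervals),
            class = "subject_spec")
}

#' Define a multi-subject breathing scenario
#'
#' Collects the ground truth a phase-stream simulation is generated from:
#' the subjects (each with per-body-part baseline distance, amplitude and
#' rate), the reader's mean interrogation rate and its jitter, the phase
#' noise level, and the per-sample probability of a pi-radian ambiguity
#' event. Defaults reflect a UHF reader interrogating a handful of tags
#' (~25 reads/s/tag with a non-constant interval) and quiet adult breathing
#' (rates within 0.2-0.33 Hz, 0.5 cm chest excursion).
#'
#' @param subjects A list of [subject_spec()] objects, or an integer n to
#'   auto-build n subjects with rates evenly spread over `[0.2, 0.33]` Hz and
#'   baseline distances staggered from 0.8 m.
#' @param sample_rate_mean Mean per-tag read rate in Hz.
#' @param sample_jitter Fractional jitter of the inter-read interval:
#'   intervals are `(1/rate) * (1 + U(-jitter, jitter))`.
#' @param noise_sigma Standard deviation of Gaussian phase noise, radians.
#' @param ambiguity_prob Per-sample probability that the reader reports
#'   `(phase + pi) mod 2*pi` instead of the phase.
#' @param seed Integer seed making the simulation reproducible.
#' @param params A [phase_model_params()] object.
#' @return An object of class `breathing_scenario`.
#' @examples
#' sc <- breathing_scenario(2, seed = 1)
#' length(sc$subjects)
#' @export
breathing_scenario <- function(subjects = 3, sample_rate_mean = 25,
                               sample_jitter = 0.2, noise_sigma = 0.02,
                               ambiguity_prob = 0.05, seed = 1,
                               params = phase_model_params()) {
  if (is.numeric(subjects) && length(subjects) == 1L) {
    n <- as.integer(subjects)
    if (n < 1L) stop("scenario needs at least one subject", call. = FALSE)
    rates <- if (n == 1L) 0.25 else seq(0.2, 0.33, length.out = n)
    subjects <- lapply(seq_len(n), function(i) {
      subject_spec(i,
                   chest = list(R0 = 0.8 + 0.3 * (i - 1), A = 0.0025, rate = rates[i]),
                   abdomen = list(R0 = 0.85 + 0.3 * (i - 1), A = 0.002, rate = rates[i]))
    })
  }
  if (!length(subjects)) stop("scenario needs at least one subject", call. = FALSE)
  if (!all(vapply(subjects, inherits, logical(1), "subject_spec"))) {
    stop("`subjects` must be subject_spec objects", call. = FALSE)
  }
  if (ambiguity_prob < 0 || ambiguity_prob > 1) {
    stop("`ambiguity_prob` must be a probability", call. = FALSE)
  }
  max_rate <- max(vapply(subjects, function(s) {
    max(c(if (!is.null(s$chest)) s$chest$rate, if (!is.null(s$abdomen)) s$abdomen$rate))
  }, numeric(1)))
  if (sample_rate_mean <= 2 * max_rate) {
    stop("`sample_rate_mean` must exceed twice the fastest breathing rate",
         call. = FALSE)
  }
  if (sample_jitter < 0 || sample_jitter >= 1) {
    stop("`sample_jitter` must be in [0, 1)", call. = FALSE)
  }
  structure(list(subjects = subjects, sample_rate_mean = sample_rate_mean,
                 sample_jitter = sample_jitter, noise_sigma = noise_sigma,
                 ambiguity_prob = ambiguity_prob, seed = as.integer(seed),
                 params = params),
            class = "breathing_scenario")
}
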