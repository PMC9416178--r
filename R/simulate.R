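#' Simulate reader phase streams for a breathing scenario
#'
#' Stands in for the RFID reader: for every subject and tagged body part it
#' produces the time-ordered sequence of phase observations the reader would
#' report. Each stream is built as
#' distance -> round-trip phase -> additive Gaussian noise -> optional
#' pi-radian ambiguity -> 12-bit quantization, sampled at irregular
#' timestamps whose mean rate and jitter come from the scenario. Within a
#' subject's apnea intervals the body part stops moving (amplitude 0).
#'
#' Identical scenarios (including the seed) give identical streams.
#'
#' @param scenario A [breathing_scenario()] object.
#' @param duration Simulated recording length in seconds (> 0).
#' @return A list of class `phase_simulation` with
#'   \describe{
#'     \item{streams}{named list, EPC -> data.frame with columns `epc`,
#'       `t_ms` (integer ms), `phase` (quantized radians in `[0, 2*pi)`),
#'       `raw_code` (0..4095), `rssi` (dBm).}
#'     \item{truth}{data.frame with one row per tag: `epc`, `subject_id`,
#'       `body_part`, `rate` (Hz), `amplitude` (m), `R0` (m).}
#'     \item{apnea}{data.frame of apnea windows: `subject_id`, `t_start`,
#'       `t_end` (s).}
#'     \item{scenario, duration}{the inputs, for provenance.}
#'   }
#' @examples
#' sim <- simulate_streams(breathing_scenario(1, seed = 7), duration = 30)
#' names(sim$streams)
#' @export
simulate_streams <- function(scenario, duration) {
  stopifnot(inherits(scenario, "breathing_scenario"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (!length(scenario$subjects)) stop("scenario has no subjects", call. = FALSE)

  # Local RNG so the simulation neither depends on nor disturbs the caller's
  # random state.
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(scenario$seed)

  streams <- list()
  truth <- list()
  apnea <- list()
  for (subj in scenario$subjects) {
    for (bp in c("chest", "abdomen")) {
      part <- subj[[bp]]
      if (is.null(part)) next
      epc <- epc_encode(subj$subject_id, bp)
      streams[[epc]] <- simulate_one_tag(part, subj$apnea_intervals,
                                         scenario, duration, epc)
      truth[[epc]] <- data.frame(epc = epc, subject_id = subj$subject_id,
                                 body_part = bp, rate = part$rate,
                                 amplitude = part$A, R0 = part$R0,
                                 stringsAsFactors = FALSE)
    }
    for (iv in subj$apnea_intervals) {
      apnea[[length(apnea) + 1L]] <- data.frame(subject_id = subj$subject_id,
                                                t_start = iv[1], t_end = iv[2])
    }
  }
  structure(list(streams = streams,
                 truth = do.call(rbind, unname(truth)),
                 apnea = if (length(apnea)) do.call(rbind, apnea) else
                   data.frame(subject_id = integer(), t_start = numeric(),
                              t_end = numeric()),
                 scenario = scenario, duration = duration),
            class = "phase_simulation")
}

simulate_one_tag <- function(part, apnea_intervals, scenario, duration, epc) {
  # Irregular timestamps: inter-arrival = (1/rate) * (1 + U(-j, +j)).
  mean_dt <- 1 / scenario$sample_rate_mean
  n_max <- ceiling(duration / (mean_dt * (1 - scenario$sample_jitter))) + 2L
  gaps <- mean_dt * (1 + stats::runif(n_max, -scenario$sample_jitter,
                                      scenario$sample_jitter))
  t <- cumsum(c(0, gaps))
  t <- t[t <= duration]
  n <- length(t)

  A <- rep(part$A, n)
  for (iv in apnea_intervals) A[t >= iv[1] & t <= iv[2]] <- 0
  R <- part$R0 + A * sin(2 * pi * part$rate * t + part$phase_offset)

  theta <- ideal_phase(R, scenario$params)
  if (scenario$noise_sigma > 0) {
    theta <- theta + stats::rnorm(n, 0, scenario$noise_sigma)
  }
  flip <- stats::runif(n) < scenario$ambiguity_prob
  theta <- (theta + flip * pi) %% (2 * pi)
  q <- quantize_phase(theta)

  # Integer-ms timestamps, kept strictly increasing after rounding.
  t_ms <- as.integer(round(t * 1000))
  if (n > 1L) for (i in 2:n) if (t_ms[i] <= t_ms[i - 1L]) t_ms[i] <- t_ms[i - 1L] + 1L

  rssi <- round((-55 + stats::rnorm(n, 0, 0.5)) / 0.5) * 0.5  # 0.5 dB steps
  data.frame(epc = epc, t_ms = t_ms, phase = q$phase, raw_code = q$raw_code,
             rssi = rssi, stringsAsFactors = FALSE)
}
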