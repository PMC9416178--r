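# Small scenario builders shared across tests.

# One subject, chest tag only (abdomen dropped to halve the work).
one_tag_scenario <- function(rate = 0.25, A = 0.0025, R0 = 1.0,
                             noise = 0, ambiguity = 0, seed = 1,
                             sample_rate = 25, jitter = 0.2,
                             apnea = list()) {
  s <- subject_spec(1, chest = list(R0 = R0, A = A, rate = rate),
                    abdomen = NULL, apnea_intervals = apnea)
  breathing_scenario(list(s), sample_rate_mean = sample_rate,
                     sample_jitter = jitter, noise_sigma = noise,
                     ambiguity_prob = ambiguity, seed = seed)
}

# Standard cumulative 2*pi unwrapping (independent oracle for unwrap_phase):
# subtract the nearest multiple of 2*pi from each increment.
unwrap_oracle <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  x - c(0, cumsum(2 * pi * round(d / (2 * pi))))
}

# Literal enumeration of the wavelet-depth rule (independent oracle for
# select_levels): admissible levels by direct interval membership.
select_levels_oracle <- function(Fs, lo = 0.6, hi = 2.0, Frr = 0.3) {
  n_all <- 0:12
  omega <- n_all[Fs / 2^n_all >= lo & Fs / 2^n_all <= hi]
  if (!length(omega)) return(NA_integer_)
  f <- Fs / 2^omega - 2 * Frr
  if (any(f >= 0)) omega[f >= 0][which.min(f[f >= 0])] else omega[which.min(abs(f))]
}

# Random extremum data.frame for alternation property tests.
random_extrema <- function(n, seed) {
  set.seed(seed)
  data.frame(time = sort(runif(n, 0, 60)),
             value = rnorm(n),
             kind = sample(c("max", "min"), n, replace = TRUE),
             index = seq_len(n), stringsAsFactors = FALSE)
}
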