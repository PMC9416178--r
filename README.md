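# rfidbreath

Contactless, multi-person respiratory monitoring from the backscatter phase
of passive UHF RFID tags.

A tag on the chest or abdomen moves a few millimetres with every breath.
The reader measures the round-trip carrier phase

θ = 2π · 2R/λ + θ_t + θ_r + θ_tag (mod 2π),

so a displacement ΔR shifts the phase by 4πΔR/λ — about 0.1–0.4 rad for
breathing motion at λ ≈ 0.326 m (920.625 MHz). Because each tag has a
unique, rewritable EPC, several people can be monitored at once by mapping
each EPC to a (subject, body part) pair. The raw phase, however, is
reported through a 12-bit quantizer, carries a random π-radian ambiguity
introduced by the reader hardware, wraps at period boundaries, and arrives
at an irregular sampling rate. This package implements the full processing
chain that turns such streams into respiratory rates, reconstructed
breathing waveforms, and apnea alarms — plus a seeded physical simulator of
the reader so every stage can be validated against known ground truth.

The pipeline:

1. **Pre-processing** — π-radian disambiguation (threshold Δ = 1.8 rad on
   the jump to the running corrected value), 2π unwrapping (threshold
   1 rad, accumulating offset), sampling-rate estimation
   `Fs = (N−1)/span`, and linear resampling onto a uniform grid.
2. **Rate extraction** — DC (mean) removal, 2nd-order zero-phase
   Butterworth bandpass over 0.1–1 Hz, and the FFT magnitude peak within
   the band (readout grid ≤ 0.01 Hz via zero-padding). The peak frequency
   is the respiratory rate; ×60 gives breaths per minute.
3. **Waveform reconstruction** — Daubechies-2 wavelet decomposition to the
   depth n that puts the approximation rate Fs/2ⁿ just above twice the
   0.3 Hz reference rate (within the admissible 0.6–2.0 Hz band); extremum
   detection on the approximation; an amplitude filter that keeps an
   extremum only if it swings at least α(ē_max − ē_min) from the last kept
   one (α = 0.5); differencing d_i = e_{i+1} − e_i with sign-alternation
   enforcement; natural cubic spline through the surviving extrema.
4. **Tag selection and apnea** — a tag is informative when its difference
   sequence is long enough (2 f_min Δt < L, f_min = 0.05 Hz) and swings
   hard enough (mean |d_i| above ~10 quantization steps). Chest is
   preferred when both of a subject's tags pass; if neither passes in some
   20 s window (with the bandpass disabled, which is more reliable for
   breath-holds), the subject is flagged apneic.

## Worked example

Simulate three people breathing at 0.200, 0.265 and 0.330 Hz, two tags
each, 120 s at ~25 reads/s with phase noise σ = 0.02 rad and 5% ambiguity
events, then run the monitor:

```r
library(rfidbreath)
sim <- simulate_streams(breathing_scenario(3, seed = 11), 120)
rep <- monitor_streams(sim$streams)
rep
#> Respiratory monitoring report
#>   subject 1: 0.1999 Hz (12.0 bpm) via chest tag E20000000011
#>   subject 2: 0.2653 Hz (15.9 bpm) via chest tag E20000000021
#>   subject 3: 0.3299 Hz (19.8 bpm) via chest tag E20000000031
```

Every estimate lands within 0.001 Hz of the generator's ground truth
(accuracy ≥ 99.7% by `rate_accuracy()`). The per-tag detail shows the
selection principles at work — `L` difference counts far above the
2·0.05·120 = 12 threshold and mean |d| far above the amplitude floor:

```r
rep$tags[, c("epc", "body_part", "Fs", "L", "mean_abs_d", "passes", "rate")]
#>            epc body_part    Fs  L mean_abs_d passes   rate
#> 1 E20000000011     chest 25.00 46     0.9284   TRUE 0.1999
#> 2 E20000000012   abdomen 24.95 46     0.7493   TRUE 0.2003
#> 3 E20000000021     chest 25.06 62     0.8265   TRUE 0.2653
#> ...
```

A breath-hold is caught by the sliding-window screen:

```r
s <- subject_spec(1, apnea_intervals = list(c(20, 40)))
sim2 <- simulate_streams(breathing_scenario(list(s), seed = 3), 60)
detect_apnea(sim2$streams)
#>   subject_id apnea t_flag
#> 1          1  TRUE     15
```

The same operations are scriptable from a shell via the thin CLI at
`system.file("cli", "rfidbreath", package = "rfidbreath")` with subcommands
`simulate`, `clean`, `rate`, `reconstruct`, `monitor` and `apnea`.

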