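---
title: "Respiratory monitoring from RFID backscatter phase: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory monitoring from RFID backscatter phase: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfidbreath)
```

## The sensing model

A passive UHF tag answers the reader by modulating the reflection of the
carrier, and the reader reports the round-trip phase

$$\theta = \frac{2\pi \cdot 2R}{\lambda} + \theta_t + \theta_r + \theta_{tag} \pmod{2\pi},$$

where $R$ is the tag–antenna distance, $\lambda = c/f$ the carrier
wavelength (0.326 m at 920.625 MHz), and the three offsets are constant
hardware contributions from the transmitter, receiver and tag. Breathing
moves the chest wall by roughly 0.5 cm peak to peak, so a chest tag sweeps
$8\pi A/\lambda \approx 0.19$ rad of phase per breath at amplitude
$A = 2.5$ mm — two orders of magnitude above the 12-bit quantization step
$2\pi/4096 \approx 0.0015$ rad, which is why phase (rather than RSSI, with
its 0.5 dB steps and poor noise robustness, or Doppler, whose 0.0625 Hz
resolution dwarfs the $\sim 10^{-3}$ Hz shift breathing produces) carries
the respiratory signal.

Three artifacts stand between the raw reports and that signal:

* a **π-radian ambiguity**: the reader may return $(\theta + \pi) \bmod 2\pi$
  instead of $\theta$, independently per read;
* **2π wrapping** whenever the accumulated phase crosses a period boundary;
* **irregular sampling**: the interrogation rate depends on distance, tag
  orientation and tag type, and is not constant.

## What the simulator emulates — and what it does not

`breathing_scenario()` + `simulate_streams()` generate streams by composing
the distance-to-phase map with a sinusoidal displacement
$R(t) = R_0 + A\sin(2\pi f_r t + \phi_0)$ per body part, followed by
Gaussian phase noise, i.i.d. π-flips, 12-bit quantization and jittered
timestamps. Defaults were fixed once, from the physical setting the method
targets: breathing rates in 0.2–0.33 Hz, chest amplitude 2.5 mm (0.5 cm
excursion) and a slightly smaller 2.0 mm abdomen, baseline distances from
0.8 m, mean read rate 25 Hz (readers in this class deliver ~23 Hz per tag)
with ±20% inter-arrival jitter, phase noise σ = 0.02 rad, and a 5%
ambiguity probability. No occurrence model for ambiguity events is
published, so i.i.d. per sample is the neutral choice; the probability is a
scenario parameter. Apnea is modelled by forcing $A = 0$ inside the
configured intervals. Each subject's two tags carry their identity in the
last EPC word (12-bit id, 4-bit body part), and a file-based subject map
can override that encoding.

The simulator deliberately omits multipath and fading, RSSI path-loss
fidelity (RSSI is emitted only as a constant-plus-noise placeholder, since
it is unused downstream), reader anticollision timing, and posture or
angular effects. Passing tests on synthetic streams therefore demonstrate
the *algorithmic* chain — ambiguity/wrap recovery, band-limited peak
finding, extremum statistics — under controlled noise, not robustness to
every artifact of a real deployment.

## Pre-processing

`disambiguate()` walks the sequence comparing each sample to the **running
corrected** previous value; a circular distance within Δ of π marks a flip,
corrected by ±π toward the reference. Comparing to the corrected (not raw)
predecessor prevents one flip from cascading into spurious corrections.
The threshold defaults to Δ = 1.8 rad, the value found empirically
effective for this detector; the unwrapping threshold defaults to 1 rad.
`unwrap_phase()` maintains an accumulated multiple-of-2π offset and tests
the offset-adjusted sample against the previous corrected value — written
as a single sequential pass the rule would stop firing once the series
drifts a full period from $[0, 2\pi)$, so the offset form is used, which
reduces to the plain rule for the first wrap. Both passes are idempotent
and length-preserving, and are applied in that order (flips are a
per-sample hardware artifact; wraps are a property of the accumulated
series).

`estimate_fs()` is the interval count over the spanned time;
`resample_uniform()` then linearly interpolates onto a uniform grid at that
rate. Linear interpolation is second-order accurate in the inter-read gap,
two orders below the phase noise floor at these rates, so nothing fancier
is warranted.

## Rate extraction

The mean (the DC term introduced by the receiver circuit) is subtracted,
then a 2nd-order Butterworth bandpass over 0.1–1 Hz isolates the
respiratory band: low-frequency drift crowds the region below 0.1 Hz and
human breathing stays under 1 Hz. Butterworth is chosen for its maximally
flat passband; order 2 suppresses the drift while higher orders distort
the waveform. Filtering is **zero-phase** (forward–backward) by default:
the reconstruction stage depends on extremum *timing*, which a causal pass
would lag. A causal mode is available by flag. The rate is the FFT
magnitude peak within the band, computed with a rectangular window (no
taper) and zero-padding to the next power of two above
$\max(8N, F_s/0.01)$ so the readout grid is at least 0.01 Hz fine; ties
break toward the lower frequency.

## Waveform reconstruction

The decomposition depth $n$ is chosen from the sampling rate: the level-n
approximation has effective rate $F_s/2^n$, admissible when inside
0.6–2.0 Hz (twice the 0.3 Hz reference rate; twice the 1 Hz ceiling), and
among admissible levels the one minimising $F_s/2^n - 2 \cdot 0.3$ subject
to non-negativity is taken — the deepest level that still honours the
sampling theorem for an 18 bpm breather. When no admissible level has a
non-negative residual (possible only for unusual rates), the smallest
$|F_s/2^n - 0.6|$ is used as the nearest admissible resolution. At
23.1674 Hz this rule selects $n = 5$.

The db2 wavelet is used: Haar lacks symmetry and distorts the waveform
phase, and higher-order Daubechies wavelets buy little at more cost. The
decimated analysis step (4-tap filter, symmetric boundary extension — the
common default for biosignals; the choice only affects a filter-length of
samples at each edge) is implemented directly in R and validated against an
independent wavelet implementation's coefficients frozen into the test
suite. Extremum values are taken from the decimated level-n coefficients
with times mapped as $t_k = t_0 + k \cdot 2^n / F_s$; coefficients carry
the orthonormal $2^{n/2}$ scaling, which is irrelevant downstream because
the amplitude filter and both selection principles are scale-relative or
thresholded on differences.

Extrema are strict interior comparisons, with plateaus contributing their
first sample. The amplitude filter keeps an extremum only if it swings at
least $\alpha(\bar e_{max} - \bar e_{min})$, $\alpha = 0.5$, from the last
*kept* extremum; the means are computed once over the unfiltered extrema
(recomputing after each rejection would make the threshold depend on scan
order). The differences $d_i = e_{i+1} - e_i$ must alternate in sign —
adjacent peaks and troughs of a breath cannot repeat — and the literal
product condition is read as $\operatorname{sign}(d_i)\operatorname{sign}(d_{i-1}) = -1$,
since real-valued products essentially never equal −1 exactly. While a
violation remains, the shared middle extremum of the first offending
triple is removed (merging its two differences, i.e. keeping the larger
net swing) and the differences recomputed. Finally a natural cubic spline
through the surviving (time, value) extrema gives the reconstructed
waveform. The spline interpolates the extremum *knots*, not the difference
values: the differences alone carry no time axis or baseline, so a
waveform cannot be rebuilt from them.

## Tag selection and apnea

Per tag, over a monitoring interval of $\Delta t$ seconds with $L$
differences:

* **length principle**: $2 f_{min} \Delta t < L$ with $f_{min} = 0.05$ Hz —
  a breather at even the slowest plausible rate produces two extrema per
  breath;
* **amplitude principle**: $\frac{1}{L}\sum |d_i| > \Delta$ — the swing
  must exceed a floor, defaulting to ten quantization steps (≈0.015 rad),
  which separates respiration-scale motion from quantization noise. (No
  published value exists for this floor; it is configurable.)

Chest is selected when both tags pass (chest is the conventional
reference site); the passing tag when only one does; neither passing
means apnea. `detect_apnea()` screens sliding windows (default 20 s, step
5 s) with the bandpass **disabled** — band-limiting smears an artificial
oscillation into the start of a breath-hold — and computes the
extremum/difference chain once over the whole recording, so the amplitude
filter's threshold reflects the subject's real breaths and noise-driven
wiggles inside the hold are rejected. A subject is flagged when all their
tags fail some window.

## Numerical choices and degenerate inputs

Boundary cases are handled explicitly: empty phase sequences pass through
the cleaning algorithms; fewer than three approximation coefficients give
no extrema; a single extremum gives an empty (valid) difference sequence,
which fails the amplitude principle by definition; fewer than two spline
knots is an error. Level-set bounds use an $10^{-9}$ tolerance on the
$\log_2$ endpoints so exact powers of two land inside the admissible set.
Rate extraction requires at least 10 s of signal (~2 breaths at the
reference rate). The simulator rounds timestamps to integer milliseconds
and enforces strict monotonicity after rounding.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: direct
evaluation of the phase map, a cumulative-correction unwrapper, frozen
reference DWT coefficients, literal brute-force enumeration of the
depth rule over 200 random rates, analytic extremum counts of sines, and
generator ground truth end to end. The heavier checks run 20 seeded
120 s recordings per breathing rate for rate recovery (σ = 0.05 rad
noise, 10% ambiguity — the upper end of the simulated conditions) and 10
seeded 60 s recordings each for apnea recall and specificity; these sizes
give stable pass/fail statistics while keeping the whole suite under ten
seconds on a laptop.

## Known limitations

* The chain is offline; no streaming or real-time alarm path.
* No angular-position compensation: accuracy degrades when the subject is
  not facing the antenna, and the simulator does not model it.
* Harmonics are not disambiguated; a strongly non-sinusoidal breath could
  in principle put a harmonic above the fundamental inside the band.
* The amplitude floor is a heuristic tied to the quantizer; very shallow
  breathing near that floor will look like a failing tag.
* Multipath, body shadowing and tag detuning on skin are outside the
  simulator's physics; field performance must be assessed on real
  recordings.
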