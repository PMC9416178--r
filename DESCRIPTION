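Package: rfidbreath
Title: Respiratory Monitoring from RFID Backscatter Phase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contactless multi-person respiratory monitoring from UHF RFID
    backscatter phase. Provides a seeded physical simulator of reader phase
    streams (distance-to-phase map, 12-bit quantization, pi-radian ambiguity,
    2*pi wrapping, irregular sampling), threshold-based phase disambiguation
    and unwrapping, respiratory-rate extraction via Butterworth bandpass
    filtering and an FFT spectral peak, breathing-waveform reconstruction via
    Daubechies-2 wavelet approximation with extremum filtering and cubic-spline
    interpolation, and per-subject tag selection with apnea detection based on
    extremum-count and amplitude principles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
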