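#' Physical constants and reader phase model parameters
#'
#' Bundles the quantities that map tag-antenna distance to the phase the
#' reader reports: carrier frequency, propagation speed, and the constant
#' hardware phase offsets contributed by the reader's transmitter and
#' receiver circuits and by the tag's backscatter response. The offsets are
#' constant during one use of the reader, so by default they are lumped into
#' a single constant.
#'
#' @param carrier_freq Carrier frequency in Hz. UHF readers in the Chinese
#'   band transmit around 920.625-924.375 MHz; the default is 920.625 MHz.
#' @param c Propagation speed of the electromagnetic wave in m/s.
#' @param theta_offset Lumped constant hardware phase offset in radians
#'   (transmitter + receiver + tag).
#' @return An object of class `phase_model_params` with fields
#'   `carrier_freq`, `c`, `theta_offset` and the derived `wavelength` (m).
#' @examples
#' p <- phase_model_params()
#' p$wavelength  # ~0.326 m
#' @export
phase_model_params <- function(carrier_freq = 920.625e6, c = 3e8,
                               theta_offset = 0) {
  if (!is.numeric(carrier_freq) || length(carrier_freq) != 1L ||
      !is.finite(carrier_freq) || carrier_freq <= 0) {
    stop("`carrier_freq` must be a single positive finite number", call. = FALSE)
  }
  if (!is.finite(theta_offset)) stop("`theta_offset` must be finite", call. = FALSE)
  structure(
    list(carrier_freq = carrier_freq, c = c, theta_offset = theta_offset,
         wavelength = wavelength(carrier_freq, c)),
    class = "phase_model_params"
  )
}

#' Carrier wavelength
#'
#' @param carrier_freq Carrier frequency in Hz (> 0).
#' @param c Propagation speed in m/s.
#' @return Wavelength in metres, `c / carrier_freq`.
#' @examples
#' wavelength(920.625e6)  # ~0.326
#' @export
wavelength <- function(carrier_freq, c = 3e8) {
  if (!is.numeric(carrier_freq) || any(!is.finite(carrier_freq)) ||
      any(carrier_freq <= 0)) {
    stop("`carrier_freq` must be positive and finite", call. = FALSE)
  }
  c / carrier_freq
}

#' Ideal backscatter phase at a given distance
#'
#' The reader measures the phase accumulated over the round trip to the tag
#' (distance `2 * R`) plus constant hardware offsets, wrapped into
#' `[0, 2*pi)`:
#' \deqn{\theta = (4 \pi R / \lambda + \theta_{off}) \bmod 2\pi}
#'
#' @param R Tag-antenna distance in metres (> 0). Vectorised.
#' @param params A [phase_model_params()] object.
#' @return Phase in radians in `[0, 2*pi)`.
#' @examples
#' p <- phase_model_params(3e8, c = 3e8, theta_offset = 0)  # wavelength 1 m
#' ideal_phase(0.5, p)    # 0
#' ideal_phase(0.125, p)  # pi/2
#' @export
ideal_phase <- function(R, params = phase_model_params()) {
  if (any(R <= 0)) stop("distance `R` must be positive", call. = FALSE)
  (4 * pi * R / params$wavelength + params$theta_offset) %% (2 * pi)
}

#' Phase resolution of a 12-bit reader
#'
#' The reader's phase field is a 12-bit code, so the smallest representable
#' phase step is `2*pi / 4096` (about 0.0015 rad).
#'
#' @return The quantization step in radians.
#' @export
phase_resolution <- function() 2 * pi / 4096

#' Quantize a phase value to the reader's 12-bit code
#'
#' Maps a phase to the nearest 12-bit code `v` in `0..4095` and back to the
#' code's phase `v * 2*pi/4096`, reproducing what the reader reports. The
#' round-trip error is at most half a step, `pi/4096`, modulo `2*pi`.
#'
#' @param phase Phase in radians (any finite value; reduced mod `2*pi`).
#' @return A list with integer vector `raw_code` (0..4095) and numeric
#'   vector `phase` (the quantized phase in radians, `[0, 2*pi)`).
#' @examples
#' quantize_phase(pi)  # code 2048
#' @export
quantize_phase <- function(phase) {
  if (any(!is.finite(phase))) stop("`phase` must be finite", call. = FALSE)
  v <- as.integer(round((phase %% (2 * pi)) / (2 * pi) * 4096)) %% 4096L
  list(raw_code = v, phase = v * 2 * pi / 4096)
}

#' Doppler shift of a moving tag
#'
#' Kinematic Doppler shift of the backscattered carrier for a tag moving at
#' speed `v` at angle `alpha` to the propagation direction:
#' `f = 2 * v * cos(alpha) / lambda`. The factor 2 reflects the round trip.
#' Documentation utility only: the shift a breathing chest produces (~1e-3
#' Hz) is far below the reader's 2^-4 Hz = 0.0625 Hz resolution, which is
#' why phase rather than Doppler is used for monitoring.
#'
#' @param v Tag speed in m/s.
#' @param alpha Angle between motion and propagation direction, radians.
#' @param lam Carrier wavelength in metres (> 0).
#' @return Doppler shift in Hz.
#' @export
doppler_shift <- function(v, alpha, lam) {
  if (any(lam <= 0)) stop("wavelength `lam` must be positive", call. = FALSE)
  2 * v * cos(alpha) / lam
}

#' Doppler shift from a phase increment
#'
#' The reader derives Doppler from the phase change `dtheta` over the packet
#' time `dT`: `f = dtheta / (4 * pi * dT)`.
#'
#' @param dtheta Phase change over the packet, radians.
#' @param dT Packet duration in seconds (> 0).
#' @return Doppler shift in Hz.
#' @export
doppler_from_phase <- function(dtheta, dT) {
  if (any(dT <= 0)) stop("`dT` must be positive", call. = FALSE)
  dtheta / (4 * pi * dT)
}

#' Doppler resolution of the reader
#'
#' The Doppler field stores 4 fractional bits, so the resolution is
#' `2^-4 = 0.0625` Hz.
#'
#' @return The Doppler quantization step in Hz.
#' @export
doppler_resolution <- function() 2^-4
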