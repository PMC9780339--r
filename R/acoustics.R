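#' Occluded ear-canal acoustic cavity
#'
#' Describes the sealed ear canal as a lumped acoustic compliance: a cavity of
#' volume `volume` filled with a medium of density `medium_density` in which
#' sound travels at `speed_of_sound`, sitting at static pressure
#' `static_pressure`. For infrasound (<= 20 Hz) the smallest wavelength in air
#' is about 17 m, orders of magnitude larger than the ear canal, so the
#' lumped-element approximation is appropriate.
#'
#' @param volume Cavity volume in m^3 (an occluded ear canal is ~2e-6 m^3,
#'   i.e. 2 cc).
#' @param medium_density Density of the medium in kg/m^3 (air: 1.21).
#' @param speed_of_sound Speed of sound in the medium in m/s (air: 343).
#' @param static_pressure Static (atmospheric) pressure in Pa.
#' @return An object of class `"acoustic_cavity"`.
#' @examples
#' ear <- acoustic_cavity(volume = 2e-6)
#' acoustic_impedance(ear, hz_to_angular(10))
#' @export
acoustic_cavity <- function(volume,
                            medium_density = 1.21,
                            speed_of_sound = 343,
                            static_pressure = 101325) {
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    stop("'volume' must be a single positive number (m^3)", call. = FALSE)
  }
  if (medium_density <= 0) {
    stop("'medium_density' must be positive (kg/m^3)", call. = FALSE)
  }
  if (speed_of_sound <= 0) {
    stop("'speed_of_sound' must be positive (m/s)", call. = FALSE)
  }
  structure(
    list(
      volume = volume,
      medium_density = medium_density,
      speed_of_sound = speed_of_sound,
      static_pressure = static_pressure
    ),
    class = "acoustic_cavity"
  )
}

#' @export
print.acoustic_cavity <- function(x, ...) {
  cat(sprintf(
    "Acoustic cavity: V = %g m^3 (%.3g cc), rho = %g kg/m^3, c = %g m/s, P_atm = %g Pa\n",
    x$volume, x$volume * 1e6, x$medium_density, x$speed_of_sound,
    x$static_pressure
  ))
  invisible(x)
}

#' Convert ordinary frequency to angular frequency
#'
#' @param frequency_hz Frequency in Hz.
#' @return Angular frequency in rad/s (`2 * pi * frequency_hz`).
#' @export
hz_to_angular <- function(frequency_hz) 2 * pi * frequency_hz

#' Acoustic impedance of a sealed cavity
#'
#' For a cavity whose dimensions are much smaller than the wavelength, the
#' acoustic impedance is that of a pure compliance,
#' \deqn{Z_a = \rho c^2 / (j \omega V),}
#' with magnitude \eqn{\rho c^2 / (\omega V)} and phase \eqn{-\pi/2}. The
#' magnitude grows without bound as the cavity shrinks, which is the physical
#' basis of the occlusion effect: sealing the ear canal raises its impedance
#' and therefore the pressure produced by a given volume velocity.
#'
#' @param cavity An [acoustic_cavity()].
#' @param angular_frequency Angular frequency \eqn{\omega} in rad/s; must be
#'   positive. Use [hz_to_angular()] to convert from Hz.
#' @return An object of class `"impedance_value"` with fields `magnitude`
#'   (Pa s/m^3), `phase` (radians, always `-pi/2`) and `angular_frequency`.
#' @export
acoustic_impedance <- function(cavity, angular_frequency) {
  stopifnot(inherits(cavity, "acoustic_cavity"))
  if (!is.numeric(angular_frequency) || length(angular_frequency) != 1L ||
      !is.finite(angular_frequency) || angular_frequency <= 0) {
    stop("'angular_frequency' must be a single positive number (rad/s)",
         call. = FALSE)
  }
  magnitude <- cavity$medium_density * cavity$speed_of_sound^2 /
    (angular_frequency * cavity$volume)
  structure(
    list(
      magnitude = magnitude,
      phase = -pi / 2,
      angular_frequency = angular_frequency
    ),
    class = "impedance_value"
  )
}

#' @export
print.impedance_value <- function(x, ...) {
  cat(sprintf(
    "Acoustic impedance: |Z| = %.4g Pa s/m^3, phase = %.4f rad, omega = %.4g rad/s\n",
    x$magnitude, x$phase, x$angular_frequency
  ))
  invisible(x)
}

#' Acoustic pressure in a cavity driven by a volume-velocity source
#'
#' The total pressure is the static pressure plus the dynamic component
#' \eqn{P_\Delta = U_a \cdot |Z_a|}, the product of the acoustic volume
#' velocity and the cavity impedance magnitude.
#'
#' @param cavity An [acoustic_cavity()].
#' @param volume_velocity Acoustic volume velocity \eqn{U_a} in m^3/s.
#' @param impedance An `"impedance_value"` from [acoustic_impedance()].
#' @return A list with `pressure` (Pa, total) and `dynamic` (Pa, the
#'   \eqn{P_\Delta} component).
#' @export
cavity_pressure <- function(cavity, volume_velocity, impedance) {
  stopifnot(inherits(cavity, "acoustic_cavity"),
            inherits(impedance, "impedance_value"),
            is.numeric(volume_velocity), length(volume_velocity) == 1L)
  dynamic <- volume_velocity * impedance$magnitude
  list(pressure = cavity$static_pressure + dynamic, dynamic = dynamic)
}

#' Occlusion gain from shrinking the effective canal volume
#'
#' Cavity impedance, and hence the pressure generated by a fixed volume
#' velocity, scales as 1/V; reducing the effective acoustic volume of the ear
#' canal from `volume_open` to `volume_sealed` therefore amplifies acoustic
#' pressure by `20 * log10(volume_open / volume_sealed)` decibels (amplitude
#' convention). Shrinking 200 cc to 2 cc gives 40 dB; halving the volume
#' gives ~6 dB.
#'
#' @param volume_open Effective acoustic volume before occlusion (any unit).
#' @param volume_sealed Effective acoustic volume after occlusion (same unit).
#' @return Pressure amplification in dB.
#' @examples
#' occlusion_gain_db(200, 2)   # 40 dB
#' occlusion_gain_db(2, 1)     # ~6 dB
#' @export
occlusion_gain_db <- function(volume_open, volume_sealed) {
  if (!is.numeric(volume_open) || any(volume_open <= 0)) {
    stop("'volume_open' must be positive", call. = FALSE)
  }
  if (!is.numeric(volume_sealed) || any(volume_sealed <= 0)) {
    stop("'volume_sealed' must be positive", call. = FALSE)
  }
  20 * log10(volume_open / volume_sealed)
}

#' Smallest wavelength in the infrasonic band
#'
#' @param max_frequency Upper edge of the band in Hz (infrasound: 20 Hz).
#' @param speed_of_sound Speed of sound in m/s.
#' @return Wavelength `speed_of_sound / max_frequency` in metres.
#' @examples
#' min_infrasonic_wavelength(20)  # 17.15 m
#' @export
min_infrasonic_wavelength <- function(max_frequency, speed_of_sound = 343) {
  if (!is.numeric(max_frequency) || any(max_frequency <= 0)) {
    stop("'max_frequency' must be positive (Hz)", call. = FALSE)
  }
  if (!is.numeric(speed_of_sound) || any(speed_of_sound <= 0)) {
    stop("'speed_of_sound' must be positive (m/s)", call. = FALSE)
  }
  speed_of_sound / max_frequency
}
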