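#' Probe acquisition specification
#'
#' Describes the pulse-echo transducer and tactile pressure channel of the
#' vaginal probe: a single 5 MHz element sampled at 50 MHz (20 ns depth
#' quantisation), 100 data frames per second, with applied pressure limited
#' to 30 kPa and a pressure-sensor noise floor of 30 Pa.
#'
#' @param center_frequency Transducer centre frequency, Hz.
#' @param sampling_rate A-line sampling rate, Hz. Must satisfy Nyquist for
#'   `center_frequency`.
#' @param pulse_duration Transmit pulse length, seconds; must be below 1 us.
#' @param frame_rate Acquisition frame rate, frames/second.
#' @param max_pressure Safety limit on applied pressure, kPa.
#' @param pressure_noise_sd Pressure sensor noise standard deviation, Pa.
#' @param record_depth Recorded depth range, mm; sets the A-line length.
#' @return An object of class `probe_spec`.
#' @examples
#' p <- probe_spec()
#' n_samples(p)  # A-line length for the 60 mm default range
#' @export
probe_spec <- function(center_frequency = 5.0e6,
                       sampling_rate = 50.0e6,
                       pulse_duration = 0.5e-6,
                       frame_rate = 100,
                       max_pressure = 30,
                       pressure_noise_sd = 30,
                       record_depth = 60) {
  spec <- list(
    center_frequency = center_frequency,
    sampling_rate = sampling_rate,
    pulse_duration = pulse_duration,
    frame_rate = frame_rate,
    max_pressure = max_pressure,
    pressure_noise_sd = pressure_noise_sd,
    record_depth = record_depth
  )
  vals <- unlist(spec)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all probe_spec fields must be finite and strictly positive")
  }
  if (sampling_rate < 2 * center_frequency) {
    stop("sampling_rate must be at least 2 x center_frequency (Nyquist)")
  }
  if (pulse_duration >= 1e-6) stop("pulse_duration must be below 1e-6 s")
  if (max_pressure > 30) stop("max_pressure must not exceed 30 kPa")
  structure(spec, class = "probe_spec")
}

#' Number of samples per A-line for a probe
#'
#' One sample spans `c / (2 * sampling_rate)` of depth (15.4 um at 1540 m/s
#' and 50 MHz); the A-line covers the round trip to `record_depth`.
#'
#' @param probe A [probe_spec()].
#' @param speed_of_sound Speed of sound, m/s.
#' @return Integer sample count.
#' @export
n_samples <- function(probe, speed_of_sound = 1540) {
  as.integer(round(2 * probe$record_depth / 1000 / speed_of_sound *
                     probe$sampling_rate))
}

#' @export
print.probe_spec <- function(x, ...) {
  cat("Tactile-ultrasound probe spec\n")
  cat(sprintf("  %.1f MHz pulse-echo, sampled at %.0f MHz (%.1f um/sample at 1540 m/s)\n",
              x$center_frequency / 1e6, x$sampling_rate / 1e6,
              1540 / (2 * x$sampling_rate) * 1e6))
  cat(sprintf("  %g frames/s, record depth %g mm\n", x$frame_rate, x$record_depth))
  cat(sprintf("  pressure limit %g kPa, sensor noise sd %g Pa\n",
              x$max_pressure, x$pressure_noise_sd))
  invisible(x)
}

#' Tissue ground-truth model for simulation
#'
#' A linearly elastic cervix: under applied pressure `p` (kPa) the echo depth
#' shortens as `L(p) = max(min_compressed_length, rest_length - p / true_elasticity)`,
#' so the stress-to-strain ratio (kPa per mm of shortening) equals
#' `true_elasticity` throughout the linear range. Sub-resolution scatterers
#' produce speckle echoes; they are carried with the tissue as it compresses.
#'
#' @param true_elasticity Stress-to-strain ratio, kPa/mm (> 0).
#' @param rest_length Zero-pressure cervical length, mm.
#' @param speed_of_sound Speed of sound, m/s (soft-tissue standard 1540).
#' @param attenuation_coeff Attenuation, dB/(cm MHz), applied over the round
#'   trip.
#' @param surface_reflectivity Internal-surface echo amplitude, in (0, 1].
#' @param scatterer_density Mean scatterers per mm of tissue.
#' @param scatterer_amplitude Upper bound on scatterer echo amplitude as a
#'   fraction of `surface_reflectivity`, in \[0, 1).
#' @param min_compressed_length Hard floor on compressed length, mm.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(true_elasticity,
                         rest_length,
                         speed_of_sound = 1540,
                         attenuation_coeff = 0.5,
                         surface_reflectivity = 0.8,
                         scatterer_density = 1,
                         scatterer_amplitude = 0.15,
                         min_compressed_length = 10) {
  if (!is.finite(true_elasticity) || true_elasticity <= 0) {
    stop("true_elasticity must be > 0")
  }
  if (!is.finite(rest_length) || rest_length <= 0) stop("rest_length must be > 0")
  if (speed_of_sound <= 0) stop("speed_of_sound must be > 0")
  if (attenuation_coeff < 0) stop("attenuation_coeff must be >= 0")
  if (surface_reflectivity < 0 || surface_reflectivity > 1) {
    stop("surface_reflectivity must be in [0, 1]")
  }
  if (scatterer_density < 0) stop("scatterer_density must be >= 0")
  if (scatterer_amplitude < 0 || scatterer_amplitude >= 1) {
    stop("scatterer_amplitude must be in [0, 1)")
  }
  if (min_compressed_length <= 0 || min_compressed_length >= rest_length) {
    stop("min_compressed_length must be in (0, rest_length)")
  }
  structure(list(
    true_elasticity = true_elasticity,
    rest_length = rest_length,
    speed_of_sound = speed_of_sound,
    attenuation_coeff = attenuation_coeff,
    surface_reflectivity = surface_reflectivity,
    scatterer_density = scatterer_density,
    scatterer_amplitude = scatterer_amplitude,
    min_compressed_length = min_compressed_length
  ), class = "tissue_model")
}

#' Compressed length at a given applied pressure
#'
#' @param tissue A [tissue_model()].
#' @param pressure Applied pressure, kPa (vectorised).
#' @return Length in mm.
#' @export
compressed_length <- function(tissue, pressure) {
  pmax(tissue$min_compressed_length,
       tissue$rest_length - pressure / tissue$true_elasticity)
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("Tissue model: E = %.3f kPa/mm, L0 = %.1f mm (c = %g m/s)\n",
              x$true_elasticity, x$rest_length, x$speed_of_sound))
  invisible(x)
}

#' Compression protocol for one exam
#'
#' The operator ramps the commanded pressure linearly from first contact to a
#' peak, optionally holding at the peak. The peak must respect the probe's
#' 30 kPa safety limit.
#'
#' @param contact_pressure Pressure at first contact, kPa.
#' @param peak_pressure Commanded peak pressure, kPa (may equal
#'   `contact_pressure` for a constant-pressure exam).
#' @param ramp_duration Ramp length, seconds.
#' @param hold_frames Extra frames held at the peak.
#' @return An object of class `compression_protocol`.
#' @export
compression_protocol <- function(contact_pressure = 1,
                                 peak_pressure = 21,
                                 ramp_duration = 3,
                                 hold_frames = 0) {
  if (contact_pressure < 0) stop("contact_pressure must be >= 0")
  if (peak_pressure < contact_pressure) {
    stop("peak_pressure must be >= contact_pressure")
  }
  if (ramp_duration <= 0) stop("ramp_duration must be > 0")
  if (hold_frames < 0) stop("hold_frames must be >= 0")
  structure(list(
    contact_pressure = contact_pressure,
    peak_pressure = peak_pressure,
    ramp_duration = ramp_duration,
    hold_frames = as.integer(hold_frames)
  ), class = "compression_protocol")
}

#' @export
print.compression_protocol <- function(x, ...) {
  cat(sprintf("Compression protocol: %g -> %g kPa over %g s (+%d hold frames)\n",
              x$contact_pressure, x$peak_pressure, x$ramp_duration, x$hold_frames))
  invisible(x)
}
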