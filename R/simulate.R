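# RF A-line synthesis: Gabor echoes + speckle scatterers + white noise.

# Gaussian envelope sd (seconds) for a given fractional bandwidth (FWHM of
# the Gaussian power spectrum relative to f0).
.gabor_sigma_t <- function(center_frequency, fractional_bandwidth) {
  sigma_f <- fractional_bandwidth * center_frequency / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

# Add a Gaussian-windowed cosine burst centred at delay tau (s) in place.
# Only the +/- 4 sigma support is touched; returns the modified vector.
.add_burst <- function(samples, sampling_rate, tau, amplitude, sigma_t,
                       center_frequency) {
  n <- length(samples)
  center <- tau * sampling_rate            # 0-based fractional sample
  half <- 4 * sigma_t * sampling_rate
  i0 <- max(1L, as.integer(floor(center - half)) + 1L)
  i1 <- min(n, as.integer(ceiling(center + half)) + 1L)
  if (i0 > i1) return(samples)
  t_rel <- ((i0:i1) - 1) / sampling_rate - tau
  samples[i0:i1] <- samples[i0:i1] +
    amplitude * exp(-t_rel^2 / (2 * sigma_t^2)) *
    cos(2 * pi * center_frequency * t_rel)
  samples
}

# Round-trip exp-law attenuation factor for an echo at depth mm.
.attenuation <- function(depth_mm, attenuation_coeff, center_frequency) {
  db <- attenuation_coeff * (center_frequency / 1e6) * (2 * depth_mm / 10)
  10^(-db / 20)
}

# Synthesise one noise-free A-line for given scatterer set (rest-frame depths
# scaled by the current compression ratio) and surface depth.
.synth_aline <- function(tissue, probe, depth_mm, scat_depth_mm, scat_amp,
                         fractional_bandwidth = 0.5) {
  n <- n_samples(probe, tissue$speed_of_sound)
  s <- numeric(n)
  sigma_t <- .gabor_sigma_t(probe$center_frequency, fractional_bandwidth)
  f0 <- probe$center_frequency
  fs <- probe$sampling_rate
  c_ms <- tissue$speed_of_sound
  if (length(scat_depth_mm)) {
    att <- .attenuation(scat_depth_mm, tissue$attenuation_coeff, f0)
    for (k in seq_along(scat_depth_mm)) {
      tau <- 2 * scat_depth_mm[k] / 1000 / c_ms
      s <- .add_burst(s, fs, tau, scat_amp[k] * att[k], sigma_t, f0)
    }
  }
  amp_surface <- tissue$surface_reflectivity *
    .attenuation(depth_mm, tissue$attenuation_coeff, f0)
  if (amp_surface != 0) {
    tau <- 2 * depth_mm / 1000 / c_ms
    s <- .add_burst(s, fs, tau, amp_surface, sigma_t, f0)
  }
  s
}

#' Simulate one pulse-echo frame
#'
#' Produces a single RF A-line for a cervix under the given applied pressure.
#' The dominant echo is a Gaussian-windowed cosine (Gabor pulse) at the
#' transducer centre frequency, centred at the round-trip delay
#' `2 L(p) / c` of the internal cervical surface, with amplitude
#' `surface_reflectivity` reduced by exp-law attenuation. Speckle is modelled
#' as Poisson-placed sub-surface scatterers; white Gaussian noise is added at
#' the requested echo SNR. The recorded pressure carries the tactile sensor's
#' Gaussian noise when `pressure_noise = TRUE`.
#'
#' @param tissue A [tissue_model()].
#' @param probe A [probe_spec()].
#' @param pressure Applied pressure, kPa; must not exceed the probe limit.
#' @param snr_db Echo signal-to-noise ratio in dB relative to the (attenuated)
#'   surface echo amplitude; `Inf` disables additive noise.
#' @param pressure_noise Add Gaussian sensor noise (sd `pressure_noise_sd`)
#'   to the recorded pressure?
#' @param scatterers Optional data frame with columns `depth_mm` (current
#'   depths) and `amp` (amplitudes as fractions of `surface_reflectivity`);
#'   when `NULL`, scatterers are drawn Poisson along the compressed length.
#' @param timestamp Frame timestamp, seconds.
#' @return A list of class `cm_frame` with `timestamp`, `applied_pressure`
#'   (recorded, kPa) and `samples`.
#' @export
simulate_frame <- function(tissue, probe, pressure, snr_db = Inf,
                           pressure_noise = FALSE, scatterers = NULL,
                           timestamp = 0) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(probe, "probe_spec"))
  if (!is.finite(pressure) || pressure < 0) stop("pressure must be >= 0")
  if (pressure > probe$max_pressure) {
    stop(sprintf("pressure %.1f kPa exceeds the probe limit of %.1f kPa",
                 pressure, probe$max_pressure))
  }
  depth <- compressed_length(tissue, pressure)
  if (is.null(scatterers)) {
    n_sc <- if (tissue$scatterer_density > 0) {
      stats::rpois(1, tissue$scatterer_density * depth)
    } else 0L
    scatterers <- data.frame(
      depth_mm = stats::runif(n_sc, 0, depth),
      amp = stats::runif(n_sc, 0, tissue$scatterer_amplitude) *
        tissue$surface_reflectivity
    )
  }
  s <- .synth_aline(tissue, probe, depth, scatterers$depth_mm, scatterers$amp)
  if (is.finite(snr_db)) {
    amp_surface <- tissue$surface_reflectivity *
      .attenuation(depth, tissue$attenuation_coeff, probe$center_frequency)
    s <- s + stats::rnorm(length(s), 0, amp_surface / 10^(snr_db / 20))
  }
  recorded <- pressure +
    if (pressure_noise) stats::rnorm(1, 0, probe$pressure_noise_sd / 1000) else 0
  structure(list(timestamp = timestamp, applied_pressure = recorded,
                 samples = s), class = "cm_frame")
}

#' Simulate a full compression exam
#'
#' Ramps the commanded pressure linearly from `contact_pressure` to the peak
#' over `ramp_duration` at the probe frame rate, synthesising one A-line per
#' frame. The commanded peak is capped at the tissue's linear-range limit
#' `(rest_length - min_compressed_length) * true_elasticity`, emulating the
#' operator stopping compression once the cervix stops shortening. Scatterers
#' are drawn once per exam and carried with the compressing tissue
#' (depth scaled by `L(p)/L0`), so speckle moves coherently between frames.
#'
#' @inheritParams simulate_frame
#' @param protocol A [compression_protocol()].
#' @param seed Optional integer; fixes all randomness of the exam.
#' @param subject_id,sector Identification metadata; `sector` is `"anterior"`
#'   (12 o'clock) or `"posterior"` (6 o'clock).
#' @return An object of class `exam_recording`: probe/protocol/tissue
#'   metadata plus `timestamps`, `commanded_kpa`, `pressure_kpa` (recorded)
#'   and the frame-major `samples` matrix (one column per frame).
#' @examples
#' tis <- tissue_model(true_elasticity = 21 / 18, rest_length = 43)
#' rec <- simulate_exam(tis, probe_spec(),
#'                      compression_protocol(ramp_duration = 0.2),
#'                      seed = 1, snr_db = Inf, pressure_noise = FALSE)
#' dim(rec$samples)
#' @export
simulate_exam <- function(tissue, probe = probe_spec(),
                          protocol = compression_protocol(), seed = NULL,
                          snr_db = 20, pressure_noise = TRUE,
                          subject_id = "synthetic", sector = "anterior") {
  stopifnot(inherits(tissue, "tissue_model"), inherits(probe, "probe_spec"),
            inherits(protocol, "compression_protocol"))
  sector <- match.arg(sector, c("anterior", "posterior"))
  if (protocol$peak_pressure > probe$max_pressure) {
    stop("protocol peak_pressure exceeds the probe pressure limit")
  }
  if (!is.null(seed)) set.seed(seed)

  n_ramp <- as.integer(round(protocol$ramp_duration * probe$frame_rate))
  if (n_ramp < 1) stop("protocol yields no frames")
  n_frames <- n_ramp + protocol$hold_frames

  p_linear <- (tissue$rest_length - tissue$min_compressed_length) *
    tissue$true_elasticity
  peak_eff <- min(protocol$peak_pressure,
                  max(protocol$contact_pressure, p_linear))
  commanded <- c(seq(protocol$contact_pressure, peak_eff, length.out = n_ramp),
                 rep(peak_eff, protocol$hold_frames))

  n_sc <- if (tissue$scatterer_density > 0) {
    stats::rpois(1, tissue$scatterer_density * tissue$rest_length)
  } else 0L
  sc_rest <- stats::runif(n_sc, 0.5, tissue$rest_length)
  sc_amp <- stats::runif(n_sc, 0, tissue$scatterer_amplitude) *
    tissue$surface_reflectivity

  n_samp <- n_samples(probe, tissue$speed_of_sound)
  depths <- compressed_length(tissue, commanded)
  ratio <- depths / tissue$rest_length
  samples <- matrix(0, n_samp, n_frames)
  for (j in seq_len(n_frames)) {
    samples[, j] <- .synth_aline(tissue, probe, depths[j],
                                 sc_rest * ratio[j], sc_amp)
  }
  if (is.finite(snr_db)) {
    amp_surface <- tissue$surface_reflectivity *
      .attenuation(depths, tissue$attenuation_coeff, probe$center_frequency)
    noise_sd <- amp_surface / 10^(snr_db / 20)
    samples <- samples + matrix(stats::rnorm(n_samp * n_frames), n_samp) *
      rep(noise_sd, each = n_samp)
  }
  recorded <- commanded +
    if (pressure_noise) {
      stats::rnorm(n_frames, 0, probe$pressure_noise_sd / 1000)
    } else 0

  structure(list(
    subject_id = subject_id,
    sector = sector,
    probe = probe,
    protocol = protocol,
    tissue = tissue,
    timestamps = (seq_len(n_frames) - 1) / probe$frame_rate,
    commanded_kpa = commanded,
    pressure_kpa = recorded,
    samples = samples,
    version = "1.0"
  ), class = "exam_recording")
}

#' Extract one frame from a recording
#'
#' @param recording An [simulate_exam()] result (or one read from disk).
#' @param i Frame index.
#' @return A `cm_frame` list (`timestamp`, `applied_pressure`, `samples`).
#' @export
get_frame <- function(recording, i) {
  stopifnot(inherits(recording, "exam_recording"))
  i <- as.integer(i)
  if (i < 1 || i > ncol(recording$samples)) stop("frame index out of range")
  structure(list(timestamp = recording$timestamps[i],
                 applied_pressure = recording$pressure_kpa[i],
                 samples = recording$samples[, i]), class = "cm_frame")
}

#' @export
print.exam_recording <- function(x, ...) {
  cat(sprintf("Exam recording: subject %s, %s sector\n", x$subject_id, x$sector))
  cat(sprintf("  %d frames x %d samples, pressure %.2f -> %.2f kPa\n",
              ncol(x$samples), nrow(x$samples),
              x$commanded_kpa[1], max(x$commanded_kpa)))
  if (!is.null(x$tissue)) {
    cat(sprintf("  ground truth: E = %.3f kPa/mm, L0 = %.1f mm\n",
                x$tissue$true_elasticity, x$tissue$rest_length))
  }
  invisible(x)
}
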