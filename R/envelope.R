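#' Envelope-detection and echo-tracking parameters
#'
#' Controls the complex Gaussian wavelet demodulator and the surface-echo
#' peak search.
#'
#' @param center_frequency Wavelet centre frequency, Hz (matched to the
#'   transducer).
#' @param fractional_bandwidth Wavelet fractional bandwidth (FWHM of the
#'   Gaussian spectrum over `center_frequency`), in (0, 2).
#' @param blanking_depth Near-field zone excluded from the search, mm
#'   (probe-face ringdown).
#' @param min_peak_amplitude Validity threshold: the selected peak must reach
#'   this fraction of the frame's envelope maximum.
#' @param tracking_window Half-width of the frame-to-frame continuity search
#'   window around the previous valid depth, mm.
#' @param tgc_coeff Time-gain compensation, dB/(cm MHz), applied as an
#'   exp-law gain on the envelope before peak search so that the dominant-peak
#'   rule is depth-fair; set 0 to disable.
#' @param tgc_max_db Cap on the total compensation gain, dB; keeps the deep,
#'   signal-free end of the record from amplifying noise above a shallow
#'   surface echo (real devices cap their TGC the same way).
#' @return An object of class `envelope_params`.
#' @export
envelope_params <- function(center_frequency = 5.0e6,
                            fractional_bandwidth = 0.5,
                            blanking_depth = 5,
                            min_peak_amplitude = 0.3,
                            tracking_window = 3,
                            tgc_coeff = 0.5,
                            tgc_max_db = 20) {
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2) {
    stop("fractional_bandwidth must be in (0, 2)")
  }
  if (blanking_depth < 0) stop("blanking_depth must be >= 0")
  if (min_peak_amplitude <= 0 || min_peak_amplitude > 1) {
    stop("min_peak_amplitude must be in (0, 1]")
  }
  if (tracking_window <= 0) stop("tracking_window must be > 0")
  if (tgc_coeff < 0) stop("tgc_coeff must be >= 0")
  if (tgc_max_db < 0) stop("tgc_max_db must be >= 0")
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 blanking_depth = blanking_depth,
                 min_peak_amplitude = min_peak_amplitude,
                 tracking_window = tracking_window,
                 tgc_coeff = tgc_coeff,
                 tgc_max_db = tgc_max_db), class = "envelope_params")
}

# Complex Gaussian wavelet kernel, unit envelope gain for a narrowband
# cosine at the centre frequency: |x * w| ~ a(t) for x = a(t) cos(2 pi f0 t).
.gauss_wavelet <- function(center_frequency, fractional_bandwidth,
                           sampling_rate, support_sigmas = 4) {
  sigma_t <- .gabor_sigma_t(center_frequency, fractional_bandwidth)
  half <- max(1L, as.integer(ceiling(support_sigmas * sigma_t * sampling_rate)))
  t <- (-half:half) / sampling_rate
  g <- exp(-t^2 / (2 * sigma_t^2))
  w <- g * exp(2i * pi * center_frequency * t)
  w / (0.5 * sum(g))
}

#' Complex Gaussian wavelet envelope
#'
#' Demodulates an RF A-line by convolution with a complex Gaussian wavelet
#' `w(t) = exp(-t^2 / (2 sigma^2)) exp(i 2 pi f0 t)` at the transducer centre
#' frequency and returns the magnitude `|s * w|`. Output has the same length
#' as the input ("same" alignment, zero-padded edges). The kernel is scaled
#' so a narrowband burst of amplitude `a` yields an envelope of height ~`a`.
#'
#' @param samples RF amplitude sequence; a matrix is treated one A-line per
#'   column.
#' @param params An [envelope_params()].
#' @param sampling_rate Sampling rate, Hz; must satisfy Nyquist for the
#'   wavelet centre frequency.
#' @return Non-negative envelope, same shape as `samples`.
#' @examples
#' fs <- 50e6
#' t <- (0:999) / fs
#' burst <- exp(-(t - 10e-6)^2 / (2 * (0.3e-6)^2)) * cos(2 * pi * 5e6 * (t - 10e-6))
#' env <- wavelet_envelope(burst, envelope_params(), fs)
#' which.max(env)  # ~ sample 501
#' @export
wavelet_envelope <- function(samples, params = envelope_params(),
                             sampling_rate) {
  if (length(samples) == 0) stop("samples must be non-empty")
  if (sampling_rate < 2 * params$center_frequency) {
    stop("sampling_rate must be at least 2 x the wavelet centre frequency")
  }
  w <- .gauss_wavelet(params$center_frequency, params$fractional_bandwidth,
                      sampling_rate)
  x <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  n <- nrow(x); k <- length(w)
  half <- (k - 1L) %/% 2L
  N <- stats::nextn(n + k - 1L, c(2, 3, 5))
  W <- stats::fft(c(w, rep(0, N - k)))
  X <- stats::mvfft(rbind(x, matrix(0, N - n, ncol(x))))
  Y <- stats::mvfft(X * W, inverse = TRUE) / N
  env <- Mod(Y[(half + 1):(half + n), , drop = FALSE])
  if (is.matrix(samples)) env else as.numeric(env)
}

#' Convert a round-trip delay to depth
#'
#' Pulse-echo time-of-flight ranging: `depth = c * delay / 2`. At 1540 m/s
#' and 20 ns sampling, one sample corresponds to 15.4 um of depth.
#'
#' @param delay Round-trip delay, seconds (vectorised).
#' @param speed_of_sound Speed of sound, m/s.
#' @return Depth in mm.
#' @export
tof_to_depth <- function(delay, speed_of_sound = 1540) {
  if (any(delay < 0)) stop("delay must be >= 0")
  if (speed_of_sound <= 0) stop("speed_of_sound must be > 0")
  speed_of_sound * delay / 2 * 1000
}

# Three-point parabolic interpolation of a peak at index i; returns the
# fractional index offset in [-0.5, 0.5].
.parabolic_offset <- function(env, i) {
  if (i <= 1 || i >= length(env)) return(0)
  y0 <- env[i - 1]; y1 <- env[i]; y2 <- env[i + 1]
  denom <- y0 - 2 * y1 + y2
  if (denom >= 0) return(0)   # not a strict local max
  off <- 0.5 * (y0 - y2) / denom
  max(-0.5, min(0.5, off))
}

#' Detect the internal-surface echo in one envelope
#'
#' Selects the largest envelope peak beyond the blanking depth (restricted to
#' `prior_depth` +/- the tracking window when a prior is given), applies
#' time-gain compensation before the search, refines the peak position by
#' three-point parabolic interpolation, and converts the sample index to
#' depth by time-of-flight. The detection is flagged invalid when the
#' selected peak does not reach `min_peak_amplitude` times the frame's
#' envelope maximum (after gain), e.g. when all echo content lies inside the
#' blanking zone or the frame is dead.
#'
#' @param envelope Envelope sequence from [wavelet_envelope()].
#' @param params An [envelope_params()].
#' @param sampling_rate Sampling rate, Hz.
#' @param speed_of_sound Speed of sound, m/s.
#' @param prior_depth Optional previous depth, mm, for continuity gating.
#' @param gain_applied Set `TRUE` when the envelope has already been
#'   gain-compensated (skips the internal TGC step).
#' @param frame_max Optional precomputed envelope maximum for the validity
#'   test (after gain).
#' @return List with `depth` (mm), `amplitude` and `valid`.
#' @export
detect_surface_echo <- function(envelope, params = envelope_params(),
                                sampling_rate, speed_of_sound = 1540,
                                prior_depth = NULL, gain_applied = FALSE,
                                frame_max = NULL) {
  n <- length(envelope)
  if (n == 0) stop("envelope must be non-empty")
  step_mm <- speed_of_sound / (2 * sampling_rate) * 1000
  if (params$tgc_coeff > 0 && !gain_applied) {
    envelope <- envelope * .tgc_gain(n, step_mm, params)
  }
  if (is.null(frame_max)) frame_max <- max(envelope)
  lo <- max(1L, as.integer(ceiling(params$blanking_depth / step_mm)) + 2L)
  hi <- n
  if (!is.null(prior_depth)) {
    lo <- max(lo, as.integer(floor((prior_depth - params$tracking_window) /
                                     step_mm)) + 1L)
    hi <- min(hi, as.integer(ceiling((prior_depth + params$tracking_window) /
                                       step_mm)) + 1L)
  }
  if (lo > hi || frame_max <= 0) {
    return(list(depth = NA_real_, amplitude = 0, valid = FALSE))
  }
  i <- lo - 1L + which.max(envelope[lo:hi])
  amp <- envelope[i]
  valid <- amp > 0 && amp >= params$min_peak_amplitude * frame_max
  off <- .parabolic_offset(envelope, i)
  depth <- (i - 1 + off) * step_mm
  list(depth = depth, amplitude = amp, valid = valid)
}

# Exp-law time-gain compensation profile over a sample axis.
.tgc_gain <- function(n, step_mm, params) {
  depth_axis <- (seq_len(n) - 1) * step_mm
  gain_db <- params$tgc_coeff * (params$center_frequency / 1e6) *
    (2 * depth_axis / 10)
  cap <- params$tgc_max_db %||% Inf
  10^(pmin(gain_db, cap) / 20)
}

#' Track the internal-surface echo across an exam
#'
#' Applies [wavelet_envelope()] and [detect_surface_echo()] frame by frame.
#' The first frame is searched globally beyond the blanking depth; each later
#' frame is searched within the tracking window around the last valid depth.
#' Degraded frames are flagged invalid and skipped (the prior carries over),
#' never interpolated; the fit stage decides what to use.
#'
#' @param recording An [simulate_exam()] recording (or one read from disk).
#' @param params An [envelope_params()].
#' @param speed_of_sound Speed of sound used for ranging, m/s.
#' @return A `depth_track` data frame with columns `frame`, `timestamp_s`,
#'   `pressure_kpa`, `depth_mm`, `amplitude`, `valid`, carrying
#'   `speed_of_sound` and the parameters as attributes.
#' @export
track_exam <- function(recording, params = envelope_params(),
                       speed_of_sound = NULL) {
  stopifnot(inherits(recording, "exam_recording"))
  if (is.null(speed_of_sound)) {
    speed_of_sound <- if (!is.null(recording$tissue)) {
      recording$tissue$speed_of_sound
    } else 1540
  }
  env <- wavelet_envelope(recording$samples, params,
                          recording$probe$sampling_rate)
  step_mm <- speed_of_sound / (2 * recording$probe$sampling_rate) * 1000
  if (params$tgc_coeff > 0) {
    env <- env * .tgc_gain(nrow(env), step_mm, params)
  }
  frame_max <- apply(env, 2, max)
  n_frames <- ncol(env)
  depth <- amp <- numeric(n_frames)
  valid <- logical(n_frames)
  prior <- NULL
  for (j in seq_len(n_frames)) {
    det <- detect_surface_echo(env[, j], params,
                               recording$probe$sampling_rate,
                               speed_of_sound, prior_depth = prior,
                               gain_applied = TRUE, frame_max = frame_max[j])
    depth[j] <- det$depth
    amp[j] <- det$amplitude
    valid[j] <- det$valid
    if (det$valid) prior <- det$depth
  }
  if (!any(valid)) stop("no valid frames: exam is unusable")
  track <- data.frame(frame = seq_len(n_frames),
                      timestamp_s = recording$timestamps,
                      pressure_kpa = recording$pressure_kpa,
                      depth_mm = depth,
                      amplitude = amp,
                      valid = valid)
  attr(track, "speed_of_sound") <- speed_of_sound
  attr(track, "params") <- params
  class(track) <- c("depth_track", "data.frame")
  track
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("Depth track: %d frames (%d valid), pressure %.2f -> %.2f kPa\n",
              nrow(x), sum(x$valid), min(x$pressure_kpa), max(x$pressure_kpa)))
  ok <- x$valid
  if (any(ok)) {
    cat(sprintf("  depth %.2f -> %.2f mm\n",
                x$depth_mm[which(ok)[1]], x$depth_mm[rev(which(ok))[1]]))
  }
  invisible(x)
}
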