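#' Build a stress-strain map from a recording
#'
#' Bins each frame's wavelet envelope by depth (horizontal axis) at the
#' frame's measured pressure (vertical axis), on a linear amplitude scale
#' (no log compression). The internal-surface echo traces a line across the
#' map whose slope is minus the elasticity; extending that line to the
#' horizontal axis reads off the zero-pressure cervical length.
#'
#' @param recording An `exam_recording`.
#' @param track Optional `depth_track` from [track_exam()]; when supplied it
#'   must align with the recording (one row per frame) and its recorded
#'   pressures are used for binning.
#' @param params An [envelope_params()] (the map uses the same demodulator
#'   and time-gain compensation as the tracker).
#' @param depth_bin_mm,pressure_bin_kpa Bin widths.
#' @return An object of class `stress_strain_map`: `depth_bins` and
#'   `pressure_bins` (bin centres) and the `amplitude` matrix
#'   (pressure rows x depth columns; cell = max envelope amplitude).
#' @export
build_map <- function(recording, track = NULL, params = envelope_params(),
                      depth_bin_mm = 0.5, pressure_bin_kpa = 0.5) {
  stopifnot(inherits(recording, "exam_recording"))
  n_frames <- ncol(recording$samples)
  if (!is.null(track) && nrow(track) != n_frames) {
    stop("track and recording lengths differ")
  }
  pressures <- if (is.null(track)) recording$pressure_kpa else track$pressure_kpa
  c_ms <- if (!is.null(recording$tissue)) {
    recording$tissue$speed_of_sound
  } else 1540
  fs <- recording$probe$sampling_rate
  env <- wavelet_envelope(recording$samples, params, fs)
  step_mm <- c_ms / (2 * fs) * 1000
  depth_axis <- (seq_len(nrow(env)) - 1) * step_mm
  if (params$tgc_coeff > 0) {
    env <- env * .tgc_gain(nrow(env), step_mm, params)
  }

  d_bin <- floor(depth_axis / depth_bin_mm)
  d_levels <- seq(0, max(d_bin))
  p_bin <- floor(pressures / pressure_bin_kpa)
  p_levels <- seq(min(p_bin), max(p_bin))

  amp <- matrix(0, length(p_levels), length(d_levels))
  row_of <- match(p_bin, p_levels)
  for (j in seq_len(n_frames)) {
    prof <- vapply(split(env[, j], d_bin), max, numeric(1))
    r <- row_of[j]
    amp[r, ] <- pmax(amp[r, ], prof[as.character(d_levels)])
  }
  structure(list(
    depth_bins = (d_levels + 0.5) * depth_bin_mm,
    pressure_bins = (p_levels + 0.5) * pressure_bin_kpa,
    amplitude = amp
  ), class = "stress_strain_map")
}

#' Write / read a stress-strain map
#'
#' Plain-text container: a JSON header line holding the bin grids, then the
#' amplitude matrix in long CSV form (`pressure_bin`, `depth_bin`,
#' `amplitude`).
#'
#' @param map A [build_map()] result.
#' @param path Output file.
#' @return `write_map` returns `path` invisibly; `read_map` a
#'   `stress_strain_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "stress_strain_map"))
  hdr <- jsonlite::toJSON(list(magic = "cervelast-map", version = "1.0",
                               depth_bins = map$depth_bins,
                               pressure_bins = map$pressure_bins),
                          digits = NA)
  long <- data.frame(
    pressure_bin = rep(seq_along(map$pressure_bins),
                       times = length(map$depth_bins)),
    depth_bin = rep(seq_along(map$depth_bins),
                    each = length(map$pressure_bins)),
    amplitude = as.numeric(map$amplitude))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#CERVELASTMAP01 ", as.character(hdr)), con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#CERVELASTMAP01 ")) {
    stop("not a cervelast map (unrecognised magic)")
  }
  meta <- jsonlite::fromJSON(sub("^#CERVELASTMAP01 ", "", lines[1]))
  if (!identical(meta$magic, "cervelast-map")) stop("corrupt map header")
  long <- utils::read.csv(text = lines[-1])
  amp <- matrix(0, length(meta$pressure_bins), length(meta$depth_bins))
  amp[cbind(long$pressure_bin, long$depth_bin)] <- long$amplitude
  structure(list(depth_bins = meta$depth_bins,
                 pressure_bins = meta$pressure_bins,
                 amplitude = amp), class = "stress_strain_map")
}

#' @export
print.stress_strain_map <- function(x, ...) {
  cat(sprintf("Stress-strain map: %d pressure bins x %d depth bins\n",
              length(x$pressure_bins), length(x$depth_bins)))
  invisible(x)
}

#' Plot a stress-strain map
#'
#' Linear grayscale image of echo amplitude over (depth, applied pressure);
#' white is high amplitude, as on the device display. Optionally overlays a
#' fitted stress-strain line.
#'
#' @param x A [build_map()] result.
#' @param fit Optional [fit_stress_strain()] model to overlay (dashed line).
#' @param ... Passed to [graphics::image()].
#' @export
plot.stress_strain_map <- function(x, fit = NULL, ...) {
  graphics::image(x$depth_bins, x$pressure_bins, t(x$amplitude),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  xlab = "Depth (mm)", ylab = "Applied pressure (kPa)", ...)
  if (!is.null(fit) && all(is.finite(fit$coefficients))) {
    graphics::abline(fit$coefficients[1], fit$coefficients[2],
                     lty = 2, col = 4)
  }
  invisible(x)
}
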