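# Recording container and cohort CSV readers/writers.
#
# Binary container: a fixed 24-byte ASCII prefix ("CERVELAST01 " + zero-padded
# JSON byte length), a JSON metadata header, then little-endian payload:
# timestamps (float64), commanded and recorded pressures (float64), and the
# frame-major sample matrix (float32). CSV fallback: a "#CERVELASTCSV01 "
# comment line holding the same JSON header, then a long-format table.

.RECORDING_VERSION <- "1.0"

.recording_header <- function(rec, format) {
  list(magic = "cervelast-recording",
       version = rec$version %||% .RECORDING_VERSION,
       format = format,
       subject_id = rec$subject_id,
       sector = rec$sector,
       n_frames = ncol(rec$samples),
       n_samples = nrow(rec$samples),
       probe = unclass(rec$probe),
       protocol = unclass(rec$protocol),
       tissue = if (!is.null(rec$tissue)) unclass(rec$tissue))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an exam recording to disk
#'
#' @param recording An `exam_recording`.
#' @param path Output file.
#' @param format `"binary"` (JSON header + little-endian float payload,
#'   samples as 32-bit floats) or `"csv"` (plain-text fallback for small
#'   fixtures).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("binary", "csv")) {
  stopifnot(inherits(recording, "exam_recording"))
  format <- match.arg(format)
  hdr <- jsonlite::toJSON(.recording_header(recording, format),
                          auto_unbox = TRUE, digits = NA, null = "null")
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr_raw <- charToRaw(as.character(hdr))
    writeChar(sprintf("CERVELAST01 %011d\n", length(hdr_raw)), con, eos = NULL)
    writeBin(hdr_raw, con)
    writeBin(as.numeric(recording$timestamps), con, size = 8, endian = "little")
    writeBin(as.numeric(recording$commanded_kpa), con, size = 8, endian = "little")
    writeBin(as.numeric(recording$pressure_kpa), con, size = 8, endian = "little")
    writeBin(as.numeric(recording$samples), con, size = 4, endian = "little")
  } else {
    long <- data.frame(
      frame = rep(seq_len(ncol(recording$samples)),
                  each = nrow(recording$samples)),
      sample_index = rep(seq_len(nrow(recording$samples)),
                         times = ncol(recording$samples)),
      amplitude = as.numeric(recording$samples)
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#CERVELASTCSV01 ", as.character(hdr)), con)
    writeLines(paste0("#timestamps_s ",
                      paste(format(recording$timestamps, digits = 17),
                            collapse = ",")), con)
    writeLines(paste0("#commanded_kpa ",
                      paste(format(recording$commanded_kpa, digits = 17),
                            collapse = ",")), con)
    writeLines(paste0("#pressure_kpa ",
                      paste(format(recording$pressure_kpa, digits = 17),
                            collapse = ",")), con)
    utils::write.csv(long, con, row.names = FALSE)
  }
  invisible(path)
}

.validate_header <- function(meta) {
  required <- c("magic", "version", "format", "subject_id", "sector",
                "n_frames", "n_samples", "probe")
  for (f in required) {
    if (is.null(meta[[f]])) {
      stop(sprintf("recording header field '%s' missing or invalid", f))
    }
  }
  if (!identical(meta$magic, "cervelast-recording")) {
    stop("recording header field 'magic' missing or invalid")
  }
  if (!identical(meta$version, .RECORDING_VERSION)) {
    stop(sprintf("unsupported recording version '%s' (expected '%s')",
                 meta$version, .RECORDING_VERSION))
  }
  invisible(meta)
}

.rebuild_recording <- function(meta, timestamps, commanded, recorded, samples) {
  structure(list(
    subject_id = meta$subject_id,
    sector = meta$sector,
    probe = do.call(probe_spec, meta$probe),
    protocol = if (!is.null(meta$protocol)) {
      do.call(compression_protocol, meta$protocol)
    },
    tissue = if (!is.null(meta$tissue)) do.call(tissue_model, meta$tissue),
    timestamps = timestamps,
    commanded_kpa = commanded,
    pressure_kpa = recorded,
    samples = matrix(samples, meta$n_samples, meta$n_frames),
    version = meta$version
  ), class = "exam_recording")
}

#' Read an exam recording
#'
#' Detects the container flavour (binary or CSV fallback) from the file
#' magic and validates the header before reconstructing the recording.
#'
#' @param path File written by [write_recording()].
#' @return An `exam_recording`.
#' @export
read_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  prefix <- readChar(con, 24, useBytes = TRUE)
  if (startsWith(prefix, "CERVELAST01 ")) {
    n_hdr <- suppressWarnings(as.integer(substr(prefix, 13, 23)))
    if (is.na(n_hdr)) stop("recording header field 'length' missing or invalid")
    meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n_hdr)))
    .validate_header(meta)
    nf <- meta$n_frames; ns <- meta$n_samples
    timestamps <- readBin(con, "double", nf, size = 8, endian = "little")
    commanded <- readBin(con, "double", nf, size = 8, endian = "little")
    recorded <- readBin(con, "double", nf, size = 8, endian = "little")
    samples <- readBin(con, "double", nf * ns, size = 4, endian = "little")
    if (length(samples) != nf * ns) stop("truncated sample payload")
    return(.rebuild_recording(meta, timestamps, commanded, recorded, samples))
  }
  if (startsWith(prefix, "#CERVELASTCSV01 ")) {
    close(con)
    on.exit()
    lines <- readLines(path)
    meta <- jsonlite::fromJSON(sub("^#CERVELASTCSV01 ", "", lines[1]))
    .validate_header(meta)
    grab <- function(tag) {
      ln <- grep(paste0("^#", tag, " "), lines, value = TRUE)[1]
      as.numeric(strsplit(sub(paste0("^#", tag, " "), "", ln), ",")[[1]])
    }
    long <- utils::read.csv(text = lines[!startsWith(lines, "#")])
    return(.rebuild_recording(meta, grab("timestamps_s"), grab("commanded_kpa"),
                              grab("pressure_kpa"), long$amplitude))
  }
  stop("not a cervelast recording (unrecognised magic)")
}

.COHORT_REQUIRED <- c("subject_id", "group")
.COHORT_KNOWN <- c(
  "subject_id", "group", "maternal_age_years", "height_cm", "weight_kg",
  "parity", "prior_ptb", "ga_exam_days", "ga_birth_days",
  "true_elasticity_anterior_kpa_mm", "true_elasticity_posterior_kpa_mm",
  "true_elasticity_avg_kpa_mm", "true_length_anterior_mm",
  "true_length_posterior_mm", "true_length_avg_mm", "comfort",
  "elasticity_anterior_kpa_mm", "elasticity_posterior_kpa_mm",
  "avg_elasticity_kpa_mm", "length_anterior_mm", "length_posterior_mm",
  "avg_length_mm", "single_sector", "anterior_file", "posterior_file")

#' Write / read a cohort table as CSV
#'
#' Comma-separated, UTF-8, header row, "." decimal, units suffixed in column
#' names. Reading accepts unknown columns with a warning (forward
#' compatibility) but requires `subject_id` and `group`.
#'
#' @param cohort A cohort data frame.
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cm_cohort` data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8",
                       stringsAsFactors = FALSE)
  missing <- setdiff(.COHORT_REQUIRED, names(x))
  if (length(missing)) {
    stop(sprintf("cohort CSV lacks required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(x), .COHORT_KNOWN)
  if (length(unknown)) {
    warning(sprintf("cohort CSV has unknown column(s), retained: %s",
                    paste(unknown, collapse = ", ")))
  }
  class(x) <- c("cm_cohort", "data.frame")
  x
}

#' Write analysis results as JSON
#'
#' @param x A list of results (numbers, vectors, tables).
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
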