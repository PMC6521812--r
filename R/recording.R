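#' Construct a pupil recording
#'
#' A pupil recording holds the diameter trace of one eye of one subject:
#' strictly increasing sample times (seconds from recording start), diameters
#' in millimetres, and a per-sample validity flag. Invalid samples (blinks,
#' eye movements, tracking dropouts) may carry an `NA` diameter; valid
#' samples must have a diameter in (0, 10] mm.
#'
#' @param time_s Numeric vector of sample times in seconds, non-negative and
#'   strictly increasing.
#' @param diameter_mm Numeric vector of pupil diameters in millimetres; `NA`
#'   marks a dropout.
#' @param valid Logical validity flags. Defaults to `!is.na(diameter_mm)`.
#'   A sample with `NA` diameter is always invalid.
#' @param subject_id Opaque subject label.
#' @param eye `"left"` or `"right"`.
#' @param sampling_rate_hz Nominal sampling rate in Hz.
#' @return An object of class `pupil_recording`.
#' @export
pupil_recording <- function(time_s, diameter_mm, valid = NULL,
                            subject_id = "subject", eye = c("right", "left"),
                            sampling_rate_hz = 30) {
  eye <- match.arg(eye)
  time_s <- as.numeric(time_s)
  diameter_mm <- as.numeric(diameter_mm)
  if (length(time_s) != length(diameter_mm))
    stop("`time_s` and `diameter_mm` must have equal length", call. = FALSE)
  if (is.null(valid)) valid <- !is.na(diameter_mm)
  valid <- as.logical(valid) & !is.na(diameter_mm)
  if (length(valid) != length(time_s))
    stop("`valid` must match the number of samples", call. = FALSE)
  if (anyNA(time_s) || any(time_s < 0))
    stop("sample times must be non-negative and non-missing", call. = FALSE)
  if (length(time_s) > 1L && any(diff(time_s) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  bad <- valid & (diameter_mm <= 0 | diameter_mm > 10)
  if (any(bad))
    stop(sprintf("valid samples must have diameter in (0, 10] mm (first offender: sample %d)",
                 which(bad)[1L]), call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id)[1L], eye = eye,
         sampling_rate_hz = sampling_rate_hz,
         samples = data.frame(time_s = time_s, diameter_mm = diameter_mm,
                              valid = valid)),
    class = "pupil_recording"
  )
}

#' @export
print.pupil_recording <- function(x, ...) {
  n <- nrow(x$samples)
  dur <- if (n) max(x$samples$time_s) else 0
  cat(sprintf(
    "Pupil recording: subject %s, %s eye, %g Hz\n  %d samples (%d valid) over %.1f s\n",
    x$subject_id, x$eye, x$sampling_rate_hz, n, sum(x$samples$valid), dur))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording A `pupil_recording`.
#' @return Time of the last sample, or 0 for an empty recording.
#' @export
recording_duration <- function(recording) {
  if (nrow(recording$samples) == 0L) return(0)
  max(recording$samples$time_s)
}

csv_header <- "time_s,diameter_mm,valid"

# %.17g round-trips IEEE doubles exactly, so write/read is bit-stable
fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write a pupil recording to CSV
#'
#' The dialect is one header line `time_s,diameter_mm,valid`, UTF-8, decimal
#' point, one row per sample, `NA` as the dropout sentinel for missing
#' diameters. Numbers are written with full precision so that a written file
#' reparses to a bit-identical recording.
#'
#' @param recording A `pupil_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_pupil_csv()]
#' @export
write_pupil_csv <- function(recording, path) {
  stopifnot(inherits(recording, "pupil_recording"))
  s <- recording$samples
  lines <- c(csv_header,
             if (nrow(s)) paste(fmt_num(s$time_s), fmt_num(s$diameter_mm),
                                ifelse(s$valid, "TRUE", "FALSE"), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a pupil recording from CSV
#'
#' Parses the dialect written by [write_pupil_csv()]. Rows whose diameter is
#' the `NA` dropout sentinel become invalid samples. Malformed headers,
#' non-monotone timestamps and unparsable numbers raise an error naming the
#' offending line.
#'
#' @param path Input file path.
#' @param subject_id,eye,sampling_rate_hz Recording metadata (the CSV carries
#'   samples only). `subject_id` defaults to the file name without extension.
#' @return A `pupil_recording`.
#' @export
read_pupil_csv <- function(path, subject_id = NULL, eye = "right",
                           sampling_rate_hz = 30) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || trimws(lines[1L]) != csv_header)
    stop(sprintf("format error in %s, line 1: expected header '%s'",
                 path, csv_header), call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  if (n == 0L)
    return(pupil_recording(numeric(0), numeric(0), logical(0),
                           subject_id, eye, sampling_rate_hz))
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_ncol <- which(lengths(parts) != 3L)
  if (length(bad_ncol))
    stop(sprintf("format error in %s, line %d: expected 3 fields",
                 path, bad_ncol[1L] + 1L), call. = FALSE)
  m <- matrix(trimws(unlist(parts)), ncol = 3L, byrow = TRUE)

  time_s <- suppressWarnings(as.numeric(m[, 1L]))
  bad_t <- which(is.na(time_s))
  if (length(bad_t))
    stop(sprintf("format error in %s, line %d: unparsable time '%s'",
                 path, bad_t[1L] + 1L, m[bad_t[1L], 1L]), call. = FALSE)
  non_mono <- which(diff(time_s) <= 0)
  if (length(non_mono))
    stop(sprintf("format error in %s, line %d: non-monotone timestamp",
                 path, non_mono[1L] + 2L), call. = FALSE)

  diameter <- suppressWarnings(as.numeric(m[, 2L]))
  bad_d <- which(is.na(diameter) & m[, 2L] != "NA")
  if (length(bad_d))
    stop(sprintf("format error in %s, line %d: unparsable diameter '%s'",
                 path, bad_d[1L] + 1L, m[bad_d[1L], 2L]), call. = FALSE)

  valid <- m[, 3L] %in% c("TRUE", "true", "1")
  bad_v <- which(!m[, 3L] %in% c("TRUE", "FALSE", "true", "false", "0", "1"))
  if (length(bad_v))
    stop(sprintf("format error in %s, line %d: unparsable validity flag '%s'",
                 path, bad_v[1L] + 1L, m[bad_v[1L], 3L]), call. = FALSE)

  pupil_recording(time_s, diameter, valid, subject_id, eye, sampling_rate_hz)
}
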