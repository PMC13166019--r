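#' Construct a plantar-pressure recording
#'
#' A recording holds a frames-by-channels matrix of plantar pressures in
#' N cm^-2 sampled at a fixed rate. Missing samples (transmission dropouts)
#' are encoded as `NA`; all non-missing pressures must be non-negative.
#' Channel `i` corresponds to sensor id `i` of the accompanying layout.
#'
#' @param frames numeric matrix, frames x channels, `NA` = missing.
#' @param sample_rate sampling frequency in Hz.
#' @param subject_id free-text subject label.
#' @param side "left" or "right".
#' @return an object of class `pressure_recording`.
#' @export
pressure_recording <- function(frames, sample_rate = 100,
                               subject_id = "anon", side = "left") {
  side <- match.arg(side, c("left", "right"))
  stopifnot(is.matrix(frames), is.numeric(sample_rate), sample_rate > 0)
  storage.mode(frames) <- "double"
  if (any(frames < 0, na.rm = TRUE)) {
    stop("non-missing pressures must be >= 0 (N cm^-2)")
  }
  colnames(frames) <- sprintf("s%02d", seq_len(ncol(frames)))
  structure(
    list(frames = frames, sample_rate = as.numeric(sample_rate),
         subject_id = as.character(subject_id), side = side),
    class = "pressure_recording"
  )
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf(
    "<pressure_recording> subject %s (%s foot): %d frames x %d channels @ %g Hz, %d missing samples\n",
    x$subject_id, x$side, nrow(x$frames), ncol(x$frames), x$sample_rate,
    sum(is.na(x$frames))))
  invisible(x)
}

#' Missing-sample mask of a recording
#' @param rec a `pressure_recording`.
#' @return logical matrix, `TRUE` where the sample is missing.
#' @export
missing_mask <- function(rec) {
  stopifnot(inherits(rec, "pressure_recording"))
  is.na(rec$frames)
}

#' Write a recording to the canonical delimited-text format
#'
#' One header row, columns `time_s`, `s01`..`sNN` (pressures in N cm^-2);
#' missing samples are written as empty fields. Chosen over a binary format
#' for inspectability and lossless round-tripping.
#'
#' @param rec a `pressure_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pressure_recording"))
  t <- (seq_len(nrow(rec$frames)) - 1L) / rec$sample_rate
  df <- data.frame(time_s = t, rec$frames, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a recording from the canonical delimited-text format
#'
#' @param path CSV path written by [write_recording()].
#' @param subject_id,side recording metadata (not stored in the file).
#' @return a `pressure_recording`; the sample rate is inferred from the
#'   `time_s` column.
#' @export
read_recording <- function(path, subject_id = "anon", side = "left") {
  df <- utils::read.csv(path, na.strings = "", check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("malformed recording file: no time_s column")
  tm <- df$time_s
  fs <- if (length(tm) > 1L) 1 / stats::median(diff(tm)) else 100
  frames <- as.matrix(df[setdiff(names(df), "time_s")])
  pressure_recording(frames, sample_rate = round(fs, 6),
                     subject_id = subject_id, side = side)
}
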