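#' Fill short dropouts by gap-limited linear interpolation
#'
#' Replaces every internal run of missing samples of length `max_gap` or
#' less by linear interpolation between the flanking valid samples, per
#' channel. Longer runs and runs touching the recording edges are left
#' missing (they carry no flanking information on one side). Non-missing
#' samples are never altered, and the operation is idempotent.
#'
#' @param rec a `pressure_recording`.
#' @param max_gap maximum interpolatable run length, in frames (default 5).
#' @return a `pressure_recording` with short gaps filled.
#' @export
interpolate_missing <- function(rec, max_gap = 5) {
  stopifnot(inherits(rec, "pressure_recording"))
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (max_gap == 0 || !anyNA(rec$frames)) return(rec)
  filled <- apply(rec$frames, 2, function(col) {
    if (!anyNA(col) || all(is.na(col))) return(col)
    zoo::na.approx(col, maxgap = max_gap, na.rm = FALSE)
  })
  rec$frames <- matrix(filled, nrow = nrow(rec$frames),
                       dimnames = dimnames(rec$frames))
  rec
}

#' Fill remaining gaps by zero-order hold
#'
#' Pressure channels where no contact was detected (samples still missing
#' after interpolation) take the last preceding valid value on that
#' channel; leading missing runs, with no prior value to hold, are set to
#' 0 (no contact). The output contains no missing samples.
#'
#' @param rec a `pressure_recording`, normally after [interpolate_missing()].
#' @return a `pressure_recording` with zero missing samples.
#' @export
hold_no_contact <- function(rec) {
  stopifnot(inherits(rec, "pressure_recording"))
  if (!anyNA(rec$frames)) return(rec)
  filled <- apply(rec$frames, 2, function(col) {
    col <- zoo::na.locf(col, na.rm = FALSE)
    col[is.na(col)] <- 0
    col
  })
  rec$frames <- matrix(filled, nrow = nrow(rec$frames),
                       dimnames = dimnames(rec$frames))
  rec
}

#' Full preprocessing pipeline
#'
#' Gap-limited linear interpolation first (the more informative fill),
#' zero-order hold second as the fallback for what interpolation could not
#' recover. The result has no missing samples.
#'
#' @param rec a raw `pressure_recording`.
#' @param max_gap interpolation gap limit in frames.
#' @return a fully valid `pressure_recording`.
#' @export
preprocess_recording <- function(rec, max_gap = 5) {
  hold_no_contact(interpolate_missing(rec, max_gap = max_gap))
}
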