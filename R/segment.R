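#' Segmentation parameters
#'
#' The two concurrent criteria a candidate stance must meet: the total
#' vertical force must exceed `force_threshold` continuously for at least
#' `min_duration`, and the full-array CoP must perform a physiological
#' heel-to-toe roll-over (start in the posterior third, end in the
#' anterior third, with backward excursions bounded by
#' `regression_tolerance` times the insole length).
#'
#' @param force_threshold total-force threshold in N (default 15).
#' @param min_duration minimum continuous supra-threshold duration in ms
#'   (default 200).
#' @param regression_tolerance maximal allowed backward CoP-X excursion as
#'   a fraction of insole length (default 0.05); strict monotonicity would
#'   reject virtually all real signals.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(force_threshold = 15, min_duration = 200,
                                regression_tolerance = 0.05) {
  stopifnot(force_threshold > 0, min_duration > 0, regression_tolerance >= 0)
  structure(list(force_threshold = force_threshold,
                 min_duration = min_duration,
                 regression_tolerance = regression_tolerance),
            class = "segmentation_params")
}

#' Total vertical ground-reaction force
#'
#' Per-frame total force `F(t) = sum_i P_i(t) * A_i` over all sensors, in
#' N (pressure in N cm^-2 times area in cm^2).
#'
#' @param rec a preprocessed `pressure_recording` (no missing samples).
#' @param layout the matching `insole_layout`.
#' @return numeric vector of per-frame forces in N.
#' @export
total_force <- function(rec, layout) {
  stopifnot(inherits(rec, "pressure_recording"),
            inherits(layout, "insole_layout"))
  if (ncol(rec$frames) != nrow(layout$sensors)) {
    stop("recording has ", ncol(rec$frames), " channels but layout has ",
         nrow(layout$sensors), " sensors")
  }
  if (anyNA(rec$frames)) {
    stop("recording contains missing samples; preprocess first")
  }
  as.numeric(rec$frames %*% layout$sensors$area)
}

#' Detect candidate ground-contact intervals
#'
#' Finds maximal runs of frames whose total force strictly exceeds the
#' threshold, keeps only runs flanked by at least one sub-threshold frame
#' on each side (a stance must be surrounded by swing; recording edges do
#' not count as swing) and lasting at least `min_duration`. Run duration
#' is measured in whole frames (200 ms is 20 frames at 100 Hz).
#'
#' @param force per-frame total force in N.
#' @param params a `segmentation_params`.
#' @param sample_rate sampling rate of the force series in Hz.
#' @return data.frame with columns `start_frame`, `end_frame` (half-open,
#'   1-based) and `duration_ms`.
#' @export
detect_contacts <- function(force, params = segmentation_params(),
                            sample_rate = 100) {
  stopifnot(inherits(params, "segmentation_params"), sample_rate > 0)
  above <- force > params$force_threshold
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      duration_ms = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values &
    starts > 1L & ends < length(force) &           # flanked by swing
    (r$lengths / sample_rate * 1000) >= params$min_duration
  out <- data.frame(start_frame = starts[keep],
                    end_frame = ends[keep] + 1L,
                    duration_ms = r$lengths[keep] / sample_rate * 1000)
  rownames(out) <- NULL
  out
}

#' Check the heel-to-toe roll-over criterion
#'
#' A candidate stance is physiological if its full-array CoP-X trajectory
#' (a) starts in the posterior third of the insole, (b) ends in the
#' anterior third, and (c) progresses with net monotonicity: the maximal
#' backward excursion (running maximum minus current value) never exceeds
#' `regression_tolerance * length`. This rejects shuffling movements where
#' the CoP stays pinned under the heel.
#'
#' @param cop_x per-frame CoP-X series in mm over one candidate interval,
#'   computed from the full sensor array; `NA` frames are ignored.
#' @param layout the `insole_layout`.
#' @param params a `segmentation_params`.
#' @return `TRUE` if the roll-over is physiological.
#' @export
check_rollover <- function(cop_x, layout, params = segmentation_params()) {
  stopifnot(inherits(layout, "insole_layout"),
            inherits(params, "segmentation_params"))
  x <- cop_x[!is.na(cop_x)]
  if (!length(x)) stop("roll-over check on an empty/all-invalid CoP series")
  thirds <- posterior_anterior_thirds(layout)
  x[1] < thirds[1] &&
    x[length(x)] > thirds[2] &&
    max(cummax(x) - x) <= params$regression_tolerance * layout$length
}

#' Segment a recording into validated stance phases
#'
#' Applies both criteria: candidate contacts from the force threshold,
#' then the roll-over check on the full-16-sensor CoP-X of each candidate.
#' Retained phases are pairwise disjoint and time-ordered.
#'
#' @param rec a preprocessed `pressure_recording`.
#' @param layout the matching `insole_layout`.
#' @param params a `segmentation_params`.
#' @return data.frame of validated phases: `step_index`, `start_frame`,
#'   `end_frame` (half-open), `duration_ms`.
#' @export
segment_steps <- function(rec, layout, params = segmentation_params()) {
  force <- total_force(rec, layout)
  cand <- detect_contacts(force, params, rec$sample_rate)
  if (nrow(cand)) {
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      idx <- cand$start_frame[i]:(cand$end_frame[i] - 1L)
      P <- rec$frames[idx, , drop = FALSE]
      den <- as.numeric(P %*% layout$sensors$area)
      cx <- as.numeric(P %*% (layout$sensors$area * layout$sensors$x)) / den
      cx[den < 1e-12] <- NA
      check_rollover(cx, layout, params)
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
  }
  if (nrow(cand)) cand <- cbind(step_index = seq_len(nrow(cand)), cand)
  else cand <- data.frame(step_index = integer(), cand)
  rownames(cand) <- NULL
  cand
}

#' Crop to steady-state walking
#'
#' Discards the first and last detected steps of a recording, removing
#' the acceleration and deceleration phases so that only steady-state
#' gait enters the analysis. Fewer than three phases leave nothing.
#'
#' @param phases data.frame of phases, time-ordered (from
#'   [segment_steps()]).
#' @return the input minus its first and last rows.
#' @export
crop_steady_state <- function(phases) {
  if (nrow(phases) < 3L) return(phases[0, , drop = FALSE])
  out <- phases[2:(nrow(phases) - 1L), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a step table to delimited text
#' @param phases phases data.frame.
#' @param path output CSV path.
#' @param subject_id subject label stored in the table.
#' @return `path`, invisibly.
#' @export
write_step_table <- function(phases, path, subject_id = "anon") {
  df <- cbind(subject_id = rep(subject_id, nrow(phases)), phases)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
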