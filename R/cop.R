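#' Sensor subset bitmask helpers
#'
#' A sensor subset is represented as an integer bitmask where bit `i - 1`
#' set means sensor id `i` is a member; `ids_to_mask(c(1, 3)) == 5L`.
#'
#' @param ids integer vector of sensor ids.
#' @param mask integer bitmask.
#' @param n number of sensors in the array.
#' @return `ids_to_mask`: an integer mask; `mask_to_ids`: a sorted integer
#'   vector of ids; `mask_bitstring`: an `n`-character string of 0/1 with
#'   sensor 1 first; `subset_size`: the number of members.
#' @name sensor_subset
NULL

#' @rdname sensor_subset
#' @export
ids_to_mask <- function(ids) {
  ids <- unique(as.integer(ids))
  stopifnot(length(ids) > 0, all(ids >= 1L), all(ids <= 31L))
  as.integer(sum(bitwShiftL(1L, ids - 1L)))
}

#' @rdname sensor_subset
#' @export
mask_to_ids <- function(mask, n = 16L) {
  stopifnot(length(mask) == 1L, mask >= 1L)
  which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L)
}

#' @rdname sensor_subset
#' @export
mask_bitstring <- function(mask, n = 16L) {
  vapply(mask, function(m) {
    paste(ifelse(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L, "1", "0"),
          collapse = "")
  }, character(1))
}

#' @rdname sensor_subset
#' @export
subset_size <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:30)) > 0L),
         integer(1))
}

# 0/1 membership matrix (n_sensors x n_masks) for a vector of masks
mask_matrix <- function(masks, n) {
  bits <- bitwShiftL(1L, 0:(n - 1L))
  vapply(masks, function(m) as.numeric(bitwAnd(m, bits) > 0L), numeric(n))
}

#' Frame indices covered by a set of stance phases
#' @param phases phases data.frame with `start_frame`/`end_frame`
#'   (half-open), or `NULL` for all frames.
#' @param n_frames total frames in the recording.
#' @return integer vector of 1-based frame indices, time-ordered.
#' @export
phase_frames <- function(phases, n_frames) {
  if (is.null(phases)) return(seq_len(n_frames))
  if (!nrow(phases)) return(integer())
  sort(unique(unlist(lapply(seq_len(nrow(phases)), function(i) {
    phases$start_frame[i]:(phases$end_frame[i] - 1L)
  }))))
}

#' Barycentric center-of-pressure trajectory
#'
#' Computes the pressure-weighted barycenter of the sensor centroids,
#' per frame:
#' \deqn{CoP_x(t) = \frac{\sum_i P_i(t) A_i x_i}{\sum_i P_i(t) A_i}}
#' (and likewise for y), where the sum runs over the members of `subset`
#' — excluded sensors get weight zero. The full 16-sensor trajectory
#' serves as the reference ("ground truth") for reduced subsets.
#'
#' Frames whose subset denominator falls below `eps` cannot define a
#' barycenter (no member carries load). Under `fallback = "hold_last"`
#' (default) they repeat the last valid estimate and are flagged
#' `substituted`; under `"exclude"` they are marked invalid. Frames
#' before the first valid estimate are invalid under either policy.
#'
#' @param rec a preprocessed `pressure_recording` (no missing samples).
#' @param layout the matching `insole_layout`.
#' @param subset integer vector of member sensor ids, or an integer
#'   bitmask; `NULL` means all sensors.
#' @param phases stance phases restricting the evaluated frames
#'   (`NULL` = all frames).
#' @param fallback "hold_last" or "exclude".
#' @param eps zero-denominator threshold in force units (N), default
#'   1e-12.
#' @return an object of class `cop_trajectory`: list with `frame`
#'   (original frame indices), `cop_x`, `cop_y` (mm), `valid`,
#'   `substituted`.
#' @export
compute_cop <- function(rec, layout, subset = NULL, phases = NULL,
                        fallback = c("hold_last", "exclude"), eps = 1e-12) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(rec, "pressure_recording"),
            inherits(layout, "insole_layout"))
  n <- nrow(layout$sensors)
  if (ncol(rec$frames) != n) stop("recording/layout channel mismatch")
  if (anyNA(rec$frames)) stop("recording contains missing samples; preprocess first")
  ids <- layout$sensors$id
  if (is.null(subset)) subset <- ids
  if (length(subset) == 1L && !subset %in% ids) subset <- mask_to_ids(subset, n)
  subset <- unique(as.integer(subset))
  if (!length(subset)) stop("empty sensor subset")
  if (!all(subset %in% ids)) stop("subset contains unknown sensor id(s)")

  idx <- phase_frames(phases, nrow(rec$frames))
  if (!length(idx)) stop("no frames to evaluate")
  P <- rec$frames[idx, , drop = FALSE]
  # zero-weighting of excluded sensors keeps the arithmetic identical to
  # the vectorized multi-subset path
  member <- as.numeric(ids %in% subset)
  a <- layout$sensors$area * member
  den <- as.numeric(P %*% a)
  cx <- as.numeric(P %*% (a * layout$sensors$x)) / den
  cy <- as.numeric(P %*% (a * layout$sensors$y)) / den
  invalid <- den < eps
  cx[invalid] <- NA_real_
  cy[invalid] <- NA_real_
  substituted <- rep(FALSE, length(idx))
  if (fallback == "hold_last" && any(invalid)) {
    cx <- zoo::na.locf(cx, na.rm = FALSE)
    cy <- zoo::na.locf(cy, na.rm = FALSE)
    substituted <- invalid & !is.na(cx)
  }
  valid <- !is.na(cx)
  if (!any(valid)) stop("no valid frame for this subset")
  structure(list(frame = idx, cop_x = cx, cop_y = cy, valid = valid,
                 substituted = substituted),
            class = "cop_trajectory")
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("<cop_trajectory> %d frames (%d valid, %d substituted)\n",
              length(x$frame), sum(x$valid), sum(x$substituted)))
  invisible(x)
}

common_errors <- function(gt, est, axis = c("XY", "X", "Y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(gt, "cop_trajectory"), inherits(est, "cop_trajectory"))
  if (length(gt$frame) != length(est$frame)) {
    stop("trajectories cover different frame counts")
  }
  ok <- gt$valid & est$valid
  if (!any(ok)) stop("no common valid frames")
  dx <- est$cop_x[ok] - gt$cop_x[ok]
  dy <- est$cop_y[ok] - gt$cop_y[ok]
  switch(axis, X = list(sq = dx^2, abs = abs(dx)),
         Y = list(sq = dy^2, abs = abs(dy)),
         XY = list(sq = dx^2 + dy^2, abs = sqrt(dx^2 + dy^2)))
}

#' Root-mean-square CoP error
#'
#' \deqn{RMSE = \sqrt{\frac{1}{T}\sum_t (CoP_{GT}(t) - CoP_{est}(t))^2}}
#' evaluated over the frames valid in both trajectories. Per-axis for
#' `"X"`/`"Y"`; for `"XY"` the per-frame squared error is the squared
#' Euclidean distance, so `RMSE_XY^2 = RMSE_X^2 + RMSE_Y^2` on any shared
#' frame set.
#'
#' @param gt reference `cop_trajectory` (full sensor array).
#' @param est estimated `cop_trajectory` (reduced subset).
#' @param axis "X", "Y" or "XY".
#' @return RMSE in mm.
#' @export
cop_rmse <- function(gt, est, axis = c("XY", "X", "Y")) {
  e <- common_errors(gt, est, axis)
  sqrt(mean(e$sq))
}

#' 95th-percentile CoP error
#'
#' The 95th percentile (linear interpolation between order statistics) of
#' the per-frame absolute error (per axis) or Euclidean distance (XY):
#' a worst-case robustness summary of a reduced layout.
#'
#' @inheritParams cop_rmse
#' @return P95 error in mm.
#' @export
cop_p95 <- function(gt, est, axis = c("XY", "X", "Y")) {
  e <- common_errors(gt, est, axis)
  unname(stats::quantile(e$abs, 0.95, type = 7))
}

#' Write a CoP trajectory to delimited text
#' @param traj a `cop_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(frame = traj$frame, cop_x_mm = traj$cop_x,
                   cop_y_mm = traj$cop_y, valid = traj$valid,
                   substituted = traj$substituted)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
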