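#' Marginal-gain analysis of an optimization curve
#'
#' The marginal gain at size `k` is the reduction in best achievable
#' error when the allowed subset grows from `k - 1` to `k` sensors:
#' `gain(k) = best_metric(k - 1) - best_metric(k)`, defined for
#' `k >= 2`. The inflection point is the smallest sufficient sensor
#' count: the smallest `k` such that adding one more sensor
#' (the `k -> k + 1` transition) gains less than `threshold` mm.
#' `NA` if no gain ever drops below the threshold.
#'
#' @param curve an `optimization_curve` from [best_per_k()], complete
#'   over a contiguous `k` range.
#' @param threshold marginal-gain threshold in mm (default 1.5).
#' @return object of class `marginal_gain_series`: list with `target`,
#'   `gains` (data.frame `k`, `gain`), `inflection_k`, `threshold`.
#' @export
marginal_gains <- function(curve, threshold = 1.5) {
  stopifnot(inherits(curve, "optimization_curve"), threshold > 0)
  target <- attr(curve, "target")
  metric <- curve[[paste0("rmse_", tolower(target))]]
  ks <- curve$k
  if (any(diff(ks) != 1L)) stop("optimization curve must cover a contiguous k range")
  if (length(ks) < 2L) stop("need at least two subset sizes")
  gains <- data.frame(k = ks[-1L], gain = -diff(metric))
  below <- which(gains$gain < threshold)
  inflection_k <- if (length(below)) gains$k[below[1L]] - 1L else NA_integer_
  structure(list(target = target, gains = gains,
                 inflection_k = inflection_k, threshold = threshold),
            class = "marginal_gain_series")
}

#' @export
print.marginal_gain_series <- function(x, ...) {
  cat(sprintf("<marginal_gain_series> target %s, threshold %.2f mm, inflection at k = %s\n",
              x$target, x$threshold,
              if (is.na(x$inflection_k)) "none" else x$inflection_k))
  print(x$gains, ...)
  invisible(x)
}

#' Sensor selection-frequency matrix
#'
#' Counts, for every sensor, how many subset sizes in `k_range` include
#' it in the optimal subset, separately per optimization target. High
#' counts flag sensors that are structurally important for that axis
#' (e.g. the posterior heel for medio-lateral accuracy).
#'
#' @param curves named list of `optimization_curve`s (names = targets).
#' @param k_range subset sizes to tally over (default 2:15).
#' @param n number of sensors.
#' @return integer matrix, `n` sensors x targets.
#' @export
selection_frequency <- function(curves, k_range = 2:15, n = 16L) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  counts <- matrix(0L, nrow = n, ncol = length(curves),
                   dimnames = list(sprintf("S%d", seq_len(n)),
                                   names(curves)))
  for (j in seq_along(curves)) {
    curve <- curves[[j]]
    stopifnot(inherits(curve, "optimization_curve"))
    for (kk in intersect(k_range, curve$k)) {
      ids <- mask_to_ids(curve$mask[curve$k == kk], n)
      counts[ids, j] <- counts[ids, j] + 1L
    }
  }
  counts
}

#' Cross-performance of target-optimal layouts at a fixed size
#'
#' For one subset size `k`, takes the layouts optimal for each of the
#' three targets and reports all three RMSE metrics for each, exposing
#' the trade-off between axis-specific and global optimization (e.g. a
#' strictly Y-optimized layout degrading antero-posterior tracking).
#' By construction each target's own column is minimized on its row.
#'
#' @param evals evaluation table from [evaluate_all()].
#' @param k subset size.
#' @param n number of sensors.
#' @return data.frame: `target`, `sensors`, `rmse_x`, `rmse_y`,
#'   `rmse_xy` (mm).
#' @export
cross_performance <- function(evals, k, n = 16L) {
  if (!any(evals$k == k)) stop("no evaluations at k = ", k)
  sub <- evals[evals$k == k, , drop = FALSE]
  rows <- lapply(c("X", "Y", "XY"), function(target) {
    metric <- paste0("rmse_", tolower(target))
    cand <- sub[!is.na(sub[[metric]]), , drop = FALSE]
    if (!nrow(cand)) stop("no evaluable subset at k = ", k)
    best <- cand[cand[[metric]] == min(cand[[metric]]), , drop = FALSE]
    if (nrow(best) > 1L) {
      best <- best[order(mask_lex_key(best$mask, n)), , drop = FALSE]
    }
    data.frame(target = target,
               sensors = paste(mask_to_ids(best$mask[1L], n), collapse = ","),
               rmse_x = best$rmse_x[1L], rmse_y = best$rmse_y[1L],
               rmse_xy = best$rmse_xy[1L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned spatial error map
#'
#' Bins the reference CoP positions onto a regular grid over the insole
#' bounding box and reports the mean absolute estimation error of the
#' frames falling in each cell, localizing where on the foot a reduced
#' layout loses accuracy. Cells visited by no frame are `NA` (distinct
#' from zero error). The clip value (99th percentile of the per-frame
#' error distribution) is provided for display scaling.
#'
#' @param gt reference `cop_trajectory`.
#' @param est estimated `cop_trajectory` (same frames).
#' @param layout the `insole_layout` (defines the grid extent).
#' @param grid cells along x and y (default `c(40, 20)`).
#' @param axis "X", "Y" or "XY" (Euclidean).
#' @param clip_quantile quantile defining the display clip value.
#' @return object of class `error_map`: list with `values` and `counts`
#'   (grid matrices), `clip_value`, `axis`, `grid`, `xlim`, `ylim`.
#' @export
spatial_error_map <- function(gt, est, layout, grid = c(40L, 20L),
                              axis = c("XY", "X", "Y"),
                              clip_quantile = 0.99) {
  axis <- match.arg(axis)
  stopifnot(inherits(layout, "insole_layout"), length(grid) == 2L,
            all(grid >= 1L))
  e <- common_errors(gt, est, axis)
  ok <- gt$valid & est$valid
  px <- gt$cop_x[ok]
  py <- gt$cop_y[ok]
  ix <- pmin(grid[1L], pmax(1L, 1L + floor(px / layout$length * grid[1L])))
  iy <- pmin(grid[2L], pmax(1L, 1L + floor(py / layout$width * grid[2L])))
  cell <- (iy - 1L) * grid[1L] + ix
  values <- matrix(NA_real_, grid[1L], grid[2L])
  counts <- matrix(0L, grid[1L], grid[2L])
  sums <- tapply(e$abs, cell, sum)
  ns <- tapply(e$abs, cell, length)
  at <- as.integer(names(sums))
  values[at] <- as.numeric(sums) / as.numeric(ns)
  counts[at] <- as.integer(ns)
  structure(list(values = values, counts = counts,
                 clip_value = unname(stats::quantile(e$abs, clip_quantile,
                                                     type = 7)),
                 axis = axis, grid = as.integer(grid),
                 xlim = c(0, layout$length), ylim = c(0, layout$width)),
            class = "error_map")
}

#' @export
print.error_map <- function(x, ...) {
  cat(sprintf("<error_map> axis %s, %d x %d grid, %d occupied cells, clip %.2f mm\n",
              x$axis, x$grid[1], x$grid[2], sum(x$counts > 0), x$clip_value))
  invisible(x)
}
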