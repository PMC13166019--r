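#' Plot an optimization curve with marginal-gain bars
#'
#' Best achievable RMSE versus subset size, with grey bars showing the
#' accuracy gained by each added sensor.
#'
#' @param x an `optimization_curve`.
#' @param threshold optional marginal-gain threshold drawn as a dashed
#'   line (mm).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.optimization_curve <- function(x, threshold = 1.5, ...) {
  target <- attr(x, "target")
  metric <- x[[paste0("rmse_", tolower(target))]]
  gain <- c(NA, -diff(metric))
  graphics::plot(x$k, metric, type = "b", pch = 16,
                 xlab = "subset size k", ylab = "best RMSE (mm)",
                 main = sprintf("CoP-%s optimization", target), ...)
  ok <- !is.na(gain) & gain > 0
  graphics::segments(x$k[ok], 0, x$k[ok], gain[ok], lwd = 6,
                     col = "grey70")
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Plot a spatial error map
#'
#' Heat image of the per-cell mean absolute CoP error over the insole
#' bounding box, clipped at the stored 99th-percentile value; empty
#' cells are left blank.
#'
#' @param x an `error_map`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.error_map <- function(x, ...) {
  v <- pmin(x$values, x$clip_value)
  xs <- seq(x$xlim[1], x$xlim[2], length.out = x$grid[1] + 1L)
  ys <- seq(x$ylim[1], x$ylim[2], length.out = x$grid[2] + 1L)
  graphics::image(xs, ys, v, xlab = "x (mm, posterior > anterior)",
                  ylab = "y (mm, medial > lateral)", useRaster = FALSE,
                  main = sprintf("Mean |error| %s (clip %.1f mm)",
                                 x$axis, x$clip_value), ...)
  invisible(x)
}
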