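fake_curve <- function(metric, target = "XY") {
  k <- seq_along(metric)
  df <- data.frame(mask = k, k = k, rmse_x = metric, rmse_y = metric,
                   rmse_xy = metric, sensors = as.character(k))
  structure(df, target = target, class = c("optimization_curve", "data.frame"))
}

test_that("marginal gains are backward differences with threshold inflection", {
  curve <- fake_curve(c(20, 12, 8, 6.5, 5.8, 5.5))
  g <- marginal_gains(curve, threshold = 1.5)
  expect_equal(g$gains$k, 2:6)
  expect_equal(g$gains$gain, c(8, 4, 1.5, 0.7, 0.3))
  # first sub-threshold gain is the 4 -> 5 transition: k = 4 suffices
  expect_equal(g$inflection_k, 4L)
  # constant curve: every gain is 0, the very first size suffices
  gc <- marginal_gains(fake_curve(rep(3, 5)), threshold = 1.5)
  expect_true(all(gc$gains$gain == 0))
  expect_equal(gc$inflection_k, 1L)
  # gains always above threshold: no inflection
  gs <- marginal_gains(fake_curve(c(50, 40, 30, 20, 10)), threshold = 1.5)
  expect_true(is.na(gs$inflection_k))
  gap <- fake_curve(c(9, 8, 7))
  gap$k <- c(1L, 2L, 4L)   # hole in the k range
  expect_error(marginal_gains(gap), "contiguous")
})

test_that("gains telescope to the total improvement", {
  lay <- toy_layout(6)
  rec <- toy_recording(120, lay, seed = 44)
  ev <- evaluate_all(rec, lay, masks = enumerate_subsets(6))
  for (target in c("X", "Y", "XY")) {
    curve <- best_per_k(ev, target, n = 6)
    g <- marginal_gains(curve)
    metric <- curve[[paste0("rmse_", tolower(target))]]
    expect_equal(sum(g$gains$gain), metric[1] - metric[length(metric)])
  }
})

test_that("selection frequency tallies optimal-subset membership", {
  lay <- toy_layout(4)
  rec <- toy_recording(80, lay, seed = 55)
  ev <- evaluate_all(rec, lay, masks = enumerate_subsets(4))
  curves <- lapply(c(X = "X", Y = "Y", XY = "XY"), best_per_k,
                   evals = ev, n = 4)
  freq <- selection_frequency(curves, k_range = 2:3, n = 4)
  expect_equal(dim(freq), c(4L, 3L))
  expect_true(all(freq >= 0 & freq <= 2))
  # manual tally against the curves
  for (target in names(curves)) {
    counts <- integer(4)
    for (kk in 2:3) {
      ids <- mask_to_ids(curves[[target]]$mask[curves[[target]]$k == kk], 4)
      counts[ids] <- counts[ids] + 1L
    }
    expect_equal(unname(freq[, target]), counts)
  }
  # no count can exceed the number of tallied sizes
  expect_true(max(freq) <= length(2:3))
})

test_that("cross-performance rows are diagonal-dominant and Pythagorean", {
  lay <- toy_layout(7)
  rec <- toy_recording(150, lay, seed = 66)
  ev <- evaluate_all(rec, lay, masks = enumerate_subsets(7))
  tab <- cross_performance(ev, k = 3, n = 7)
  expect_equal(tab$target, c("X", "Y", "XY"))
  expect_equal(tab$rmse_x[1], min(tab$rmse_x))
  expect_equal(tab$rmse_y[2], min(tab$rmse_y))
  expect_equal(tab$rmse_xy[3], min(tab$rmse_xy))
  expect_equal(tab$rmse_xy^2, tab$rmse_x^2 + tab$rmse_y^2, tolerance = 1e-9)
  expect_error(cross_performance(ev, k = 9), "no evaluations")
})

test_that("X- and XY-optimal subsets coincide when X error dominates", {
  # geometry stretched along x: X errors dwarf Y errors, so the global
  # optimum follows the antero-posterior one
  lay <- insole_layout(
    "left", "stretch", length = 400, width = 12,
    sensors = data.frame(id = 1:6, label = sprintf("T%d", 1:6), zone = "toy",
                         x = c(30, 100, 170, 240, 310, 370),
                         y = rep(6, 6), area = 5))
  rec <- toy_recording(200, lay, seed = 77)
  ev <- evaluate_all(rec, lay, masks = enumerate_subsets(6))
  tab <- cross_performance(ev, k = 3, n = 6)
  expect_identical(tab$sensors[1], tab$sensors[3])
  expect_equal(tab$rmse_x[1], tab$rmse_xy[3], tolerance = 1e-9)
})

test_that("spatial error maps localize and average the error correctly", {
  lay <- toy_layout(4, length = 200, width = 80)
  gt <- make_traj(x = c(20, 60, 150, 190), y = c(10, 40, 60, 70))
  emap0 <- spatial_error_map(gt, gt, lay, grid = c(10, 4))
  expect_true(all(emap0$values[emap0$counts > 0] == 0))
  expect_equal(sum(emap0$counts), 4)
  # single frame, known error, lands in one cell
  gt1 <- make_traj(x = 100, y = 40)
  est1 <- make_traj(x = 105, y = 40)
  emap1 <- spatial_error_map(gt1, est1, lay, grid = c(10, 4), axis = "X")
  expect_equal(sum(emap1$counts > 0), 1)
  expect_equal(emap1$values[emap1$counts > 0], 5)
  expect_true(is.na(emap1$values[1, 1]))
  # errors confined to the anterior third stay in anterior bins
  n <- 60
  gx <- seq(10, 190, length.out = n)
  err <- ifelse(gx > 2 / 3 * 200, 6, 0)
  gta <- make_traj(x = gx, y = rep(40, n))
  esta <- make_traj(x = gx + err, y = rep(40, n))
  em <- spatial_error_map(gta, esta, lay, grid = c(30, 4), axis = "X")
  elevated <- which(em$values > 0, arr.ind = TRUE)
  cell_x_mm <- (elevated[, 1] - 0.5) / 30 * 200
  expect_true(all(cell_x_mm > 2 / 3 * 200 - 200 / 30))
  # weighted mean of occupied cells equals the overall mean absolute error
  set.seed(9)
  estr <- make_traj(x = gx + rnorm(n), y = rep(40, n) + rnorm(n))
  emr <- spatial_error_map(gta, estr, lay, grid = c(8, 3))
  occ <- emr$counts > 0
  expect_equal(sum(emr$values[occ] * emr$counts[occ]) / sum(emr$counts),
               mean(sqrt((estr$cop_x - gta$cop_x)^2 +
                           (estr$cop_y - gta$cop_y)^2)))
  # clip value is the 99th percentile of the per-frame error distribution
  errs <- sqrt((estr$cop_x - gta$cop_x)^2 + (estr$cop_y - gta$cop_y)^2)
  expect_equal(emr$clip_value, unname(quantile(errs, 0.99, type = 7)))
})
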