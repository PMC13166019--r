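test_that("barycentric CoP matches hand-computed weighted means", {
  lay <- toy_layout(3, length = 300, width = 80)
  lay$sensors$x <- c(0, 100, 200)
  lay$sensors$area <- c(2, 2, 2)
  # P*A weights 1, 2, 1 -> CoP-X = 100
  r <- pressure_recording(matrix(c(0.5, 1, 0.5), 1, 3), 100)
  traj <- compute_cop(r, lay)
  expect_equal(traj$cop_x, 100)
  # single loaded sensor: CoP sits at its centroid
  r1 <- pressure_recording(matrix(c(0, 3, 0), 1, 3), 100)
  t1 <- compute_cop(r1, lay)
  expect_equal(c(t1$cop_x, t1$cop_y), c(lay$sensors$x[2], lay$sensors$y[2]))
  # equal P*A on two sensors: midpoint of their centroids
  r2 <- pressure_recording(matrix(c(1, 0, 1), 1, 3), 100)
  t2 <- compute_cop(r2, lay)
  expect_equal(t2$cop_x, 100)
  expect_equal(t2$cop_y, mean(lay$sensors$y[c(1, 3)]))
  # independent oracle: explicit loops over sensors and frames
  set.seed(2)
  P <- matrix(runif(15), 5, 3)
  rr <- pressure_recording(P, 100)
  tt <- compute_cop(rr, lay)
  for (t in 1:5) {
    w <- P[t, ] * lay$sensors$area
    expect_equal(tt$cop_x[t], sum(w * lay$sensors$x) / sum(w))
    expect_equal(tt$cop_y[t], sum(w * lay$sensors$y) / sum(w))
  }
})

test_that("CoP is invariant to global pressure rescaling", {
  fx <- std_fixture(n_steps = 4, seed = 5, missing_prob = 0)
  r3 <- fx$rec
  r3$frames <- r3$frames * 3
  t1 <- compute_cop(fx$rec, fx$layout, phases = fx$phases)
  t3 <- compute_cop(r3, fx$layout, phases = fx$phases)
  expect_equal(t1$cop_x, t3$cop_x)
  expect_equal(t1$cop_y, t3$cop_y)
})

test_that("splitting a sensor into two co-located halves leaves CoP unchanged", {
  lay <- toy_layout(4)
  set.seed(3)
  P <- matrix(runif(40, 0.5, 2), 10, 4)
  base <- compute_cop(pressure_recording(P, 100), lay)
  s <- lay$sensors
  half <- s[1, ]; half$id <- 5L
  s$area[1] <- s$area[1] / 2
  half$area <- half$area / 2
  lay5 <- insole_layout(lay$side, "split", lay$length, lay$width,
                        rbind(s, half))
  split <- compute_cop(pressure_recording(cbind(P, P[, 1]), 100), lay5)
  expect_equal(split$cop_x, base$cop_x)
  expect_equal(split$cop_y, base$cop_y)
})

test_that("zero-denominator frames follow the fallback policy", {
  lay <- toy_layout(3)
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0), c(0, 2, 0))
  r <- pressure_recording(P, 100)
  hold <- compute_cop(r, lay, fallback = "hold_last")
  expect_false(hold$valid[1])                    # nothing to hold yet
  expect_true(hold$valid[3] && hold$substituted[3])
  expect_equal(hold$cop_x[3], hold$cop_x[2])
  excl <- compute_cop(r, lay, fallback = "exclude")
  expect_equal(excl$valid, c(FALSE, TRUE, FALSE, TRUE))
  expect_false(any(excl$substituted))
  # subset with no load at all has no valid frame
  expect_error(compute_cop(r, lay, subset = 3), "no valid frame")
  expect_error(compute_cop(r, lay, subset = integer()), "empty")
})

test_that("valid unsubstituted CoP stays in the subset's convex hull", {
  fx <- std_fixture(n_steps = 4, seed = 5, missing_prob = 0)
  s <- fx$layout$sensors
  set.seed(8)
  for (rep in 1:10) {
    ids <- sort(sample(1:16, sample(3:8, 1)))
    traj <- compute_cop(fx$rec, fx$layout, subset = ids, phases = fx$phases)
    keep <- traj$valid & !traj$substituted
    pts <- which(keep)
    for (t in pts[seq(1, length(pts), length.out = min(25, length(pts)))]) {
      expect_true(in_hull(traj$cop_x[t], traj$cop_y[t],
                          s$x[ids], s$y[ids], tol = 1e-9))
    }
  }
})

test_that("RMSE follows the per-axis and Euclidean definitions", {
  gt <- make_traj(x = rep(10, 50), y = rep(5, 50))
  est <- make_traj(x = rep(14, 50), y = rep(5, 50))  # constant +4 mm on X
  expect_equal(cop_rmse(gt, est, "X"), 4)
  expect_equal(cop_rmse(gt, est, "Y"), 0)
  expect_equal(cop_rmse(gt, est, "XY"), 4)
  expect_equal(cop_rmse(gt, gt, "XY"), 0)
  # Pythagorean identity on a shared frame set, with noisy errors
  set.seed(4)
  est2 <- make_traj(x = rnorm(50, 10, 3), y = rnorm(50, 5, 2),
                    valid = runif(50) > 0.2)
  for (fn in list(cop_rmse)) {
    expect_equal(fn(gt, est2, "XY")^2,
                 fn(gt, est2, "X")^2 + fn(gt, est2, "Y")^2)
  }
  # only frames valid in both contribute
  est3 <- make_traj(x = c(10 + 4, rep(10, 9)), y = rep(5, 10),
                    valid = c(TRUE, rep(FALSE, 9)))
  gt10 <- make_traj(x = rep(10, 10), y = rep(5, 10))
  expect_equal(cop_rmse(gt10, est3, "X"), 4)
  expect_error(cop_rmse(gt10, make_traj(rep(1, 10), valid = rep(FALSE, 10))),
               "no common valid frames")
  expect_error(cop_rmse(gt10, make_traj(1:5)), "frame counts")
})

test_that("P95 uses the linear-interpolation percentile of absolute errors", {
  gt <- make_traj(x = rep(0, 100), y = rep(0, 100))
  est <- make_traj(x = 1:100, y = rep(0, 100))
  expect_equal(cop_p95(gt, est, "X"), 95.05)
  expect_equal(cop_p95(gt, est, "XY"), 95.05)
  expect_equal(cop_p95(gt, gt, "XY"), 0)
  one <- make_traj(7); zero <- make_traj(0)
  expect_equal(cop_p95(zero, one, "X"), 7)
})
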