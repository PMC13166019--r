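# Shared fixtures, built in code.

# small linear toy array for brute-force cross-checks (ids 1..n)
toy_layout <- function(n = 6, length = 200, width = 80) {
  insole_layout(
    side = "left", size_variant = "toy", length = length, width = width,
    sensors = data.frame(
      id = seq_len(n), label = sprintf("T%d", seq_len(n)), zone = "toy",
      x = seq(20, length - 20, length.out = n),
      y = rep(c(25, 55), length.out = n),
      area = seq(4, 6, length.out = n)))
}

# sparse random pressures: many zero samples so that small subsets hit
# zero-denominator frames and exercise the fallback path
toy_recording <- function(n_frames = 500, layout = toy_layout(), seed = 99) {
  n <- nrow(layout$sensors)
  set.seed(seed)
  P <- matrix(stats::runif(n_frames * n, 0, 4), n_frames, n)
  P[stats::runif(n_frames * n) < 0.35] <- 0
  pressure_recording(P, sample_rate = 100)
}

# naive per-subset oracle: one compute_cop + metric call per subset
naive_evaluate <- function(rec, layout, masks, phases = NULL,
                           fallback = "hold_last") {
  n <- nrow(layout$sensors)
  gt <- compute_cop(rec, layout, phases = phases, fallback = fallback)
  do.call(rbind, lapply(masks, function(m) {
    est <- tryCatch(
      compute_cop(rec, layout, subset = mask_to_ids(m, n), phases = phases,
                  fallback = fallback),
      error = function(e) NULL)
    if (is.null(est)) {
      return(data.frame(mask = m, k = subset_size(m), rmse_x = NA_real_,
                        rmse_y = NA_real_, rmse_xy = NA_real_,
                        p95_x = NA_real_, p95_y = NA_real_,
                        p95_xy = NA_real_))
    }
    data.frame(mask = m, k = subset_size(m),
               rmse_x = cop_rmse(gt, est, "X"),
               rmse_y = cop_rmse(gt, est, "Y"),
               rmse_xy = cop_rmse(gt, est, "XY"),
               p95_x = cop_p95(gt, est, "X"),
               p95_y = cop_p95(gt, est, "Y"),
               p95_xy = cop_p95(gt, est, "XY"))
  }))
}

# hand-built CoP trajectory for metric tests
make_traj <- function(x, y = rep(0, length(x)), valid = rep(TRUE, length(x))) {
  structure(list(frame = seq_along(x), cop_x = x, cop_y = y, valid = valid,
                 substituted = rep(FALSE, length(x))),
            class = "cop_trajectory")
}

# simulated, preprocessed standard recording (cached: several files use it)
.fixture_cache <- new.env(parent = emptyenv())
std_fixture <- function(n_steps = 10, seed = 42, ...) {
  key <- paste(n_steps, seed, ..., sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    lay <- default_layout()
    rec <- simulate_recording(gait_sim_config(n_steps = n_steps, seed = seed,
                                              ...), lay)
    pp <- preprocess_recording(rec)
    .fixture_cache[[key]] <- list(layout = lay, raw = rec, rec = pp,
                                  phases = segment_steps(pp, lay))
  }
  .fixture_cache[[key]]
}

# point-in-convex-hull test with tolerance (mm)
in_hull <- function(px, py, hx, hy, tol = 1e-9) {
  if (length(hx) == 1) return(abs(px - hx) <= tol && abs(py - hy) <= tol)
  h <- grDevices::chull(hx, hy)
  if (length(h) < 3) { # collinear: distance to the segment between extremes
    a <- c(hx[h[1]], hy[h[1]]); b <- c(hx[h[length(h)]], hy[h[length(h)]])
    ab <- b - a; t <- sum((c(px, py) - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t)); p0 <- a + t * ab
    return(sqrt(sum((c(px, py) - p0)^2)) <= tol)
  }
  vx <- hx[h]; vy <- hy[h]
  m <- length(h)
  cross <- (vx[c(2:m, 1)] - vx) * (py - vy) - (vy[c(2:m, 1)] - vy) * (px - vx)
  all(cross >= -tol) || all(cross <= tol)
}
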