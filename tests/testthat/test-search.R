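test_that("subset enumeration is complete and correctly stratified", {
  masks <- enumerate_subsets(16)
  expect_equal(length(masks), 65535)
  expect_equal(anyDuplicated(masks), 0)
  sizes <- subset_size(masks)
  expect_equal(as.integer(table(sizes)), as.integer(choose(16, 1:16)))
  expect_equal(length(enumerate_subsets(4)), 15)
  expect_equal(length(enumerate_subsets(16, k = 1)), 16)
  expect_equal(sort(enumerate_subsets(16, k = 1)), 2L^(0:15))
  expect_error(enumerate_subsets(16, k = 0), "1..n")
})

test_that("bitmask helpers round-trip ids and masks", {
  expect_equal(ids_to_mask(c(1, 3)), 5L)
  expect_equal(mask_to_ids(5L), c(1L, 3L))
  expect_equal(mask_bitstring(5L, 4), "1010")
  expect_equal(subset_size(c(5L, 65535L)), c(2L, 16L))
  for (ids in list(1L, c(2L, 7L, 16L), 1:16)) {
    expect_equal(mask_to_ids(ids_to_mask(ids)), ids)
  }
})

test_that("vectorized search equals the naive per-subset oracle", {
  lay <- toy_layout(6)
  rec <- toy_recording(120, lay, seed = 99)
  masks <- enumerate_subsets(6)
  for (fb in c("hold_last", "exclude")) {
    fast <- evaluate_all(rec, lay, masks = masks, fallback = fb,
                         chunk_size = 17L)   # force multiple chunks
    naive <- naive_evaluate(rec, lay, masks, fallback = fb)
    expect_equal(fast$mask, naive$mask)
    for (col in c("rmse_x", "rmse_y", "rmse_xy", "p95_x", "p95_y", "p95_xy")) {
      expect_equal(fast[[col]], naive[[col]], tolerance = 1e-12)
    }
  }
})

test_that("full-array evaluation reproduces the reference exactly", {
  fx <- std_fixture(n_steps = 4, seed = 5, missing_prob = 0)
  ev <- evaluate_all(fx$rec, fx$layout, phases = fx$phases,
                     masks = c(ids_to_mask(1:16), ids_to_mask(c(1, 4))))
  full <- ev[ev$k == 16, ]
  expect_equal(full$rmse_x, 0, tolerance = 1e-10)
  expect_equal(full$rmse_y, 0, tolerance = 1e-10)
  expect_equal(full$rmse_xy, 0, tolerance = 1e-10)
  expect_equal(full$p95_xy, 0, tolerance = 1e-10)
  expect_equal(full$coverage, 1)
})

test_that("inactive sensors contribute nothing: active subset has zero error", {
  lay <- toy_layout(8)
  set.seed(12)
  P <- matrix(0, 200, 8)
  active <- c(2, 3, 5, 8)
  P[, active] <- runif(200 * 4, 0.1, 2)
  rec <- pressure_recording(P, 100)
  ev <- evaluate_all(rec, lay, masks = enumerate_subsets(8))
  row <- ev[ev$mask == ids_to_mask(active), ]
  expect_equal(row$rmse_xy, 0, tolerance = 1e-10)
  # and it is the unique zero-error subset at its size
  k4 <- ev[ev$k == 4 & ev$mask != ids_to_mask(active), ]
  expect_true(all(k4$rmse_xy > 1e-6 | is.na(k4$rmse_xy)))
  best <- best_per_k(ev, "XY", n = 8)
  expect_equal(best$sensors[best$k == 4], paste(active, collapse = ","))
})

test_that("per-k optima match a brute-force argmin with the tie rule", {
  lay <- toy_layout(5)
  rec <- toy_recording(80, lay, seed = 17)
  ev <- evaluate_all(rec, lay, masks = enumerate_subsets(5))
  for (target in c("X", "Y", "XY")) {
    metric <- paste0("rmse_", tolower(target))
    best <- best_per_k(ev, target, n = 5)
    expect_equal(best$k, 1:5)
    for (kk in 1:5) {
      sub <- ev[ev$k == kk & !is.na(ev[[metric]]), ]
      expect_equal(best[[metric]][best$k == kk], min(sub[[metric]]))
    }
    # k = n is the full set with zero error
    expect_equal(best$mask[best$k == 5], ids_to_mask(1:5))
    expect_equal(best[[metric]][best$k == 5], 0, tolerance = 1e-10)
  }
})

test_that("equal-metric ties resolve to the smallest sorted id tuple", {
  ev <- data.frame(mask = c(ids_to_mask(c(1, 4)), ids_to_mask(c(2, 3))),
                   k = 2L, rmse_x = c(1, 1), rmse_y = c(2, 2),
                   rmse_xy = c(3, 3))
  best <- best_per_k(ev, "XY", n = 4)
  expect_equal(best$sensors, "1,4")   # (1,4) < (2,3) lexicographically
})

test_that("running best metric is non-increasing and runs are deterministic", {
  lay <- toy_layout(6)
  rec <- toy_recording(150, lay, seed = 21)
  ev1 <- evaluate_all(rec, lay, masks = enumerate_subsets(6))
  ev2 <- evaluate_all(rec, lay, masks = enumerate_subsets(6))
  expect_identical(ev1, ev2)
  for (target in c("X", "Y", "XY")) {
    best <- best_per_k(ev1, target, n = 6)
    metric <- best[[paste0("rmse_", tolower(target))]]
    expect_true(all(diff(cummin(metric)) <= 0))
    expect_identical(best_per_k(ev2, target, n = 6)$mask, best$mask)
  }
})

test_that("Pythagorean identity holds on every evaluation row", {
  lay <- toy_layout(6)
  rec <- toy_recording(100, lay, seed = 33)
  ev <- evaluate_all(rec, lay, masks = enumerate_subsets(6))
  ok <- !is.na(ev$rmse_xy)
  expect_equal(ev$rmse_xy[ok]^2, ev$rmse_x[ok]^2 + ev$rmse_y[ok]^2,
               tolerance = 1e-9)
})
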