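#' Enumerate sensor subsets
#'
#' Yields every non-empty subset of an `n`-sensor array exactly once, as
#' integer bitmasks ordered by subset size then mask value. For the
#' 16-sensor insole this is all `2^16 - 1 = 65535` subsets; the full set
#' is included as the zero-error reference row.
#'
#' @param n number of sensors in the array (default 16).
#' @param k optional subset size(s) to restrict to (default all of
#'   `1:n`).
#' @return integer vector of bitmasks.
#' @export
enumerate_subsets <- function(n = 16L, k = NULL) {
  stopifnot(n >= 1L, n <= 24L)
  masks <- seq_len(2^n - 1)
  sizes <- popcount(masks)
  if (!is.null(k)) {
    if (any(k < 1L | k > n)) stop("subset sizes must lie in 1..n")
    keep <- sizes %in% k
    masks <- masks[keep]
    sizes <- sizes[keep]
  }
  as.integer(masks[order(sizes, masks)])
}

# vectorized population count
popcount <- function(masks) {
  bits <- matrix(as.integer(intToBits(as.integer(masks))), nrow = 32L)
  as.integer(colSums(bits))
}

# column-wise last-observation-carried-forward on a numeric matrix;
# leading NAs stay NA
locf_cols <- function(M) {
  if (!anyNA(M)) return(M)
  last <- matrix(row(M) * as.numeric(!is.na(M)), nrow(M))
  last <- apply(last, 2, cummax)
  if (!is.matrix(last)) last <- matrix(last, nrow = nrow(M))
  pick <- last > 0
  out <- matrix(NA_real_, nrow(M), ncol(M))
  cc <- col(M)
  out[pick] <- M[cbind(last[pick], cc[pick])]
  out
}

# type-7 95th percentile per column (partial sort; matches
# stats::quantile(type = 7) exactly)
p95_cols <- function(E) {
  res <- rep(NA_real_, ncol(E))
  for (j in seq_len(ncol(E))) {
    v <- E[, j]
    v <- v[!is.na(v)]
    m <- length(v)
    if (!m) next
    h <- (m - 1) * 0.95 + 1
    lo <- floor(h)
    hi <- ceiling(h)
    v <- sort(v, partial = unique(c(lo, hi)))
    res[j] <- v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  res
}

#' Evaluate CoP reconstruction error for many sensor subsets
#'
#' For each subset, recomputes the CoP from the member sensors only
#' (excluded sensors weighted zero) over the pooled stance frames and
#' compares it with the full-array reference trajectory. The
#' implementation precomputes per-frame moment triples
#' (`P_i A_i`, `P_i A_i x_i`, `P_i A_i y_i`) once and sums them per
#' subset in chunked matrix products; results are identical to a naive
#' per-subset loop and independent of evaluation order.
#'
#' @param rec a preprocessed `pressure_recording`.
#' @param layout the matching `insole_layout` (sensor ids must be
#'   `1..n`).
#' @param phases stance phases restricting evaluation (`NULL` = all
#'   frames).
#' @param masks integer bitmasks of the subsets to evaluate (default:
#'   all `2^n - 1`).
#' @param fallback zero-denominator policy, see [compute_cop()].
#' @param eps zero-denominator threshold (N).
#' @param chunk_size subsets evaluated per matrix-product block.
#' @return data.frame with one row per subset: `mask`, `bits` (bitstring,
#'   sensor 1 first), `k`, `rmse_x`, `rmse_y`, `rmse_xy`, `p95_x`,
#'   `p95_y`, `p95_xy` (mm), `coverage` (fraction of frames not needing
#'   fallback) and `n_valid`. Subsets with no valid frame get `NA`
#'   metrics.
#' @export
evaluate_all <- function(rec, layout, phases = NULL, masks = NULL,
                         fallback = c("hold_last", "exclude"),
                         eps = 1e-12, chunk_size = 2048L) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(rec, "pressure_recording"),
            inherits(layout, "insole_layout"))
  n <- nrow(layout$sensors)
  if (!identical(sort(layout$sensors$id), seq_len(n))) {
    stop("subset search requires sensor ids 1..n")
  }
  if (ncol(rec$frames) != n) stop("recording/layout channel mismatch")
  if (anyNA(rec$frames)) stop("recording contains missing samples; preprocess first")
  if (is.null(masks)) masks <- enumerate_subsets(n)
  idx <- phase_frames(phases, nrow(rec$frames))
  if (!length(idx)) stop("no retained frames to evaluate")

  P <- rec$frames[idx, , drop = FALSE]
  ord <- order(layout$sensors$id)
  a <- layout$sensors$area[ord]
  x <- layout$sensors$x[ord]
  y <- layout$sensors$y[ord]
  W  <- P * rep(a, each = nrow(P))
  MX <- W * rep(x, each = nrow(P))
  MY <- W * rep(y, each = nrow(P))

  # full-array reference trajectory, same fallback policy
  full <- matrix(1, n, 1)
  gden <- as.numeric(W %*% full)
  gx <- as.numeric(MX %*% full) / gden
  gy <- as.numeric(MY %*% full) / gden
  ginv <- gden < eps
  gx[ginv] <- NA_real_; gy[ginv] <- NA_real_
  if (fallback == "hold_last") {
    gx <- zoo::na.locf(gx, na.rm = FALSE)
    gy <- zoo::na.locf(gy, na.rm = FALSE)
  }
  gvalid <- !is.na(gx)

  nmask <- length(masks)
  res <- data.frame(
    mask = as.integer(masks), bits = mask_bitstring(masks, n),
    k = popcount(masks),
    rmse_x = NA_real_, rmse_y = NA_real_, rmse_xy = NA_real_,
    p95_x = NA_real_, p95_y = NA_real_, p95_xy = NA_real_,
    coverage = NA_real_, n_valid = NA_integer_)

  for (lo in seq(1L, nmask, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, nmask)
    B <- mask_matrix(masks[lo:hi], n)
    if (!is.matrix(B)) B <- matrix(B, nrow = n)
    D  <- W %*% B
    X <- (MX %*% B) / D
    Y <- (MY %*% B) / D
    inval <- D < eps
    X[inval] <- NA_real_
    Y[inval] <- NA_real_
    if (fallback == "hold_last") {
      X <- locf_cols(X)
      Y <- locf_cols(Y)
    }
    valid <- !is.na(X) & gvalid
    X[!valid] <- NA_real_
    Y[!valid] <- NA_real_
    EX <- X - gx
    EY <- Y - gy
    nv <- colSums(valid)
    sx <- colSums(EX^2, na.rm = TRUE)
    sy <- colSums(EY^2, na.rm = TRUE)
    rows <- lo:hi
    res$rmse_x[rows]  <- ifelse(nv > 0, sqrt(sx / nv), NA_real_)
    res$rmse_y[rows]  <- ifelse(nv > 0, sqrt(sy / nv), NA_real_)
    res$rmse_xy[rows] <- ifelse(nv > 0, sqrt((sx + sy) / nv), NA_real_)
    res$p95_x[rows]  <- p95_cols(abs(EX))
    res$p95_y[rows]  <- p95_cols(abs(EY))
    res$p95_xy[rows] <- p95_cols(sqrt(EX^2 + EY^2))
    res$coverage[rows] <- colMeans(!inval)
    res$n_valid[rows] <- as.integer(nv)
  }
  res
}

# lexicographic tie-break key: fixed-width concatenation of sorted member
# ids, so string order equals sorted-tuple order within one subset size
mask_lex_key <- function(mask, n) {
  vapply(mask, function(m) {
    paste(sprintf("%02d", mask_to_ids(m, n)), collapse = "")
  }, character(1))
}

#' Optimal subset per size for one optimization target
#'
#' For each subset size `k`, selects the subset minimizing the target
#' metric (`rmse_x`, `rmse_y` or `rmse_xy`) among all evaluated size-`k`
#' subsets. Ties are broken by the lexicographically smallest sorted
#' id tuple, making the argmin total and the search deterministic.
#'
#' @param evals evaluation table from [evaluate_all()].
#' @param target "X", "Y" or "XY".
#' @param n number of sensors in the array.
#' @return data.frame of class `optimization_curve`, one row per `k`
#'   with the winning subset (`mask`, `sensors` id string) and all its
#'   metrics; attribute `target` records the optimized axis.
#' @export
best_per_k <- function(evals, target = c("XY", "X", "Y"), n = 16L) {
  target <- match.arg(target)
  metric <- paste0("rmse_", tolower(target))
  stopifnot(metric %in% names(evals))
  ks <- sort(unique(evals$k))
  rows <- lapply(ks, function(kk) {
    sub <- evals[evals$k == kk & !is.na(evals[[metric]]), , drop = FALSE]
    if (!nrow(sub)) stop("no evaluable subset at k = ", kk)
    best <- sub[sub[[metric]] == min(sub[[metric]]), , drop = FALSE]
    if (nrow(best) > 1L) {
      best <- best[order(mask_lex_key(best$mask, n)), , drop = FALSE]
    }
    best[1L, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out$sensors <- vapply(out$mask, function(m) {
    paste(mask_to_ids(m, n), collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  structure(out, target = target,
            class = c("optimization_curve", "data.frame"))
}
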