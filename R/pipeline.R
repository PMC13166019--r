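#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis: the insole layout,
#' the recordings (paths to canonical CSV files, or simulation
#' configurations to generate them), segmentation parameters, the
#' zero-denominator fallback policy, the optimization targets and subset
#' sizes, the marginal-gain threshold, the error-map grid and the sizes
#' at which cross-performance tables are produced. Defaults reproduce
#' the standard study settings (15 N / 200 ms segmentation, 1.5 mm gain
#' threshold, all 65,535 subsets).
#'
#' @param out_dir output directory (created if absent).
#' @param layout an `insole_layout` (default: bundled synthetic layout).
#' @param sims list of `gait_sim_config` objects, one recording each.
#' @param recordings character paths to recording CSVs (alternative to
#'   `sims`).
#' @param params a `segmentation_params`.
#' @param fallback "hold_last" or "exclude".
#' @param k_range subset sizes to search.
#' @param targets optimization targets among "X", "Y", "XY".
#' @param gain_threshold marginal-gain threshold in mm.
#' @param frequency_k_range sizes tallied by the selection-frequency
#'   analysis.
#' @param cross_k sizes at which cross-performance tables are written.
#' @param grid error-map grid (cells along x, y).
#' @param max_gap interpolation gap limit in frames.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       layout = default_layout(),
                       sims = list(gait_sim_config()),
                       recordings = NULL,
                       params = segmentation_params(),
                       fallback = c("hold_last", "exclude"),
                       k_range = 1:16,
                       targets = c("X", "Y", "XY"),
                       gain_threshold = 1.5,
                       frequency_k_range = 2:15,
                       cross_k = c(5L, 7L),
                       grid = c(40L, 20L),
                       max_gap = 5) {
  fallback <- match.arg(fallback)
  targets <- match.arg(targets, c("X", "Y", "XY"), several.ok = TRUE)
  stopifnot(inherits(layout, "insole_layout"),
            inherits(params, "segmentation_params"),
            gain_threshold > 0, all(k_range >= 1L))
  if (is.null(recordings) && !length(sims)) {
    stop("provide either `sims` or `recordings`")
  }
  structure(list(out_dir = out_dir, layout = layout, sims = sims,
                 recordings = recordings, params = params,
                 fallback = fallback, k_range = as.integer(k_range),
                 targets = targets, gain_threshold = gain_threshold,
                 frequency_k_range = as.integer(frequency_k_range),
                 cross_k = as.integer(cross_k), grid = as.integer(grid),
                 max_gap = max_gap),
            class = "run_config")
}

pool_recordings <- function(config) {
  layout <- config$layout
  recs <- if (!is.null(config$recordings)) {
    lapply(seq_along(config$recordings), function(i) {
      read_recording(config$recordings[i], subject_id = sprintf("sub%02d", i))
    })
  } else {
    lapply(config$sims, simulate_recording, layout = layout)
  }
  pooled <- NULL
  steps <- list()
  for (i in seq_along(recs)) {
    rec <- preprocess_recording(recs[[i]], max_gap = config$max_gap)
    phases <- crop_steady_state(segment_steps(rec, layout, config$params))
    if (!nrow(phases)) next
    idx <- phase_frames(phases, nrow(rec$frames))
    pooled <- rbind(pooled, rec$frames[idx, , drop = FALSE])
    steps[[length(steps) + 1L]] <-
      cbind(recording = i, phases)
  }
  if (is.null(pooled)) stop("no valid steady-state steps in any recording")
  list(recs = recs,
       pooled = pressure_recording(pooled, sample_rate = recs[[1]]$sample_rate,
                                   subject_id = "pooled", side = layout$side),
       steps = do.call(rbind, steps))
}

#' Run the full analysis pipeline
#'
#' Simulate or ingest recordings, preprocess, segment to steady-state
#' stance phases, pool the retained frames, compute the full-array
#' reference CoP, exhaustively evaluate sensor subsets, pick per-size
#' optima per target, and derive marginal gains, selection frequencies,
#' cross-performance tables and spatial error maps. Every artifact is
#' written as delimited text under `config$out_dir`, and a manifest of
#' output files with MD5 content hashes is written last: identical
#' configurations (and seeds) yield identical manifests.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the in-memory results (`evaluations`,
#'   `curves`, `gains`, `frequency`, `cross`, `manifest`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  layout <- config$layout
  written <- character()

  pools <- pool_recordings(config)
  utils::write.csv(pools$steps, out("steps.csv"), row.names = FALSE)
  written <- c(written, "steps.csv")

  pooled <- pools$pooled
  masks <- enumerate_subsets(nrow(layout$sensors), k = config$k_range)
  evals <- evaluate_all(pooled, layout, masks = masks,
                        fallback = config$fallback)
  utils::write.csv(evals, out("evaluations.csv"), row.names = FALSE)
  written <- c(written, "evaluations.csv")

  curves <- list()
  gains <- list()
  complete_k <- identical(config$k_range, seq(min(config$k_range),
                                              max(config$k_range)))
  for (target in config$targets) {
    curve <- best_per_k(evals, target, n = nrow(layout$sensors))
    curves[[target]] <- curve
    f <- sprintf("curve_%s.csv", target)
    utils::write.csv(as.data.frame(curve), out(f), row.names = FALSE)
    written <- c(written, f)
    if (complete_k && length(config$k_range) >= 2L) {
      g <- marginal_gains(curve, config$gain_threshold)
      gains[[target]] <- g
      f <- sprintf("gains_%s.csv", target)
      utils::write.csv(cbind(g$gains,
                             inflection_k = g$inflection_k,
                             threshold = g$threshold),
                       out(f), row.names = FALSE)
      written <- c(written, f)
    }
  }

  freq <- selection_frequency(curves,
                              intersect(config$frequency_k_range,
                                        config$k_range),
                              n = nrow(layout$sensors))
  utils::write.csv(data.frame(sensor = rownames(freq), freq,
                              check.names = FALSE),
                   out("selection_frequency.csv"), row.names = FALSE)
  written <- c(written, "selection_frequency.csv")

  cross <- list()
  gt <- compute_cop(pooled, layout, fallback = config$fallback)
  for (kk in intersect(config$cross_k, config$k_range)) {
    tab <- cross_performance(evals, kk, n = nrow(layout$sensors))
    cross[[as.character(kk)]] <- tab
    f <- sprintf("cross_performance_k%d.csv", kk)
    utils::write.csv(tab, out(f), row.names = FALSE)
    written <- c(written, f)
    for (r in seq_len(nrow(tab))) {
      ids <- as.integer(strsplit(tab$sensors[r], ",")[[1]])
      est <- compute_cop(pooled, layout, subset = ids,
                         fallback = config$fallback)
      emap <- spatial_error_map(gt, est, layout, grid = config$grid)
      f <- sprintf("errormap_k%d_%s.csv", kk, tab$target[r])
      utils::write.csv(as.data.frame(emap$values), out(f),
                       row.names = FALSE)
      written <- c(written, f)
    }
  }

  manifest <- data.frame(file = written,
                         md5 = unname(tools::md5sum(file.path(config$out_dir,
                                                              written))))
  utils::write.csv(manifest, out("manifest.csv"), row.names = FALSE)
  invisible(list(layout = layout, pooled = pooled, steps = pools$steps,
                 evaluations = evals, curves = curves, gains = gains,
                 frequency = freq, cross = cross, manifest = manifest))
}
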