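#!/usr/bin/env Rscript
# Step 4 — summary analyses.
#
# Marginal-gain curves with the 1.5 mm inflection rule, per-sensor
# selection frequencies over the optimal subsets (k = 2..15),
# cross-performance of the target-optimal 5- and 7-sensor layouts, and
# binned spatial error maps for the 5-sensor layouts.

library(insolecop)

layout <- load_layout("results/layout.yaml")
evals <- read.csv("results/evaluations.csv")
steps <- read.csv("results/steps.csv")
cohort <- read.csv("results/cohort.csv")

curves <- list()
for (target in c("X", "Y", "XY")) {
  curve <- best_per_k(evals, target)
  curves[[target]] <- curve
  g <- marginal_gains(curve, threshold = 1.5)
  write.csv(cbind(g$gains, inflection_k = g$inflection_k),
            sprintf("results/gains_%s.csv", target), row.names = FALSE)
  cat(sprintf("CoP-%s inflection: k = %s (adding a sensor beyond this gains < 1.5 mm)\n",
              target, ifelse(is.na(g$inflection_k), "none", g$inflection_k)))
}

freq <- selection_frequency(curves, k_range = 2:15)
write.csv(data.frame(sensor = rownames(freq), freq, check.names = FALSE),
          "results/selection_frequency.csv", row.names = FALSE)
cat("most-selected sensors per target:\n")
for (target in colnames(freq)) {
  top <- order(freq[, target], decreasing = TRUE)[1:4]
  cat(sprintf("  %s: %s\n", target,
              paste(sprintf("S%d (%d)", top, freq[top, target]),
                    collapse = ", ")))
}

for (kk in c(5, 7)) {
  tab <- cross_performance(evals, kk)
  write.csv(tab, sprintf("results/cross_performance_k%d.csv", kk),
            row.names = FALSE)
  cat(sprintf("\ncross-performance, k = %d:\n", kk))
  print(tab, digits = 3)
}

# error maps for the two distinct 5-sensor layouts (global/X vs Y optimal)
pooled <- NULL
for (sub in cohort$subject) {
  pp <- preprocess_recording(read_recording(
    file.path("results/recordings", paste0(sub, ".csv")), subject_id = sub))
  idx <- phase_frames(steps[steps$subject_id == sub, ], nrow(pp$frames))
  pooled <- rbind(pooled, pp$frames[idx, , drop = FALSE])
}
prec <- pressure_recording(pooled, sample_rate = 100)
gt <- compute_cop(prec, layout)
tab5 <- cross_performance(evals, 5)
for (r in c(1, 2)) {      # X/XY-optimal (identical or close) and Y-optimal
  ids <- as.integer(strsplit(tab5$sensors[r], ",")[[1]])
  est <- compute_cop(prec, layout, subset = ids)
  for (axis in c("X", "Y", "XY")) {
    emap <- spatial_error_map(gt, est, layout, axis = axis)
    write.csv(as.data.frame(emap$values),
              sprintf("results/errormap_k5_%sopt_%s.csv", tab5$target[r],
                      axis),
              row.names = FALSE)
  }
  cat(sprintf("error maps written for the %s-optimal 5-sensor layout {%s}\n",
              tab5$target[r], tab5$sensors[r]))
}
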