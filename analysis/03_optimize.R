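#!/usr/bin/env Rscript
# Step 3 — exhaustive subset search.
#
# Pools the steady-state stance frames of all subjects, takes the
# full-16-sensor barycentric CoP as the reference, and recomputes the CoP
# for every one of the 2^16 - 1 = 65,535 sensor subsets (excluded sensors
# weighted zero), scoring RMSE and P95 per axis and as the Euclidean
# distance. Optima per subset size are extracted for the three targets.

library(insolecop)

layout <- load_layout("results/layout.yaml")
cohort <- read.csv("results/cohort.csv")
steps <- read.csv("results/steps.csv")

pooled <- NULL
for (sub in cohort$subject) {
  rec <- read_recording(file.path("results/recordings", paste0(sub, ".csv")),
                        subject_id = sub)
  pp <- preprocess_recording(rec)
  ph <- steps[steps$subject_id == sub, ]
  idx <- phase_frames(ph, nrow(pp$frames))
  pooled <- rbind(pooled, pp$frames[idx, , drop = FALSE])
}
cat("pooled", nrow(pooled), "stance frames from", nrow(cohort), "subjects\n")
prec <- pressure_recording(pooled, sample_rate = 100, subject_id = "pooled")

t0 <- Sys.time()
evals <- evaluate_all(prec, layout)
cat(sprintf("evaluated %d subsets in %.1f s\n", nrow(evals),
            as.numeric(Sys.time() - t0, units = "secs")))
write.csv(evals, "results/evaluations.csv", row.names = FALSE)

for (target in c("X", "Y", "XY")) {
  curve <- best_per_k(evals, target)
  write.csv(as.data.frame(curve),
            sprintf("results/curve_%s.csv", target), row.names = FALSE)
  m <- curve[[paste0("rmse_", tolower(target))]]
  cat(sprintf("CoP-%s: best k=5 {%s} RMSE %.2f mm | best k=7 {%s} RMSE %.2f mm\n",
              target, curve$sensors[curve$k == 5], m[curve$k == 5],
              curve$sensors[curve$k == 7], m[curve$k == 7]))
}
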