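#!/usr/bin/env Rscript
# Step 2 — preprocess and segment every recording.
#
# Dropouts are filled by gap-limited linear interpolation (5 frames) with
# a zero-order hold fallback; steps are kept only if total force exceeds
# 15 N for at least 200 ms AND the full-array CoP performs a heel-to-toe
# roll-over; the first and last steps are discarded (steady state).

library(insolecop)

layout <- load_layout("results/layout.yaml")
cohort <- read.csv("results/cohort.csv")

all_steps <- NULL
for (i in seq_len(nrow(cohort))) {
  rec <- read_recording(file.path("results/recordings",
                                  paste0(cohort$subject[i], ".csv")),
                        subject_id = cohort$subject[i])
  pp <- preprocess_recording(rec)
  phases <- segment_steps(pp, layout)
  kept <- crop_steady_state(phases)
  cat(sprintf("%s: %d detected, %d steady-state\n", cohort$subject[i],
              nrow(phases), nrow(kept)))
  if (nrow(kept)) {
    all_steps <- rbind(all_steps, cbind(subject_id = cohort$subject[i], kept))
  }
}
write.csv(all_steps, "results/steps.csv", row.names = FALSE)
cat(sprintf("retained %d steady-state steps (%.1f +/- %.1f per subject)\n",
            nrow(all_steps),
            mean(table(all_steps$subject_id)),
            sd(table(all_steps$subject_id))))
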