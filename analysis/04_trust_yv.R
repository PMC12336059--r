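#!/usr/bin/env Rscript

# Step 4: venous oxygenation from the rendered TRUST data.
#
# For every subject and state: read the label/control series across
# effective TEs, subtract pairwise, pick the top-4 sinus voxels on the
# shortest-eTE difference image, fit the mono-exponential T2 decay and
# calibrate to venous oxygenation with the subject's sex-based hematocrit.

library(cvrquant)

in_dir <- "scratch/cohort"
cohort <- read.csv("results/ground_truth.csv")
calib <- trust_calibration()

rows <- lapply(seq_len(nrow(cohort)), function(i) {
  subj <- cohort[i, ]
  do.call(rbind, lapply(c("pre", "post"), function(st) {
    ser <- read_trust_series(file.path(in_dir, subj$subject_id, st))
    est <- estimate_yv(ser, subj$sex, calib = calib)
    data.frame(subject_id = subj$subject_id, group = subj$group, state = st,
               yv = est$yv * 100, t2 = est$t2, hct = est$hct,
               yv_true = subj[[paste0("yv_", st)]])
  }))
})
res <- do.call(rbind, rows)
write.csv(res, "results/yv_estimates.csv", row.names = FALSE)

agg <- aggregate(cbind(yv, yv_true) ~ group + state, res, mean)
message("Group-mean venous oxygenation (estimated vs true), percent:")
print(agg, digits = 3)
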