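#!/usr/bin/env Rscript

# Step 2: measure alignment angles.
#
# Reads the simulated landmark tree from step 1 (mirroring left knees back
# to canonical orientation), measures the femoro-tibial angle under all
# nine axis-definition combinations and the gold-standard hip-knee-ankle
# angle from the full-limb key points, and writes the long measurement
# tables under results/.

suppressPackageStartupMessages(library(kneealign))

in_dir <- "scratch/cohort"
if (!dir.exists(in_dir)) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

meas <- measure_cohort(in_dir, run_config())

write.csv(meas$fta, "results/measurements.csv", row.names = FALSE)
write.csv(meas$hkaa, "results/hkaa.csv", row.names = FALSE)

ok <- meas$fta$status == "ok"
cat(sprintf("Measured %d FTA values (%d definitions x %d cases); %d failures\n",
            sum(ok), length(unique(meas$fta$definition)),
            nrow(meas$hkaa), sum(!ok)))
agg <- aggregate(value_deg ~ definition, meas$fta[ok, ],
                 function(v) c(mean = mean(v), sd = sd(v)))
cat("Per-definition FTA mean (sd), degrees, varus negative:\n")
for (i in seq_len(nrow(agg))) {
  cat(sprintf("  %-10s %6.2f (%.2f)\n", agg$definition[i],
              agg$value_deg[i, "mean"], agg$value_deg[i, "sd"]))
}
cat(sprintf("Gold-standard HKAA: mean %.2f deg (sd %.2f)\n",
            mean(meas$hkaa$hkaa_deg), sd(meas$hkaa$hkaa_deg)))
cat("Wrote results/measurements.csv and results/hkaa.csv\n")
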