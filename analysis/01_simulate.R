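#!/usr/bin/env Rscript

# Step 1: simulate the study cohort.
#
# Builds a synthetic clinical cohort of 100 lower limbs (50 male / 50
# female; true HKAA ~ N(-2, 5^2) for males and N(0, 5^2) for females, so
# females skew valgus; landmark noise 9 px, see ?clinical_cohort_config)
# and writes it as a landmark-file tree: one knee outline (111-point
# schema) and one full-limb key-point file per case, plus meta.csv and the
# ground-truth table. Left-sided cases are stored in native (mirrored)
# orientation, as radiographs would be.

suppressPackageStartupMessages(library(kneealign))

seed <- 20260926L
out_dir <- "scratch/cohort"

cohort <- generate_cohort(100, clinical_cohort_config(), seed = seed)
write_cohort(cohort, out_dir)

tr <- cohort$truth
cat(sprintf("Simulated %d cases (seed %d) into %s\n", nrow(tr), seed, out_dir))
cat(sprintf("  sexes: %d male / %d female; sides: %d right / %d left\n",
            sum(tr$sex == "male"), sum(tr$sex == "female"),
            sum(tr$side == "right"), sum(tr$side == "left")))
cat(sprintf("  true HKAA: mean %.2f deg, sd %.2f, range %.1f to %.1f\n",
            mean(tr$true_hkaa_deg), sd(tr$true_hkaa_deg),
            min(tr$true_hkaa_deg), max(tr$true_hkaa_deg)))
by_sex <- tapply(tr$true_hkaa_deg, tr$sex, mean)
cat(sprintf("  mean by sex: male %.2f deg, female %.2f deg (females more valgus)\n",
            by_sex["male"], by_sex["female"]))
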