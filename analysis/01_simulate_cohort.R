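#!/usr/bin/env Rscript
# Generate the default synthetic experiment: 8 control (C) and 8 intervention
# (P) pigs on the 30-min grid from -60 to 240 min, trajectory mode. The
# P-group follows the staged pneumoperitoneum protocol (IAP 15 mmHg at t = 0,
# 30 mmHg at t = 120). Writes the raw-data CSVs consumed by the later steps.

library(iahfluid)

seed <- 1
ds <- simulate_cohort(8, 8, mode = "trajectory", master_seed = seed)
write_dataset(ds, "results/data")

cat("Synthetic cohort written to results/data (master seed", seed, ")\n")
cat(sprintf("  timepoints : %d rows (%d animals x %d grid times)\n",
            nrow(ds$timepoints), length(unique(ds$timepoints$animal_id)),
            length(unique(ds$timepoints$time))))
cat(sprintf("  co_dilution: %d records\n", nrow(ds$co_dilution)))
cat(sprintf("  microspheres: %d counts, tissue_water: %d samples\n",
            nrow(ds$microspheres), nrow(ds$tissue_water)))
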