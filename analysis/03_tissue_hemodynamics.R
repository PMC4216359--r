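#!/usr/bin/env Rscript
# Derived hemodynamic indices (SVR, PVR, CPP), circulating protein/albumin
# masses, microsphere regional blood flow with the kidney percent-reduction
# statistic, and gravimetric total tissue water.

library(iahfluid)

ds <- read_dataset("results/data")
rep <- run_pipeline(ds, verbose = FALSE)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

write.csv(rep$hemo_summary, "results/tables/hemodynamics_summary.csv",
          row.names = FALSE)
write.csv(rep$solutes, "results/tables/solute_masses.csv", row.names = FALSE)
write.csv(rep$flows, "results/tables/microsphere_flows.csv",
          row.names = FALSE)
write.csv(rep$flow_pct_change, "results/tables/flow_percent_change.csv",
          row.names = FALSE)
write.csv(rep$ttw_summary, "results/tables/tissue_water_summary.csv",
          row.names = FALSE)

hs <- rep$hemo_summary
base_c <- hs[hs$group == "C" & hs$time == 0, ]
cat(sprintf("C-group baseline SVR %.0f dynes s cm^-5, CPP %.1f mmHg\n",
            base_c$svr_mean, base_c$cpp_mean))
kid <- rep$flow_pct_change
for (g in c("C", "P")) {
  r <- kid[kid$group == g & kid$tissue == "left_kidney", ]
  cat(sprintf("Left-kidney flow reduction, %s-group: %.1f (%.1f) %%\n",
              g, r$pct_reduction_mean, r$pct_reduction_sd))
}
lw <- rep$ttw_summary[rep$ttw_summary$tissue == "lung", ]
cat(sprintf("Lung water C %.2f vs P %.2f g/g dry weight (Welch p = %.3f)\n",
            lw$c_mean, lw$p_mean, lw$p_welch))
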