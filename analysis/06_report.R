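#!/usr/bin/env Rscript
# Stage 6: assemble the per-region summary table and region contrasts.
#
# Joins disparity (stage 2), allometry (stage 3), model selection and rate
# (stage 4) and lability (stage 5) into one row per region -- the analogue
# of a "Table 2" for the synthetic study -- plus face-vs-braincase and
# cranium-vs-mandible ratio reports.

suppressMessages(library(morpholab))

disp <- read.csv("results/02_disparity.csv")
allo <- read.csv("results/03_allometry.csv")
fits <- read.csv("results/04_model_fits.csv")
lab <- read.csv("results/05_lability.csv")

best <- do.call(rbind, lapply(split(fits, fits$region), function(d)
  d[which.min(d$aic), ]))
tab <- Reduce(function(a, b) merge(a, b, by = "region"), list(
  disp[, c("region", "n", "P2")],
  allo[, c("region", "pct_var_size", "p_value")],
  best[, c("region", "model", "delta", "alpha", "sigma2_mult")],
  lab[, c("region", "respondability", "evolvability", "flexibility")]))
tab <- tab[match(c("face", "braincase", "cranium", "mandible"), tab$region), ]
write.csv(tab, "results/06_summary_table.csv", row.names = FALSE)
print(tab, digits = 3)

ratios <- rbind(compare_regions(tab, "face", "braincase"),
                compare_regions(tab, "cranium", "mandible"))
write.csv(ratios, "results/06_region_ratios.csv", row.names = FALSE)
cat("\nregion contrasts:\n")
print(ratios, digits = 3)
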