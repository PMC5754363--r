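#!/usr/bin/env Rscript
# Receptor-density scan: predicted enzyme activity as inert monomer dilutes
# the DNA handles at fixed 0.5 uM BTA-DNA.

suppressPackageStartupMessages(library(btarecruit))

fiber <- fiber_model()
enzyme <- recruited_species("enzyme", 20e-9, 1e-9)
inhibitor <- recruited_species("inhibitor", 20e-9, 10e-9)

densities <- c(0.0025, 0.005, 0.0075, 0.01, 0.025, 0.05, 0.1, 0.25)
scan <- density_scan(densities, 0.5e-6, fiber, enzyme, inhibitor)
print(scan, row.names = FALSE, digits = 4)

below <- scan$activity[scan$density_fraction == 0.0025]
above <- scan$activity[scan$density_fraction == 0.25]
cat(sprintf(
  "\npredicted activity rises from %.2f at 25%% BTA-DNA to %.2f at 0.25%%:\nonce the in-fiber inhibitor concentration falls below the 1.5 uM solution\nKi (crossover near 0.75%% density), templated inhibition is lost.\n",
  above, below))
cat("the empirical activity rise ABOVE 25% density (steric hindrance of\ncrowded handles) is deliberately not modelled.\n")

dir.create("results", showWarnings = FALSE)
write_table(scan, "results/density_scan.csv",
            provenance = list(stage = "density_scan",
                              fixed_btadna_M = 0.5e-6))
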