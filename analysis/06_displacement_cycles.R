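#!/usr/bin/env Rscript
# Reversible recruitment: cycling enzyme activity by alternating additions
# of toehold-bearing recruiter and fully complementary displacer.

suppressPackageStartupMessages(library(btarecruit))

fiber <- fiber_model()
comp <- assembly_composition(0.5e-6, 1.5e-6)
enzyme <- recruited_species("enzyme", 0, 1e-9, has_toehold = TRUE)
inhibitor <- recruited_species("inhibitor", 20e-9, 10e-9)

# each iteration adds a twofold excess over the previous stage
steps <- data.frame(strand = rep(c("R_ET", "D"), 3),
                    amount = c(20e-9, 40e-9, 80e-9, 160e-9, 320e-9, 640e-9))
out <- displacement_cycle(steps, comp, fiber, enzyme, inhibitor)
print(out, row.names = FALSE, digits = 4)
cat(sprintf(
  "\nactivity alternates between ~%.2f (recruited) and exactly 1 (displaced)\nover three cycles: stoichiometric displacement fully releases the enzyme.\nthe attenuation seen experimentally at high strand loads is not modelled.\n",
  mean(out$activity[out$strand == "R_ET"])))

dir.create("results", showWarnings = FALSE)
write_table(out, "results/displacement_cycles.csv",
            provenance = list(stage = "displacement"))
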