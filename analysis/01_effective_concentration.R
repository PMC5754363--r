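#!/usr/bin/env Rscript
# Cylinder effective-concentration model: how strongly do the fibers
# concentrate a nanomolar protein, and how does receptor density tune it?

suppressPackageStartupMessages(library(btarecruit))

fiber <- fiber_model() # r = 15 nm, h = 0.452 nm/monomer
bulk <- 10e-9          # 10 nM inhibitor protein

# Calibration: the axial rise that makes 10 nM bulk on 2 uM BTA fibers an
# in-fiber 26 uM
comp25 <- assembly_composition(0.5e-6, 1.5e-6)
h <- calibrate_axial_rise(26e-6, bulk, comp25)
cat(sprintf("calibrated axial rise: %.4f nm/monomer (default %.3f)\n",
            h, fiber$axial_rise))

# Receptor-density sweep at fixed 0.5 uM BTA-DNA (0.25%..100%)
densities <- c(0.0025, 0.005, 0.0075, 0.01, 0.05, 0.25, 1)
tab <- do.call(rbind, lapply(densities, function(d) {
  comp <- assembly_composition(0.5e-6, 0.5e-6 / d - 0.5e-6)
  data.frame(density_fraction = d,
             total_bta_uM = comp$total * 1e6,
             ceff_uM = effective_concentration(bulk, comp, fiber) * 1e6,
             fold = fold_enhancement(bulk, comp, fiber))
}))
print(tab, row.names = FALSE, digits = 4)
cat(sprintf(
  "at 25%% BTA-DNA the 10 nM inhibitor is concentrated %.0f-fold to %.1f uM;\n",
  tab$fold[tab$density_fraction == 0.25],
  tab$ceff_uM[tab$density_fraction == 0.25]))
cat(sprintf(
  "at 0.75%% it is diluted to %.2f uM, below the 1.5 uM solution Ki.\n",
  tab$ceff_uM[tab$density_fraction == 0.0075]))

# Mean spacing of 11 nM recruited protein (1 nM enzyme + 10 nM inhibitor)
spacing <- mean_protein_spacing(11e-9, comp25, fiber)
cat(sprintf(
  "mean inter-protein spacing on 2 uM BTA fibers: %.0f nm -> complexes need\nprotein redistribution along the fiber, not static proximity.\n",
  spacing))

dir.create("results", showWarnings = FALSE)
write_table(tab, "results/effective_concentration.csv",
            provenance = list(stage = "effective_concentration",
                              bulk_inhibitor_M = bulk,
                              radius_nm = fiber$radius,
                              axial_rise_nm = fiber$axial_rise))
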