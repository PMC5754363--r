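#!/usr/bin/env Rscript
# Kinetics: substrate-turnover traces with their initial rates, the slow
# monomer-exchange relaxation, and the fast/slow timescale separation.

suppressPackageStartupMessages(library(btarecruit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 11L

kin <- enzyme_kinetics()

# Assay-style trace set: controls fully active, assembled system inhibited
fiber <- fiber_model()
comp <- assembly_composition(0.5e-6, 1.5e-6)
act_plus <- normalized_activity(comp, fiber,
                                recruited_species("enzyme", 20e-9, 1e-9),
                                recruited_species("inhibitor", 20e-9, 10e-9))
fracs <- c(minus_inhibitor = 1, minus_RE = 1, minus_RI = 1, minus_BTA = 1,
           plus = act_plus)
traces <- generate_trace_set(fracs, kin = kin,
                             noise = noise_model(sd_fluorescence = 0.05,
                                                 seed = seed))
rates <- vapply(traces, initial_rate, numeric(1))
norm <- normalize_rates(rates, rates[["minus_inhibitor"]])
cat("normalized initial rates per condition:\n")
print(round(norm, 3))
cat(sprintf("only the fully assembled system is inhibited (predicted %.3f).\n\n",
            act_plus))

# Slow monomer-exchange relaxation: noisy series, fixed-endpoint fit
t_grid <- seq(0, 5, length.out = 11)
series <- generate_exchange_series(t_grid, a0 = 0.3, a_inf = 1, t_half = 3,
                                   noise = noise_model(sd_activity = 0.03,
                                                       seed = seed))
fit <- fit_exchange(series$time_h, series$activity, a0 = 0.3, a_inf = 1)
cat("monomer-exchange relaxation fit:\n")
print(fit)

# Timescale separation
cat(sprintf(
  "\nduplex unbinding half-time %.1f s << protein equilibration (minutes)\n<< monomer exchange t1/2 %.1f h: protein redistribution is duplex-mediated.\n",
  redistribution_halftime(kin), fit$t_half))

dir.create("results", showWarnings = FALSE)
write_table(series, "results/exchange_series.csv",
            provenance = list(stage = "exchange", seed = seed,
                              t_half_truth_h = 3))
write_table(data.frame(condition = names(norm), normalized_rate = unname(norm)),
            "results/trace_rates.csv",
            provenance = list(stage = "traces", seed = seed))
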