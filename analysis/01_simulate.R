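#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Emulates one screening campaign: an ANTS-loaded, gramicidin-doped LUV
# preparation (130 nm, PDI 0.09), stopped-flow sessions for the drug-free
# control and two example drugs (a near-inert one and a potent bilayer
# modifier), and a 400-drug library table whose CC20 values are
# stochastically coupled to the planted bilayer-modifying potency.

suppressPackageStartupMessages(library(bilayerscreen))
dir.create("results", showWarnings = FALSE)
seed <- 1L

pop <- simulate_luv_population(3000, seed = seed)
print(pop)
cat(sprintf("empirical PDI %.3f (requested 0.09)\n\n", compute_pdi(pop)))

sessions <- list(control = 1, inert_drug = 1.07, potent_drug = 11.9)
for (name in names(sessions)) {
  nr <- sessions[[name]]
  traces <- c(
    lapply(1:8, function(i) simulate_quench_trace(
      pop, mix_type = "buffer", replicate_id = paste0("b", i),
      seed = seed * 1000 + i)),
    lapply(1:10, function(i) simulate_quench_trace(
      pop, drug_normrate = nr, replicate_id = paste0("q", i),
      seed = seed * 1000 + 100 + i)))
  dir <- file.path("results", paste0("session_", name))
  write_trace_session(traces, dir)
  cat(sprintf("%s session (planted NormRate %.2f): 8 buffer + 10 quencher -> %s\n",
              name, nr, dir))
}

lib <- simulate_drug_library(400, seed = seed)
write_drug_table(lib, "results/drug_library.csv")
cat(sprintf("\nlibrary: %d drugs, %d with CC20, potency split %s -> results/drug_library.csv\n",
            nrow(lib), sum(!is.na(lib$cc20)),
            paste(table(categorize_normrate(lib$true_normrate)), collapse = "/")))
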