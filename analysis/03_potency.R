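#!/usr/bin/env Rscript
# Step 3: convert fitted rates into per-drug potency quantities.
#
# NormRate against the control session, potency category, bilayer
# free-energy shift, and the equilibrium aqueous/membrane concentrations at
# the 10 uM screening concentration. Also illustrates the linear
# concentration extrapolation of the drug-induced excess.

suppressPackageStartupMessages(library(bilayerscreen))

rates <- read.csv("results/session_rates.csv")
cntrl <- rates$rate[rates$session == "control"]
drugs <- rates[rates$session != "control", ]

pot <- do.call(rbind, lapply(seq_len(nrow(drugs)), function(i) {
  cbind(session = drugs$session[i],
        potency_result(drugs$rate[i], cntrl, alogp = c(2.1, 4.5)[i]))
}))
write.csv(pot, "results/potency.csv", row.names = FALSE)
print(pot, digits = 3)
cat(sprintf("\ncontrol rate %.2f 1/s; NormRates %.2f (inert) and %.1f (potent)\n",
            cntrl, pot$normrate[1], pot$normrate[2]))
cat(sprintf("potent drug at 5 uM (linear extrapolation): NormRate %.2f\n",
            scale_normrate(pot$normrate[2], 10e-6, 5e-6)))
cat("wrote results/potency.csv\n")
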