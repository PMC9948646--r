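#!/usr/bin/env Rscript
# Step 2: fit the quench model to every quencher-mix trace.
#
# Each session's quencher traces are fitted individually (2 ms - 1 s window,
# K_SV = 60 1/M, [Tl+]e = 25 mM fixed), outliers are fenced out by the MAD
# rule, and the session rate is the mean over the surviving fits. Writes the
# per-trace fit report and the per-session rate table.

suppressPackageStartupMessages(library(bilayerscreen))

sessions <- c("control", "inert_drug", "potent_drug")
report <- list(); rates <- list()
for (name in sessions) {
  traces <- read_trace_session(file.path("results", paste0("session_", name)))
  qu <- Filter(function(tr) attr(tr, "mix_type") == "quencher", traces)
  f0b <- mean(vapply(Filter(function(tr) attr(tr, "mix_type") == "buffer",
                            traces),
                     function(tr) mean(tr$signal), numeric(1)))
  fits <- lapply(qu, function(tr) fit_trace(tr, f0b = f0b))
  fits <- reject_bad_traces(fits)
  report[[name]] <- data.frame(
    session = name,
    replicate = vapply(qu, function(tr) attr(tr, "replicate_id"), character(1)),
    rate0 = vapply(fits, function(f) f$rate0, numeric(1)),
    beta = vapply(fits, function(f) f$params$beta, numeric(1)),
    tau0 = vapply(fits, function(f) f$params$tau0, numeric(1)),
    r2 = vapply(fits, function(f) f$r2, numeric(1)),
    flags = vapply(fits, function(f) paste(f$qc_flags, collapse = ";"),
                   character(1)))
  rates[[name]] <- data.frame(session = name, rate = session_rate(fits),
                              mean_r2 = mean(report[[name]]$r2))
  kept <- sum(!grepl("outlier_rejected|fit_failure", report[[name]]$flags))
  cat(sprintf("%s: session rate %.2f 1/s, mean r2 %.3f, %d/%d traces kept\n",
              name, rates[[name]]$rate, rates[[name]]$mean_r2,
              kept, length(fits)))
}
write.csv(do.call(rbind, report), "results/fit_report.csv", row.names = FALSE)
write.csv(do.call(rbind, rates), "results/session_rates.csv", row.names = FALSE)
cat("wrote results/fit_report.csv and results/session_rates.csv\n")
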