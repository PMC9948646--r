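# Shared fixture builders (all generated in code; no stored data).

# Dense sample grid matching the instrument: 5000 points/s over 1 s with the
# pre-deadtime samples dropped.
trace_grid <- function(duration = 1, sample_rate = 5000, deadtime = 1.2e-3) {
  tt <- seq(0, duration, by = 1 / sample_rate)
  tt[tt >= deadtime]
}

# Quencher-mix trace generated directly from the closed-form quench model,
# optionally with Gaussian noise.
model_trace <- function(params, noise_sd = 0, seed = 1L,
                        tt = trace_grid()) {
  set.seed(seed)
  y <- predict_fluorescence(tt, params) + stats::rnorm(length(tt), 0, noise_sd)
  fluorescence_trace(tt, y)
}

# Small drug table with known composition for binning / share tests.
toy_drug_table <- function() {
  data.frame(
    id = sprintf("D%02d", 1:8),
    alogp = c(2, 2, 4, 4, 2, 4, 4, 2),
    psa = c(50, 90, 50, 90, 60, 80, 95, 70),
    qed = c(0.9, 0.4, 0.6, 0.3, 0.7, 0.45, 0.2, 0.8),
    pscore = c(0, 50, 120, 350, 10, 280, 400, 90),
    cc20 = c(80, 30, 5, 50, NA, 9, 60, 12),
    normrate = c(0.8, 1.1, 1.25, 1.5, 1.3, 2.0, 1.49, 1.0),
    stringsAsFactors = FALSE
  )
}
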