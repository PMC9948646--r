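#' Simulate a drug-library table with potency-coupled cytotoxicity
#'
#' Generates a synthetic screening library shaped like a 400-compound
#' antiparasitic box: per-drug physicochemical descriptors (ALogP, PSA, QED,
#' pScore), a ground-truth bilayer-modifying potency (`true_normrate`), a
#' duplicate-measurement NormRate with its half-range dispersion, and an
#' HepG2 CC20 value stochastically coupled to the true potency so the
#' downstream odds-ratio analysis has recoverable structure.
#'
#' True NormRates are lognormal; the defaults (`meanlog = log(1.25)`,
#' `sdlog = 0.39`) put about 50% of drugs below NormRate 1.25, 18% in
#' \[1.25, 1.5), and 32% at or above 1.5, the composition observed in the
#' screened library. The probability that a drug is likely cytotoxic
#' (CC20 < 50 uM) follows a logistic curve in log(true_normrate),
#' `plogis(coupling_intercept + coupling_slope * log(true_normrate))`; the
#' defaults give roughly 0.62 at NormRate 1.1 rising to 0.90 at NormRate 2,
#' with overall event probability near 0.71. Conditional on the event, CC20
#' is log-uniform on (0.1, 50) uM, otherwise log-uniform on (50, 120) uM
#' truncated at 80 uM (the database truncation). `missing_cc20` drugs get a
#' missing CC20 (default 3, leaving 397 of 400 with toxicity data).
#'
#' Descriptors are coupled to potency only through the `*_coupling`
#' arguments: ALogP weakly positive by default (r^2 below 0.1, as observed),
#' QED weakly negative, PSA and pScore uncoupled.
#'
#' @param n_drugs Number of drugs (>= 1). Default 400.
#' @param meanlog,sdlog Lognormal parameters of `true_normrate`.
#' @param coupling_slope Logistic slope linking log(true_normrate) to
#'   P(CC20 < 50 uM). 0 decouples cytotoxicity from potency. Default 2.85.
#' @param coupling_intercept Logistic intercept. Default 0.22.
#' @param missing_cc20 Number of drugs with missing CC20. Default 3.
#' @param measurement_cv Coefficient of variation of a single NormRate
#'   measurement; duplicates are summarized as mean and half-range. Default
#'   0.07, the typical duplicate spread of the assay.
#' @param alogp_coupling,qed_coupling Linear couplings of the descriptors to
#'   log(true_normrate).
#' @param cc20_truncation Upper truncation of CC20 (uM). Default 80.
#' @param seed Integer seed.
#' @return A data.frame of class `drug_library` with columns `id`, `alogp`,
#'   `psa`, `qed`, `pscore`, `cc20`, `fu_mouse`, `fu_mic`, `normrate`,
#'   `normrate_disp`, `disp_kind`, `true_normrate`. Entirely synthetic.
#' @export
simulate_drug_library <- function(n_drugs = 400,
                                  meanlog = log(1.25), sdlog = 0.39,
                                  coupling_slope = 2.85,
                                  coupling_intercept = 0.22,
                                  missing_cc20 = 3,
                                  measurement_cv = 0.07,
                                  alogp_coupling = 0.8,
                                  qed_coupling = 1.2,
                                  cc20_truncation = 80,
                                  seed = 1L) {
  stopifnot(n_drugs >= 1, missing_cc20 >= 0, missing_cc20 <= n_drugs)
  if (!is.finite(sdlog) || sdlog < 0) stop("invalid `sdlog`")
  if (!is.finite(coupling_slope)) stop("invalid `coupling_slope`")
  set.seed(seed)

  true_nr <- stats::rlnorm(n_drugs, meanlog, sdlog)
  lnr <- log(true_nr)

  # duplicate measurements -> mean +/- half-range
  r1 <- true_nr * (1 + stats::rnorm(n_drugs, 0, measurement_cv))
  r2 <- true_nr * (1 + stats::rnorm(n_drugs, 0, measurement_cv))
  r1 <- pmax(r1, 0.05); r2 <- pmax(r2, 0.05)
  normrate <- (r1 + r2) / 2
  normrate_disp <- abs(r1 - r2) / 2

  p_tox <- stats::plogis(coupling_intercept + coupling_slope * lnr)
  event <- stats::runif(n_drugs) < p_tox
  cc20 <- ifelse(event,
                 10^stats::runif(n_drugs, -1, log10(50)),
                 10^stats::runif(n_drugs, log10(50), log10(120)))
  cc20 <- pmin(cc20, cc20_truncation)
  if (missing_cc20 > 0) cc20[sample.int(n_drugs, missing_cc20)] <- NA_real_

  alogp <- stats::rnorm(n_drugs, 3.2, 1.1) + alogp_coupling * lnr
  psa <- pmax(stats::rnorm(n_drugs, 85, 30), 1)
  qed <- stats::plogis(stats::rnorm(n_drugs, 0.4, 1.0) - qed_coupling * lnr)
  pscore <- round(stats::rlnorm(n_drugs, log(60), 1.1))

  out <- data.frame(
    id = sprintf("SYN%04d", seq_len(n_drugs)),
    alogp = alogp, psa = psa, qed = qed, pscore = pscore,
    cc20 = cc20,
    fu_mouse = stats::rbeta(n_drugs, 2, 1),
    fu_mic = stats::rbeta(n_drugs, 2, 1),
    normrate = normrate,
    normrate_disp = normrate_disp,
    disp_kind = "half_range",
    true_normrate = true_nr,
    stringsAsFactors = FALSE
  )
  class(out) <- c("drug_library", "data.frame")
  out
}
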