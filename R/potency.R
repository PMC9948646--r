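#' Quench rate normalized to the drug-free control
#'
#' `NormRate = Rate_drug(0) / Rate_cntrl(0)`, the bilayer-modifying-potency
#' statistic: values above 1 mean the drug shifts the gramicidin
#' monomer-dimer equilibrium toward conducting dimers (bilayer softening),
#' values below 1 toward monomers (stiffening). The ratio is reported
#' unclipped.
#'
#' @param rate_drug Initial quench rate with drug (1/s).
#' @param rate_cntrl Drug-free control rate (1/s), > 0.
#' @return NormRate (dimensionless), vectorized over `rate_drug`.
#' @export
norm_rate <- function(rate_drug, rate_cntrl) {
  stopifnot(is.numeric(rate_drug), is.numeric(rate_cntrl))
  if (any(rate_cntrl <= 0)) stop("`rate_cntrl` must be > 0")
  rate_drug / rate_cntrl
}

#' NormRate in the presence of albumin
#'
#' Same ratio as [norm_rate()] but against the BSA-only control,
#' `NormRate_BSA = Rate_drug+BSA(0) / Rate_BSA(0)`. A NormRate_BSA below the
#' plain NormRate indicates the drug binds albumin, reducing its free
#' aqueous concentration.
#'
#' @param rate_drug_bsa Rate with drug plus BSA (1/s).
#' @param rate_bsa BSA-only control rate (1/s), > 0.
#' @return NormRate_BSA (dimensionless).
#' @export
norm_rate_bsa <- function(rate_drug_bsa, rate_bsa) {
  norm_rate(rate_drug_bsa, rate_bsa)
}

#' Gas constant in kcal/(mol K)
#' @keywords internal
R_KCAL <- 1.9872e-3

#' Drug-induced change in the bilayer dimerization energy
#'
#' The shift in the bilayer contribution to the gramicidin dimerization free
#' energy, approximated from the normalized quench rate:
#' \deqn{\Delta\Delta G_{bilayer} \approx -RT \ln(NormRate),}
#' valid when the monomer-dimer equilibrium is strongly biased toward
#' monomers in both conditions (as in thick DC22:1PC bilayers), so the
#' monomer pool is essentially unchanged by the drug. Negative values mean
#' softening (equilibrium shifted toward dimers).
#'
#' @param normrate NormRate (> 0), vectorized.
#' @param temperature Temperature in K. Default 298.15 (25 C).
#' @return Free-energy shift in kcal/mol.
#' @export
delta_delta_g <- function(normrate, temperature = 298.15) {
  stopifnot(is.numeric(normrate))
  if (any(normrate <= 0)) stop("`normrate` must be > 0")
  -R_KCAL * temperature * log(normrate)
}

#' Potency category from NormRate
#'
#' The screen's three potency bands: low (NormRate < 1.25, including
#' NormRates below 1), moderate (1.25 <= NormRate < 1.5), and high
#' (1.5 <= NormRate); both boundaries belong to the upper band.
#'
#' @param normrate NormRate values (> 0).
#' @param edges Category boundaries. Default `c(1.25, 1.5)`.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @seealso [display_normrate()] for the reciprocal display of NormRates < 1.
#' @export
categorize_normrate <- function(normrate, edges = c(1.25, 1.5)) {
  stopifnot(all(normrate > 0), length(edges) == 2, edges[1] < edges[2])
  cut(normrate, breaks = c(0, edges, Inf),
      labels = c("low", "moderate", "high"), right = FALSE)
}

#' Display transform for NormRates below 1
#'
#' For plotting, NormRates below 1 (stiffening) are shown as their
#' reciprocal so potency magnitude reads the same in both directions.
#'
#' @param normrate NormRate values (> 0).
#' @return `normrate` where >= 1, `1/normrate` otherwise.
#' @export
display_normrate <- function(normrate) {
  stopifnot(all(normrate > 0))
  ifelse(normrate < 1, 1 / normrate, normrate)
}

#' Membrane/water partition coefficient from ALogP
#'
#' Approximates the partition coefficient K1 = \[Drug\]m / \[Drug\]a by the
#' antilog of the calculated log-partition descriptor, K1 = 10^ALogP.
#'
#' @param alogp Calculated hydrophobicity descriptor.
#' @return K1 (dimensionless).
#' @export
k1_from_alogp <- function(alogp) 10^alogp

#' Aqueous and membrane drug concentrations at equilibrium
#'
#' Mass-balance partitioning of the nominal drug concentration between the
#' aqueous and lipid phases:
#' \deqn{[Drug]_a = \frac{[Drug]_{nom}}{1 + K_1 V_{lip}/V_{aq}}, \qquad
#'       [Drug]_m = K_1 [Drug]_a.}
#' As K1 grows, \[Drug\]m saturates at \[Drug\]nom / (V_lip/V_aq) (about
#' 0.278 M for 10 uM nominal at the default volume ratio).
#'
#' @param nominal Total (nominal) drug concentration (M), vectorized.
#' @param k1 Partition coefficient (>= 0), e.g. [k1_from_alogp()].
#' @param vlip_over_vaq Lipid/aqueous volume ratio (> 0). Default 3.6e-5, the
#'   ratio for a 50 uM lipid suspension in the quench assay.
#' @return A data.frame with columns `drug_aq` and `drug_mem` (M); row-wise
#'   mass balance `drug_aq + drug_mem * vlip_over_vaq = nominal` holds
#'   exactly.
#' @export
partition_concentrations <- function(nominal, k1, vlip_over_vaq = 3.6e-5) {
  stopifnot(all(k1 >= 0), vlip_over_vaq > 0, all(nominal >= 0))
  aq <- nominal / (1 + k1 * vlip_over_vaq)
  data.frame(drug_aq = aq, drug_mem = k1 * aq)
}

#' Rescale a NormRate to another nominal concentration
#'
#' Linearized concentration extrapolation: the drug-induced excess
#' (NormRate - 1) is treated as proportional to the aqueous drug
#' concentration, so
#' `NormRate(c2) = 1 + (NormRate(c1) - 1) * c2/c1`. This is an explicit
#' first-order approximation, adequate for modest extrapolations around the
#' screening concentration.
#'
#' @param normrate_at_c1 NormRate measured at concentration `c1`.
#' @param c1 Reference concentration (> 0), any unit.
#' @param c2 Target concentration, same unit.
#' @return Extrapolated NormRate at `c2`.
#' @export
scale_normrate <- function(normrate_at_c1, c1, c2) {
  stopifnot(all(c1 > 0))
  1 + (normrate_at_c1 - 1) * (c2 / c1)
}

#' Per-drug potency summary
#'
#' Convenience wrapper combining the per-drug potency quantities: NormRate,
#' category, free-energy shift, and equilibrium aqueous/membrane
#' concentrations.
#'
#' @param rate_drug,rate_cntrl Initial rates (1/s).
#' @param alogp ALogP descriptor (for K1). Optional.
#' @param nominal Nominal drug concentration (M). Default 10e-6.
#' @param temperature Temperature (K). Default 298.15.
#' @param vlip_over_vaq Lipid/aqueous volume ratio. Default 3.6e-5.
#' @return A one-row data.frame with `normrate`, `category`, `ddg`
#'   (kcal/mol), `drug_aq`, `drug_mem` (M; NA when `alogp` missing).
#' @export
potency_result <- function(rate_drug, rate_cntrl, alogp = NA_real_,
                           nominal = 10e-6, temperature = 298.15,
                           vlip_over_vaq = 3.6e-5) {
  nr <- norm_rate(rate_drug, rate_cntrl)
  if (is.finite(alogp)) {
    pc <- partition_concentrations(nominal, k1_from_alogp(alogp), vlip_over_vaq)
  } else {
    pc <- data.frame(drug_aq = NA_real_, drug_mem = NA_real_)
  }
  data.frame(normrate = nr,
             category = categorize_normrate(nr),
             ddg = delta_delta_g(nr, temperature),
             drug_aq = pc$drug_aq, drug_mem = pc$drug_mem)
}
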