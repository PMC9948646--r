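# bilayerscreen

Analytics for gramicidin-based screens of **bilayer-modifying potency** —
a fast biophysical predictor of membrane-mediated off-target effects and
likely cytotoxicity of drugs and drug-like molecules.

Many bioactive molecules are amphiphiles that partition into lipid bilayers
and change their elastic properties, indiscriminately perturbing membrane
proteins and, at sufficient magnitude, causing cytotoxicity. The screen
quantifies this through the gramicidin monomer↔dimer equilibrium:
fluorophore (ANTS)-loaded, gramicidin-doped large unilamellar vesicles are
stopped-flow mixed with the channel-permeant quencher Tl⁺, and the
fluorescence quench rate reports the number of conducting channels. The
package implements the full analysis chain for such screens:

* **Forward model** — Stern–Volmer quenching driven by a modified stretched
  exponential for Tl⁺ influx into a dispersed vesicle population,

  F(t)/F(0) = 1 / (1 + K_SV·[Tl⁺]ₑ·(1 − exp{1 − (1 + t/τ₀)^β})),

  with the three-compartment decomposition (extravesicular / quenchable /
  unquenchable) and the initial rate
  Rate(0) = (1 + K_SV[Tl⁺]ₑ)·β/τ₀ (= 2.5·β/τ₀ at K_SV = 60 M⁻¹,
  [Tl⁺]ₑ = 25 mM).
* **Trace fitting** — bounded nonlinear least squares on the 2 ms–1 s
  window, per-trace QC flags, MAD-fenced outlier rejection, duplicate /
  triplicate replicate summaries.
* **Potency** — NormRate = Rate_drug(0)/Rate_cntrl(0), potency categories
  (1.25/1.5 band edges), ΔΔG_bilayer ≈ −RT·ln NormRate, albumin-normalized
  rates, and aqueous/membrane drug concentrations from mass-balance
  partitioning with K₁ ≈ 10^ALogP.
* **Cohort statistics** — half-open binning, 2×2 odds ratios with Woolf
  intervals, probability-versus-bin curves, exact/tie-corrected
  Mann–Whitney tests with Bonferroni correction, 1.5·IQR box summaries,
  silhouette cluster diagnostics, r².
* **Synthetic data** — LUV populations (130 nm, PDI 0.09), stopped-flow
  traces with analytic rate oracles, and 400-drug library tables with a
  planted potency–cytotoxicity coupling, so the entire pipeline is testable
  without instrument data.

## Worked example

Simulate a vesicle preparation, record a control and a drug trace, fit
them, and convert to potency:

```r
library(bilayerscreen)

pop <- simulate_luv_population(3000, d_mean = 130, pdi = 0.09, seed = 1)
ctrl <- fit_trace(simulate_quench_trace(pop, seed = 101))
drug <- fit_trace(simulate_quench_trace(pop, drug_normrate = 11.9, seed = 102))
ctrl$rate0
#> [1] 2.67445
drug$rate0
#> [1] 33.72093
potency_result(drug$rate0, ctrl$rate0, alogp = 4.5)
#>   normrate category       ddg     drug_aq  drug_mem
#> 1 12.60855     high -1.501576 4.67635e-06 0.1478792
```

The drug raises the quench rate ~12.6-fold (a *high*-potency bilayer
modifier), corresponding to a −1.5 kcal/mol shift of the bilayer
contribution to the dimerization free energy; at 10 µM nominal, partition
equilibrium leaves 4.7 µM in water and ~148 mM in the membrane phase.

The published screen's aggregate tables are reproduced from their printed
counts:

```r
bil <- counts_to_odds(published_screen_counts()$bilayer)
round(bil$odds, 2)
#> [1] 0.16 0.52 1.38 1.71
bil$or
#> OR = 10.804 (95% CI 4.139-28.201); odds 1.706 vs 0.158
```

Drugs with high ALogP (> 3) **and** high PSA (> 75 Å²) have ~11-fold higher
odds of being bilayer-modifying (NormRate ≥ 1.25) than drugs low on both.

## Analysis workflow

The `analysis/` scripts run the whole campaign on synthetic data, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # LUV population, trace sessions, drug library
Rscript analysis/02_fit_traces.R   # per-trace fits, QC, session rates
Rscript analysis/03_potency.R      # NormRate, category, ΔΔG, partitioning
Rscript analysis/04_cohort.R       # odds tables, probability curves, group tests
```

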