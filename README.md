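# dsnboot

Endpoint derivation and noninferiority inference for G-CSF trials in
chemotherapy-induced neutropenia.

Myelosuppressive chemotherapy depresses the absolute neutrophil count (ANC)
into a trough toward the end of each 21-day cycle; long-acting granulocyte
colony-stimulating factors (G-CSFs) blunt it.  Dose-ranging trials of new
G-CSFs compare each dose against an active control (pegfilgrastim) on
**duration of severe neutropenia (DSN)** in Cycle 1 — the days from the first
observed ANC < 0.5 × 10⁹/L to the first recovery to ≥ 2.0 × 10⁹/L — under a
noninferiority design.  `dsnboot` is for trial statisticians and
reproducibility-minded readers of such studies: it turns longitudinal CBC
records collected under the protocol's adaptive monitoring schedule into
protocol endpoints, and tests arms against control exactly as such designs
specify.

At its core:

* **Endpoints** from an observed series {(dᵢ, ANCᵢ)}: DSN; time to ANC
  recovery (first ANC ≥ 2.0 after the nadir, among patients who dipped
  below 2.0); nadir depth and time; febrile neutropenia (temp > 38.2 °C
  within 1 day of ANC < 0.5).
* **Inference**: the difference in mean DSN, Δ̂ = x̄ₑ − x̄꜀, with a bootstrap
  stratified by baseline weight (<65, 65–75, >75 kg) — each of N = 10,000
  replicates resamples patients within every arm × stratum cell at its
  observed size.  Reported: the 95 % percentile CI, the noninferiority
  P-value `min(1, 2·#{Δ* > 1}/N)`, the superiority P-value
  `min(1, 2·#{Δ* > 0}/N)`, and the decision *noninferior ⇔ CI upper
  limit < 1 day*.
* **Design**: analytic power Φ(δ/(σ√(1/nE+1/nC)) − z₀.₉₅) and its simulation
  counterpart, plus minimal sample sizes; with σ = 2.1 days and 108:36
  allocation this recovers the "80 % power with 144 patients" planning claim
  (79.7 %).
* **Simulation**: latent ANC curves as baseline × three Gaussian day-kernels
  (Day-3 stimulation, Day-7 suppression, Day-11.5 rebound) with
  dose-potency trade-off and lognormal noise, thinned through the adaptive
  CBC schedule (Days 1–3, twice-weekly grid, daily while ANC < 1.5).
* **Fixture**: `reference_cohort()` rebuilds a patient-level cohort whose
  Cycle-1 DSN distribution equals the published frequency rows of the
  dose-ranging study the package models, for golden-value validation.

## Worked example

```r
library(dsnboot)

co  <- reference_cohort()           # published Cycle-1 DSN distribution
cmp <- compare_arms(co, "eflapegrastim_270", "pegfilgrastim",
                    spec = bootstrap_spec(n_resamples = 10000, seed = 20180323))
print(cmp)
#> DSN comparison, cycle 1: eflapegrastim_270 (n=36) vs pegfilgrastim (n=36)
#>   mean DSN 0.03 vs 0.31; difference -0.28 days, 95% CI (-0.56, -0.03)
#>   P(noninferiority) = 0.000, P(superiority) = 0.012; NONINFERIOR (margin 1 day)
#>   [10000 stratified resamples, seed 20180323]
```

The high dose averages 0.03 days of severe neutropenia versus 0.31 on
control; the whole 95 % CI for the difference sits below zero, so the dose
is not merely noninferior at the 1-day margin (upper limit −0.03 < 1) but
superior (P = 0.012).  The published analysis reports the same difference
(−0.28), an interval of (−0.56, −0.06), and the same two decisions; CI
endpoints are method-uncertain at the second decimal because the trial's
realized weight strata and bootstrap CI flavour are unpublished.

The numbered scripts under `analysis/` run the full workflow and write
tables under `results/`: `01_simulate_cohort.R` (synthetic four-arm cohort
under the adaptive schedule), `02_reference_reproduction.R` (cell-by-cell
reproduction of the published Cycle-1 analysis; 37/37 cells pass),
`03_power.R` (power verification and sample-size tables).

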