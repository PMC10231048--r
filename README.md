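# psir — insecticide resistance surveillance for mosquito vectors

`psir` is a decision-support toolkit for public-health entomologists and
vector-control programmes running territory-scale surveillance of
insecticide resistance. It takes the raw records such a programme
produces — WHO tube/bottle bioassays at the diagnostic concentration (DC)
and at 5×/10× intensity, larval dose–response series, synergist (PBO)
assays, genotype samples and a sentinel-site registry — and turns them
into:

* **single-assay indicators** — Abbott-corrected mortality with the WHO
  control-validity rules, adult emergence inhibition (EI%) for insect
  growth regulators, and the three-way synergist-test interpretation;
* **dose–response estimates** — log-probit LC50/IE50 with delta-method
  confidence intervals (heterogeneity-adjusted), and the resistance ratio
  RR50 against a susceptible reference strain, from the model
  P(response | c) = Φ(α + β·log₁₀ c), LC50 = 10^(−α/β);
* **population classification** — the 0–3 resistance level per (site,
  species, insecticide): ≥ 98% DC mortality ⇒ susceptible (level 0, or 1
  if resistance alleles are detected); < 98% at 5× but ≥ 98% at 10× ⇒
  moderate (level 2); < 98% at 10× ⇒ strong (level 3); RR50 < 5 / 5–10 /
  > 10 on the larval route;
* **territory stratification** — the Risk-of-Resistance score (RiR 0–3)
  from the cumulative proportion of sentinel sites at or above each
  level, binned as isolated (< 10%), multiple (10–50%) or majority
  (> 50%), plus the matched surveillance and vector-control action
  bundle;
* **design tools** — sampling-design validators (site counts, ovitrap
  density, breeding-site spacing by haversine, genotyping sample sizes,
  survey recency), the allele-detection probability 1 − (1 − p)^(2n), and
  the tipping-point calculator for geometric allele growth;
* **a seeded synthetic-data generator** with known ground truth, so the
  whole pipeline is testable end to end without field data.

## Worked example

A field population assayed at the DC (72/100 dead, 8/100 control deaths),
at 5× (91%) and at 10× (99%), with a temephos larval series:

```r
library(psir)

corrected_mortality(72, 100, 8, 100)
#> <mortality_result> 69.57% (raw 72.00%, control 8.00%, Abbott-corrected)

interpret_synergist(69.6, 91, 69.6)
#> <synergist_outcome> partial_restoration (delta +21.4 points)

s <- larval_series("MRT-S01", "Aedes aegypti", "temephos",
  concentration = c(0.01, 0.02, 0.05, 0.1, 0.2),
  n_exposed = rep(100, 5), n_responded = c(4, 17, 52, 88, 99),
  control_n_exposed = 100, control_n_responded = 1)
fit_probit(s)
#> <probit_fit> MRT-S01 / Aedes aegypti / temephos
#>   slope 3.008, LC50 = 0.04276 mg/L (95% CI 0.03817-0.0479), heterogeneity 1.00

classify_adult(dc = corrected_mortality(72, 100, 8, 100), dc5x = 91, dc10x = 99,
               site_id = "MRT-S01", species = "Aedes aegypti",
               insecticide = "deltamethrin")
#> <population_classification> MRT-S01 / Aedes aegypti / deltamethrin
#>   level 2 (moderate_resistance)
```

The corrected DC mortality (69.6%) is well under 98%, so the population
is resistant; it is controlled at 10× but not 5×, hence moderate
resistance (level 2). The synergist test says detoxification enzymes
explain part — not all — of that phenotype. One moderate site among 12
otherwise-susceptible sites puts the territory at RiR 1 (isolated level-2
population):

```r
cls <- c(list(cl), lapply(2:12, function(i) classify_adult(dc = 99, ...)))
stratify(cls, territory_id = "MRT")
#> <territory_assessment> MRT / Aedes aegypti / deltamethrin
#>   RiR 1 (driver level 2); 12 site(s) assessed, 0 excluded
#>   sites at level >= 1/2/3: 8% / 8% / 0%
```

with the RiR 1 action bundle (strengthened monitoring; vector control
unchanged; start drafting a local resistance-management plan). Design
aids:

```r
detection_probability(50, 0.01)   # 0.634 — why >= 50 individuals are genotyped
generations_to_fixation(0.02, 2)  # 6 — a 2% allele doubling per generation
```

The full pipeline (`run_pipeline()`) runs validation → assay statistics →
probit fits → classification → stratification → recommendations on a
directory of CSVs and writes per-territory JSON reports plus summary
tables. The same stages are exposed as a CLI
(`inst/cli/psir simulate|validate|fit|classify|stratify|report`).

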