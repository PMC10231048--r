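---
title: "Methods: from bioassay counts to territory risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bioassay counts to territory risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psir)
```

# The surveillance problem

Vector-control programmes apply a small set of public-health insecticides
(e.g. deltamethrin against adult mosquitoes, *Bti* against larvae) over
large areas, and resistance erodes their efficacy faster than new actives
arrive. The package implements a two-tier surveillance workflow:

1. **Population level.** At fixed sentinel sites, standardised WHO
   bioassays, molecular genotyping and synergist tests classify each
   (site, species, insecticide) population on a 0–3 resistance scale:
   susceptible; susceptible but carrying resistance alleles (the *tipping
   point*); moderate resistance; strong resistance.
2. **Territory level.** The prevalence of resistant sites across a
   territory — an area homogeneous enough that one management strategy
   applies — is converted into a Risk-of-Resistance score (RiR 0–3), which
   indexes a graded bundle of surveillance and vector-control actions.

All inputs are stored as raw counts, never pre-computed percentages, so
corrections are exact and auditable.

# Single-assay indicators

**Corrected mortality.** Treated-arm mortality is corrected for natural
(control) mortality by Abbott's formula, under the WHO validity
convention: control mortality above 20% voids the test; between 5% and
20% the correction $M' = 100\,(M - C)/(100 - C)$ is applied; below 5% the
raw mortality is used. `corrected_mortality()` is monotone in the death
count and clamps to $[0, 100]$.

**Emergence inhibition.** For insect growth regulators, the larval
endpoint is the proportion of exposed larvae that fail to emerge as adults
relative to the control: $EI = 100\,(1 - E_T/E_C)$. A zero control
emergence rate leaves the indicator undefined and is an error, not a 100%.

**Synergist tests.** When mortality at the diagnostic concentration (DC)
is below 90% (resistance confirmed), comparing mortality with and without
a detoxification-enzyme inhibitor (e.g. PBO) splits the phenotype into
full restoration (combined mortality ≥ 98%: purely metabolic), partial
restoration (< 98% but more than 10 points above the insecticide alone)
and no restoration. Two readings were open here and are fixed as package
policy: "10% higher" is treated as 10 *percentage points*, strictly
greater, because the complementary class is worded "not more than 10%
higher"; and since no guidance exists on whether synergist arms are
Abbott-corrected, the pipeline corrects **both** arms identically whenever
control counts are available, so the comparison is internally consistent.

# Log-probit dose–response

Larval series are modelled as $P(\text{response} \mid c) =
\Phi(\alpha + \beta \log_{10} c)$ with $LC_{50} = 10^{-\alpha/\beta}$
(IE50 for emergence-inhibition endpoints, fitted identically on
EI-corrected counts). Numerical choices:

* Maximum likelihood via iteratively reweighted least squares
  (`stats::glm`, probit link), log-likelihood tolerance $10^{-8}$, at most
  100 iterations, on control-corrected response proportions weighted by
  the exposed counts.
* 95% CI on $\log_{10} LC_{50}$ by the delta method, back-transformed.
  The delta method was preferred to Fieller's theorem for simplicity and
  transparency; with 5 well-spaced concentrations of $n = 100$ the two are
  near-indistinguishable, and the simulation suite verifies ≥ 90%
  coverage empirically.
* Over-dispersion (Pearson $\chi^2/\mathrm{df} > 1$) inflates the CI
  variance by the heterogeneity factor and switches to a $t$ quantile —
  standard probit-analysis practice.
* Degenerate series (all-0 or all-100 response) carry no information
  about the median and return `converged = FALSE` rather than an estimate;
  a negative fitted slope is treated as a data error (mislabelled
  concentrations). Series need at least 4 distinct concentrations — a
  floor chosen so the 2-parameter model retains residual degrees of
  freedom for the heterogeneity check.

The resistance ratio $RR_{50}$ is the LC50 of the field population over
that of the susceptible reference strain run in parallel; it is
scale-equivariant in concentration units by construction.

# Population classification

The adult decision cascade compares corrected mortalities to the printed
thresholds exactly as written (≥ 98% susceptible; < 98% resistant; 90–98%
additionally "suspected — confirm"):

| Pattern | Level |
|---|---|
| DC ≥ 98%, no markers | 0 |
| DC ≥ 98%, marker frequency > 0 | 1 (tipping point) |
| DC < 98%, 5× ≥ 98% | 1 (low) |
| DC < 98%, 5× < 98%, 10× ≥ 98% | 2 |
| DC < 98%, 10× < 98% | 3 |

Three gaps in the published rules required package policy. (i) The
pattern "resistant at DC, susceptible at 5×" is mapped to level 1 with a
`low_resistance` label, consistent with the low/moderate/high intensity
ladder; the label is retained so users can re-bin. (ii) "Present at low
frequency" carries no numeric bound, so **any** positive estimated allele
frequency in a bioassay-susceptible population triggers level 1; an upper
bound would be arbitrary and the stratifier is only sensitive to the
level, not the frequency. (iii) Missing intensity data yields an explicit
`unresolved` state with a provisional level never above what the evidence
supports (level 2 when 5× < 98% is known, else level 1) and a
`confirm_with_intensity_tests` flag — never a guessed definitive level.
Larval RR50 thresholds are closed on the moderate interval
($5 \le RR_{50} \le 10$) as printed. When both routes are available,
`merge_evidence()` takes the maximum level, definitive as soon as a
resolved route backs it.

# Territory stratification

For each level $l \in \{1,2,3\}$ the stratifier computes the cumulative
proportion $q_l$ of assessed sites at level ≥ $l$, bins it (isolated
< 10%, multiple 10–50%, majority > 50%) and reads a candidate score from
the 4 × 3 matrix (`rir_matrix()`); the territory's RiR is the maximum
candidate. The *cumulative* reading, with the maximum over rows, is a
deliberate design choice: it is the only reading that reproduces both the
matrix and every textual attribution rule simultaneously (a single
level-3 site among level-0 sites must give RiR 2; "frequency of sites
with the highest levels" read as a single row cannot). Two boundary
policies: exactly 10% falls in the "multiple" bin (the matrix's "10–50%"
label wins over the ">10%" phrasing of the prose), and exactly 50% stays
"multiple". Both cut points are configurable (`psir_config()`), since the
guidance values are explicitly adjustable per vector species and
territory configuration; every report echoes the thresholds used.
Unresolved sites are excluded from the denominator rather than imputed,
and the report states how many were excluded.

Recommendations are a deterministic lookup on the RiR, with two riders:
derogatory-substance identification is flagged from RiR 2 and operational
use only at RiR 3, and any single level-3 site appends a local-hotspot
note regardless of the territory score.

# Design validators and allele dynamics

`validate_design()` checks the sampling prescriptions: ≥ 10 sentinel
sites per territory, ≥ 4 ovitraps/ha, ≥ 10 breeding-site locations ≥
100 m apart (haversine on WGS84 via geosphere; missing coordinates make
the rule *not assessable*, not failed), ≥ 30 wild-caught females behind
an F1 colony, ≥ 50 genotyped individuals per marker, and a survey within
365 days ("at least once a year" under ISO dates).

`detection_probability()` is the closed form $1 - (1-p)^{2n}$ under
independent chromosome draws; genotyping 50 individuals detects a
1%-frequency allele with probability 0.634. Relatedness among
field-caught individuals (which shrinks the effective chromosome count)
is acknowledged but not modelled — the spacing rule above is the field
mitigation. `generations_to_fixation()` uses uncapped geometric growth
with fixation at frequency ≥ 1, $\lceil \log(1/p_0)/\log r \rceil$: the
only reading under which an allele at 2% that doubles each generation
fixes in six generations. This is a deliberately crude envelope — real
selection decelerates near fixation — used as an early-warning
illustration, not a forecast.

# The synthetic-data generator

`generate_dataset()` draws a complete campaign from known ground truth so
every downstream stage is testable without field data. Level-conditional
parameters (chosen once as field-realistic):

| Level | E[DC] | E[5×] | E[10×] | allele freq | larval RR |
|---|---|---|---|---|---|
| 0 | 99.8% | 99.9% | 100% | 0 | 1 |
| 1 | 99.5% | 99.9% | 100% | 0.02 | 1 |
| 2 | 70% | 90% | 99.5% | 0.20 | 7 |
| 3 | 40% | 70% | 90% | 0.50 | 20 |

The level-1 allele frequency is the canonical 2% tipping point; the
reference strain has LC50 0.05 mg/L with probit slope 3 per decade, and
series place 5 concentrations log-spaced ±0.8 decades around the true
LC50. Control arms respond at 1%. Defaults use 100 individuals per arm
(a realistic field test); the `"high-n"` preset uses 500, at which
misclassification probabilities are negligible and end-to-end ground-truth
recovery is near-deterministic. Genotyping defaults to 50 individuals per
site — matching the design rule — which is also why a level-1 site is
occasionally read as level 0: a 2% allele escapes a 50-individual sample
with probability $0.98^{100} \approx 0.13$. That is a property of the
sampling design, not a bug, and it rarely moves the territory score.

Randomness is seeded through per-record substreams keyed by (territory,
site, assay), so adding a site leaves all other draws unchanged and the
same seed reproduces files byte-for-byte.

What the generator does **not** emulate: spatial autocorrelation and gene
flow between sites, temporal dynamics, assay-operator effects, related
individuals within collections, and deviations from Hardy–Weinberg in
genotype draws. Passing tests therefore demonstrate that the *rules* are
implemented correctly and recoverable under sampling noise — not that
field data will be as clean.

# Problem sizes used in the automated checks

The packaged test-suite simulations are sized for a laptop-class single
core: 200 seeded replicates for LC50 recovery and CI calibration
(n = 100 × 5 concentrations), a $10^6$-draw Monte-Carlo cross-check of the
detection-probability closed form, exhaustive integer-grid sweeps of the
classification and synergist rule surfaces, and 50 seeded end-to-end
pipeline runs on 20-site high-n territories.

# Known limitations

* LC90/LC99 and time–mortality models are out of scope.
* Diagnostic concentrations ship only as a placeholder template; users
  must supply authoritative values for their species and assay type.
* The classifier treats marker evidence as binary (present/absent); no
  frequency threshold separates levels beyond the bioassay.
* The RiR machinery weights every sentinel site equally; site
  representativeness is handled by the design validators, not the score.
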