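# psadpathways

Risk-stratified biopsy decision analysis for suspected prostate cancer:
evaluate diagnostic pathways that combine MRI suspicion scores (PI-RADS)
with PSA density (PSAD) risk bands, and compare them by decision-curve
analysis.

## Who this is for

Urology/radiology researchers and biostatisticians who want to test biopsy
triage rules of the form "biopsy if PI-RADS ≥ x, or PI-RADS = y and
PSAD ≥ z" on patient-level cohorts — measuring how many biopsies each rule
avoids, how many clinically significant cancers it misses, and how much
insignificant-cancer overdiagnosis it prevents — and to weigh those
trade-offs formally with net-benefit curves.

## The model

Patients carry a PI-RADS score (1–5) and a PSA density
PSAD = PSA / prostate volume (ng/mL²), banded as

| band | PSAD |
|---|---|
| low | < 0.10 |
| intermediate | 0.10 – 0.15 |
| high | 0.15 – 0.20 |
| very high | ≥ 0.20 |

Ground truth from biopsy histology: ISUP grade group ≥ 2 is clinically
significant cancer (csPCa), grade group 1 is insignificant cancer (iPCa),
a benign biopsy or no biopsy (with follow-up) is negative.

A *pathway* is an ordered list of rules over the 5 × 4 grid of
(PI-RADS, PSAD band) with first-match semantics and a mandatory default.
Four pathways are built in: `biopsy_all`, `mri_focused` (biopsy iff
PI-RADS ≥ 3), `risk_low` (PI-RADS 1–2 at PSAD ≥ 0.20, PI-RADS 3 at
PSAD ≥ 0.10, PI-RADS 4–5 always) and `risk_high` (PI-RADS 3 at
PSAD ≥ 0.20, PI-RADS 4–5 always).

Pathways are compared by decision-curve analysis. At threshold probability
p_t (the minimum cancer probability at which a decision-maker accepts a
biopsy), the net benefit of a strategy with TP true positives (csPCa
detected) and FP false positives (biopsies without csPCa) among N patients
is

```
NB(p_t) = TP/N − (FP/N) · p_t / (1 − p_t)
```

Two fixed strategies cross at p_t\* = ΔTP / (ΔTP + ΔFP), and
`dominance_intervals()` reports which strategy is optimal over each range
of p_t.

Because real patient records for the motivating cohort are not public, the
package ships a calibrated generator: `fixture_cohort()` expands a
12-cell contingency specification (2055 patients; 623 csPCa; 196 iPCa,
allocated by a small constraint solve) into a deterministic patient-level
cohort reproducing every cell exactly, and `sample_cohort()` draws
stochastic cohorts with the same cell probabilities for simulation
studies.

## Worked example

```r
library(psadpathways)

cohort <- fixture_cohort(default_cohort_spec(), seed = 1)
cross_tabulate(cohort)
#> <cspca_crosstab> 2055 patients, 623 csPCa (30.3%)
#>  pirads_group            low    intermediate           high       very_high
#>           1-2   7/602 (1.2%)    9/341 (2.6%)   9/100 (9.0%)    9/70 (12.9%)
#>             3   8/76 (10.5%)    9/63 (14.3%)  10/40 (25.0%)    9/27 (33.3%)
#>           4-5 50/112 (44.6%) 115/172 (66.9%) 99/129 (76.7%) 289/323 (89.5%)

outcomes <- outcome_table(cohort, builtin_pathways())
outcomes[, c("pathway", "n_avoided", "cspca_detected", "cspca_missed",
             "ipca_detected")]
#>   pathway     n_avoided cspca_detected cspca_missed ipca_detected
#> 1 biopsy_all          0            623            0           196
#> 2 mri_focused      1113            589           34           150
#> 3 risk_low         1119            590           33           151
#> 4 risk_high        1292            562           61           120
```

Reading a row: `risk_low` spares 1119/2055 = 54.5% of men a biopsy while
missing 33/2055 = 1.6% of significant cancers and cutting iPCa
overdiagnosis from 196 to 151.

```r
strategies <- purrr::map_dfr(seq_len(nrow(outcomes)), function(i)
  strategy_counts_from_outcome(outcomes[i, ]))
curve <- decision_curves(strategies)
dominance_intervals(curve)
#> <dominance_report>
#>   [0.000, 0.029] biopsy_all
#>   [0.030, 0.161] risk_low
#>   [0.162, 0.600] risk_high
#>   crossovers:
#>     biopsy_all / risk_low at p_t = 0.0295
#>     risk_low / risk_high at p_t = 0.1618
```

So below a 2.9% threshold probability biopsy-all has the highest net
benefit, the low-threshold risk pathway dominates up to ~16%, and the
high-threshold pathway beyond that. `plot_decision_curves(curve)` draws
the figure.

Cohorts round-trip through a documented CSV schema
(`patient_id, age, psa, prostate_volume, psad, pirads, biopsied,
isup_grade_group, followup_months, study_date`; booleans `true`/`false`,
empty = missing) via `read_cohort_csv()` / `write_cohort_csv()`, and
custom pathways can be defined in YAML via `parse_pathway_config()`. A
command-line wrapper with `simulate` / `evaluate` / `dca` subcommands is
at `inst/cli/psadpathways.R`.

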