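---
title: "Evaluating PI-RADS × PSA-density biopsy pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating PI-RADS × PSA-density biopsy pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psadpathways)
```

## The problem

Multiparametric MRI has become the first test for men with suspected
prostate cancer, but there is no single accepted rule for who should then
proceed to biopsy. Biopsying everyone maximises cancer detection at the
cost of many negative procedures and overdiagnosis of indolent (ISUP grade
group 1) disease; an MRI-only rule (biopsy iff PI-RADS ≥ 3) avoids about
half of biopsies but ignores the substantial risk gradient *within* each
PI-RADS category that PSA density (PSAD = PSA / prostate volume, ng/mL²)
captures. Risk-adapted pathways combine the two: a PI-RADS 3 lesion in a
man with PSAD 0.05 carries roughly the same significant-cancer risk as a
negative MRI, while PI-RADS 1–2 with PSAD above 0.20 does not.

This package evaluates such pathways on patient-level cohorts and compares
them formally with decision-curve analysis.

## Data model and assumptions

A cohort is a tibble with one row per patient: `patient_id`, `age`, `psa`,
`prostate_volume`, `psad`, `pirads` (1–5), `biopsied`, `isup_grade_group`
(0 = benign, 1–5 = ISUP group; absent when not biopsied),
`followup_months`, `study_date`. Validation enforces the invariants:
unique ids, PI-RADS in 1..5, positive PSAD consistent with
`psa/prostate_volume` to a relative 1e-6 when both routes are present
(a supplied `psad` column wins; inconsistency is an error, not a silent
preference), and grade groups only for biopsied men.

Ground truth follows the standard histological rule: ISUP ≥ 2 is
clinically significant cancer (csPCa), ISUP 1 insignificant (iPCa), benign
biopsy negative. Men without a biopsy are *presumed negative* — the
convention used when non-biopsied men have ≥ 6 months of PSA follow-up.
This is an assumption, not an observation: any csPCa in the non-biopsied
group deflates the missed-cancer counts of restrictive pathways. A
`strict_biopsied_truth` flag in `validate_cohort()` instead restricts
analysis to biopsied men for sensitivity checks; it is off by default
because the headline avoidance/missed rates are defined over the whole
cohort.

PSAD bands are half-open on the right: low [0, 0.10), intermediate
[0.10, 0.15), high [0.15, 0.20), very high [0.20, ∞). Published clinical
descriptions are ambiguous at the boundaries (the same cut-point appears
as "0.15–0.20" and "> 0.20" in different places); we fix the convention
that a boundary value belongs to the *higher* band, matching the "≥ 0.20"
column heading of the prevalence tables this package is calibrated
against. The boundaries live in the single exported constant
`psad_band_breaks`, so the convention is changeable in one place. The
synthetic generator additionally keeps every simulated PSAD strictly
inside its band, so no generated analysis depends on the tie-break.

## The pathway rule engine

A pathway is an ordered rule list over the 5 × 4 (PI-RADS, band) grid with
first-match semantics and a mandatory default decision, so every pathway
is total by construction and user configs cannot be accidentally partial
(a config without a default is rejected rather than patched). The four
built-ins:

```{r builtins}
builtin_pathways()[["risk_low"]]
```

The low-threshold pathway's PI-RADS 3 criterion is "PSAD ≥ 0.10", i.e.
intermediate band and above; its PI-RADS 1–2 criterion "> 0.20" maps to
the very-high band under the half-open convention. These readings are the
ones that reproduce the published avoidance and missed-cancer counts
(1119 and 33 of 2055) exactly, which is why we adopted them where the
published rule table is typographically ambiguous.

`apply_pathway()` evaluates the expanded 5 × 4 decision grid
(`pathway_grid()`) by indexing, and the test suite checks it cell-by-cell
against a brute-force first-match interpreter.

## Outcome metrics

`pathway_outcomes()` intersects decisions with disease status. All primary
rates use the full cohort size N as denominator — the convention that
makes avoidance, missed-csPCa and detection rates directly comparable
across pathways; per-biopsy rates are provided as secondary columns.

"Negative biopsy" has two defensible accountings and published tables mix
them: `negative_biopsies` counts biopsied men with *no cancer of any
grade*, while `fp_non_cspca` counts biopsied men *without significant
cancer* (i.e. benign plus iPCa). For the comparator biopsy-all arm the
published negative-biopsy cell (1236/2055, 60.1%) is the benign-only
count; for the three selective pathways the published cells (353, 346,
201) equal biopsied-minus-csPCa, i.e. `fp_non_cspca`. We report both and
let the user pick.

Pairwise pathway comparisons use Pearson's chi-square on the 2 × 2 table
`[count, N − count]` per pathway, without continuity correction by default
(N is large; Yates' correction is available via `correct = TRUE`).
P-values are reported at full precision and unadjusted — the package
performs no multiplicity correction because the comparisons are
descriptive, not confirmatory.

## Decision-curve analysis

At threshold probability $p_t$, net benefit is
$$NB(p_t) = \frac{TP}{N} - \frac{FP}{N}\cdot\frac{p_t}{1-p_t},$$
where TP = csPCa detected. The FP convention defaults to
`biopsied_non_cspca` — a biopsy that does not find significant cancer is
the harm, so iPCa detection counts as a false positive (overdiagnosis);
`benign_only` is available as the alternative. The strategies here are
*fixed decision sets*, so each curve is a single hyperbola in $p_t$; no
per-patient risk model is fitted, and bootstrap bands or standardised net
benefit are out of scope.

The default grid is 0–0.6 in steps of 0.001. Crossovers between strategies
are solved in closed form, $p_t^\* = \Delta TP / (\Delta TP + \Delta FP)$,
and `dominance_intervals()` verifies them against the grid argmax (they
must agree within one grid step; exact ties are reported as comma-joined
strategy names). References `treat_all` / `treat_none` are added
automatically; when a supplied strategy already biopsies everyone, the
treat-all reference coincides with it.

On the calibrated fixture the computed crossovers are 33/1119 ≈ 2.95%
(biopsy-all / risk-low) and 28/173 ≈ 16.2% (risk-low / risk-high). The
motivating analysis, run on the original patient-level records with an
external DCA package, reported 3.6% and 13.9%; those values are not
reproducible from the published aggregate counts under either FP
convention, so this package reports its own closed-form crossovers rather
than forcing agreement.

## The synthetic-cohort generator

The generator emulates a 2055-man biopsy-naïve cohort summarised by a
3 × 4 contingency table of patient and csPCa counts
(PI-RADS group × PSAD band), a PI-RADS score split (15 / 1098 / 206 /
238 / 498 for scores 1–5), 196 iPCa cases, an ISUP grade-group
distribution within csPCa of 339 / 124 / 47 / 113 for groups 2–5, and
median (IQR) age 65 (59–69) years, PSA 6.31 (4.65–9.12) ng/mL, volume
54.7 (38–79) mL. Where two published marginals disagree by one patient
(268/421 vs 269/420 in the top two PSAD bands), the spec follows the
internally consistent cell-level table.

`fixture_cohort()` is deterministic in structure: cell membership, disease
labels and grade groups are fixed; only continuous attributes are seeded
draws. Per-cell iPCa counts are not published, so they are solved from
four aggregate constraints (the iPCa detected by the MRI-focused,
low-threshold and high-threshold pathways — 150, 151, 120 — and the total
196) over six strata. The system is underdetermined by two degrees of
freedom, fixed at zero iPCa in the PI-RADS 3 low and very-high bands (the
two smallest strata); the resulting allocation (45, 1, 0, 30, 0, 120) is a
*calibrated derivation*, not an observation, and is labelled as such.
Grade groups within csPCa are assigned greedily, higher grades to
higher-risk cells — a plausibility heuristic with no effect on any
reported metric, which depends only on the csPCa/iPCa/negative
trichotomy.

Continuous attributes use log-normal PSA-density and volume matched to
the published medians and IQRs (σ from the IQR ratio), with PSAD drawn
from the band-truncated distribution via inverse-CDF sampling and PSA
derived as PSAD × volume so the consistency invariant holds exactly.
Only band membership is exact; marginal medians/IQRs are approximate and
no test asserts them. Biopsy flags mirror the presumed-negative design:
all PI-RADS 3–5 men and all PI-RADS 1–2 men with cancer are biopsied,
the rest followed ≥ 6 months.

`sample_cohort()` replaces the exact expansion with multinomial cell
draws and per-cell binomial disease draws, for property tests and
Monte-Carlo work. What passing tests on these cohorts shows is that the
*pipeline* is correct under the calibrated structure; they cannot show
that the structure generalises — real cohorts differ in prevalence,
PI-RADS 3 call rates, reader quality and the unknowable status of
non-biopsied men.

## Numerical choices and problem sizes

Banding and rule evaluation are exact integer/lookup operations; the only
tolerances are the 1e-6 relative PSAD-consistency check, the 1e-12 tie
tolerance in dominance argmax, and CSV round-trip equality at 1e-9 for
reals. The test suite exercises sampled cohorts of 200–2055 patients (one
20 000-patient recovery check), and the sampler-statistics check in the
acceptance suite runs 200 seeds at n = 2055 — sizes chosen to keep
binomial standard errors small relative to the effects being checked
while the whole suite stays fast on a laptop.

## Known limitations

Patient-level, index-lesion analysis only (no per-lesion structures, no
MRI acquisition modelling); no survival/follow-up modelling beyond the
presumed-negative rule; fixed-strategy DCA only; the iPCa placement and
grade-group heuristic inside cells are calibrated conveniences; era
sub-analyses are supported only generically via the `study_date` column.
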