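---
title: "Methods: pooled genetic-association analysis with genemeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled genetic-association analysis with genemeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemeta)
```

## The model and its assumptions

genemeta pools case-control genotype data for one variant at a time. Each
study contributes a genotype triple per arm — risk-allele homozygotes,
heterozygotes, other-allele homozygotes — which is collapsed to a 2×2
exposure table under one of three genetic models. The allele model counts
chromosomes (a heterozygous person contributes one risk and one other
allele; the heterozygote column is never split fractionally), the dominant
and recessive models count persons. The allele model's unit change means
its table total is twice the person total; dominance patterns are read off
the person-level models instead.

Assumptions inherited from this design:

- **Independence of studies.** Overlapping cohorts violate it; the input
  schema carries an explicit `superseded_by` column so a re-analysed cohort
  can name the record it replaces, and the reader excludes the superseded
  record from all analysis totals. We chose an explicit column over silent
  de-duplication because which cohort supersedes which is a judgement the
  analyst must record, not something derivable from the data.
- **Allele-level independence within person** (allele model only): exact
  under Hardy–Weinberg equilibrium in each arm. A chi-square HWE
  diagnostic (`hwe_test`) is provided for control arms but is deliberately
  not an exclusion filter.
- **Large-sample normality of log OR** per study, which degrades with zero
  cells — hence the continuity correction below.

Per-study effects are Woolf-type: `OR = ad/bc`,
`SE = sqrt(1/a + 1/b + 1/c + 1/d)`. Fixed-effects pooling is
Mantel–Haenszel with the Robins–Breslow–Greenland variance; random-effects
pooling is DerSimonian–Laird on inverse-variance log ORs. These estimator
choices mirror the defaults of the widely used dedicated meta-analysis GUI
software for dichotomous outcomes, so results are comparable to the bulk
of the published candidate-gene literature; the inverse-variance fixed
estimator is also exported (`pool_fixed_iv`) for comparison because GUI
analyses do not record which fixed estimator was clicked. No Peto OR,
Hartung–Knapp adjustment or REML τ² are offered.

The pooling method is selected *per variant × group × genetic model* by
the disjunctive heterogeneity rule: fixed effects if `p_Q > 0.1` **or**
`I² ≤ 50%`, random effects otherwise. Both comparisons are implemented
exactly as written (strict `>`, inclusive `≤`).

## Tunable parameters

| Parameter | Default | Unit | Why this default |
|---|---|---|---|
| `tier1` | 0.05 | p-value | conventional significance; defines "recommended" |
| `tier2` | 1e-5 | p-value | defines "most recommended"; exposed as a parameter because it originates as the display floor of the GUI software rather than a principled constant |
| `min_studies` | 4 | studies | eligibility for the overall pooled analysis |
| `subgroup_min_studies` | 2 | studies | subgroup analyses need ≥2 studies to pool; whether the ≥4 rule also applies within subgroups is not settled in the source procedure, so it is configuration (`apply_min_to_subgroups`), not a guess |
| continuity correction | +0.5 | count | added to all four cells of any table with a zero cell, per study, including inside the MH sums; double-zero tables are excluded as non-informative sentinels |
| CI quantile | 1.96 | — | normal 95% interval (not t), matching the estimator theory |
| `stability_tolerance` | 0.2 | relative OR change | leave-one-out "stability" is otherwise qualitative; 20% is reported with the verdict, never silently applied |
| `control_af` | 0.40 | frequency | a common-variant frequency at which power calculations are typical |
| `true_or` | 1.30 | odds ratio | the magnitude of replicated common-variant associations (published pooled ORs for the variants this emulates span 0.77–1.53) |
| `n_cases_range`, `n_controls_range` | 100–5000 | persons | span of study sizes in published case-control rosters (roughly 100 to 5300 per arm) |
| `ethnicity_weights` | 20:13:1:1:1 /36 | — | the East Asian / European / Latino / Mixed / West Asian composition of a 36-study roster |
| `between_study_sd` | 0 | SD of log OR | homogeneous by default; 0.3 reliably triggers the random-effects branch at k = 15 |

Classification thresholds are strict inequalities throughout: a p-value
exactly at a cutoff falls in the weaker tier. Printed summary tables use a
`"<0.00001"` display convention for p below `tier2`; this is presentation
only — classification always uses the raw double, and when only a censored
printed value is available (`snca_reference()`), it is treated as strictly
below its bound, which determines the tier exactly because the bound
coincides with `tier2`.

## What the synthetic generator emulates — and what it does not

`simulate_study` draws control genotypes multinomially from HWE
proportions (q², 2q(1−q), (1−q)²) at the ethnicity-specific control
allele frequency, then tilts the control distribution by genotype odds —
multiplicative (ψ², ψ, 1), dominant (ψ, ψ, 1) or recessive (ψ, 1, 1) —
renormalises, and draws case genotypes multinomially. This is a logistic
disease model on genotype odds and is exact: it does not rely on a
rare-disease approximation. Per-study heterogeneity is log-normal on ψ.
Reproducibility uses one master seed with a fixed counter scheme for
per-study substreams, so study *i* is byte-identical whether simulated
alone or within a dataset, and dataset generation never perturbs the
caller's RNG stream.

The generator emulates: multi-study rosters with realistic arm sizes, the
five-group ethnicity structure with per-ethnicity allele frequencies
(defaults contrast an East Asian frequency near 0.62 with a European one
near 0.07 for the same variant, as observed for real synuclein-region
variants), HWE controls, model-specific penetrance patterns, and optional
between-study heterogeneity.

It does **not** emulate: linkage disequilibrium between variants (each
variant independent; no haplotypes), genotyping error, population
stratification within a study, covariate confounding (age, sex, onset),
publication bias in which studies exist, or deviations from HWE in
controls. A green simulation-based test therefore establishes internal
statistical correctness (calibration, recovery, coverage) of the
estimators and pipeline — not robustness to the epidemiological
complications listed above.

## Numerical choices and degenerate inputs

- **Zero cells**: +0.5 to all four cells (flagged `corrected`); applied
  both for per-study effects and inside the MH sums so the two stay
  consistent.
- **Non-informative tables** (both exposed cells zero, or both unexposed
  cells zero): excluded with an explicit sentinel (`excluded = TRUE`),
  never NaN; pooling drops them and errors only if nothing informative
  remains.
- **Single study**: MH pooling equals the crude OR exactly; DL returns the
  study unchanged with τ² = 0; `I²` is defined as 0.
- **Q < df**: both τ² and I² floor at zero.
- **Egger with constant precision**: when every study has the same SE the
  regression slope is unidentifiable. The implementation returns intercept
  0 with p = 1 (pure-effect decomposition), which reduces to the natural
  answer — no asymmetry evidence — and is exact when all effects are
  equal. With at least two distinct SEs the ordinary least-squares fit of
  `log OR / SE` on `1 / SE` is used, with a t test on k − 2 degrees of
  freedom.
- **`null_calibration` at α ≥ 1** returns rate 1 by convention: a level-1
  test always rejects, and on discrete count data the pooled p can equal
  1.0 exactly, so the strict comparison alone would undercount.
- **Allele harmonisation**: within a variant, rows whose declared risk
  allele is the complement of the dataset-level risk allele (taken from
  the first accepted row) have their genotype triples reversed and are
  flagged `flipped`; rows with alleles incompatible with the dataset's
  pair are rejected with row-addressed messages.
- **Ties and ordering**: eligible variants are returned in lexicographic
  rsID order; funnel coordinates are sorted by SE ascending; both make
  outputs deterministic.

## Design choices where the design was open

- **Subgroup eligibility.** The ≥4-study rule is stated only for the
  overall pooled analysis. Requiring 4 studies within every ethnicity
  subgroup would silence most subgroup findings (several published
  subgroup results rest on 2–3 studies), so subgroups default to a 2-study
  minimum with the stricter rule available as `apply_min_to_subgroups`.
- **Country subgrouping** is generic (`by_country`), since a
  country-specific analysis is just the ethnicity mechanism keyed on a
  different column.
- **Censored printed p-values** in the packaged reference table are
  classified via their bound (see above) rather than imputed as an
  arbitrary number; the loader refuses to classify a censored value whose
  bound would leave the tier undetermined.
- **Multiplicity**: a `bonferroni_cutoff` utility exists but is not wired
  into classification; the two-tier scheme *is* the screening procedure
  being reproduced, and silently changing it would defeat the purpose.

## Known limitations

- Pooled ORs for the real study base cannot be validated end-to-end here
  because per-study genotype counts live in supplementary material not
  shipped with the package; validation rests on the printed-summary
  classification, independent estimator oracles, and simulation
  calibration.
- DL τ² is the only random-effects estimator; for small k it is known to
  underestimate between-study variance, and CI coverage in the
  package's own recovery experiments runs ~1–2 points below nominal —
  consistent with the normal-quantile CI choice the emulated software
  makes.
- The Egger test at small k (< 10) has low power and its type-I behaviour
  depends on the SE spread; the funnel coordinates are exported so the
  visual judgement the original procedure used remains possible.
- The stability verdict of the leave-one-out analysis depends on the
  configurable 20% tolerance; the report always carries the full
  per-deletion table so the verdict can be re-derived under any tolerance.
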