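# genemeta

Case-control SNP association meta-analysis in R: from per-study genotype
counts to pooled odds ratios, heterogeneity-driven model selection,
two-tier screening classification, subgroup and allele-frequency
summaries, leave-one-out sensitivity analysis and publication-bias
diagnostics — with a synthetic-data generator providing known ground truth
for every stage.

## The problem

Candidate-gene association studies (for example of *SNCA* variants and
Parkinson's disease risk) report genotype counts for cases and controls,
study by study, with inconsistent and under-powered individual results.
Meta-analysis pools them. For each variant, each study's genotype triple
(risk-allele homozygotes, heterozygotes, other-allele homozygotes) is
collapsed into a 2×2 exposure table under a genetic model:

- **allele model** — risk vs other allele counts (each person contributes
  two alleles),
- **dominant model** — carriers (het + hom) vs non-carriers, persons,
- **recessive model** — risk homozygotes vs everyone else, persons.

Per-study effects are odds ratios, `OR = ad/bc`, with Woolf standard error
`SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)` (+0.5 continuity correction to
every cell of a table with a zero cell). Studies are pooled by
**Mantel–Haenszel** fixed effects,

    OR_MH = Σᵢ(aᵢdᵢ/nᵢ) / Σᵢ(bᵢcᵢ/nᵢ)

with the Robins–Breslow–Greenland variance, or by **DerSimonian–Laird**
random effects with the moment estimator
`τ² = max(0, (Q − df)/C)`, `C = Σw − Σw²/Σw` on inverse-variance weights.
Heterogeneity is summarised by Cochran's `Q` and
`I² = max(0, (Q − df)/Q)·100`; the method is chosen per analysis by the
rule *fixed if `p_Q > 0.1` or `I² ≤ 50%`, random otherwise*.

Variants reported by at least 4 studies are classified into a two-tier
screening recommendation from the allele-model pooled p-value:
`p < 1×10⁻⁵` → **most recommended**, `p < 0.05` → **recommended**, else
not recommended. Most-recommended variants are decomposed with the
dominant and recessive models (same `1×10⁻⁵` cutoff) to attribute the
effect to heterozygotes, homozygotes, both, or neither. Diagnostics cover
leave-one-out stability and Egger's regression test for funnel-plot
asymmetry.

## Worked example

Simulate an 8-study dataset for a variant with true per-allele OR 1.36 and
ethnicity-specific control allele frequencies, then run the pipeline:

```r
library(genemeta)

cfg <- sim_config(variant_id = "rs11931074", true_or = 1.36,
                  control_af = DEFAULT_AF_MAP, k_studies = 8,
                  n_cases_range = c(300, 1500),
                  n_controls_range = c(300, 1500), seed = 42)
sim <- simulate_dataset(cfg)
col <- as_variant_collection(sim$records)

run <- run_pipeline(col, groupings = "overall")
run$results[, c("method", "k", "pooled_or", "ci_low", "ci_high", "p",
                "i_squared", "tier", "direction", "contribution")]
#>     method k pooled_or ci_low ci_high         p i_squared
#> 1 fixed_MH 8     1.373  1.301    1.45 1.912e-30         0
#>               tier direction contribution
#> 1 most_recommended      risk         both
```

The pooled OR 1.373 [1.301, 1.45] recovers the simulated 1.36 within its
CI; `I² = 0` keeps the fixed-effects Mantel–Haenszel estimator; the
allele-model p far below 1×10⁻⁵ makes the variant *most recommended*, and
both dominant and recessive models are independently significant
(*contribution = both* — expected under a multiplicative effect of this
size).

```r
leave_one_out(col$rs11931074)
#> Leave-one-out for rs11931074 / overall: baseline OR 1.3733,
#>   range [1.3571, 1.3852], stable

egger_test(dataset_effects(col$rs11931074))
#> Egger test (k = 8): intercept -1.5965 (SE 0.6468), t = -2.468, p = 0.0486
```

No single study moves the pooled OR by more than the 20% stability
tolerance. (The borderline Egger p on only 8 unbiased simulated studies is
a reminder that the asymmetry test is noisy at small k.)

The same workflow is scriptable via the CLI:

```sh
Rscript exec/genemeta simulate --k 8 --true-or 1.36 --seed 42 --out sim/
Rscript exec/genemeta run --input sim/simulated.tsv --group overall,ethnicity --out results/
Rscript exec/genemeta loo --input sim/simulated.tsv --out loo.tsv
Rscript exec/genemeta bias --input sim/simulated.tsv --out bias/
```

Input is a UTF-8 TSV, one row per study × variant, with columns
`study_id author_year ethnicity country nos variant_id risk_allele
other_allele case_hom_risk case_het case_hom_other ctrl_hom_risk ctrl_het
ctrl_hom_other [superseded_by] [af_gnomad]`.

## Documentation

See the methods vignette (`vignettes/methods.Rmd`) for the statistical
model, every tunable parameter with its default and rationale, what the
synthetic-data generator does and does not emulate, and numerical edge
cases.
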