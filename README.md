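# fhetiology

Attribution of primary hypercholesterolemia to monogenic, polygenic, or
unexplained etiology, and quantification of the overlap between genetic
etiology and the familial-hypercholesterolemia (FH) phenotype.

## Who this is for

Severely elevated LDL cholesterol (LDL-C ≥ 155 mg/dl, ≈ 4 mmol/l, without
a secondary cause) can be **monogenic** — a rare pathogenic/likely
pathogenic (P/LP) variant in *LDLR*, *APOB* or *PCSK9* — **polygenic** —
an aggregate burden of common LDL-raising alleles — or unexplained.
The clinical FH diagnosis, meanwhile, is phenotypic: the Dutch Lipid
Clinic Network (DLCN) point score, with FH defined as DLCN ≥ 6. This
package is for statistical geneticists and lipidologists who want a
tested, configurable implementation of the whole attribution pipeline:

* inclusion/exclusion funnel with index-date detection (first LDL-C ≥ 155
  mg/dl), age 18–70, and secondary-cause exclusion within ±365 days;
* statin-adjusted untreated LDL-C (`observed / (1 − r)` by type and
  dose) and age/sex-specific 95th/99th percentile strata;
* DLCN scoring from structured phenotype inputs (DNA criterion excluded
  by default so the phenotype stays independent of genotype);
* an ACMG/AMP evidence-combining rule engine with functional and
  rarity (< 0.1%) pre-filters, a per-gene loss-of-function mechanism
  gate for PVS1, and exhaustive equivalence tests against a brute-force
  enumerator of the combining table;
* a 12-SNV weighted polygenic score
  `PGS = Σ_j w_j · d_j` (dosage d ∈ {0,1,2}, weights in mmol/l), with
  polygenic etiology defined as `PGS ≥ 1.16` (the reference 90th
  percentile) in a non-carrier — monogenic takes precedence;
* overlap cross-tabulation with audited numerators/denominators and
  shared half-up rounding, group tests (chi-square / Welch t / ANOVA),
  and variance-explained regressions (genetic vs clinical predictors);
* a synthetic cohort generator (Hardy–Weinberg genotypes, configurable
  effect sizes and prevalences) plus a deterministic count-fixture
  builder, so every stage is testable with no data download.

All clinically meaningful constants — SNV panel, DLCN points, statin
coefficients, percentile reference, thresholds — are YAML configuration,
not code (`inst/extdata/default_config.yaml`).

## Worked example

```r
library(fhetiology)

cfg    <- fh_default_config()
cohort <- generate_population(cfg, n = 20000, seed = 1)
res    <- run_pipeline(cohort)

res$selection$funnel
#>                       stage     n
#>                    screened 20000
#>                not_eligible     0
#>               no_index_date  9046
#>            age_out_of_range     0
#>   secondary_cause_in_window   378
#>                    retained 10576
```

Of 20,000 simulated adults, 10,576 have some LDL-C ≥ 155 mg/dl and no
secondary cause in the exclusion window. The etiology marginals in the
retained cohort:

```r
res$summary[res$summary$name %in%
  c("monogenic", "polygenic", "genetic_etiology", "phenotypic_fh"), ]
#>              name numerator denominator percent
#>         monogenic       277       10576    2.6%
#>         polygenic      1493       10576   14.1%
#>  genetic_etiology      1770       10576   16.7%
#>     phenotypic_fh       150       10576    1.4%

res$variance
#> <fh_variance> n = 10576
#>   genetic model R2:  0.0547
#>   clinical model R2: 0.0042
```

So 16.7% of the selected synthetic cohort has an identifiable genetic
etiology (P/LP carriers are enriched by the LDL selection from the 1.5%
population rate to 2.6%), and the genetic model explains ~5.5% of LDL-C
variance *within* the selected cohort (selection attenuates the
population value of 7%).

The deterministic fixture pathway reproduces a reference cohort's
overlap statistics exactly — note the poor overlap in both directions:

```r
fx <- run_pipeline(fixture_from_counts())
fx$summary[fx$summary$name %in%
  c("genetic_among_fh_sum_of_rounded", "fh_among_genetic",
    "fh_among_monogenic", "fh_among_polygenic"), ]
#>                             name numerator denominator percent
#>                 fh_among_genetic        37         287   12.9%
#>               fh_among_monogenic        10          25   40.0%
#>               fh_among_polygenic        27         262   10.3%
#>  genetic_among_fh_sum_of_rounded        37         142   26.0%
```

Only 26% of phenotypic-FH cases have an identifiable genetic etiology,
and only 12.9% of genetic-etiology cases meet the clinical FH criteria.

A thin command-line wrapper over the same functions ships in
`inst/cli/fhpipeline.R` (subcommands `simulate`, `select`, `adjust`,
`score-dlcn`, `classify-variants`, `score-pgs`, `summarize`, `run`).

## Package layout

* `R/` — one file per stage: `synthetic_cohort.R`, `cohort_selection.R`,
  `lipid_adjustment.R`, `dlcn.R`, `variant_pathogenicity.R`, `pgs.R`,
  `etiology_overlap.R`, `io.R`, `pipeline.R`, `config.R`.
* `inst/extdata/default_config.yaml` — every tunable, documented inline.
* `vignettes/etiology-pipeline.Rmd` — the methods write-up: model,
  assumptions, calibration of the generator, numerical conventions,
  limitations.
* `tests/testthat/` — unit and property tests per stage plus end-to-end
  acceptance checks.
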