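---
title: "Attributing monogenic and polygenic etiology in primary hypercholesterolemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing monogenic and polygenic etiology in primary hypercholesterolemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhetiology)
```

## The problem

Severely elevated LDL cholesterol in an adult can have three broad
explanations: a *monogenic* cause (a rare pathogenic variant in `LDLR`,
`APOB` or `PCSK9`, the classical familial-hypercholesterolemia genes), a
*polygenic* cause (an unlucky aggregate of many common LDL-raising
alleles), or neither. The clinical diagnosis of familial
hypercholesterolemia (FH), by contrast, is phenotypic: the Dutch Lipid
Clinic Network (DLCN) score sums points over family history, personal
vascular history, physical signs and the (untreated) LDL-C level. The two
definitions need not agree, and quantifying their overlap is the purpose
of this package: given genotypes and structured phenotype records for a
screening cohort of adults with primary hypercholesterolemia
(LDL-C ≥ 155 mg/dl without a secondary cause), attribute each participant
to a monogenic, polygenic or unexplained etiology and cross-tabulate the
attribution against the DLCN phenotype.

## The pipeline

`run_pipeline()` executes six stages, each also available as an exported
function.

**1. Cohort selection** (`apply_selection()`). The index date is the first
date with LDL-C ≥ 155 mg/dl (≈ 4 mmol/l; inclusive). Participants are
retained when alive/eligible, aged 18–70 at index (inclusive at both
ends), and free of a secondary cause of hypercholesterolemia
(hypothyroidism, cholestatic liver disease, severe kidney disease,
nephrotic syndrome, pregnancy) dated within ±365 days of the index date.
The window is symmetric and boundary-inclusive; both conventions are
configurable because "within a 1-year window around" admits either
reading. Exclusions are tallied under the first failing rule in a fixed
order (eligibility → no index → age → secondary cause) so the funnel is
reproducible; the funnel always conserves totals.

**2. Lipid adjustment** (`impute_untreated_ldl()`,
`assign_percentile_strata()`). For participants on a statin at the index
date the untreated LDL-C is recovered multiplicatively,
`untreated = observed / (1 − r)`, with `r` the expected proportional
reduction for that statin type and daily dose. The division convention
(rather than `observed × (1 + r)`) reflects that statin effects are
proportional reductions. The coefficient table ships as configuration
with commonly published reduction fractions, strictly inside (0, 1) and
non-decreasing in dose; it is meant to be replaced when a site-specific
table is available. Imputation uses the highest recorded LDL-C by
default (an index-only mode falls out of supplying only that measure).
Untreated LDL-C then feeds both the DLCN LDL band and the age/sex
percentile strata (≥ 95th, ≥ 99th, inclusive comparisons, nested by
construction). The shipped percentile reference is a synthetic,
Gaussian-derived table by sex and age band, clearly non-clinical: it
exists so the stratum logic is fully testable without a licensed
population reference.

**3. DLCN scoring** (`score_dlcn()`). Within each criterion group only
the highest-scoring satisfied condition counts; the total is the sum
over groups. Points are configuration, defaulting to the standard DLCN
values (family history 1–2; premature CHD 2, premature
cerebrovascular/peripheral disease 1; tendon xanthomata 6, arcus
cornealis before 45 years 4; LDL bands 155–189 → 1, 190–249 → 3,
250–329 → 5, ≥ 330 → 8; causative DNA variant 8). Categories: unlikely
(< 3), possible (3–5), probable (6–8), definite (≥ 9); phenotypic FH is a
total ≥ 6. The DNA criterion is **excluded by default**: phenotypic FH
must stay independent of the genetic calls for the overlap analysis to
be non-circular. Premature ASCVD means an event strictly before 55
(males) or 65 (females). Missing inputs count as criterion-not-met.

**4. Variant classification** (`classify_variants()`, `combine_acmg()`).
Candidate rare variants in the three FH genes pass a functional filter
(missense, stop-gain, frameshift, splice donor/acceptor, in-frame indel,
start/stop lost) and a rarity filter (reference allele frequency
strictly < 0.1%, or never observed), with first-failure attribution.
Survivors get automatable ACMG/AMP evidence tags: PVS1 for
null-consequence variants in genes whose configured disease mechanism is
loss of function (LDLR yes; APOB and PCSK9 no), PM2 for rarity, PP3/BP4
from a computational verdict, PP5/BP6 from a clinical-database assertion
(toggleable, as later recommendations deprecate them). Evidence that
requires human curation — functional studies, segregation, literature —
enters as supplied tags. The combining engine implements the full
published combining table (pathogenic, likely pathogenic, benign, likely
benign, otherwise uncertain; simultaneous pathogenic- and
benign-direction rules yield uncertain). The engine's equivalence to an
independently written brute-force enumerator is checked exhaustively
over all evidence-count combinations up to four per category.
A participant is *monogenic* when carrying ≥ 1 alternate allele of ≥ 1
pathogenic / likely-pathogenic variant. Copy-number variants are out of
scope and rejected explicitly.

**5. Polygenic score** (`compute_pgs()`, `classify_polygenic()`). The
raw score is the weighted sum of effect-allele dosages over a 12-SNV
LDL-C panel, in the mmol/l units of the weights. Missing dosages are
imputed as 2 × effect-allele frequency (expected dosage under
Hardy–Weinberg) up to a 50% missingness cap; a strict mode rejects any
missingness for audit runs. Allele orientation is resolved by matching
the panel's effect allele against the VCF REF/ALT alleles; a mismatch is
an error, never a silent flip. *Polygenic* etiology is a raw score
≥ 1.16 — the 90th percentile of the reference distribution — in a
participant without monogenic etiology; monogenic takes precedence.
A percentile against a user-supplied empirical reference distribution is
available as an alternative decision rule; none ships because the
reference cohort's scores are not public.

**6. Overlap and variance** (`crosstab_overlap()`,
`variance_explained()`). The cross-tab reports every percentage with its
numerator and denominator, rounded half-up to one decimal by a single
shared routine; empty subgroups are *undefined*, never 0. The genetic
share of phenotypic FH is reported twice: as the direct ratio and as the
sum of the rounded monogenic and polygenic components, which can differ
in the last decimal (with the reference counts: 37/142 → 26.1 directly,
7.0 + 19.0 = 26.0 as a sum of rounded parts). Variance in untreated
LDL-C explained by genetic factors (raw score + monogenic indicator) and
by clinical/demographic factors (age, sex, race, BMI, diabetes, family
history of hypercholesterolemia) is estimated by two *separate*
ordinary-least-squares fits, matching the way the two figures are
conventionally quoted; constant or collinear predictors are an error
rather than a silent drop. Group comparisons use chi-square, Welch's
t-test and one-way ANOVA, two-sided, at the 0.05 convention.

## The synthetic cohort generator

Protected clinical-genomic data cannot ship with a package, so
`generate_population()` simulates the cohort structure every stage
needs, and all tests run on generated data.

* **Genotypes.** Panel dosages are Binomial(2, p) per SNV — exact
  Hardy–Weinberg — so the raw score has analytically known moments:
  mean Σ 2p~j~w~j~, variance Σ 2p~j~(1−p~j~)w~j~². The default panel uses
  the rsIDs, genes and effect alleles of the validated 12-SNV LDL-C
  score; its weights and frequencies were calibrated once, with
  published-like values as the starting point, so that the implied score
  distribution has mean 0.891 and SD 0.210 — placing its 90th percentile
  exactly at the 1.16 decision threshold. It is a synthetic default, not
  a transcription of any proprietary panel, and is editable as data.
* **LDL-C.** `untreated = intercept + 0.25·(age − 50) − 3·male +
  38.67·score + shift·carrier + ε`, with ε Gaussian (SD 35.63 mg/dl) and
  the carrier shift Gaussian (mean +46, SD 15 mg/dl) — the mean carrier
  excess matches the observed carrier/non-carrier contrast
  (≈ 232 vs 186 mg/dl). 38.67 mg/dl per score unit is exactly the
  mmol/l→mg/dl conversion. With these defaults the genetic block (score +
  carrier status) accounts for 7.0% of LDL-C variance and the clinical
  block about 1%, and the LDL-selected cohort mean is ≈ 187 mg/dl.
* **Rare variants.** Carriers (1.5% of subjects) draw from a catalogue
  whose records classify P/LP *through the engine* (LDLR null variants
  via PVS1 + PM2; APOB/PCSK9 missense via curated evidence tags), with a
  72/24/4% LDLR/APOB/PCSK9 gene mix. A second catalogue of
  synonymous/common/VUS records (2% of subjects) exercises the filters
  without producing monogenic calls.
* **Everything else.** Statin use 3.9% with type/dose drawn from the
  coefficient table (observed LDL = untreated × (1 − r)), secondary-cause
  diagnoses scattered around the measure date so the exclusion window has
  work to do, family-history and physical-sign flags at plausible
  prevalences, ages uniform 18–70, 41.3% male.

What the generator does **not** emulate: right-skewed LDL distributions
(a Gaussian population matched to the truncated mean ≈ 187 mg/dl yields a
truncated SD of ≈ 24 rather than ≈ 32 mg/dl), linkage disequilibrium
between panel SNVs, relatedness and founder structure, ancestry
stratification, EHR missingness and longitudinal LDL trajectories.
Passing tests therefore demonstrate correctness of the *computational
procedure*, not clinical performance on real data.

`fixture_from_counts()` complements the generator: it deterministically
builds a cohort of exactly the requested size whose etiology, DLCN and
LDL-stratum counts hit requested marginals and joints exactly, assigning
the *minimal* attributes that trigger each label through the real
classifiers (a catalogued P/LP variant for monogenic, all-2 panel
dosages for polygenic, tendon xanthomata for phenotypic FH, stratum-
midpoint LDL values of 255/240/210/175/160 mg/dl against a one-band
reference with cuts at 170/235). LDL strata are treated as nested.
Inconsistent counts (a joint exceeding a marginal) are rejected.

## Numerical and design choices

* Percent rounding is half-up to one decimal, centralised in
  `round_half_up()`; `base::round()`'s banker's rounding would disagree
  on exact ties.
* Unit conversion uses 1 mmol/l = 38.67 mg/dl in both directions.
* The ±365-day exclusion window and the 18/70 age bounds are inclusive;
  both are stated conventions, configurable in the `selection` block.
* The rarity threshold uses strict `<` (0.1%), so a frequency of exactly
  0.001 is *not* rare; absence of a frequency is rare.
* The polygenic threshold uses inclusive `≥ 1.16`; the monogenic gate is
  applied after thresholding.
* The polygenic denominator in marginal percentages is the full cohort,
  not the non-monogenic subset.
* Degenerate inputs: empty lipid lists give "no index date" rather than
  an error; empty reference distributions, unknown statin/dose pairs,
  unknown ACMG tags, out-of-range configuration values and CNV records
  all fail loudly with the offending field or entry named.
* Test problem sizes: calibration properties run at n = 50,000
  (Hardy–Weinberg χ², score moments within 1%, regression recovery of
  the score scale and carrier shift within 3 SE, genetic R² within one
  point of the configured 7%); funnel and filter properties at
  n = 1,000 randomized records; the ACMG engine is checked exhaustively
  (5⁷ evidence-count combinations).

## Known limitations

The automated evidence assignment covers only annotation-derivable ACMG
criteria; a clinical laboratory's manual review (segregation, functional
data, literature) must be expressed as supplied tags. The shipped
percentile reference and statin coefficients are placeholders for real
tables. The 12-SNV score is not ancestry-recalibrated, and the printed
cohort score mean (0.97 ± 0.21) depends on the real cohort's genotypes —
the generator reproduces it only approximately (the LDL-selected
synthetic cohort mean is ≈ 0.92) because selection strength and the
score-LDL coupling jointly determine the enrichment.
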