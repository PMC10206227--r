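# pgxcohort

Population-scale pharmacogenomics in R: call star alleles and whole-gene
copy number from phased variant calls plus read depth, translate
diplotypes into predicted metabolizer phenotypes, classify those
phenotypes against EHR priority risk notation, cross-reference them with
medication records for PharmGKB evidence level 1A drug–gene pairs, and
summarize the resulting haplotype, diplotype and phenotype frequencies at
cohort scale.

The package is aimed at groups running pharmacogenomic characterizations
of sequenced cohorts — the kind of analysis where individual-level inputs
are access-restricted. Because of that, `pgxcohort` ships a first-class
**synthetic cohort generator**: it samples per-gene diplotypes at
configurable haplotype frequencies under Hardy–Weinberg equilibrium,
encodes them into a phased multi-sample VCF and a GDF-like per-position
depth table (deletions and duplications live in the depth signal),
and attaches demographics and medication records with a configurable
missing-data fraction. Every downstream stage is therefore testable
against known truth.

## The model in brief

**Star alleles.** A star allele (`CYP2D6*4`, `UGT1A1*28`, …) is a named
haplotype defined by a set of variants; `*1` is the reference haplotype.
Given phased genotypes, haplotype *k* of a sample is the set of sites
where allele *k* of `GT = a|b` is non-reference. A haplotype is matched to
the allele whose defining-variant set is contained in it and is largest
(maximal-subset rule; ties break by definition-table order; no candidate
means `*1`).

**Copy number.** Per-position depth is normalized within sample by the
mean depth of a control region, so a diploid gene sits at ratio 1.0. The
whole-gene copy number is `clamp(round(2 · median ratio), 0, 3)`. CN 0/1
introduce the deletion allele (`*5` for CYP2D6, `*DEL` otherwise); CN 3
adds an `x2` suffix to the duplicated allele.

**Phenotypes.** Diplotypes translate to phenotypes through
diplotype–phenotype translation tables (symmetric, unordered lookup);
misses are `Unknown`, except CYP2D6, which falls back to the CPIC
activity-score sum: AS(allele1) + AS(allele2), with `xN` multiplying the
base score, binned as 0 → Poor, (0, 1.25) → Intermediate,
[1.25, 2.25] → Normal, > 2.25 → Ultrarapid. CYP4F2 and VKORC1 use the
warfarin dose-category rules: one or two copies of CYP4F2`*3` → higher
warfarin dose; one or two copies of VKORC1`*2` → decreased warfarin dose.

**Risk and medications.** Phenotypes map to EHR Priority Result Notation
(high-risk yes/no per gene), and an interaction flag is raised for every
(sample, drug, gene) where a taken level 1A drug pairs with a high-risk
gene. Individuals with missing medication data are excluded from
medication denominators.

## Worked example

```r
library(pgxcohort)
refs   <- load_reference_bundle()                     # 11-gene fixture bundle
cfg    <- default_cohort_config(n = 200, seed = 42)
cohort <- sample_medications(cfg, sample_cohort(cfg, refs$defs))
paths  <- write_cohort_files(cohort, refs$defs, "cohort_inputs")

calls  <- call_cohort(paths$vcf, paths$depth, refs$defs)
subset(calls, sample == "S0003")
#>      sample    gene allele1 allele2 diplotype cn mean_ratio exact1 exact2
#> 3     S0003  CYP2B6      *6      *6     *6/*6  2  1.0314945   TRUE   TRUE
#> 403   S0003 CYP2C19     *17     *17   *17/*17  2  0.9720293   TRUE   TRUE
#> 803   S0003  CYP3A5      *3      *3     *3/*3  2  0.9701459   TRUE   TRUE
#> 1803  S0003  CYP4F2      *1      *3     *1/*3  2  1.0587168   TRUE   TRUE
#> ...

ph  <- phenotype_cohort(calls, refs$translation, refs$defs)
head(subset(ph, gene == "CYP2D6"), 4)
#>     sample   gene diplotype                phenotype         method  activity_score_total
#> 601  S0001 CYP2D6     *1/*1       Normal Metabolizer activity_score                    2
#> 604  S0004 CYP2D6     *1/*4 Intermediate Metabolizer activity_score                    1

ann <- annotate_risk(ph, refs$risk)
mean(any_high_risk(ann))      # fraction with >=1 high-risk genotype
#> [1] 0.985

cohort_interaction_summary(cohort$medications, ann, refs$pairs, refs$synonyms)
#> Medication summary: 200 individuals (189 reporting)
#>   taking >=1 level 1A drug:        54.5%
#>   >=1 high-risk interaction:       38.1% (69.9% of users)
#>   >1 high-risk interaction:        4.2%
#>   median drugs 3 (IQR 2-4); >=5 drugs: 11.6%
```

The diplotype call for `S0003` shows the caller reading phased variants
(`*6/*6`, `*17/*17`) and a depth ratio near 1.0 (two gene copies); the
phenotype rows show the CYP2D6 activity-score path (`*1/*4` sums to AS 1,
an intermediate metabolizer); the summary cross-references medication
records with high-risk phenotypes — here 38.1% of reporting individuals
take at least one level 1A drug while carrying a high-risk phenotype for
its paired gene.

`run_pipeline(list(n = 200, seed = 42, out_dir = "out"))` chains all of
the above and writes the call/phenotype/risk/interaction tables plus a
JSON report; `inst/scripts/pgxpipe.R` wraps it for shell use
(`simulate`, `call`, `run-all` subcommands).

## Scope notes

Hybrid/tandem rearrangement alleles (`*68+*4`, `*36+*10`) are supported
as named units in tables and diplotype input, but are not detected from
signal; partial-gene structural variants and gene–pseudogene
disambiguation are out of scope. See the methods vignette
(`vignettes/pgxcohort-methods.Rmd`) for assumptions, parameter defaults
and limitations.
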