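---
title: "Star-allele calling, phenotype prediction and gene-drug risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele calling, phenotype prediction and gene-drug risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pgxcohort` implements a cohort-scale pharmacogenomic analysis as a chain
of small, testable stages, together with a synthetic-cohort generator
that produces inputs with known truth. This vignette explains the
procedure each stage implements, the assumptions behind it, the tunable
parameters and their defaults, and what the package deliberately does not
model.

## Star-allele calling

### Haplotype extraction

Inputs are a phased multi-sample VCF (hg19, 1-based coordinates) and a
GDF-like per-position depth table with a control-region block. For each
gene region, haplotype *k* of a sample is the set of variant keys
(`chrom:pos:ref:alt`) at which allele *k* of the phased genotype `a|b`
is non-reference. Unphased genotypes (`a/b`) are a hard error naming the
sample and site: the pipeline assumes statistical phasing happened
upstream and refuses to guess. Indel representation must be
left-normalized so that keys match definition rows byte-for-byte.

### Defining-variant matching

A star-allele definition table lists, per gene, each allele's defining
variants (the reference allele `*1` has none). A haplotype is matched by
the *maximal-subset rule*: candidates are alleles whose defining set is
contained in the haplotype; the candidate with the most defining
variants wins; ties break by table order; no candidate (or an empty
haplotype) yields `*1`. This is the dominant convention among star-allele
callers and behaves correctly for nested definitions (e.g. SLCO1B1 `*15`
contains `*5`'s variant, TPMT `*3A` contains `*3B` and `*3C`). An
`exact` flag records whether the winner's defining set equals the
haplotype; residual variants demote the flag but never fail the call, so
novel secondary variants degrade gracefully.

### Copy number

Whole-gene copy number comes from intrasample depth normalization: the
gene's per-position depth divided by the sample's mean control-region
depth, so two copies sit at ratio 1.0. The call is
`cn = clamp(round(2 * median(ratio)), 0, 3)` with ties rounded half away
from zero. The median (rather than mean) makes the estimate robust to a
few noisy positions; the cap at three copies matches the supported
whole-gene event range. Per-segment changepoint detection — what would
be needed for hybrid or partial-gene rearrangements — is a declared
non-goal; tandem alleles such as `*68+*4` exist only as named units in
tables and direct diplotype input.

### Combining haplotypes with copy number

* CN 2 — both matched alleles are kept.
* CN 0 — homozygous whole-gene deletion (`*5` for CYP2D6, `*DEL`
  otherwise).
* CN 1 — the deletion replaces the haplotype carrying fewer
  non-reference variants (tie: haplotype 2). Read-level phasing of the
  deletion is unavailable from these inputs, so this is a deterministic
  convention, not an inference.
* CN 3 — the `x2` suffix goes to the sole non-reference allele when
  exactly one haplotype is non-reference, otherwise to haplotype 1, and
  in the ambiguous case the allele's exact flag is demoted.

Because whole-gene depth cannot reveal *which* haplotype carries an
extra copy, the generator stores sampled truth in the same canonical
form. Round-trip recovery is therefore guaranteed exactly for
SNV/indel-defined diplotypes and whole-gene events with 0, 1 or 3 total
copies; copy-neutral combinations such as `*DEL/*1x2` (two total copies,
ratio 1.0) are genuinely unidentifiable from these inputs and are
excluded from the guarantee.

## Phenotype prediction

Most genes translate through diplotype–phenotype tables with symmetric,
unordered lookup; a pair missing from the table is `Unknown`. CYP2D6
instead falls back to the activity-score (AS) sum, since published
tables routinely miss diplotypes seen in real cohorts: each allele
carries an AS (0 loss, 0.5 decreased, 1.0 normal; `xN` multiplies the
base score; composite units carry their own score), and the total maps
to bins 0 → Poor, (0, 1.25) → Intermediate, [1.25, 2.25] → Normal,
> 2.25 → Ultrarapid (current CPIC consensus). An allele with unknown AS
poisons the sum to `Indeterminate`, mirroring CPIC practice. Function
class is always *derived* from the activity score (0 loss, (0,1)
decreased, 1 normal, >1 increased, missing unknown) rather than stored,
so the two can never disagree.

CYP4F2 and VKORC1 have no translation tables; they use the warfarin
dose-category rules: one or two copies of CYP4F2 `*3` (rs2108622) give
the *higher* warfarin dose category — the direction consistent with the
guideline's 5–10% dose increase for carriers — and one or two copies of
VKORC1 `*2` (rs9923231) give the *decreased* dose category. The two
flags are independent.

"Likely"/"Possible" phenotype qualifiers collapse onto their base
phenotype for risk matching, the same grouping EHR notation uses.

## Risk annotation and medication cross-referencing

The EHR priority table flags, per gene, which phenotypes warrant
priority alerting. The shipped notation follows the per-gene conventions
for the nine level 1A genes: CYP2C19 flags every non-normal metabolizer
class (carriers of `*2`, `*3`, `*17`); CYP2C9, CYP2B6 and NUDT15 flag
intermediate and poor; CYP2D6 flags ultrarapid, intermediate and poor;
CYP3A5 flags normal and intermediate (the expressor genotypes);
SLCO1B1 flags decreased and poor function; TPMT flags intermediate,
poor and indeterminate; UGT1A1 flags poor only.

An interaction flag is one (sample, drug, gene) event where a taken
drug appears in the level 1A pair list and the sample is high-risk for
the paired gene. Drug names are lower-cased, trimmed and passed through
a brand→generic synonym table; unmatched names pass through and simply
never flag. Individuals with missing medication data produce no flags
and are excluded from all medication denominators — the summary reports
both the fraction of reporting individuals with an interaction and the
fraction among those actually taking a level 1A drug, since both
denominators are used in practice. The warfarin genes flag only through
warfarin and only for the non-normal dose categories.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not sequencing itself:

* **Diplotypes** are drawn per gene either from haplotype frequencies
  under Hardy–Weinberg equilibrium (two independent draws) or from
  joint diplotype frequencies. Genes are independent; within-gene LD is
  implicit in treating haplotypes as atomic units.
* **Phased VCF**: haplotype 1 carries allele 1's defining variants,
  haplotype 2 allele 2's. Deletion haplotypes emit reference genotypes —
  their signal lives in depth. Composite alleles cannot be emitted
  (no defining set) and raise an error.
* **Depth**: expected per-position depth is
  `depth_mean * copies / 2` with Gaussian noise (`depth_sd`, default
  3 at a 30x mean — i.e. 10% positional noise), over 16 positions per
  gene plus a control block at 1.0x.
* **Medications**: each drug is an independent Bernoulli draw at its
  configured frequency; a configurable fraction of individuals
  (default 5.3%) is flagged as missing medication data entirely,
  reflecting the gap between interview denominators and cohort size in
  real registries. An optional gamma-distributed per-individual
  propensity multiplier can inflate polypharmacy; it is off by default.
* **Demographics**: sex (36.5/63.5), census color/race categories
  (58.1/28.2/6.4/2.7/2.1/2.5) and ages 60 + Gamma(1.5, scale 9),
  giving a median near 71 with an IQR spanning roughly 65–78 — the
  profile of an elderly census-sampled cohort.

The default scenario (`default_cohort_config()`) fixes haplotype
frequencies at published Brazilian population estimates for the eleven
bundled genes (UGT1A1 `*28` 0.329, VKORC1 `*2` 0.331, CYP4F2 `*3`
0.292, CYP3A5 loss alleles ≈ 0.82, CYP2C9 `*2`/`*3` 0.113/0.052, a
CYP2D6 spectrum with 3% deletion and 2.5% duplication, …) and drug-use
frequencies led by simvastatin (0.201) and omeprazole (0.195), with
common non-PGx medication as filler so total drug counts are realistic.
These are the generator's emulation targets, set once; they are not
fitted to any output.

All sampling derives from the config seed (the VCF/depth and medication
emitters use fixed small offsets of it so each stage is independently
reproducible); identical configs give byte-identical output files.

**What passing tests do and do not show.** The generator is HWE,
independent across genes and independent between genotype and
medication use. Real cohorts deviate from all three (population
structure, cross-gene ancestry correlation, prescription-by-indication).
Tests against the generator validate the *pipeline machinery* —
matching, CN arithmetic, rule application, bookkeeping — not the
population-genetic realism of any particular cohort; cohort-specific
observed values from real data (overall high-risk fractions,
interaction percentages, per-gene frequencies) depend on
access-restricted inputs and are represented here only as configurable
generator parameters.

## Numerical choices and degenerate inputs

* Frequency vectors must sum to 1 within 1e-9; probabilities are range
  checked.
* Percentages print half-up to one decimal (matching cohort-report
  style); `2 * median(ratio)` rounds half away from zero.
* Diplotypes are unordered and rendered canonically with the
  numerically lower star allele first; non-numeric labels (`*DEL`)
  sort last.
* Empty cohorts: `sample_cohort` accepts n = 0 and produces empty
  tables, while summary functions (`demographics_summary`,
  `cohort_interaction_summary`) reject empty input, and `run_pipeline`
  validates n ≥ 1 before simulating.
* A gene present in the definitions but absent from the depth table is
  treated as diploid (CN 2) rather than failing, so variant-only
  workflows still call.
* Sample sets of the VCF and depth table must match exactly; the error
  lists the disjoint samples. Output is invariant to VCF record order
  and sample column order.

## Problem sizes used by the test suite

The suite exercises the caller round trip over 20 seeded cohorts of
n = 200 (all eleven genes), frequency recovery over 100 seeded
replicates at the emulated study size n = 1171 (haplotype and drug-use
frequencies within 3 binomial SE, pooled coverage ≥ 99%), closed-form
HWE checks at n = 100,000 haplotype draws, and exhaustive enumeration
over all variant subsets of a toy table for the matcher. These sizes
were chosen to make binomial tolerances tight enough to catch
off-by-one and denominator errors while keeping the full suite
comfortably interactive.

## Known limitations

* No detection of hybrid/tandem rearrangements, partial-gene SVs, or
  gene–pseudogene recombination from signal; CN is whole-gene and
  capped at three copies.
* Duplication attribution and CN-1 deletion placement are conventions,
  recorded in exact flags, not read-backed inferences.
* The shipped reference bundle is a curated minimal subset (2–6 alleles
  per gene, eleven genes) intended for testing and demonstration; full
  PharmVar/PharmGKB-scale tables load through the same TSV formats but
  are not distributed with the package.
* Phenotype vocabulary is fixed to the standard metabolizer/function
  labels plus the warfarin dose categories; bespoke labels require
  extending the vocabulary before loading.
* No dosing algorithms: the warfarin handling stops at categorical
  dose-direction flags, and no recommendation text is produced.
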