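---
title: "Methods: exact rare-variant burden analysis of germline ATM variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact rare-variant burden analysis of germline ATM variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmburden)
```

## The design

`atmburden` implements a case-cohort rare-variant burden design for a single
gene (*ATM*) in which the comparison group is not a sequenced control cohort
but a population reference summarised as per-variant allele counts
(gnomAD-NFE-style AC / AN / homozygote tables). The unit of analysis is the
allele: a diploid cohort of *N* individuals contributes *2N* alleles, a
reference of 64,603 individuals contributes 129,206. For a variant class
(all LOF variants grouped, or all VUS grouped) the data reduce to a 2×2
table

|            | variant alleles | other alleles |
|------------|-----------------|---------------|
| cases      | *a*             | *b* = 2N − a  |
| reference  | *c*             | *d* = AN − c  |

on which exact inference is performed. The key assumptions are those of any
external-reference burden design: cases and reference draw from comparable
ancestral populations (hence the NFE restriction), variant calling is
comparable across platforms, and carriers are unrelated so alleles can be
treated as independent Bernoulli draws. None of these can be verified from
inside the package; the internal case–control comparison
(`internal_case_control()`) against same-center controls exists precisely as
a robustness check on the first two.

## Variant selection

Classification (`classify_variants()`) applies, in order:

1. **Curated overrides.** A small table of variant → consequence
   reassignments backed by functional evidence wins over the nominal
   annotation. The shipped default contains one entry: c.3576G>A, nominally
   synonymous p.(Lys1192=), which abolishes the exon 26 donor site and
   deletes 58 residues from the transcript; it is treated as a splice-donor
   LOF. Overrides are idempotent: re-applying the table to already
   overridden consequences changes nothing.
2. **LOF assignment.** Nonsense, frameshift, splice-acceptor and
   splice-donor variants are loss-of-function. In-frame deletions,
   start-loss and other protein-altering classes are conservatively
   excluded (`excluded_other_class`) rather than promoted to LOF.
3. **Missense filters.** A missense variant is retained as a VUS only if
   its reference allele frequency AC/AN is at most 0.005 (strict
   inequality excludes) *and* at most two reference individuals are
   homozygous (`homozygote_count > 2` excludes). The 0.005 cutoff is the
   upper estimate of the ataxia–telangiectasia heterozygote frequency
   (AT prevalence 1:40,000–1:100,000 implies a carrier allele frequency of
   0.003–0.005): a missense allele more common than the AT carrier pool is
   unlikely to be a fully penetrant AT allele. A variant absent from the
   reference has AF treated as 0 and is retained — no secondary frequency
   source is consulted.

When no consequence annotation is supplied, `derive_consequence()` infers
one from the HGVS strings: intronic offsets −1/−2 (+1/+2) mark canonical
splice acceptors (donors); `fs` marks a frameshift; a stop at a substituted
residue marks nonsense; `=` synonymous; a plain single-residue substitution
missense; any other parseable protein change (e.g. an in-frame deletion)
falls through to `other`. A cDNA with no protein change and no canonical
intronic offset is also `other`: its effect cannot be asserted from
nomenclature alone, which is exactly the c.3576G>A situation the override
table exists for.

## Exact inference on the 2×2 table

The statistical core (`burden_test()` and friends) fixes the conventions
that plain "Fisher's exact test" leaves open:

* **p-value** — two-sided under the *point-probability rule*: with both
  margins fixed, sum the hypergeometric probabilities of every table no
  more likely than the observed one. A relative tolerance of 1e-7 guards
  the comparison against floating-point ties (the same guard base R uses).
* **Odds ratio** — the headline estimate is the sample cross-product
  *ad/bc*. The conditional maximum-likelihood estimate (the value of the
  noncentral hypergeometric odds parameter for which the conditional mean
  equals the observed *a*) is computed and stored alongside, because the
  two differ noticeably in heavy tables and published reports do not always
  say which they print.
* **Confidence interval** — default `conditional_exact`: the bounds invert
  the noncentral hypergeometric tail probabilities at (1 − level)/2 per
  side, found by bracketed root-finding on log-odds with tolerance
  `.Machine$double.eps^0.5`. At the support boundary the bounds open to 0
  or ∞. A Wald interval
  exp(log OR ± z·√(1/a + 1/b + 1/c + 1/d)) is available for comparison;
  the two converge as all cells grow.
* **Zero cells** — exact p-values and conditional bounds need no
  correction. The sample OR and the Wald interval apply the
  Haldane–Anscombe +0.5 to *all* cells only when a zero is present, and the
  result is flagged. A table with an empty variant margin carries no signal
  at all: the OR is reported as `NA` and p = 1.
* **Reporting** — ORs are printed to 2 decimals (3 significant figures
  below 1), p-values in scientific notation with 2 significant digits, AFs
  at a configurable number of digits. Significance is a plain two-sided
  0.05; no multiple-testing correction is applied by default because the
  design runs a small, pre-specified set of grouped tests (an adjustment
  can be layered on with `p.adjust` if a user runs many per-variant tests).

The implementation is verified two independent ways in the test suite:
against brute-force enumeration of the full hypergeometric support with
`choose()` (exact to 1e-12 over all margins ≤ 30), and against
`stats::fisher.test` (whose interval root-finder carries its own ~1e-4
tolerance, so CI agreement is asserted at that precision while the defining
tail equations are checked at 1e-6).

## Subsets, domains and per-variant analyses

Analysis plans (`analysis_plan()`) combine a variant class with a case
subset and an optional domain restriction:

* the **genetically enriched subset** is exactly the familial-proband plus
  MPM strata; sporadic cases enter only the "all cases" analyses;
* **domain restriction** (VUS only, mirroring the study design) keeps
  variants whose protein residue lies inside any of FAT (1940–2566),
  PI3K/PI4K (2712–2962) or FATC (3024–3056), inclusive bounds. Residue
  anchors are parsed from the protein HGVS; splice variants with only cDNA
  coordinates receive a `ceiling(position/3)` anchor *for plotting only*
  and never qualify as in-domain, since a residue imputed from a cDNA
  coordinate is not evidence of domain membership;
* grouped tests use one configured aggregate reference allele number
  (default 129,206) as the denominator, matching the single-denominator
  convention of published summary tables, while per-variant tests use the
  variant's own AN when a reference row exists (gnomAD coverage varies by
  site) and the aggregate otherwise;
* "observed in ≥ 3 cases" counts distinct individuals, not alleles, so a
  homozygous carrier counts once.

## Cosegregation

`classify_cosegregation()` reduces each family to (carriers, sequenced
affected relatives): one sequenced case determines nothing
(`not_determined`); all of ≥ 2 carrying is `yes`; exactly one carrier among
several is `no`; anything between is `partial`. This boundary — one carrier
is "no" evidence rather than "partial" — is reverse-engineered from the
usage in published family tables (1/6 and 1/3 labelled No, 2/3 and 3/4
Partial) and reproduces every published label, but it is a repository
convention, not an author-stated rule. Likelihood-based cosegregation
evidence (pedigree LOD scores) is out of scope; only count ratios are
modelled.

## The synthetic-data generator

`scenario()` / `simulate_cohort()` / `simulate_reference()` /
`simulate_families()` generate data with the structure the analysis
assumes. Carriage is sampled **per allele**: each of an individual's two
alleles independently carries a variant with probability
AF × multiplier, so a unit multiplier reproduces the reference allele
frequency exactly in expectation, and an individual drawing both alleles is
a (rare) homozygote. The multiplier is an odds-scale enrichment treated as
acting on probability directly, an approximation accurate for AF < 0.01
(odds ≈ probability); probabilities are clipped at 1 with a warning.
Reference allele counts are binomial over AN trials; homozygote counts are
binomial over ⌊AC/2⌋ so `2·hom ≤ AC` always holds. Every generator is
deterministic given the scenario seed, and generated tables re-validate on
ingestion.

The default scenario (`scenario_study_scale()`) mirrors the study
conditions: 878 familial + 410 MPM + 816 sporadic cases (2,104), 1,446
internal controls, a 64,603-individual reference, 16 LOF-like variants with
reference AFs summing to 0.002 and multiplier 2.6, and 100 VUS-like
missense variants with AFs summing to 0.033 and multiplier 1.41.

What the generator deliberately does **not** emulate: relatedness and
population structure, linkage between variants, per-site coverage
differences (a single AN), sequencing platform heterogeneity, and
pedigree-level transmission (family records are drawn from regimes, not
simulated through genotypes). Passing calibration tests therefore shows the
statistics behave correctly under the design's idealised assumptions — not
that real cohorts satisfy those assumptions.

## Calibration checks and problem sizes

The test suite runs two stochastic guarantees at sizes chosen to keep the
whole suite fast while leaving Monte-Carlo error well below the asserted
margins:

* **Null calibration** — a one-variant scenario (500 cases, 5,000 reference
  individuals, AF 0.01, multiplier 1) over 2,000 seeded replicates: the
  fraction of p < 0.05 must not exceed 0.05 by more than 3 Monte-Carlo
  standard errors (exact tests are conservative).
* **Interval coverage** — 1,000 replicates at the study-scale margins
  (4,208 case alleles, 129,206 reference alleles, reference AF 0.002) with
  a true odds ratio of exactly 2.6 on the odds scale: conditional-exact 95%
  intervals must cover the truth in at least 93% of replicates.

## Bundled study reconstruction

`atm_study_dataset()` and `atm_two_center_dataset()` rebuild, in code, a
dataset whose aggregate counts match a published 2,104-case multicenter
melanoma cohort. The 20 LOF carriers, their variants, strata and family
ratios are public at the individual level and are reproduced faithfully.
The VUS side is public only in aggregate, so individual-level VUS rows are
*synthetic*, constructed to reproduce every published marginal exactly
(192 alleles in 102/20/51 carriers per stratum, 135 alleles in the enriched
subset, 117 unique case variants, 13 recurrent in ≥ 3 cases); internal
splits the aggregates do not pin down (which carriers double up, the
familial/MPM composition of the two-center non-carriers, which five case
LOF variants besides c.3576G>A are shared with the reference) were fixed
once as documented constants. The reference is shipped as aggregate
pseudo-variant rows (237 LOF / 4,268 VUS alleles over AN 129,206) plus a
per-variant row for c.3576G>A (AC 5, the only integer count consistent with
its published reference AF of 0.00004); because an aggregate row must not
pass through the per-variant missense frequency filter, its category is
supplied directly through the `classified` argument of `atm_burden()`.

## Known limitations

* Variant identity is the normalised cDNA HGVS string; no transcript-aware
  validation or genomic liftover is attempted, so cohort and reference
  tables must already share nomenclature.
* The missense filters consult a single reference AF; population-maximum
  frequencies across ancestries are not considered.
* The per-variant odds ratio against a reference AC as small as 5 is
  unstable by nature; the conditional-exact interval conveys that width
  honestly, but such estimates should not be over-read.
* No covariate adjustment, kinship correction or regression-based burden
  model is provided — the design is exact 2×2 inference throughout.
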