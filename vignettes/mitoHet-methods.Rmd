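---
title: "mitoHet: methods and design notes"
author: "mitoHet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoHet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoHet)
```

## The problem

Mitochondrial DNA heteroplasmy — the coexistence of more than one mtDNA
sequence variant within an individual — is quantified here as the minor
allele frequency (MAF) at a site.  At ultra-deep coverage (tens of
thousands of reads per position), heteroplasmies well below 1% become
measurable, but so does sequencing error, so the calling rules and their
validation matter as much as the measurement itself.  `mitoHet`
implements a complete analysis of low-level blood heteroplasmy in the
853-bp mtDNA control-region fragment (rCRS positions 15978--16569 and
1--261) for a cohort of centenarian mothers (CENT), their offspring
(CO) and offspring of non-long-lived parents (ONLL): calling,
replicate-PCR validation, cohort statistics, and mother--offspring
transmission analysis against reshuffling nulls.

The pipeline's entry point is *post-alignment, post-quality-filter*
strand-resolved allele counts (`StrandCounts`).  Read mapping, base
quality recalibration and numts exclusion are upstream, wet-lab or
aligner concerns and are out of scope; equally out of scope is the
estimation of per-site mutation rates, which enter as a user-supplied
table.

## Coordinates and regions

All coordinates are 1-based rCRS positions; intervals are closed and
may cross the circular origin (the fragment itself does: 15978 → 16569
→ 1 → 261).  Circularity is handled by explicit arc enumeration rather
than modular arithmetic, so region boundaries stay auditable:

```{r}
regionSizes()          # HV1, intermediate, HV2; sums to 853
```

HV1 spans 15978--16364, the intermediate region 16365--72 (crossing
the origin) and HV2 73--261.  The three segments partition the
fragment; `assignRegion()` is total and single-valued over it.

## Calling model

At each site the combined-strand counts define the sample's **major**
allele (most frequent base) and **minor** allele (second most
frequent); MAF is the minor count over the total depth.  Key choices:

* **Threshold.** A site is called heteroplasmic when MAF ≥ 0.2%
  (`threshold = 0.002`), with ≥ so that boundary sites are retained.
* **Per-sample definition.** The minor allele is defined against the
  sample's own major allele, not the rCRS base: heteroplasmy is
  intra-individual variation, and a homoplasmic difference from the
  reference is not a heteroplasmy.
* **Double-strand validation.** The same minor allele must reach the
  per-strand threshold independently on the plus and the minus strand
  (`strandMultiplier`, default 1.0, scales the per-strand threshold).
  The per-strand minor allele is the most frequent non-major base on
  that strand; an identity mismatch between strands fails validation,
  as does strand dropout (zero depth on either strand).  This is the
  piece that suppresses strand-specific artifacts, and the
  strand-asymmetric error option of the generator exists to exercise
  it.
* **Tie-breaking.** Equal counts resolve alphabetically
  (A < C < G < T), deterministically.
* **QC.** Mean coverage is averaged over all 853 positions (absent
  positions count 0); samples below 10,000× are excluded, with
  exactly 10,000 passing.  QC-failed samples carry an empty call set.

SNVs only: the count table has four base columns and indels are
excluded upstream by construction.

One open point inherited from the field: whether MAF denominators
should count all aligned bases or A/C/G/T only.  Counts here are
A/C/G/T by schema, so the distinction dissolves at the table level.

## Replicate concordance

For samples amplified as three independent PCR products, a site is
"true heteroplasmic" when supported by at least `k = 2` of the 3
replicate call sets (`consensusTruth()`).  Each replicate is then
scored against the consensus over all 853 positions
(`replicateConfusion()`: tp + fp + fn + tn = 853), giving per-replicate
sensitivity and specificity.  Aggregation averages within sample first
and then across samples (`aggregate = "within"`); pooled
replicate-level aggregation is available, since the original analysis
does not state its order.  Undefined ratios (empty truth sets) are
excluded and counted, never imputed.  Concordance is judged on site
identity; MAF agreement across replicates is a separate diagnostic
(`replicateMafConcordance()`, mean pairwise absolute MAF difference).

## Cohort statistics

The cohort's central object is the MAF matrix, a
`SummarizedExperiment` with the 853 positions as rows, QC-passing
samples as columns and zeros at uncalled sites.

* **Region enrichment.** Per region, a 2×2 table of heteroplasmic vs
  non-heteroplasmic positions inside vs outside, tested two-sided with
  `fisher.test`.  The reported odds ratio is the sample cross-product
  OR (with Haldane--Anscombe 0.5 correction when a cell is empty) and
  a Woolf log-OR 95% CI; the conditional-MLE OR that `fisher.test`
  reports is close but not identical, and the cross-product form is
  the one whose arithmetic a reader can check by hand.  A table with
  an empty margin carries no association information and reports OR 1
  with an unbounded CI.
* **Mutation rates.** Pearson correlation between per-position
  occurrence counts and the rate table; mean rate at heteroplasmic vs
  all sites per stratum (fragment, HV1, HV2, intermediate) with a
  two-sided Mann--Whitney test.  Complete ties give p = 1 by
  convention (no evidence of a shift).
* **Per-site ANOVA.** Classical one-way ANOVA of MAF on group, zeros
  included for samples without a call — excluding them
  (`hetOnly = TRUE`) leaves most sites untestable.  Sites with zero
  variance report F = 0, p = 1.  Nominally significant sites get
  Tukey HSD contrasts at 0.05; the family-wide correction across 853
  positions is Bonferroni by default (Benjamini--Hochberg optional).
  The classical (not Welch) form was chosen because group variances
  are comparable under the zero-inflated coding and it preserves the
  textbook F = t² identity with two groups, which the tests verify.
* **Age.** Pearson correlations per position and for the per-sample
  heteroplasmic-site count; constant columns are flagged undefined.
* **Clustering.** Complete-linkage agglomeration on Euclidean
  distances between sample MAF vectors; samples are sorted by id
  before clustering so ties break deterministically; export to Newick
  via `ape`.

## Transmission statistics

* **Total heteroplasmy** is the per-individual mutation load: the sum
  of called MAFs × 100, in percent.
* **Pair correlation** is the Pearson correlation of a per-sample
  statistic across the 29 mother--offspring pairs.
* **TNCS** (total number of common sites) sums, over pairs, the
  positions heteroplasmic in both members.
* **Site distance** for a position heteroplasmic in both members is
  `100·|m₁ − m₂| / max(m₁, m₂)` — 0 for identical MAFs, approaching
  100 as one MAF dwarfs the other.  It is only defined for jointly
  heteroplasmic sites.
* **Public vs private.** A position heteroplasmic in both members of
  at least half the pairs (`publicFraction = 0.5`) is *public* — the
  recurrent, cohort-wide sites such as 146, 204 and 16129; shared by
  at least one but fewer pairs, *private*; otherwise absent.  The 0.5
  fraction is this package's operationalisation of "shared by most
  pairs", configurable.

**Reshuffling nulls.** Each of 2000 replicates applies a uniform
random permutation to the offspring side and recomputes the statistic.
The identity permutation is allowed by default — among n! possibilities
its effect is negligible, and excluding it is an option.  The empirical
p uses the add-one convention `(1 + #{replicates ≥ observed})/(1 + B)`,
which cannot return 0.  Degenerate replicates (zero variance) are
resampled and counted.  For cross-group comparisons with no family
structure (CENT--ONLL, CO--ONLL), replicates pair values drawn without
replacement, truncated to the smaller group (28), and the result has
no observed value — it summarises where chance correlations fall.

A note on the null's shape, established by brute-force enumeration in
the test suite: for two fixed value vectors, the permutation
distribution of Pearson r has mean exactly 0 (the permutation-averaged
cross-product factorises into two centred sums).  The familiar
−1/(n−1) mean belongs to a different construction — a vector correlated
with a derangement of itself, i.e. sampling without replacement from
one finite population — and the suite verifies both facts so the two
are not conflated.

## The synthetic cohort generator

The generator (`generatorConfig()`, `generateTruthCohort()`,
`simulateStrandCounts()`) emulates the statistical structure the
analysis assumes, with full truth bookkeeping so recovery is checkable
end to end.  Defaults are the study conditions: 29 pairs + 28 ONLL,
mean combined coverage 50,000× (split per strand), per-strand error
5×10⁻⁴, detection threshold 0.2%.

* **Rate table.** Gamma-distributed relative rates with region means
  4.7 (HV1), 6.2 (HV2) and 1.6 (intermediate) — the scale of
  Phylotree-derived control-region estimates — and shape 0.3.  The
  small shape gives a strongly heavy-tailed spectrum in which a
  minority of positions carries most of the mutational flux; lighter
  tails visibly under-produce the occurrence--rate correlation
  (r ≈ 0.34--0.45 at this shape) that a realistic cohort shows.
  Hotspots (146, 204, 16129) are pinned into the top decile.
* **Truth model.** Mothers and ONLL receive Poisson(6) baseline sites
  placed ∝ mutation rate, plus each public site with probability 0.9;
  site MAFs are exponential (scale 0.004) truncated to [0.002, 0.5].
  Offspring inherit each maternal site with retention ρ = 0.8, the
  inherited MAF multiplied by lognormal jitter (sd 0.3 on the log
  scale), plus Poisson(2) de novo sites and their own public-site
  draws.  Inheritance is phenomenological — retention plus jitter, not
  an explicit germline bottleneck, whose size the field treats as
  open.  De novo placement ∝ rate makes the characteristic
  occurrence/level shape emerge: frequent sites are hotspot-driven and
  low-level, high-MAF sites are rare draws, and the
  high-frequency/high-level corner stays empty.
* **Counts.** Per site and strand, depth is Poisson around half the
  mean (negative binomial under overdispersion); minor reads are
  binomial at the true MAF; error reads are binomial at the per-strand
  error rate, split uniformly over the three non-major bases.
  Strand-asymmetric error rates are available to exercise
  double-strand validation.  At these settings the per-base error
  expectation sits far below the 0.2% threshold at 50,000×, so false
  positives are rare and planted sites with MAF ≥ 0.4% are recovered
  essentially always — which is what the recovery tests assert.
* **Replicates.** Independent count realizations from the same truth;
  optional lognormal per-replicate MAF perturbation for PCR drift
  (default off).

Everything is a pure function of (config, seed); the determinism tests
compare byte-identical outputs.

What the generator does **not** emulate: read-level artifacts (PCR
chimeras, alignment error), numts contamination, linkage between
sites, somatic clonal expansion, or any association between
heteroplasmy and longevity — group labels differ only in age
distributions (101.6 ± 2.8, 69.9 ± 6.6, 70.7 ± 4.8 years) and family
structure.  Passing recovery tests therefore demonstrates that the
pipeline measures what the model plants, not that real blood data obey
the model.

## Problem sizes and numerical conventions

The test suite runs the full calling-recovery check over 100
single-sample seeds, the transmission recovery over 50 full-pipeline
seeds (plus 200 truth-level seeds for the no-inheritance uniformity
check), and the ANOVA calibration over 853 null sites with 3 groups of
30 — sizes chosen to give stable Monte-Carlo estimates at desk scale.
The end-to-end determinism check uses a reduced cohort (8 pairs,
20,000×), since determinism is scale-free.  Floating-point output uses
fixed precision: MAFs 6 decimals, statistics 6 significant digits.
Empirical p-values can never be 0 (add-one convention); exact ties at
thresholds are kept (≥ everywhere).

## Worked example

```{r, eval = FALSE}
out <- runFullStudy("study_out", generatorConfig(), seed = 1)
out$pairSummary          # per-family total heteroplasmy and shared sites
out$thNull               # reshuffling null of the pair correlation
classifySites(out$pairs) # public / private / absent per position
```

## Known limitations

* The calling rule validates the combined-strand minor allele against
  each strand's own minor; a site with two genuine minor alleles at
  comparable frequency would validate only the stronger one.
* The double-strand rule is a per-strand threshold test, a documented
  design choice; published pipelines differ in the exact statistic.
* ANOVA on zero-inflated MAF columns is the field's convention, not a
  calibrated model for zero-heavy data; the type-I calibration test
  covers the null case only.
* Cross-group nulls truncate to the smaller group, discarding one
  value per replicate when groups are unequal.
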