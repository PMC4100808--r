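# mitoHet

Low-level mitochondrial DNA heteroplasmy calling and familial
transmission analysis.

## What it is for

Heteroplasmy — the coexistence of more than one mtDNA variant within an
individual — can be measured down to minor allele frequencies (MAF) of
0.2% when coverage reaches tens of thousands of reads per position.
`mitoHet` is for researchers analysing ultra-deep amplicon resequencing
of the 853-bp mtDNA control-region fragment (rCRS positions
15978–16569 and 1–261, spanning HV1, the intermediate region and part
of HV2) in cohorts with family structure: it calls low-level
heteroplasmies from strand-resolved allele counts, validates the
calling with triplicate-PCR concordance, and quantifies how
heteroplasmy profiles are transmitted from mothers to offspring.

The package includes a synthetic cohort generator with full truth
bookkeeping, so every stage of the pipeline — calling, replicate
consensus, cohort statistics, transmission — is testable end to end
without access to raw sequencing data.

## The model in brief

**Calling.** At each site the combined-strand counts define the
sample's major and minor allele; MAF = minor count / depth.  A site is
heteroplasmic when MAF ≥ 0.002 *and* the same minor allele reaches the
threshold independently on each strand (double-strand validation,
which suppresses strand-specific artifacts).  Samples with mean
coverage < 10,000× are excluded.

**Replicates.** A site is "true heteroplasmic" when supported by ≥ 2
of 3 PCR replicates; each replicate is scored against that consensus
over all 853 positions, giving sensitivity = tp/(tp+fn) and
specificity = tn/(tn+fp).

**Cohort statistics.** Region enrichment of heteroplasmic positions by
two-sided Fisher exact test (cross-product OR, Woolf 95% CI); Pearson
correlation of per-position occurrence with site mutation rates;
per-site one-way ANOVA of MAF across groups with Tukey contrasts and
Bonferroni correction; age correlations; complete-linkage clustering
of sample MAF vectors.

**Transmission.** Per individual, total heteroplasmy = Σ MAF × 100
(percent).  Across the mother–offspring pairs: the Pearson correlation
of total heteroplasmy, the total number of common sites
(TNCS = Σ_pairs |mother ∩ offspring|), the per-site distance
100·|m₁−m₂|/max(m₁,m₂) for jointly heteroplasmic sites, and a
public/private classification of positions by the fraction of pairs
sharing them.  Each statistic is compared against a null distribution
from 2000 random reshuffles of the offspring side, with the add-one
empirical p = (1 + #{null ≥ observed})/(1 + 2000).

## Worked example

Simulate the default study cohort (29 mother–offspring pairs plus 28
unrelated controls at 50,000× coverage), run the whole pipeline and
inspect the transmission results:

```r
library(mitoHet)
res <- runFullStudy("study_out", generatorConfig(), seed = 1)

head(res$pairSummary, 4)
#>   familyId thMother thOffspring sharedSites
#>        F01 3.634851    4.620248           6
#>        F02 4.075482    6.166166           5
#>        F03 4.476013    5.203266           8
#>        F04 4.479567    5.783542           7

res$thNull
#> NullDistribution [pearson]: observed 0.7705; 2000 reshuffles
#> (mean -0.00678, sd 0.188); p = 0.0004998

table(res$classification)
#>  absent private  public
#>     762      88       3
```

Reading this: each family's total heteroplasmy (percent) is similar
between mother and offspring — across the 29 pairs the correlation is
r = 0.77, while random mother–offspring matchings scatter around zero
(sd 0.19), so the observed concordance is essentially never reached by
chance (empirical p ≈ 0.0005).  Three positions (146, 204, 16129 in
this run) are *public* — heteroplasmic in both members of most
families — while 88 are *private* to one or a few families.  Region
enrichment from the same run puts the hypervariable segments above the
intermediate region (OR 1.69 for HV1, 1.41 for HV2, 0.37 for the
intermediate region), and the triplicate analysis reports mean
sensitivity 0.984 and specificity 0.9999 for calling at the 0.2%
threshold.

`study_out/` then contains the tab-separated reports (calls, per-site
statistics, enrichment, pair summary, null summaries, Newick
clustering) plus a JSON manifest recording seeds and configuration.

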