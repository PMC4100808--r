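Package: mitoHet
Title: Low-Level mtDNA Heteroplasmy Calling and Familial Transmission
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls low-level mitochondrial DNA heteroplasmies (minor
    allele frequency >= 0.2%) from ultra-deep strand-resolved allele
    counts over the 853-bp mtDNA control-region fragment (rCRS positions
    15978-16569 and 1-261), with double-strand validation and
    mean-coverage quality control.  Provides triplicate-PCR concordance
    analysis (majority-consensus truth sets, confusion matrices,
    sensitivity/specificity), cohort-level statistics (per-site
    occurrence and level, hypervariable-region enrichment by Fisher
    exact test, mutation-rate correlations, per-site ANOVA across
    groups, age correlations, complete-linkage clustering), and
    mother-offspring transmission statistics (total heteroplasmy, shared
    heteroplasmic sites, site-by-site distances, public/private site
    classification) with reshuffling null distributions.  A synthetic
    cohort generator with full truth bookkeeping emulates inherited and
    de novo heteroplasmies, mutation-rate hotspots and strand-specific
    deep-sequencing error, so every stage of the pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
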