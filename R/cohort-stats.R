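# Cohort-level statistics on the sample x site MAF matrix: occurrence
# and level, hypervariable-region enrichment, mutation-rate correlations,
# per-site ANOVA, age correlations, hierarchical clustering.

#' Build the MAF matrix as a SummarizedExperiment
#'
#' Rows are the 853 fragment positions (in fragment order), columns are
#' QC-passing samples; the `maf` assay holds the called minor allele
#' frequency (0 where the sample has no call).  Row metadata carries the
#' control-region segment; column metadata the sample annotations.
#'
#' @param cohort A [HetCohort-class] (or list of
#'   [SampleProfile-class] objects).
#' @param dropFailed Drop QC-failed samples (default `TRUE`).
#' @param map Region map for row annotation.
#' @return A [SummarizedExperiment::SummarizedExperiment-class].
#' @export
mafMatrix <- function(cohort, dropFailed = TRUE, map = defaultRegionMap()) {
  profs <- if (is(cohort, "HetCohort")) profiles(cohort) else cohort
  if (dropFailed) profs <- Filter(qcPass, profs)
  if (!length(profs))
    stop2("no QC-passing samples", class = "mitoHet_qc_error")
  pos <- fragmentPositions()
  m <- vapply(profs, function(p) {
    v <- numeric(length(pos))
    cl <- hetCalls(p)
    if (nrow(cl)) v[match(cl$site, pos)] <- cl$maf
    v
  }, numeric(length(pos)))
  rownames(m) <- as.character(pos)
  colnames(m) <- vapply(profs, sampleId, character(1))
  SummarizedExperiment(
    assays = list(maf = m),
    rowData = DataFrame(position = pos, region = assignRegion(pos, map)),
    colData = DataFrame(
      sampleId = colnames(m),
      group = vapply(profs, slot, character(1), "group"),
      familyId = vapply(profs, slot, character(1), "familyId"),
      age = vapply(profs, slot, numeric(1), "age"),
      meanCoverage = vapply(profs, slot, numeric(1), "meanCoverage"),
      row.names = colnames(m)))
}

#' Per-position heteroplasmy occurrence and mean level within a group
#'
#' @param se MAF matrix ([mafMatrix()]).
#' @param group Group label (`CENT`, `CO` or `ONLL`).
#' @param threshold Detection threshold; a sample counts as heteroplasmic
#'   at a position when its MAF is at or above it.
#' @return `data.frame` with `position`, `count` (samples heteroplasmic),
#'   `meanMaf` (mean MAF over those samples; `NA` where `count` is 0).
#' @export
occurrenceCounts <- function(se, group, threshold = 0.002) {
  if (!group %in% colData(se)$group)
    stop2("unknown group: ", group, class = "mitoHet_parameter_error")
  m <- assay(se, "maf")[, colData(se)$group == group, drop = FALSE]
  het <- m >= threshold
  count <- rowSums(het)
  meanMaf <- ifelse(count > 0, rowSums(m * het) / count, NA_real_)
  data.frame(position = rowData(se)$position, count = as.integer(count),
             meanMaf = meanMaf, row.names = NULL)
}

# Cross-product odds ratio with Haldane-Anscombe 0.5 correction when any
# cell is empty, plus the Woolf (log-OR normal) 95% CI.  A table with an
# empty margin (all positions heteroplasmic, or none) carries no
# association information: OR is 1 with an unbounded CI.
wolffOR <- function(a, b, c, d, conf = 0.95) {
  if (a + c == 0 || b + d == 0 || a + b == 0 || c + d == 0)
    return(list(or = 1, low = 0, high = Inf))
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5
                                 c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1/a + 1/b + 1/c + 1/d)
  z <- qnorm(1 - (1 - conf) / 2)
  list(or = or, low = exp(log(or) - z * se), high = exp(log(or) + z * se))
}

#' Region enrichment of heteroplasmic positions (Fisher exact test)
#'
#' For each control-region segment, tabulates heteroplasmic versus
#' non-heteroplasmic positions inside versus outside the segment and
#' tests the 2x2 table with a two-sided Fisher exact test.  The reported
#' odds ratio is the sample (cross-product) OR with Haldane-Anscombe 0.5
#' correction when any cell is empty, and a Woolf log-OR 95\% CI.
#'
#' @param hetSites Integer vector of heteroplasmic positions (within the
#'   fragment).
#' @param map Region map.
#' @return `data.frame` with one row per region: cells `hetIn`,
#'   `nonHetIn`, `hetOut`, `nonHetOut`, `oddsRatio`, `ciLow`, `ciHigh`,
#'   `pValue`, `degenerate` (no heteroplasmic site at all).
#' @export
regionEnrichment <- function(hetSites, map = defaultRegionMap()) {
  frag <- fragmentPositions()
  hetSites <- unique(as.integer(hetSites))
  if (length(setdiff(hetSites, frag)))
    stop2("heteroplasmic site(s) outside the fragment",
          class = "mitoHet_coordinate_error")
  posList <- regionPositions(map)
  degenerate <- length(hetSites) == 0L
  res <- lapply(names(posList), function(r) {
    inR <- posList[[r]]
    a <- length(intersect(hetSites, inR))          # het, in region
    b <- length(inR) - a                           # non-het, in region
    c_ <- length(hetSites) - a                     # het, outside
    d <- length(frag) - length(inR) - c_           # non-het, outside
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    wo <- wolffOR(a, b, c_, d)
    data.frame(region = r, hetIn = a, nonHetIn = b, hetOut = c_,
               nonHetOut = d, oddsRatio = wo$or, ciLow = wo$low,
               ciHigh = wo$high, pValue = ft$p.value,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Correlation between heteroplasmy occurrence and site mutation rate
#'
#' Pearson correlation, over all fragment positions, between per-position
#' occurrence counts (from [occurrenceCounts()]) and the relative
#' mutation rate of the site.
#'
#' @param occurrences `data.frame` from [occurrenceCounts()] (or any with
#'   `position` and `count`).
#' @param rates Mutation-rate table: `data.frame` with `position` and
#'   `rate`, covering every fragment position.
#' @return List with `r` and `p` (two-sided).
#' @export
mrCorrelation <- function(occurrences, rates) {
  x <- occurrences$count[match(rates$position, occurrences$position)]
  y <- rates$rate
  if (anyNA(x))
    stop2("occurrence table does not cover the rate table positions",
          class = "mitoHet_parameter_error")
  if (var(x) == 0 || var(y) == 0)
    stop2("zero variance: correlation undefined",
          class = "mitoHet_degenerate_error")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Mean mutation rate at all sites versus heteroplasmic sites
#'
#' Per stratum (entire fragment, HV1, HV2, intermediate region), the mean
#' relative mutation rate over all positions and over heteroplasmic
#' positions only, with a two-sided Mann-Whitney test comparing the two
#' sets of rates.
#'
#' @param hetSites Integer vector of heteroplasmic positions (non-empty).
#' @param rates Mutation-rate table (`position`, `rate`).
#' @param map Region map.
#' @return `data.frame` with `stratum`, `nHet`, `meanAll`, `meanHet`
#'   (`NA` when the stratum has no heteroplasmic site), `pValue`,
#'   `lowPower` (fewer than 2 heteroplasmic sites in the stratum).
#' @export
meanRateComparison <- function(hetSites, rates, map = defaultRegionMap()) {
  hetSites <- unique(as.integer(hetSites))
  if (!length(hetSites))
    stop2("no heteroplasmic sites", class = "mitoHet_degenerate_error")
  rate <- setNames(rates$rate, rates$position)
  strata <- c(list(FRAGMENT = fragmentPositions()), regionPositions(map))
  do.call(rbind, lapply(names(strata), function(s) {
    posAll <- strata[[s]]
    posHet <- intersect(hetSites, posAll)
    rAll <- rate[as.character(posAll)]
    rHet <- rate[as.character(posHet)]
    p <- if (length(posHet) >= 1L)
      suppressWarnings(wilcox.test(rHet, rAll)$p.value) else NA_real_
    # complete ties leave the normal approximation 0/0; no evidence of
    # a shift means p = 1
    if (is.nan(p)) p <- 1
    data.frame(stratum = s, nHet = length(posHet),
               meanAll = mean(rAll),
               meanHet = if (length(posHet)) mean(rHet) else NA_real_,
               pValue = p, lowPower = length(posHet) < 2L,
               stringsAsFactors = FALSE)
  }))
}

#' Per-site one-way ANOVA of heteroplasmy level across groups
#'
#' Classical one-way ANOVA of MAF on group, site by site.  Samples
#' without a call at a site contribute MAF 0 by default (`hetOnly =
#' FALSE`); with `hetOnly = TRUE` they are excluded (most sites then
#' become untestable).  Pairwise contrasts for nominally significant
#' sites use Tukey HSD at 0.05.  The family-wide adjustment across the
#' 853 positions is Bonferroni by default (Benjamini-Hochberg via
#' `adjust = "BH"`).  Sites with zero total variance get `F = 0`,
#' `p = 1`.
#'
#' @param se MAF matrix ([mafMatrix()]).
#' @param adjust `"bonferroni"` or `"BH"`.
#' @param hetOnly Exclude zero (non-called) MAFs.
#' @param threshold Detection threshold used with `hetOnly`.
#' @return `data.frame` with `position`, `F`, `p`, `pAdj`,
#'   `significantContrasts` (comma-separated Tukey-significant pairs for
#'   sites with nominal p < 0.05, else "").
#' @export
perSiteAnova <- function(se, adjust = c("bonferroni", "BH"),
                         hetOnly = FALSE, threshold = 0.002) {
  adjust <- match.arg(adjust)
  g <- factor(colData(se)$group)
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop2("need at least 2 groups with at least 2 samples each",
          class = "mitoHet_parameter_error")
  m <- assay(se, "maf")
  res <- lapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]; gi <- g
    if (hetOnly) { keep <- y >= threshold; y <- y[keep]; gi <- droplevels(g[keep]) }
    if (length(y) < 3L || nlevels(gi) < 2L || var(y) == 0)
      return(list(F = 0, p = 1, contrasts = ""))
    ssw <- sum(tapply(y, gi, function(v) sum((v - mean(v))^2)))
    if (ssw == 0) {                      # groups internally constant, means differ
      return(list(F = Inf, p = 0, contrasts = ""))
    }
    ow <- oneway.test(y ~ gi, var.equal = TRUE)
    contr <- ""
    if (!is.na(ow$p.value) && ow$p.value < 0.05 && all(table(gi) >= 2L)) {
      tk <- TukeyHSD(aov(y ~ gi))$gi
      sig <- rownames(tk)[tk[, "p adj"] < 0.05]
      contr <- paste(sig, collapse = ",")
    }
    list(F = unname(ow$statistic), p = ow$p.value, contrasts = contr)
  })
  data.frame(position = rowData(se)$position,
             F = vapply(res, `[[`, numeric(1), "F"),
             p = vapply(res, `[[`, numeric(1), "p"),
             pAdj = p.adjust(vapply(res, `[[`, numeric(1), "p"),
                             method = adjust, n = nrow(m)),
             significantContrasts = vapply(res, `[[`, character(1),
                                           "contrasts"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlations between age and heteroplasmy
#'
#' Per position, the Pearson correlation (two-sided p) between sample
#' ages and MAF; constant MAF columns are flagged undefined.  Also
#' reports the correlation between age and the per-sample number of
#' heteroplasmic sites.
#'
#' @param se MAF matrix; `colData(se)$age` must be available for all
#'   samples.
#' @param threshold Detection threshold for the site count.
#' @return List with `perSite` (`data.frame`: `position`, `r`, `p`,
#'   `undefined`) and `countVsAge` (list `r`, `p`).
#' @export
ageCorrelations <- function(se, threshold = 0.002) {
  age <- colData(se)$age
  if (anyNA(age))
    stop2("ages missing for some samples", class = "mitoHet_parameter_error")
  m <- assay(se, "maf")
  perSite <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    if (var(y) == 0)
      return(data.frame(position = rowData(se)$position[i], r = NA_real_,
                        p = NA_real_, undefined = TRUE))
    ct <- cor.test(age, y)
    data.frame(position = rowData(se)$position[i], r = unname(ct$estimate),
               p = ct$p.value, undefined = FALSE)
  }))
  counts <- colSums(m >= threshold)
  countVsAge <- if (var(counts) == 0) list(r = NA_real_, p = NA_real_)
  else { ct <- cor.test(age, counts)
         list(r = unname(ct$estimate), p = ct$p.value) }
  list(perSite = perSite, countVsAge = countVsAge)
}

#' Unsupervised hierarchical clustering of samples
#'
#' Complete-linkage agglomeration on Euclidean distances between sample
#' MAF vectors.  Samples are ordered by sample id before clustering so
#' ties are broken deterministically.
#'
#' @param se MAF matrix.
#' @param distMethod Distance metric passed to [stats::dist()].
#' @return An [stats::hclust] object.
#' @export
clusterSamples <- function(se, distMethod = "euclidean") {
  if (ncol(se) < 2L)
    stop2("need at least 2 samples", class = "mitoHet_parameter_error")
  if (anyDuplicated(colnames(se)))
    stop2("duplicate sample ids", class = "mitoHet_parameter_error")
  m <- t(assay(se, "maf"))
  m <- m[order(rownames(m)), , drop = FALSE]
  hclust(dist(m, method = distMethod), method = "complete")
}

#' Serialise a dendrogram to Newick
#'
#' @param hc An [stats::hclust] object (e.g. from [clusterSamples()]).
#' @param path Optional file path; when given the tree is written there.
#' @return Newick string (invisibly when written to file).
#' @export
clusterNewick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  if (is.null(path)) ape::write.tree(tr)
  else { ape::write.tree(tr, file = path); invisible(path) }
}
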