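# Mother-offspring transmission statistics: total heteroplasmy, shared
# sites (TNCS), site-by-site distances, public/private classification,
# and reshuffling null distributions.

#' Build the mother-offspring pairing structure
#'
#' Pairs each QC-passing CENT profile with the QC-passing CO profile
#' sharing its family id; families missing either member are dropped.
#' QC-passing ONLL profiles are carried along for cross-group
#' reshuffling.
#'
#' @param cohort A [HetCohort-class] or list of
#'   [SampleProfile-class] objects.
#' @return A [PairSet-class] object.
#' @export
pairSet <- function(cohort) {
  profs <- if (is(cohort, "HetCohort")) profiles(cohort) else cohort
  profs <- Filter(qcPass, profs)
  grp <- vapply(profs, slot, character(1), "group")
  fam <- vapply(profs, slot, character(1), "familyId")
  cent <- profs[grp == "CENT" & !is.na(fam)]
  co <- profs[grp == "CO" & !is.na(fam)]
  famC <- vapply(cent, slot, character(1), "familyId")
  famO <- vapply(co, slot, character(1), "familyId")
  shared <- sort(intersect(famC, famO))
  new("PairSet", familyId = shared,
      mothers = cent[match(shared, famC)],
      offspring = co[match(shared, famO)],
      onll = profs[grp == "ONLL"])
}

#' Total heteroplasmy of a sample
#'
#' The per-individual mutation load: the sum of minor allele frequencies
#' over all called heteroplasmic sites, expressed in percent.
#'
#' @param x A [SampleProfile-class] (or a list / [HetCohort-class], in
#'   which case a named numeric vector is returned).
#' @return Total heteroplasmy in percent (0 for an empty call set).
#' @export
#' @examples
#' p <- SampleProfile("s1", "CENT",
#'        calls = data.frame(site = c(146L, 204L, 16129L),
#'                           major = "A", minor = "G",
#'                           maf = c(0.005, 0.003, 0.002),
#'                           depth = 50000L, dsValidated = TRUE))
#' totalHeteroplasmy(p)  # 1.0
setGeneric("totalHeteroplasmy", function(x) standardGeneric("totalHeteroplasmy"))

#' @export
setMethod("totalHeteroplasmy", "SampleProfile", function(x) {
  if (!x@qcPass)
    stop2("total heteroplasmy undefined for QC-failed sample ",
          x@sampleId, class = "mitoHet_qc_error")
  sum(x@calls$maf) * 100
})

#' @export
setMethod("totalHeteroplasmy", "HetCohort", function(x) {
  vapply(profiles(x), totalHeteroplasmy, numeric(1))
})

#' @export
setMethod("totalHeteroplasmy", "list", function(x) {
  setNames(vapply(x, totalHeteroplasmy, numeric(1)),
           vapply(x, sampleId, character(1)))
})

#' Mother-offspring correlation of a per-sample statistic
#'
#' Pearson correlation over (mother value, offspring value) pairs.
#'
#' @param pairs A [PairSet-class].
#' @param statistic Function mapping a [SampleProfile-class] to a
#'   number (default [totalHeteroplasmy()]).
#' @return List with `r` and two-sided `p`.
#' @export
pairCorrelation <- function(pairs, statistic = totalHeteroplasmy) {
  x <- vapply(pairs@mothers, statistic, numeric(1))
  y <- vapply(pairs@offspring, statistic, numeric(1))
  if (length(x) < 3L)
    stop2("need at least 3 pairs", class = "mitoHet_parameter_error")
  if (var(x) == 0 || var(y) == 0)
    stop2("zero variance: correlation undefined",
          class = "mitoHet_degenerate_error")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Total number of common sites (TNCS)
#'
#' Sum over mother-offspring pairs of the number of positions
#' heteroplasmic in both members.
#'
#' @param x A [PairSet-class], or a list of mother site vectors.
#' @param y When `x` is a list: the parallel list of offspring site
#'   vectors.
#' @return Integer shared-site count.
#' @export
setGeneric("tncs", function(x, y) standardGeneric("tncs"))

#' @export
setMethod("tncs", signature("PairSet", "missing"), function(x, y) {
  tncs(lapply(x@mothers, hetSites), lapply(x@offspring, hetSites))
})

#' @export
setMethod("tncs", signature("list", "list"), function(x, y) {
  stopifnot(length(x) == length(y))
  sum(vapply(seq_along(x),
             function(i) length(intersect(x[[i]], y[[i]])), integer(1)))
})

#' Shared heteroplasmic sites per pair
#'
#' @param pairs A [PairSet-class].
#' @return `data.frame` with `familyId`, `thMother`, `thOffspring`
#'   (total heteroplasmy, percent), `sharedSites`.
#' @export
pairSummary <- function(pairs) {
  data.frame(
    familyId = pairs@familyId,
    thMother = vapply(pairs@mothers, totalHeteroplasmy, numeric(1)),
    thOffspring = vapply(pairs@offspring, totalHeteroplasmy, numeric(1)),
    sharedSites = vapply(seq_len(nPairs(pairs)), function(i)
      length(intersect(hetSites(pairs@mothers[[i]]),
                       hetSites(pairs@offspring[[i]]))), integer(1)),
    stringsAsFactors = FALSE)
}

#' Reshuffling null distribution for a transmission statistic
#'
#' Recomputes the statistic after applying, per replicate, a uniform
#' random permutation to the offspring side (the true pairing is broken;
#' the identity permutation is allowed by default, negligible among `n!`
#' possibilities, and can be excluded).  The observed value is computed
#' on the true pairing, and the empirical p uses the add-one upper-tail
#' convention `(1 + #\{replicates >= observed\}) / (1 + n)`.  A replicate
#' on which the statistic is degenerate (e.g. zero variance for the
#' correlation) is resampled and counted.
#'
#' @param mothers,offspring For `statistic = "pearson"`: numeric value
#'   vectors (e.g. total heteroplasmy).  For `statistic = "tncs"`: lists
#'   of heteroplasmic-site vectors.
#' @param statistic `"pearson"` or `"tncs"`.
#' @param nReshuffles Number of reshuffles (default 2000).
#' @param seed Integer seed for the reshuffles.
#' @param excludeIdentity Reject the identity permutation.
#' @return A [NullDistribution-class] object.
#' @export
reshuffleNull <- function(mothers, offspring,
                          statistic = c("pearson", "tncs"),
                          nReshuffles = 2000, seed = 1L,
                          excludeIdentity = FALSE) {
  statistic <- match.arg(statistic)
  if (nReshuffles < 1)
    stop2("nReshuffles must be at least 1", class = "mitoHet_parameter_error")
  n <- length(mothers)
  stopifnot(length(offspring) == n)
  statFun <- switch(statistic,
    pearson = function(ix) {
      y <- offspring[ix]
      if (var(unlist(y)) == 0) NA_real_ else cor(mothers, y)
    },
    tncs = function(ix) as.numeric(tncs(mothers, offspring[ix])))
  if (statistic == "pearson") {
    mothers <- as.numeric(mothers); offspring <- as.numeric(offspring)
    if (var(mothers) == 0 || var(offspring) == 0)
      stop2("zero variance: observed statistic degenerate",
            class = "mitoHet_degenerate_error")
  }
  observed <- statFun(seq_len(n))
  set.seed(seed)
  reps <- numeric(nReshuffles)
  nDeg <- 0L
  for (b in seq_len(nReshuffles)) {
    repeat {
      ix <- sample.int(n)
      if (excludeIdentity && all(ix == seq_len(n))) { nDeg <- nDeg + 0L; next }
      v <- statFun(ix)
      if (is.na(v)) { nDeg <- nDeg + 1L; next }
      reps[b] <- v
      break
    }
  }
  p <- (1 + sum(reps >= observed)) / (1 + nReshuffles)
  new("NullDistribution", statistic = statistic, observed = observed,
      replicates = reps, p = p, seed = as.integer(seed),
      nDegenerate = nDeg)
}

#' Cross-group reshuffling null (no true pairing)
#'
#' For comparisons between groups with no family structure (CENT-ONLL,
#' CO-ONLL), each replicate pairs values drawn uniformly at random
#' without replacement from the two groups, truncated to the smaller
#' group size, and computes the Pearson correlation.  There is no
#' observed value; the result summarises where chance correlations fall.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @param nReshuffles Number of replicates (default 2000).
#' @param seed Integer seed.
#' @return A [NullDistribution-class] with `observed = NA`.
#' @export
crossGroupNull <- function(x, y, nReshuffles = 2000, seed = 1L) {
  m <- min(length(x), length(y))
  if (m < 3L)
    stop2("need at least 3 values per group",
          class = "mitoHet_parameter_error")
  set.seed(seed)
  reps <- numeric(nReshuffles)
  nDeg <- 0L
  for (b in seq_len(nReshuffles)) {
    repeat {
      xv <- sample(x, m); yv <- sample(y, m)
      if (var(xv) == 0 || var(yv) == 0) { nDeg <- nDeg + 1L; next }
      reps[b] <- cor(xv, yv)
      break
    }
  }
  new("NullDistribution", statistic = "pearson", observed = NA_real_,
      replicates = reps, p = NA_real_, seed = as.integer(seed),
      nDegenerate = nDeg)
}

#' Site-by-site distance between two MAFs
#'
#' The ratio between the absolute MAF difference and the higher of the
#' two MAFs, in percent: `100 * |m1 - m2| / max(m1, m2)`.  Defined only
#' for sites heteroplasmic in both individuals; values below the
#' detection threshold are a precondition error (such sites are excluded
#' upstream).
#'
#' @param mafMother,mafOffspring MAF fractions (each at or above
#'   `threshold`); vectorised.
#' @param threshold Detection threshold.
#' @return Distance(s) in `[0, 100]`.
#' @export
#' @examples
#' siteDistance(0.005, 0.0025)  # 50
siteDistance <- function(mafMother, mafOffspring, threshold = 0.002) {
  if (any(mafMother < threshold) || any(mafOffspring < threshold))
    stop2("site distance requires both MAFs at or above the detection ",
          "threshold", class = "mitoHet_parameter_error")
  100 * abs(mafMother - mafOffspring) / pmax(mafMother, mafOffspring)
}

#' Pairwise site-distance matrix
#'
#' Distances per pair and position for the positions heteroplasmic in
#' both members of the pair; all other cells are `NA`.
#'
#' @param pairs A [PairSet-class].
#' @param threshold Detection threshold.
#' @return Numeric matrix (pairs x 853 positions), rownames family ids.
#' @export
pairDistanceMatrix <- function(pairs, threshold = 0.002) {
  pos <- fragmentPositions()
  out <- matrix(NA_real_, nrow = nPairs(pairs), ncol = length(pos),
                dimnames = list(pairs@familyId, as.character(pos)))
  for (i in seq_len(nPairs(pairs))) {
    cm <- hetCalls(pairs@mothers[[i]]); co <- hetCalls(pairs@offspring[[i]])
    joint <- intersect(cm$site, co$site)
    if (length(joint)) {
      m1 <- cm$maf[match(joint, cm$site)]
      m2 <- co$maf[match(joint, co$site)]
      out[i, as.character(joint)] <- siteDistance(m1, m2, threshold)
    }
  }
  out
}

#' Classify positions as public, private or absent
#'
#' A position is *public* when it is heteroplasmic in both members of at
#' least a fraction `publicFraction` of pairs (the recurrent, cohort-wide
#' sites such as 146, 204 and 16129); *private* when shared by at least
#' one but fewer pairs; *absent* otherwise.
#'
#' @param pairs A [PairSet-class].
#' @param publicFraction Fraction of pairs required for a public site
#'   (default 0.5).
#' @return Named character vector over the 853 positions with values
#'   `"public"`, `"private"`, `"absent"`.
#' @export
classifySites <- function(pairs, publicFraction = 0.5) {
  if (nPairs(pairs) < 1L)
    stop2("need at least 1 pair", class = "mitoHet_parameter_error")
  pos <- fragmentPositions()
  shared <- integer(length(pos))
  names(shared) <- as.character(pos)
  for (i in seq_len(nPairs(pairs))) {
    joint <- intersect(hetSites(pairs@mothers[[i]]),
                       hetSites(pairs@offspring[[i]]))
    shared[as.character(joint)] <- shared[as.character(joint)] + 1L
  }
  frac <- shared / nPairs(pairs)
  ifelse(frac >= publicFraction, "public",
         ifelse(shared >= 1L, "private", "absent"))
}
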