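# Heteroplasmy calling: MAF thresholding, double-strand validation,
# coverage QC.  The minor allele is defined per sample against that
# sample's own major allele (heteroplasmy is intra-individual variation);
# homoplasmic differences from the rCRS are not heteroplasmies.

#' Summarise alleles at one site from strand-resolved counts
#'
#' Combines plus- and minus-strand counts, ranks bases by combined count
#' (ties broken alphabetically A < C < G < T), and reports the major and
#' minor allele, the minor allele frequency, total depth, and per-strand
#' minor alleles/frequencies used for double-strand validation.  The
#' per-strand minor allele is the most frequent non-major base on that
#' strand.
#'
#' @param plus,minus Named numeric vectors of counts for bases
#'   `A, C, G, T` on each strand.
#' @return List with elements `major`, `minor`, `maf`, `depth`,
#'   `minorPlus`, `minorMinus` (per-strand minor base), `freqPlus`,
#'   `freqMinus` (that base's frequency on its strand; 0 when the strand
#'   has no depth).
#' @export
#' @examples
#' siteAlleleSummary(c(A = 49900, C = 0, G = 50, T = 0),
#'                   c(A = 49900, C = 0, G = 50, T = 0))
siteAlleleSummary <- function(plus, minus) {
  plus <- plus[BASES]; minus <- minus[BASES]
  comb <- plus + minus
  depth <- sum(comb)
  if (is.na(depth) || depth <= 0)
    stop2("no coverage at site (depth 0)", class = "mitoHet_no_coverage")
  ord <- order(-comb, BASES)      # count desc, then alphabetical
  major <- BASES[ord[1L]]
  minor <- BASES[ord[2L]]
  maf <- unname(comb[minor] / depth)
  strandMinor <- function(cnt) {
    nm <- setdiff(BASES, major)
    d <- sum(cnt)
    sub <- cnt[nm]
    b <- nm[order(-sub, nm)[1L]]
    list(base = b, freq = if (d > 0) unname(cnt[b] / d) else 0)
  }
  sp <- strandMinor(plus); sm <- strandMinor(minus)
  list(major = major, minor = minor, maf = maf, depth = unname(depth),
       minorPlus = sp$base, minorMinus = sm$base,
       freqPlus = sp$freq, freqMinus = sm$freq)
}

#' Double-strand validation of a candidate minor allele
#'
#' A candidate heteroplasmy is validated only if the *same* minor allele
#' reaches the per-strand threshold independently on the plus and the
#' minus strand, which suppresses strand-specific sequencing artifacts.
#'
#' @param minorPlus,minorMinus Minor allele observed on each strand.
#' @param freqPlus,freqMinus That allele's frequency on its strand.
#' @param threshold Per-strand frequency threshold (the calling threshold
#'   times the strand multiplier).
#' @return Logical.
#' @export
doubleStrandValidate <- function(minorPlus, minorMinus, freqPlus, freqMinus,
                                 threshold) {
  identical(minorPlus, minorMinus) &&
    freqPlus >= threshold && freqMinus >= threshold
}

#' Call heteroplasmic sites in one sample
#'
#' Emits one call per site whose combined minor allele frequency is at or
#' above `threshold` (the detection threshold, default 0.2\%) and which
#' passes double-strand validation.  A site where either strand has zero
#' depth fails validation (strand dropout, warned).
#'
#' @param x A [StrandCounts-class] object.
#' @param threshold Minor allele frequency detection threshold
#'   (fraction; sites at exactly the threshold are called).
#' @param strandMultiplier Multiplier applied to `threshold` for the
#'   per-strand validation rule (default 1: each strand must reach the
#'   full threshold independently).
#' @return Call `data.frame` with columns `site`, `major`, `minor`,
#'   `maf`, `depth`, `dsValidated`; only validated calls are returned,
#'   so `dsValidated` is all `TRUE`.
#' @export
callSample <- function(x, threshold = 0.002, strandMultiplier = 1) {
  stopifnot(is(x, "StrandCounts"))
  n <- length(x@site)
  if (n == 0L) {
    warning("empty count table for sample ", x@sampleId)
    return(emptyCalls())
  }
  P <- x@plus; M <- x@minus
  C <- P + M
  depth <- rowSums(C)
  keepRows <- depth > 0
  out <- emptyCalls()
  # combined major/minor via max.col; ties.method = "first" implements
  # the alphabetical tie-break because columns are in base order
  Cw <- C[keepRows, , drop = FALSE]
  if (!nrow(Cw)) return(out)
  majIdx <- max.col(Cw, ties.method = "first")
  Cminor <- Cw
  Cminor[cbind(seq_len(nrow(Cw)), majIdx)] <- -1L
  minIdx <- max.col(Cminor, ties.method = "first")
  dep <- depth[keepRows]
  maf <- Cw[cbind(seq_len(nrow(Cw)), minIdx)] / dep
  cand <- maf >= threshold
  if (!any(cand)) return(out)
  idx <- which(keepRows)[cand]
  perStrand <- threshold * strandMultiplier
  rows <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    s <- siteAlleleSummary(P[i, ], M[i, ])
    dropout <- sum(P[i, ]) == 0 || sum(M[i, ]) == 0
    if (dropout) {
      warning("strand dropout at site ", x@site[i], " in sample ",
              x@sampleId, "; double-strand validation failed")
      return(NULL)
    }
    if (!doubleStrandValidate(s$minorPlus, s$minorMinus,
                              s$freqPlus, s$freqMinus, perStrand))
      return(NULL)
    data.frame(site = x@site[i], major = s$major, minor = s$minor,
               maf = s$maf, depth = s$depth, dsValidated = TRUE,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows) else out
}

#' Sample-level coverage QC
#'
#' Mean coverage is the mean combined-strand depth over all 853 fragment
#' positions; positions absent from the table count as depth 0.  A sample
#' passes QC when mean coverage is at or above `floor` (samples with mean
#' coverage strictly below the floor are excluded).
#'
#' @param x A [StrandCounts-class] object.
#' @param floor Coverage floor (default 10,000x).
#' @return List with `meanCoverage` and `qcPass`.
#' @export
sampleQC <- function(x, floor = 10000) {
  stopifnot(is(x, "StrandCounts"))
  frag <- fragmentPositions()
  depth <- rowSums(x@plus) + rowSums(x@minus)
  meanCoverage <- sum(depth) / length(frag)
  list(meanCoverage = meanCoverage, qcPass = meanCoverage >= floor)
}

#' Build a SampleProfile from counts and metadata
#'
#' Runs coverage QC and, for QC-passing samples, heteroplasmy calling.
#' QC-failed samples get an empty call set.
#'
#' @param x A [StrandCounts-class] object.
#' @param group,familyId,age Sample metadata (see
#'   [SampleProfile-class]).
#' @param threshold,strandMultiplier Passed to [callSample()].
#' @param coverageFloor Passed to [sampleQC()].
#' @return A [SampleProfile-class] object.
#' @export
buildProfile <- function(x, group, familyId = NA_character_, age = NA_real_,
                         threshold = 0.002, strandMultiplier = 1,
                         coverageFloor = 10000) {
  qc <- sampleQC(x, floor = coverageFloor)
  calls <- if (qc$qcPass) callSample(x, threshold, strandMultiplier)
           else emptyCalls()
  SampleProfile(sampleId = x@sampleId, group = group, familyId = familyId,
                age = age, meanCoverage = qc$meanCoverage,
                qcPass = qc$qcPass, calls = calls)
}
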