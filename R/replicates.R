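# Triplicate-PCR concordance: consensus truth sets, confusion matrices,
# per-sample and cohort sensitivity/specificity.

#' Majority-consensus truth set across PCR replicates
#'
#' A site is "true heteroplasmic" for a sample when it is supported by at
#' least `k` of the replicate observations (default 2 of 3).
#'
#' @param replicates List of integer vectors of called sites, one per
#'   replicate (at least 2 replicates).
#' @param k Minimum number of supporting replicates.
#' @return Sorted integer vector of consensus-true sites.
#' @export
#' @examples
#' consensusTruth(list(c(146L, 204L), 146L, c(146L, 150L)))
consensusTruth <- function(replicates, k = 2) {
  if (k < 1) stop2("k must be at least 1", class = "mitoHet_parameter_error")
  if (!is.list(replicates) || length(replicates) < 2L)
    stop2("need at least 2 replicate call sets",
          class = "mitoHet_parameter_error")
  if (k > length(replicates))
    stop2("k exceeds the number of replicates",
          class = "mitoHet_parameter_error")
  tab <- table(unlist(lapply(replicates, unique)))
  sort(as.integer(names(tab)[tab >= k]))
}

#' Confusion summary of one replicate against a truth set
#'
#' Site-identity concordance over the assessed positions (853 fragment
#' positions by default): `tp` sites called and true, `fn` true but
#' missed, `fp` called but not true, `tn` the remainder.  Sensitivity is
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)`; either is `NA` (flagged, not
#' imputed) when its denominator is zero.
#'
#' @param replicateSites Integer vector of sites called in the replicate.
#' @param truth Integer vector of consensus-true sites.
#' @param allSites Ordered positions assessed (default the fragment).
#' @return One-row `data.frame` with columns `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`.
#' @export
replicateConfusion <- function(replicateSites, truth,
                               allSites = fragmentPositions()) {
  replicateSites <- unique(as.integer(replicateSites))
  truth <- unique(as.integer(truth))
  bad <- setdiff(c(replicateSites, truth), allSites)
  if (length(bad))
    stop2("site(s) outside the assessed positions: ",
          paste(bad, collapse = ", "), class = "mitoHet_coordinate_error")
  tp <- length(intersect(replicateSites, truth))
  fn <- length(setdiff(truth, replicateSites))
  fp <- length(setdiff(replicateSites, truth))
  tn <- length(allSites) - tp - fn - fp
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Cohort replicate-concordance report
#'
#' For each sample, builds the >= `k` consensus truth set, scores every
#' replicate against it, and aggregates sensitivity/specificity.  With
#' `aggregate = "within"` (default) replicate values are averaged within
#' each sample first and the cohort mean/sd is taken over samples; with
#' `"pooled"` the cohort mean/sd is over all replicate-level values.
#' Undefined ratios (zero denominators) are excluded from means and
#' counted.
#'
#' @param replicateSets Named list (one element per sample) of lists of
#'   integer site vectors (one per replicate).
#' @param k Consensus threshold (default 2).
#' @param allSites Assessed positions.
#' @param aggregate `"within"` or `"pooled"`.
#' @return List with `perReplicate` and `perSample` data frames and a
#'   `summary` list (`meanSensitivity`, `sdSensitivity`,
#'   `meanSpecificity`, `sdSpecificity`, `nUndefinedSensitivity`,
#'   `nUndefinedSpecificity`).
#' @export
cohortReplicateReport <- function(replicateSets, k = 2,
                                  allSites = fragmentPositions(),
                                  aggregate = c("within", "pooled")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(replicateSets), length(replicateSets) >= 1L)
  if (is.null(names(replicateSets)))
    names(replicateSets) <- paste0("sample", seq_along(replicateSets))
  perRep <- do.call(rbind, lapply(names(replicateSets), function(id) {
    reps <- replicateSets[[id]]
    truth <- consensusTruth(reps, k = k)
    do.call(rbind, lapply(seq_along(reps), function(j) {
      cbind(data.frame(sampleId = id, replicate = j,
                       stringsAsFactors = FALSE),
            replicateConfusion(reps[[j]], truth, allSites))
    }))
  }))
  meanNA <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  perSample <- do.call(rbind, lapply(split(perRep, perRep$sampleId),
    function(d) data.frame(sampleId = d$sampleId[1L],
                           sensitivity = meanNA(d$sensitivity),
                           specificity = meanNA(d$specificity),
                           stringsAsFactors = FALSE)))
  rownames(perSample) <- NULL
  vals <- if (aggregate == "within") perSample else perRep
  sens <- vals$sensitivity[!is.na(vals$sensitivity)]
  spec <- vals$specificity[!is.na(vals$specificity)]
  if (!length(sens))
    stop2("sensitivity undefined for every sample",
          class = "mitoHet_degenerate_error")
  list(perReplicate = perRep, perSample = perSample,
       summary = list(
         meanSensitivity = mean(sens), sdSensitivity = sd(sens),
         meanSpecificity = mean(spec), sdSpecificity = sd(spec),
         nUndefinedSensitivity = sum(is.na(vals$sensitivity)),
         nUndefinedSpecificity = sum(is.na(vals$specificity))))
}

#' Replicate MAF concordance diagnostic
#'
#' Supplementary diagnostic beyond site-identity concordance: mean
#' pairwise absolute MAF difference across replicates, over the union of
#' sites called in any replicate (a missing call contributes MAF 0).
#'
#' @param callTables List of call `data.frame`s (as from [callSample()]),
#'   one per replicate.
#' @return Mean pairwise absolute MAF difference (`NA` if no replicate
#'   called any site).
#' @export
replicateMafConcordance <- function(callTables) {
  stopifnot(length(callTables) >= 2L)
  sites <- sort(unique(unlist(lapply(callTables, `[[`, "site"))))
  if (!length(sites)) return(NA_real_)
  mafAt <- function(tab) {
    v <- setNames(rep(0, length(sites)), sites)
    v[as.character(tab$site)] <- tab$maf
    v
  }
  M <- vapply(callTables, mafAt, numeric(length(sites)))
  pairs <- utils::combn(ncol(M), 2)
  mean(apply(pairs, 2, function(ij) mean(abs(M[, ij[1]] - M[, ij[2]]))))
}
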