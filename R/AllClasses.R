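# S4 classes for the heteroplasmy pipeline.

BASES <- c("A", "C", "G", "T")

#' StrandCounts: strand-resolved allele counts for one sample
#'
#' Per-site, per-strand base counts over (a subset of) the 853 fragment
#' positions.  Counts are assumed post-alignment and post-base-quality
#' filtering; the pipeline's entry point.
#'
#' @slot sampleId Sample identifier.
#' @slot site Integer vector of rCRS positions (1-based), unique, within
#'   the fragment.
#' @slot plus,minus Integer matrices (`length(site)` x 4, columns
#'   A, C, G, T) of read counts on the plus and minus strand.
#' @export
setClass("StrandCounts",
  representation(sampleId = "character", site = "integer",
                 plus = "matrix", minus = "matrix"))

setValidity("StrandCounts", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  n <- length(object@site)
  if (anyDuplicated(object@site))
    msg <- c(msg, "duplicate sites")
  if (!all(object@site %in% fragmentPositions()))
    msg <- c(msg, "sites outside the 853-bp fragment")
  for (s in c("plus", "minus")) {
    m <- slot(object, s)
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != 4L)
      msg <- c(msg, sprintf("%s must be a %d x 4 count matrix", s, n))
    else if (any(m < 0) || anyNA(m))
      msg <- c(msg, sprintf("%s counts must be non-negative", s))
    else if (!identical(colnames(m), BASES))
      msg <- c(msg, sprintf("%s columns must be A, C, G, T", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StrandCounts object
#'
#' @param sampleId Sample identifier.
#' @param site Integer rCRS positions.
#' @param plus,minus Count matrices (sites x A/C/G/T).
#' @return A [StrandCounts-class] object.
#' @export
StrandCounts <- function(sampleId, site, plus, minus) {
  site <- as.integer(site)
  fix <- function(m) {
    m <- as.matrix(m); storage.mode(m) <- "integer"
    colnames(m) <- BASES; rownames(m) <- as.character(site); m
  }
  new("StrandCounts", sampleId = as.character(sampleId), site = site,
      plus = fix(plus), minus = fix(minus))
}

#' SampleProfile: metadata, QC status and heteroplasmy calls for a sample
#'
#' @slot sampleId Sample identifier.
#' @slot group One of `CENT` (centenarian), `CO` (centenarian offspring),
#'   `ONLL` (offspring of non-long-lived parents).
#' @slot familyId Family identifier (`NA` for unrelated samples).
#' @slot age Age in years.
#' @slot meanCoverage Mean combined-strand depth over the 853 positions.
#' @slot qcPass `TRUE` iff `meanCoverage` is at or above the coverage
#'   floor; calls are empty when QC fails.
#' @slot calls `data.frame` with columns `site`, `major`, `minor`, `maf`,
#'   `depth`, `dsValidated` (one row per validated heteroplasmic site).
#' @export
setClass("SampleProfile",
  representation(sampleId = "character", group = "character",
                 familyId = "character", age = "numeric",
                 meanCoverage = "numeric", qcPass = "logical",
                 calls = "data.frame"))

setValidity("SampleProfile", function(object) {
  msg <- character()
  if (!object@group %in% c("CENT", "CO", "ONLL"))
    msg <- c(msg, "group must be one of CENT, CO, ONLL")
  if (!object@qcPass && nrow(object@calls) > 0L)
    msg <- c(msg, "QC-failed profiles must have no calls")
  cl <- object@calls
  need <- c("site", "major", "minor", "maf", "depth", "dsValidated")
  if (!all(need %in% names(cl)))
    msg <- c(msg, "calls must have columns site, major, minor, maf, depth, dsValidated")
  else if (nrow(cl)) {
    if (any(cl$maf < 0 | cl$maf > 0.5)) msg <- c(msg, "maf outside [0, 0.5]")
    if (any(cl$major == cl$minor)) msg <- c(msg, "major == minor in calls")
    if (any(cl$depth <= 0)) msg <- c(msg, "non-positive depth in calls")
  }
  if (length(msg)) msg else TRUE
})

emptyCalls <- function() {
  data.frame(site = integer(), major = character(), minor = character(),
             maf = numeric(), depth = integer(), dsValidated = logical(),
             stringsAsFactors = FALSE)
}

#' Construct a SampleProfile
#'
#' @param sampleId,group,familyId,age Sample metadata.
#' @param meanCoverage Mean combined-strand depth.
#' @param qcPass Logical QC flag.
#' @param calls Call `data.frame` (see [SampleProfile-class]).
#' @return A [SampleProfile-class] object.
#' @export
SampleProfile <- function(sampleId, group, familyId = NA_character_,
                          age = NA_real_, meanCoverage = NA_real_,
                          qcPass = TRUE, calls = emptyCalls()) {
  new("SampleProfile", sampleId = as.character(sampleId),
      group = as.character(group), familyId = as.character(familyId),
      age = as.numeric(age), meanCoverage = as.numeric(meanCoverage),
      qcPass = qcPass, calls = calls)
}

#' HetCohort: a collection of sample profiles
#'
#' @slot profiles List of [SampleProfile-class] objects with unique
#'   sample ids.
#' @export
setClass("HetCohort", representation(profiles = "list"))

setValidity("HetCohort", function(object) {
  ok <- vapply(object@profiles, is, logical(1), "SampleProfile")
  if (!all(ok)) return("profiles must all be SampleProfile objects")
  ids <- vapply(object@profiles, slot, character(1), "sampleId")
  if (anyDuplicated(ids)) return("duplicate sample ids")
  TRUE
})

#' Construct a HetCohort
#' @param profiles List of [SampleProfile-class] objects.
#' @return A [HetCohort-class] object.
#' @export
HetCohort <- function(profiles) {
  names(profiles) <- vapply(profiles, slot, character(1), "sampleId")
  new("HetCohort", profiles = profiles)
}

#' PairSet: mother-offspring pairing structure
#'
#' Holds the QC-passing mother (CENT) and offspring (CO) profiles matched
#' by family id, plus the unrelated ONLL profiles used for cross-group
#' reshuffling.
#'
#' @slot familyId Character vector of family ids (unique).
#' @slot mothers,offspring Lists of [SampleProfile-class], parallel to
#'   `familyId`.
#' @slot onll List of unrelated [SampleProfile-class] objects.
#' @export
setClass("PairSet",
  representation(familyId = "character", mothers = "list",
                 offspring = "list", onll = "list"))

setValidity("PairSet", function(object) {
  msg <- character()
  n <- length(object@familyId)
  if (anyDuplicated(object@familyId))
    msg <- c(msg, "each family id must appear in exactly one pair")
  if (length(object@mothers) != n || length(object@offspring) != n)
    msg <- c(msg, "mothers/offspring must parallel familyId")
  qc <- vapply(c(object@mothers, object@offspring), slot, logical(1), "qcPass")
  if (length(qc) && !all(qc))
    msg <- c(msg, "all pair members must be QC-passing")
  if (length(msg)) msg else TRUE
})

#' NullDistribution: observed statistic plus reshuffled replicates
#'
#' @slot statistic Name of the statistic (`"pearson"` or `"tncs"`).
#' @slot observed Observed value on the true pairing (`NA` for
#'   cross-group nulls that have no true pairing).
#' @slot replicates Numeric vector of reshuffled values.
#' @slot p Upper-tail empirical p with the add-one convention,
#'   `(1 + #\{replicates >= observed\}) / (1 + n)`.
#' @slot seed Seed used for the reshuffles.
#' @slot nDegenerate Number of degenerate replicates that were resampled.
#' @export
setClass("NullDistribution",
  representation(statistic = "character", observed = "numeric",
                 replicates = "numeric", p = "numeric", seed = "integer",
                 nDegenerate = "integer"))

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (!is.na(object@observed)) {
    pExp <- (1 + sum(object@replicates >= object@observed)) /
      (1 + length(object@replicates))
    if (!isTRUE(all.equal(object@p, pExp)))
      msg <- c(msg, "p must follow the add-one empirical convention")
  }
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------

setMethod("show", "StrandCounts", function(object) {
  cat("StrandCounts for sample", object@sampleId, "\n",
      length(object@site), "sites;",
      "mean combined depth", round(mean(rowSums(object@plus) +
                                          rowSums(object@minus))), "\n")
})

setMethod("show", "SampleProfile", function(object) {
  cat(sprintf("SampleProfile %s [%s]%s age %.1f\n", object@sampleId,
              object@group,
              if (is.na(object@familyId)) "" else
                paste0(" family ", object@familyId), object@age))
  cat(sprintf("  mean coverage %.0f (QC %s); %d heteroplasmic call(s)\n",
              object@meanCoverage, if (object@qcPass) "pass" else "FAIL",
              nrow(object@calls)))
})

setMethod("show", "HetCohort", function(object) {
  gr <- table(vapply(object@profiles, slot, character(1), "group"))
  cat("HetCohort with", length(object@profiles), "samples (",
      paste(names(gr), as.integer(gr), collapse = ", "), ")\n")
})

setMethod("show", "PairSet", function(object) {
  cat("PairSet:", length(object@familyId), "mother-offspring pairs,",
      length(object@onll), "unrelated ONLL samples\n")
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution [%s]: observed %.4g; %d reshuffles (mean %.4g, sd %.4g); p = %.4g\n",
    object@statistic, object@observed, length(object@replicates),
    mean(object@replicates), sd(object@replicates), object@p))
})

# ---- accessors --------------------------------------------------------

#' @describeIn StrandCounts-class Sample identifier.
#' @param x Object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @export
setMethod("sampleId", "StrandCounts", function(x) x@sampleId)
#' @export
setMethod("sampleId", "SampleProfile", function(x) x@sampleId)

#' Heteroplasmy calls of a profile
#' @param x A [SampleProfile-class].
#' @return The call `data.frame`.
#' @export
setGeneric("hetCalls", function(x) standardGeneric("hetCalls"))
#' @export
setMethod("hetCalls", "SampleProfile", function(x) x@calls)

#' Heteroplasmic site positions of a profile
#' @param x A [SampleProfile-class].
#' @return Integer vector of called sites.
#' @export
setGeneric("hetSites", function(x) standardGeneric("hetSites"))
#' @export
setMethod("hetSites", "SampleProfile", function(x) x@calls$site)

#' QC status
#' @param x A [SampleProfile-class].
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))
#' @export
setMethod("qcPass", "SampleProfile", function(x) x@qcPass)

#' Profiles of a cohort
#' @param x A [HetCohort-class] or [PairSet-class].
#' @return List of [SampleProfile-class] objects.
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @export
setMethod("profiles", "HetCohort", function(x) x@profiles)
#' @export
setMethod("profiles", "PairSet",
          function(x) c(x@mothers, x@offspring, x@onll))

#' Number of mother-offspring pairs
#' @param x A [PairSet-class].
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @export
setMethod("nPairs", "PairSet", function(x) length(x@familyId))

#' Replicate values of a null distribution
#' @param x A [NullDistribution-class].
#' @export
setGeneric("nullReplicates", function(x) standardGeneric("nullReplicates"))
#' @export
setMethod("nullReplicates", "NullDistribution", function(x) x@replicates)

#' Observed statistic of a null distribution
#' @param x A [NullDistribution-class].
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))
#' @export
setMethod("observedStat", "NullDistribution", function(x) x@observed)

#' Empirical p-value of a null distribution
#' @param x A [NullDistribution-class].
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))
#' @export
setMethod("empiricalP", "NullDistribution", function(x) x@p)
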