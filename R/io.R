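# Tab-separated file formats.  All coordinates are 1-based rCRS
# positions; all formats round-trip losslessly.

#' Read a strand-resolved count table
#'
#' Tab-separated with header `sample_id site strand A C G T`; `strand`
#' is `+` or `-`.  Malformed rows (unknown strand symbol, negative or
#' non-integer counts, out-of-fragment site, duplicated
#' sample/site/strand) are schema errors naming the offending line.
#'
#' @param path File path.
#' @return Named list of [StrandCounts-class] objects, one per sample.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path))
    stop2("file not found: ", path, class = "mitoHet_schema_error")
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character"))
  need <- c("sample_id", "site", "strand", "A", "C", "G", "T")
  if (!identical(names(d), need))
    stop2("bad header: expected '", paste(need, collapse = " "), "'",
          class = "mitoHet_schema_error")
  line <- seq_len(nrow(d)) + 1L      # header is line 1
  bad <- function(test, what) {
    if (any(test))
      stop2("schema error at line ", line[which(test)[1L]], ": ", what,
            class = "mitoHet_schema_error")
  }
  bad(!d$strand %in% c("+", "-"), "unknown strand symbol")
  for (b in BASES) {
    v <- d[[b]]
    bad(!is.numeric(v) | is.na(v), paste0("non-numeric ", b, " count"))
    bad(v < 0, paste0("negative ", b, " count"))
    bad(v != floor(v), paste0("non-integer ", b, " count"))
  }
  bad(!d$site %in% fragmentPositions(), "site outside the fragment")
  bad(duplicated(d[c("sample_id", "site", "strand")]),
      "duplicate (sample, site, strand) row")
  lapply(split(d, d$sample_id), function(ds) {
    sites <- sort(unique(ds$site))
    mk <- function(sym) {
      m <- matrix(0L, length(sites), 4L,
                  dimnames = list(as.character(sites), BASES))
      sub <- ds[ds$strand == sym, , drop = FALSE]
      m[match(sub$site, sites), ] <- as.matrix(sub[, BASES])
      m
    }
    StrandCounts(ds$sample_id[1L], sites, mk("+"), mk("-"))
  })
}

#' Write strand-resolved count tables
#'
#' @param counts A [StrandCounts-class] object or list of them.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(counts, path) {
  if (is(counts, "StrandCounts")) counts <- list(counts)
  rows <- lapply(counts, function(x) {
    do.call(rbind, lapply(c("+", "-"), function(sym) {
      m <- if (sym == "+") x@plus else x@minus
      data.frame(sample_id = x@sampleId, site = x@site, strand = sym,
                 A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
                 stringsAsFactors = FALSE)
    }))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a heteroplasmy call table
#'
#' Tab-separated, header
#' `sample_id site major minor maf depth ds_validated`; MAF with 6
#' decimal places.
#'
#' @param cohort A [HetCohort-class], list of
#'   [SampleProfile-class] objects, or a single profile.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeCallTable <- function(cohort, path) {
  profs <- if (is(cohort, "HetCohort")) profiles(cohort)
           else if (is(cohort, "SampleProfile")) list(cohort) else cohort
  rows <- lapply(profs, function(p) {
    cl <- hetCalls(p)
    if (!nrow(cl)) return(NULL)
    data.frame(sample_id = sampleId(p), site = cl$site, major = cl$major,
               minor = cl$minor, maf = sprintf("%.6f", cl$maf),
               depth = cl$depth, ds_validated = cl$dsValidated,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(sample_id = character(), site = integer(),
                  major = character(), minor = character(),
                  maf = character(), depth = integer(),
                  ds_validated = logical())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call table back into per-sample site sets
#'
#' @param path File path written by [writeCallTable()].
#' @return `data.frame` with columns `sample_id`, `site`, `major`,
#'   `minor`, `maf` (numeric), `depth`, `ds_validated`.
#' @export
readCallTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character"))
  d$maf <- as.numeric(d$maf)
  d
}

#' Read / write a mutation-rate table
#'
#' Tab-separated, columns `position` and `rate`; must cover every
#' fragment position with non-negative rates.
#'
#' @param path File path.
#' @param rates Rate `data.frame`.
#' @return `readRateTable` returns the validated table.
#' @export
readRateTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "rate") %in% names(d)))
    stop2("rate table needs columns position, rate",
          class = "mitoHet_schema_error")
  if (!setequal(d$position, fragmentPositions()))
    stop2("rate table must cover every fragment position exactly once",
          class = "mitoHet_schema_error")
  if (any(d$rate < 0))
    stop2("negative mutation rate", class = "mitoHet_schema_error")
  d[match(fragmentPositions(), d$position), , drop = FALSE]
}

#' @rdname readRateTable
#' @export
writeRateTable <- function(rates, path) {
  write.table(rates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample metadata table
#'
#' @param cohort A [HetCohort-class] or list of profiles.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeMetadataTable <- function(cohort, path) {
  profs <- if (is(cohort, "HetCohort")) profiles(cohort) else cohort
  tab <- data.frame(
    sample_id = vapply(profs, sampleId, character(1)),
    group = vapply(profs, slot, character(1), "group"),
    family_id = vapply(profs, slot, character(1), "familyId"),
    age = vapply(profs, slot, numeric(1), "age"),
    mean_coverage = sprintf("%.2f",
                            vapply(profs, slot, numeric(1), "meanCoverage")),
    qc_pass = vapply(profs, qcPass, logical(1)),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a truth table for test harnesses
#'
#' Columns `sample_id site true_maf minor`.
#'
#' @param truthCohort Result of [generateTruthCohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truthCohort, path) {
  rows <- lapply(truthCohort$profiles, function(tr) {
    if (!nrow(tr$sites)) return(NULL)
    data.frame(sample_id = tr$sampleId, site = tr$sites$position,
               true_maf = sprintf("%.6f", tr$sites$maf),
               minor = tr$sites$minor, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a null-distribution summary
#'
#' Tab-separated key-value block recording the statistic, observed
#' value, replicate count, replicate mean and sd, empirical p and seed.
#'
#' @param nd A [NullDistribution-class].
#' @param path File path.
#' @param label Label for the comparison (e.g. `"CENT-CO"`).
#' @return `path`, invisibly.
#' @export
writeNullSummary <- function(nd, path, label = "") {
  tab <- data.frame(
    label = label, statistic = nd@statistic,
    observed = sprintf("%.6g", nd@observed),
    n_reshuffles = length(nd@replicates),
    null_mean = sprintf("%.6g", mean(nd@replicates)),
    null_sd = sprintf("%.6g", sd(nd@replicates)),
    empirical_p = sprintf("%.6g", nd@p),
    seed = nd@seed, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
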