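# End-to-end orchestration of the synthetic study: simulate -> call ->
# replicates -> cohort statistics -> transmission, with a run manifest.

#' Run the full synthetic study
#'
#' Generates a rate table and truth cohort, simulates strand counts,
#' runs QC and heteroplasmy calling, performs the replicate-concordance
#' analysis (first `nReplicateSamples` samples, 3 PCR realizations
#' each), computes cohort statistics (per-site table, region
#' enrichment, mutation-rate correlations, clustering) and transmission
#' statistics (pair summary, reshuffling nulls for the total-
#' heteroplasmy correlation and TNCS, cross-group nulls, distance
#' matrix, public/private classification), writing tab-separated
#' reports plus a JSON manifest to `outDir`.  Statistics tables are
#' byte-identical across runs with the same configuration and seed;
#' the manifest additionally records timestamps.
#'
#' @param outDir Output directory (created if missing).
#' @param config A `mitoHetConfig` ([generatorConfig()]).
#' @param seed Integer seed; generator and reshuffling sub-seeds are
#'   derived from it and recorded in the manifest.
#' @param threshold Detection threshold (fraction).
#' @param coverageFloor Mean-coverage QC floor.
#' @param nReshuffles Reshuffles per null distribution.
#' @param nReplicateSamples Samples entering the triplicate analysis.
#' @param writeCounts Also write the simulated count tables (large).
#' @return Invisible list with the main in-memory results and output
#'   paths.
#' @export
runFullStudy <- function(outDir, config = generatorConfig(), seed = 1L,
                         threshold = 0.002, coverageFloor = 10000,
                         nReshuffles = 2000, nReplicateSamples = 12L,
                         writeCounts = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  set.seed(seed)
  seeds <- as.list(sample.int(2^31 - 1, 6))
  names(seeds) <- c("rates", "truth", "counts", "replicates",
                    "reshuffle", "crossGroup")
  log <- function(...) message("[mitoHet] ", ...)

  log("stage simulate: ", config$nPairs, " pairs + ", config$nOnll,
      " ONLL, mean depth ", config$meanDepth)
  rates <- generateRateTable(seeds$rates)
  truth <- generateTruthCohort(config, rates, seed = seeds$truth,
                               threshold = threshold)
  cohort <- simulateCohort(truth, config, seed = seeds$counts,
                           threshold = threshold,
                           coverageFloor = coverageFloor)
  profs <- profiles(cohort)
  nPass <- sum(vapply(profs, qcPass, logical(1)))
  log("stage call: ", length(profs), " samples in, ", nPass,
      " QC-passing (floor ", coverageFloor, "), threshold ", threshold)
  if (nPass == 0L)
    stop2("no QC-passing samples", class = "mitoHet_qc_error")
  writeRateTable(rates, file.path(outDir, "mutation_rates.tsv"))
  writeTruthTable(truth, file.path(outDir, "truth.tsv"))
  writeMetadataTable(cohort, file.path(outDir, "metadata.tsv"))
  writeCallTable(cohort, file.path(outDir, "calls.tsv"))
  if (writeCounts)
    writeCountTable(simulateCohortCounts(truth, config, seeds$counts),
                    file.path(outDir, "counts.tsv"))

  # replicate concordance on the first samples
  nRep <- min(nReplicateSamples, length(truth$profiles))
  log("stage replicates: ", nRep, " samples x 3 PCR realizations")
  set.seed(seeds$replicates)
  repSeeds <- sample.int(2^31 - 1, nRep)
  repSets <- lapply(seq_len(nRep), function(i) {
    reps <- simulateReplicates(truth$profiles[[i]], n = 3L, config,
                               seed = repSeeds[i])
    lapply(reps, function(x) callSample(x, threshold)$site)
  })
  names(repSets) <- names(truth$profiles)[seq_len(nRep)]
  repReport <- cohortReplicateReport(repSets)
  repTab <- repReport$perReplicate
  repTab$sensitivity <- sprintf("%.6f", repTab$sensitivity)
  repTab$specificity <- sprintf("%.6f", repTab$specificity)
  write.table(repTab, file.path(outDir, "replicate_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # cohort statistics
  se <- mafMatrix(cohort)
  hetSitesAll <- rowData(se)$position[rowSums(assay(se) >= threshold) > 0]
  log("stage cohort-stats: ", length(hetSitesAll),
      " heteroplasmic positions")
  occ <- lapply(c("CENT", "CO", "ONLL"), function(g)
    occurrenceCounts(se, g, threshold))
  names(occ) <- c("CENT", "CO", "ONLL")
  anova <- perSiteAnova(se)
  perSite <- data.frame(
    site = rowData(se)$position, region = rowData(se)$region,
    occ_CENT = occ$CENT$count, occ_CO = occ$CO$count,
    occ_ONLL = occ$ONLL$count,
    mean_maf_CENT = sprintf("%.6f", ifelse(is.na(occ$CENT$meanMaf), 0,
                                           occ$CENT$meanMaf)),
    mean_maf_CO = sprintf("%.6f", ifelse(is.na(occ$CO$meanMaf), 0,
                                         occ$CO$meanMaf)),
    mean_maf_ONLL = sprintf("%.6f", ifelse(is.na(occ$ONLL$meanMaf), 0,
                                           occ$ONLL$meanMaf)),
    anova_F = sprintf("%.6g", anova$F),
    anova_p = sprintf("%.6g", anova$p),
    anova_p_adj = sprintf("%.6g", anova$pAdj),
    stringsAsFactors = FALSE)
  write.table(perSite, file.path(outDir, "per_site_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- regionEnrichment(hetSitesAll)
  enrOut <- enr
  for (cn in c("oddsRatio", "ciLow", "ciHigh", "pValue"))
    enrOut[[cn]] <- sprintf("%.6g", enr[[cn]])
  write.table(enrOut, file.path(outDir, "region_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mrc <- lapply(occ, mrCorrelation, rates = rates)
  mrTab <- data.frame(group = names(mrc),
                      r = sprintf("%.6g", vapply(mrc, `[[`, 1, "r")),
                      p = sprintf("%.6g", vapply(mrc, `[[`, 1, "p")))
  write.table(mrTab, file.path(outDir, "mr_correlation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mrcmp <- meanRateComparison(hetSitesAll, rates)
  mrcmp$meanAll <- sprintf("%.6g", as.numeric(mrcmp$meanAll))
  mrcmp$meanHet <- sprintf("%.6g", as.numeric(mrcmp$meanHet))
  mrcmp$pValue <- sprintf("%.6g", as.numeric(mrcmp$pValue))
  write.table(mrcmp, file.path(outDir, "mean_rate_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  clusterNewick(clusterSamples(se), file.path(outDir, "clustering.nwk"))

  # transmission
  pairs <- pairSet(cohort)
  log("stage transmission: ", nPairs(pairs), " pairs, ",
      nReshuffles, " reshuffles")
  if (nPairs(pairs) < 3L)
    stop2("fewer than 3 QC-passing mother-offspring pairs",
          class = "mitoHet_degenerate_error")
  ps <- pairSummary(pairs)
  psOut <- ps
  psOut$thMother <- sprintf("%.6f", ps$thMother)
  psOut$thOffspring <- sprintf("%.6f", ps$thOffspring)
  write.table(psOut, file.path(outDir, "pair_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  thNull <- reshuffleNull(ps$thMother, ps$thOffspring, "pearson",
                          nReshuffles, seed = seeds$reshuffle)
  tncsNull <- reshuffleNull(lapply(pairs@mothers, hetSites),
                            lapply(pairs@offspring, hetSites), "tncs",
                            nReshuffles, seed = seeds$reshuffle)
  writeNullSummary(thNull, file.path(outDir, "null_total_heteroplasmy.tsv"),
                   label = "CENT-CO")
  writeNullSummary(tncsNull, file.path(outDir, "null_tncs.tsv"),
                   label = "CENT-CO")
  thOnll <- vapply(pairs@onll, totalHeteroplasmy, numeric(1))
  crossNulls <- list()
  if (length(thOnll) >= 3L) {
    crossNulls$CENT_ONLL <- crossGroupNull(ps$thMother, thOnll,
                                           nReshuffles,
                                           seed = seeds$crossGroup)
    crossNulls$CO_ONLL <- crossGroupNull(ps$thOffspring, thOnll,
                                         nReshuffles,
                                         seed = seeds$crossGroup)
    writeNullSummary(crossNulls$CENT_ONLL,
                     file.path(outDir, "null_cent_onll.tsv"),
                     label = "CENT-ONLL")
    writeNullSummary(crossNulls$CO_ONLL,
                     file.path(outDir, "null_co_onll.tsv"),
                     label = "CO-ONLL")
  }
  dm <- pairDistanceMatrix(pairs, threshold)
  dmOut <- data.frame(family_id = rownames(dm),
                      apply(dm, 2, function(v)
                        ifelse(is.na(v), "", sprintf("%.4f", v))),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write.table(dmOut, file.path(outDir, "pair_distance_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- classifySites(pairs)
  write.table(data.frame(site = as.integer(names(cls)), class = cls,
                         row.names = NULL),
              file.path(outDir, "site_classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "mitoHet",
    version = as.character(packageVersion("mitoHet")),
    seed = seed, stageSeeds = seeds,
    config = unclass(config),
    configHash = rlang::hash(unclass(config)),
    threshold = threshold, coverageFloor = coverageFloor,
    nReshuffles = nReshuffles,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = list.files(outDir))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log("done: ", length(list.files(outDir)), " files in ", outDir)
  invisible(list(rates = rates, truth = truth, cohort = cohort,
                 se = se, replicateReport = repReport, anova = anova,
                 enrichment = enr, mrCorrelation = mrc,
                 meanRateComparison = mrcmp, pairs = pairs,
                 pairSummary = ps, thNull = thNull, tncsNull = tncsNull,
                 crossNulls = crossNulls, classification = cls,
                 distanceMatrix = dm, outDir = outDir))
}
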