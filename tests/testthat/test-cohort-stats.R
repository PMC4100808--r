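# helper: cohort of profiles from a named list of (site -> maf) calls
profileFromMaf <- function(id, group, mafs, familyId = NA_character_,
                           age = 70) {
  calls <- if (length(mafs))
    data.frame(site = as.integer(names(mafs)), major = "A", minor = "G",
               maf = unname(mafs), depth = 50000L, dsValidated = TRUE,
               stringsAsFactors = FALSE)
  else emptyCallsDf()
  SampleProfile(id, group, familyId, age, meanCoverage = 50000,
                qcPass = TRUE, calls = calls)
}
emptyCallsDf <- function()
  data.frame(site = integer(), major = character(), minor = character(),
             maf = numeric(), depth = integer(), dsValidated = logical())

test_that("the MAF matrix has fragment-ordered rows and group metadata", {
  profs <- list(
    profileFromMaf("a", "CENT", c(`146` = 0.01, `16129` = 0.004)),
    profileFromMaf("b", "CO", c(`146` = 0.008)),
    profileFromMaf("c", "ONLL", numeric()))
  se <- mafMatrix(HetCohort(profs))
  expect_identical(dim(assay(se)), c(853L, 3L))
  expect_identical(SummarizedExperiment::rowData(se)$position,
                   fragmentPositions())
  expect_equal(assay(se)["146", "a"], 0.01)
  expect_equal(assay(se)["146", "b"], 0.008)
  expect_equal(sum(assay(se)[, "c"]), 0)
  # QC-failed samples are dropped
  profs2 <- c(profs, SampleProfile("d", "CENT", meanCoverage = 10,
                                   qcPass = FALSE))
  expect_identical(ncol(mafMatrix(HetCohort(profs2))), 3L)
})

test_that("occurrence counts and mean levels recover planted values", {
  profs <- c(
    lapply(1:3, function(i)
      profileFromMaf(paste0("c", i), "CENT", c(`146` = 0.01 * i))),
    lapply(4:10, function(i)
      profileFromMaf(paste0("c", i), "CENT", numeric())),
    list(profileFromMaf("o1", "CO", c(`204` = 0.005))))
  se <- mafMatrix(HetCohort(profs))
  occ <- occurrenceCounts(se, "CENT")
  expect_identical(occ$count[occ$position == 146], 3L)
  expect_equal(occ$meanMaf[occ$position == 146], 0.02)
  expect_identical(sum(occ$count), 3L)
  expect_true(is.na(occ$meanMaf[occ$position == 204]))
  expect_error(occurrenceCounts(se, "NOPE"),
               class = "mitoHet_parameter_error")
})

test_that("Fisher enrichment matches the cross-product OR and exact
           hypergeometric p", {
  # toy contingency (10, 90, 5, 95) checked against the textbook
  # arithmetic and the independent enumeration oracle
  or <- fisherOracle(10, 90, 5, 95)
  expect_equal(or$orCrossProduct, 950 / 450)
  ft <- fisher.test(matrix(c(10, 90, 5, 95), 2, byrow = TRUE))
  expect_lt(abs(ft$p.value - or$p), 1e-9)
})

test_that("region enrichment builds 2x2 tables over the 853 positions", {
  hv2 <- fragmentPositions(73, 261)
  res <- regionEnrichment(hv2[1:50])
  expect_true(all(res$hetIn + res$nonHetIn + res$hetOut +
                    res$nonHetOut == 853L))
  # all het sites inside HV2: OR > 1 there, < 1 elsewhere
  expect_gt(res$oddsRatio[res$region == "HV2"], 1)
  expect_lt(res$oddsRatio[res$region == "HV1"], 1)
  expect_lt(res$oddsRatio[res$region == "INTERMEDIATE"], 1)
  # p-values agree with the enumeration oracle
  for (i in seq_len(nrow(res)))
    expect_lt(abs(res$pValue[i] -
                    fisherOracle(res$hetIn[i], res$nonHetIn[i],
                                 res$hetOut[i], res$nonHetOut[i])$p),
              1e-9)
  # uniform coverage: OR = 1 for every region
  resAll <- regionEnrichment(fragmentPositions())
  expect_equal(resAll$oddsRatio, rep(1, 3))
  # degenerate empty set is flagged
  expect_true(all(regionEnrichment(integer(0))$degenerate))
})

test_that("mutation-rate correlation hits the exact limits", {
  rates <- data.frame(position = fragmentPositions(),
                      rate = seq_len(853) / 100)
  occPerfect <- data.frame(position = fragmentPositions(),
                           count = seq_len(853))
  expect_equal(mrCorrelation(occPerfect, rates)$r, 1)
  occAnti <- data.frame(position = fragmentPositions(),
                        count = rev(seq_len(853)))
  expect_equal(mrCorrelation(occAnti, rates)$r, -1)
  # independence: |r| small
  set.seed(5)
  occNull <- data.frame(position = fragmentPositions(),
                        count = rpois(853, 2))
  expect_lt(abs(mrCorrelation(occNull, rates)$r), 0.1)
  occConst <- data.frame(position = fragmentPositions(), count = 1L)
  expect_error(mrCorrelation(occConst, rates),
               class = "mitoHet_degenerate_error")
})

test_that("mean-rate comparison separates hotspot heteroplasmies", {
  set.seed(21)
  rates <- data.frame(position = fragmentPositions(),
                      rate = rgamma(853, 1.5, 1))
  # heteroplasmies planted at the top-decile rate positions
  top <- rates$position[rank(-rates$rate) <= 40]
  res <- meanRateComparison(top, rates)
  frag <- res[res$stratum == "FRAGMENT", ]
  expect_gt(frag$meanHet, frag$meanAll)
  expect_lt(frag$pValue, 1e-6)
  # all-equal rates: means equal, p = 1
  ratesEq <- data.frame(position = fragmentPositions(), rate = 1)
  resEq <- meanRateComparison(c(16100L, 16400L, 100L, 146L), ratesEq)
  expect_equal(resEq$meanAll, resEq$meanHet)
  expect_equal(resEq$pValue, rep(1, 4))
  # single het site: computable but flagged low power
  res1 <- meanRateComparison(146L, rates)
  expect_true(res1$lowPower[res1$stratum == "FRAGMENT"])
  expect_false(is.na(res1$meanHet[res1$stratum == "FRAGMENT"]))
})

test_that("per-site ANOVA: zero variance gives F = 0 and with two
           groups F equals t squared", {
  set.seed(13)
  profs <- c(
    lapply(1:10, function(i) profileFromMaf(sprintf("a%02d", i), "CO",
      c(`146` = 0.004 + 0.0005 * rnorm(1)))),
    lapply(1:10, function(i) profileFromMaf(sprintf("b%02d", i), "ONLL",
      c(`146` = 0.006 + 0.0005 * rnorm(1)))))
  se <- mafMatrix(HetCohort(profs))
  res <- perSiteAnova(se)
  # all-zero sites: F = 0, p = 1
  expect_true(all(res$F[res$position != 146] == 0))
  expect_true(all(res$p[res$position != 146] == 1))
  # F = t^2 against the equal-variance t-test
  y <- assay(se)["146", ]
  g <- SummarizedExperiment::colData(se)$group
  tt <- t.test(y[g == "CO"], y[g == "ONLL"], var.equal = TRUE)
  expect_equal(res$F[res$position == 146], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(res$p[res$position == 146], tt$p.value, tolerance = 1e-10)
  # Bonferroni: adjusted p >= nominal, capped at 1
  expect_true(all(res$pAdj >= res$p))
  expect_true(all(res$pAdj <= 1))
  expect_equal(res$pAdj[res$position == 146],
               min(1, res$p[res$position == 146] * 853))
})

test_that("a planted group shift is the top-ranked ANOVA site", {
  set.seed(31)
  mk <- function(id, group, shift) {
    mafs <- c(0.01 + shift + 0.001 * rnorm(1), 0.005 + 0.001 * rnorm(1))
    names(mafs) <- c("146", "204")
    profileFromMaf(id, group, pmax(mafs, 1e-4))
  }
  profs <- c(
    lapply(1:30, function(i) mk(sprintf("c%02d", i), "CENT", 0.01)),
    lapply(1:30, function(i) mk(sprintf("o%02d", i), "CO", 0)),
    lapply(1:30, function(i) mk(sprintf("n%02d", i), "ONLL", 0)))
  se <- mafMatrix(HetCohort(profs))
  res <- perSiteAnova(se)
  expect_identical(res$position[which.min(res$pAdj)], 146L)
  expect_lt(res$pAdj[res$position == 146], 0.05)
  # Tukey names the planted contrasts
  contr <- res$significantContrasts[res$position == 146]
  expect_match(contr, "CENT")
})

test_that("age correlations recover exact linear structure", {
  ages <- seq(60, 100, length.out = 11)
  profs <- lapply(seq_along(ages), function(i)
    profileFromMaf(sprintf("s%02d", i), "CENT",
                   c(`146` = 0.001 + 0.0001 * ages[i]), age = ages[i]))
  se <- mafMatrix(HetCohort(profs))
  ac <- ageCorrelations(se)
  r146 <- ac$perSite[ac$perSite$position == 146, ]
  expect_equal(r146$r, 1)
  # all-zero columns are flagged undefined
  expect_true(all(ac$perSite$undefined[ac$perSite$position != 146]))
  # count vs age constant here (1 site each) -> undefined
  expect_true(is.na(ac$countVsAge$r))
})

test_that("complete-linkage clustering merges by maximum distance", {
  profs <- list(
    profileFromMaf("a", "CENT", c(`146` = 0.010)),
    profileFromMaf("b", "CENT", c(`146` = 0.010)),
    profileFromMaf("c", "CENT", c(`146` = 0.030)))
  se <- mafMatrix(HetCohort(profs))
  hc <- clusterSamples(se)
  # identical samples merge at height 0
  expect_equal(hc$height[1], 0)
  expect_true(all(diff(hc$height) >= 0))
  # planted two-cluster structure is recovered at a cut of 2
  set.seed(8)
  profs2 <- c(
    lapply(1:5, function(i) profileFromMaf(paste0("x", i), "CENT",
      c(`146` = 0.01 + 1e-4 * rnorm(1)))),
    lapply(1:5, function(i) profileFromMaf(paste0("y", i), "CO",
      c(`16129` = 0.04 + 1e-4 * rnorm(1)))))
  se2 <- mafMatrix(HetCohort(profs2))
  cl <- cutree(clusterSamples(se2), 2)
  expect_identical(length(unique(cl[paste0("x", 1:5)])), 1L)
  expect_identical(length(unique(cl[paste0("y", 1:5)])), 1L)
  expect_false(cl[["x1"]] == cl[["y1"]])
  # the Newick export carries all leaves
  nwk <- clusterNewick(clusterSamples(se2))
  expect_true(all(vapply(paste0("x", 1:5), grepl, logical(1), nwk)))
})
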