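test_that("generator config validates its invariants", {
  expect_s3_class(generatorConfig(), "mitoHetConfig")
  expect_error(generatorConfig(retention = 1.2),
               class = "mitoHet_parameter_error")
  expect_error(generatorConfig(meanDepth = 0),
               class = "mitoHet_parameter_error")
  expect_error(generatorConfig(mafMin = 0.6),
               class = "mitoHet_parameter_error")
  expect_error(generatorConfig(publicSites = 1000L),
               class = "mitoHet_parameter_error")
})

test_that("rate table: hotspots in the top decile, hypervariable
           regions elevated, deterministic in the seed", {
  r1 <- generateRateTable(seed = 5)
  expect_identical(r1$position, fragmentPositions())
  expect_true(all(r1$rate >= 0))
  hot <- r1$rate[r1$position %in% c(146L, 204L, 16129L)]
  expect_true(all(hot >= quantile(r1$rate, 0.9)))
  reg <- assignRegion(r1$position)
  expect_gt(mean(r1$rate[reg == "HV1"]),
            mean(r1$rate[reg == "INTERMEDIATE"]))
  expect_gt(mean(r1$rate[reg == "HV2"]),
            mean(r1$rate[reg == "INTERMEDIATE"]))
  expect_identical(generateRateTable(seed = 5), r1)
  expect_false(identical(generateRateTable(seed = 6), r1))
})

test_that("degenerate generator limits behave exactly", {
  rates <- generateRateTable(seed = 1)
  # rho = 1, no jitter, no de novo, no public: offspring == mother
  cfgId <- generatorConfig(nPairs = 5L, nOnll = 2L, retention = 1,
                           jitterSd = 0, deNovoRate = 0, publicProb = 0)
  tc <- generateTruthCohort(cfgId, rates, seed = 3)
  for (i in 1:5) {
    mom <- tc$profiles[[sprintf("CENT%02d", i)]]
    off <- tc$profiles[[sprintf("CO%02d", i)]]
    expect_identical(mom$sites$position, off$sites$position)
    expect_equal(mom$sites$maf, off$sites$maf)
  }
  expect_equal(tc$pairs$plantedThMother, tc$pairs$plantedThOffspring)
  # rho = 0 and no public sites: no planted sharing
  cfg0 <- generatorConfig(nPairs = 5L, nOnll = 2L, retention = 0,
                          publicProb = 0, deNovoRate = 0)
  tc0 <- generateTruthCohort(cfg0, rates, seed = 3)
  expect_identical(tc0$pairs$plantedShared, rep(0L, 5))
})

test_that("planted truth respects MAF bounds and fragment positions", {
  tc <- generateTruthCohort(generatorConfig(nPairs = 6L, nOnll = 4L),
                            generateRateTable(seed = 2), seed = 9)
  for (tr in tc$profiles) {
    expect_true(all(tr$sites$maf > 0 & tr$sites$maf <= 0.5))
    expect_true(all(tr$sites$position %in% fragmentPositions()))
    expect_false(anyDuplicated(tr$sites$position) > 0)
  }
  # groups and families are laid out as configured
  groups <- vapply(tc$profiles, `[[`, character(1), "group")
  expect_identical(as.integer(table(groups)[c("CENT", "CO", "ONLL")]),
                   c(6L, 6L, 4L))
})

test_that("strand-count simulation matches its binomial model", {
  cfg <- generatorConfig(errorRate = 0, meanDepth = 2e6)
  truth <- list(sampleId = "t", group = "CENT", familyId = "F01",
                age = 100,
                sites = data.frame(position = 146L, maf = 0.01,
                                   minor = "A",
                                   stringsAsFactors = FALSE))
  x <- simulateStrandCounts(truth, cfg, seed = 12)
  # zero error, zero MAF -> monomorphic at every other site
  comb <- x@plus + x@minus
  off <- comb[rownames(comb) != "146", ]
  expect_true(all(apply(off > 0, 1, sum) == 1))
  # empirical MAF within 3 binomial sds of 0.01 at depth 2e6
  s <- siteAlleleSummary(x@plus["146", ], x@minus["146", ])
  expect_lt(abs(s$maf - 0.01), 3 * sqrt(0.01 * 0.99 / 2e6))
  expect_identical(s$minor, "A")
  # determinism
  expect_identical(simulateStrandCounts(truth, cfg, seed = 12), x)
})

test_that("replicates share the truth but differ by noise", {
  cfg <- generatorConfig(meanDepth = 20000)
  truth <- list(sampleId = "t", group = "CENT", familyId = "F01",
                age = 100,
                sites = data.frame(position = c(146L, 16129L),
                                   maf = c(0.05, 0.02),
                                   minor = c("A", "A"),
                                   stringsAsFactors = FALSE))
  reps <- simulateReplicates(truth, n = 3, cfg, seed = 8)
  expect_length(reps, 3)
  sets <- lapply(reps, function(x) callSample(x, 0.002)$site)
  # high-MAF truth: all replicates call identical site sets
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[2]], sets[[3]])
  expect_setequal(sets[[1]], c(146L, 16129L))
  # raw counts differ across replicates (fresh noise)
  expect_false(identical(reps[[1]]@plus, reps[[2]]@plus))
  expect_error(simulateReplicates(truth, n = 1, cfg),
               class = "mitoHet_parameter_error")
})

test_that("the pipeline recovers planted occurrence-rate correlation", {
  cfg <- generatorConfig()   # default 29 pairs + 28 ONLL
  rates <- generateRateTable(seed = 30)
  tc <- generateTruthCohort(cfg, rates, seed = 30)
  plantedOcc <- table(factor(
    unlist(lapply(tc$profiles, function(tr)
      tr$sites$position[tr$sites$maf >= 0.002])),
    levels = fragmentPositions()))
  occ <- data.frame(position = fragmentPositions(),
                    count = as.integer(plantedOcc))
  expect_gt(mrCorrelation(occ, rates)$r, 0.3)
})

test_that("cohort simulation is a pure function of config and seed", {
  cfg <- generatorConfig(nPairs = 3L, nOnll = 2L, meanDepth = 5000)
  tc <- generateTruthCohort(cfg, generateRateTable(seed = 1), seed = 2)
  c1 <- simulateCohortCounts(tc, cfg, seed = 7)
  c2 <- simulateCohortCounts(tc, cfg, seed = 7)
  expect_identical(c1, c2)
  expect_false(identical(
    c1, simulateCohortCounts(tc, cfg, seed = 8)))
})
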