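# Synthetic cohort generator with full truth bookkeeping: inherited and
# de novo heteroplasmies, mutation-rate hotspots, public sites,
# deep-coverage strand-specific sequencing error, replicate PCR
# realizations.  Every output is a pure function of (config, seed).

#' Generator configuration
#'
#' Defaults emulate the study cohort: 29 mother-offspring pairs plus 28
#' unrelated controls, maternal sites retained by offspring with
#' probability 0.8 under lognormal MAF jitter (sd 0.3 on the log scale),
#' Poisson(2) de novo sites per offspring, recurrent public sites at
#' 146/204/16129 present with probability 0.9 in every individual, site
#' MAFs exponential (scale 0.004) truncated to [0.002, 0.5], mean
#' combined coverage 50,000x and per-strand per-base error 5e-4.
#'
#' @param nPairs Number of mother-offspring pairs.
#' @param nOnll Number of unrelated ONLL controls.
#' @param retention Probability an offspring retains each maternal site.
#' @param jitterSd Lognormal sd (log scale) multiplying inherited MAFs.
#' @param deNovoRate Poisson mean of de novo sites per offspring.
#' @param meanSitesBase Poisson mean of baseline (non-public) sites per
#'   mother / ONLL individual.
#' @param publicSites Recurrent hotspot positions.
#' @param publicProb Per-individual occurrence probability of each
#'   public site.
#' @param mafScale,mafMin,mafMax Truncated-exponential MAF distribution
#'   for newly arising sites.
#' @param meanDepth Mean combined-strand coverage per position (split
#'   evenly between strands).
#' @param errorRate Per-strand per-base error rate; length 1 or 2
#'   (plus, minus) to model strand-asymmetric error.
#' @param overdispersion Depth overdispersion; 0 gives Poisson depths,
#'   otherwise negative binomial with `size = 1/overdispersion`.
#' @param ageMeans,ageSds Named (CENT, CO, ONLL) normal age parameters.
#' @return Validated list of class `mitoHetConfig`.
#' @export
generatorConfig <- function(nPairs = 29L, nOnll = 28L, retention = 0.8,
                            jitterSd = 0.3, deNovoRate = 2,
                            meanSitesBase = 6,
                            publicSites = c(146L, 204L, 16129L),
                            publicProb = 0.9, mafScale = 0.004,
                            mafMin = 0.002, mafMax = 0.5,
                            meanDepth = 50000, errorRate = 5e-4,
                            overdispersion = 0,
                            ageMeans = c(CENT = 101.6, CO = 69.9,
                                         ONLL = 70.7),
                            ageSds = c(CENT = 2.8, CO = 6.6,
                                       ONLL = 4.8)) {
  cfg <- list(nPairs = as.integer(nPairs), nOnll = as.integer(nOnll),
              retention = retention, jitterSd = jitterSd,
              deNovoRate = deNovoRate, meanSitesBase = meanSitesBase,
              publicSites = as.integer(publicSites),
              publicProb = publicProb, mafScale = mafScale,
              mafMin = mafMin, mafMax = mafMax, meanDepth = meanDepth,
              errorRate = rep_len(errorRate, 2L),
              overdispersion = overdispersion,
              ageMeans = ageMeans, ageSds = ageSds)
  probs <- c(cfg$retention, cfg$publicProb)
  if (any(probs < 0 | probs > 1))
    stop2("probabilities must lie in [0, 1]",
          class = "mitoHet_parameter_error")
  if (cfg$meanDepth <= 0)
    stop2("meanDepth must be positive", class = "mitoHet_parameter_error")
  if (cfg$jitterSd < 0 || cfg$deNovoRate < 0 || any(cfg$errorRate < 0) ||
      cfg$overdispersion < 0)
    stop2("rates must be non-negative", class = "mitoHet_parameter_error")
  if (!(cfg$mafMin > 0 && cfg$mafMin < cfg$mafMax && cfg$mafMax <= 0.5))
    stop2("require 0 < mafMin < mafMax <= 0.5",
          class = "mitoHet_parameter_error")
  if (!all(cfg$publicSites %in% fragmentPositions()))
    stop2("public sites must lie in the fragment",
          class = "mitoHet_parameter_error")
  class(cfg) <- "mitoHetConfig"
  cfg
}

#' Generate a per-site relative mutation-rate table
#'
#' Gamma-distributed relative rates over the 853 positions, with region
#' means elevated in HV1 and HV2 relative to the intermediate segment
#' (means 4.7, 6.2 and 1.6 respectively, the scale of Phylotree-derived
#' control-region estimates).  Designated hotspot positions (the public
#' sites by default) are placed in the top decile.
#'
#' @param seed Integer seed.
#' @param map Region map.
#' @param hotspots Positions forced into the top rate decile.
#' @param regionMeans Named mean relative rate per region.
#' @param shape Gamma shape (scale set to mean/shape per region).  The
#'   small default gives the strongly heavy-tailed rate spectrum of
#'   control-region hotspots, where a minority of positions carries most
#'   of the mutational flux.
#' @return `data.frame` with `position` and `rate` covering every
#'   fragment position.
#' @export
generateRateTable <- function(seed = 1L, map = defaultRegionMap(),
                              hotspots = c(146L, 204L, 16129L),
                              regionMeans = c(HV1 = 4.7,
                                              INTERMEDIATE = 1.6,
                                              HV2 = 6.2),
                              shape = 0.3) {
  set.seed(seed)
  pos <- fragmentPositions()
  region <- assignRegion(pos, map)
  rate <- rgamma(length(pos), shape = shape,
                 scale = regionMeans[region] / shape)
  names(rate) <- as.character(pos)
  # pin hotspots into the top decile
  q95 <- unname(stats::quantile(rate, 0.95))
  rate[as.character(hotspots)] <- q95 * runif(length(hotspots), 1.05, 1.5)
  data.frame(position = pos, rate = unname(rate), row.names = NULL)
}

# truncated exponential on [lo, hi] via inverse CDF
rtexp <- function(n, scale, lo, hi) {
  Flo <- 1 - exp(-lo / scale); Fhi <- 1 - exp(-hi / scale)
  u <- runif(n, Flo, Fhi)
  -scale * log(1 - u)
}

# deterministic reference (major) base per position
refBase <- function(pos) BASES[(pos %% 4L) + 1L]

# draw a fresh truth site set: positions ~ rates, MAF ~ truncated exp,
# minor base uniform among non-reference bases
drawSites <- function(nSites, rates, cfg, exclude = integer()) {
  avail <- setdiff(rates$position, exclude)
  nSites <- min(nSites, length(avail))
  if (nSites == 0L)
    return(data.frame(position = integer(), maf = numeric(),
                      minor = character(), stringsAsFactors = FALSE))
  pr <- rates$rate[match(avail, rates$position)]
  posDraw <- sample(avail, nSites, prob = pr)
  maf <- rtexp(nSites, cfg$mafScale, cfg$mafMin, cfg$mafMax)
  minor <- vapply(posDraw, function(p)
    sample(setdiff(BASES, refBase(p)), 1L), character(1))
  data.frame(position = posDraw, maf = maf, minor = minor,
             stringsAsFactors = FALSE)
}

mergeSites <- function(a, b) {
  # keep existing entries (a) where positions collide
  rbind(a, b[!b$position %in% a$position, , drop = FALSE])
}

newTruthProfile <- function(sampleId, group, familyId, age, sites) {
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  list(sampleId = sampleId, group = group, familyId = familyId,
       age = age, sites = sites)
}

#' Generate a ground-truth cohort
#'
#' Mothers (CENT) and unrelated controls (ONLL) receive Poisson
#' (`meanSitesBase`) baseline sites placed proportionally to the
#' mutation rate with truncated-exponential MAFs, plus each public site
#' with probability `publicProb`.  Offspring (CO) inherit each maternal
#' site with probability `retention` (MAF multiplied by lognormal
#' jitter, capped at `mafMax`), gain Poisson(`deNovoRate`) de novo sites
#' placed proportionally to the mutation rate, and draw public sites
#' like everyone else (recurrent mutation).  Bookkeeping records the
#' planted per-pair shared-site counts and per-sample total
#' heteroplasmy, evaluated at the detection threshold.
#'
#' @param config A `mitoHetConfig` ([generatorConfig()]).
#' @param rates Mutation-rate table ([generateRateTable()]).
#' @param seed Integer seed.
#' @param threshold Detection threshold used for the bookkeeping of
#'   detectable planted sites.
#' @return List with `profiles` (list of truth profiles: `sampleId`,
#'   `group`, `familyId`, `age`, `sites` data.frame
#'   `position`/`maf`/`minor`), `pairs` (`data.frame` `familyId`,
#'   `motherId`, `offspringId`, `plantedShared`, `plantedThMother`,
#'   `plantedThOffspring`), and the `config` and `seed` used.
#' @export
generateTruthCohort <- function(config = generatorConfig(),
                                rates = generateRateTable(),
                                seed = 1L, threshold = 0.002) {
  stopifnot(inherits(config, "mitoHetConfig"))
  set.seed(seed)
  cfg <- config
  drawPublic <- function() {
    keep <- runif(length(cfg$publicSites)) < cfg$publicProb
    ps <- cfg$publicSites[keep]
    data.frame(position = ps,
               maf = rtexp(length(ps), cfg$mafScale, cfg$mafMin, cfg$mafMax),
               minor = vapply(ps, function(p)
                 sample(setdiff(BASES, refBase(p)), 1L), character(1)),
               stringsAsFactors = FALSE)
  }
  baseIndividual <- function() {
    n <- rpois(1L, cfg$meanSitesBase)
    mergeSites(drawSites(n, rates, cfg, exclude = cfg$publicSites),
               drawPublic())
  }
  drawAge <- function(group)
    round(rnorm(1L, cfg$ageMeans[[group]], cfg$ageSds[[group]]), 1)

  profilesList <- list()
  pairRows <- list()
  for (i in seq_len(cfg$nPairs)) {
    famId <- sprintf("F%02d", i)
    momSites <- baseIndividual()
    # offspring: inherited subset with jittered MAFs ...
    keep <- runif(nrow(momSites)) < cfg$retention
    inh <- momSites[keep, , drop = FALSE]
    if (nrow(inh)) {
      inh$maf <- pmin(inh$maf * exp(rnorm(nrow(inh), 0, cfg$jitterSd)),
                      cfg$mafMax)
    }
    # ... plus de novo sites and recurrent public sites
    dn <- drawSites(rpois(1L, cfg$deNovoRate), rates, cfg,
                    exclude = c(inh$position, cfg$publicSites))
    offSites <- mergeSites(mergeSites(inh, dn), drawPublic())
    momId <- sprintf("CENT%02d", i); offId <- sprintf("CO%02d", i)
    mom <- newTruthProfile(momId, "CENT", famId, drawAge("CENT"), momSites)
    off <- newTruthProfile(offId, "CO", famId, drawAge("CO"), offSites)
    profilesList[[momId]] <- mom
    profilesList[[offId]] <- off
    det <- function(s) s$position[s$maf >= threshold]
    pairRows[[i]] <- data.frame(
      familyId = famId, motherId = momId, offspringId = offId,
      plantedShared = length(intersect(det(mom$sites), det(off$sites))),
      plantedThMother = sum(mom$sites$maf[mom$sites$maf >= threshold]) * 100,
      plantedThOffspring = sum(off$sites$maf[off$sites$maf >= threshold]) * 100,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$nOnll)) {
    id <- sprintf("ONLL%02d", i)
    profilesList[[id]] <- newTruthProfile(id, "ONLL", NA_character_,
                                          drawAge("ONLL"), baseIndividual())
  }
  list(profiles = profilesList, pairs = do.call(rbind, pairRows),
       config = cfg, seed = as.integer(seed))
}

#' Simulate strand-resolved counts from a truth profile
#'
#' Per site and strand, depth is drawn around half the mean combined
#' depth (Poisson, or negative binomial when `overdispersion > 0`);
#' minor-allele reads are binomial at the true MAF; error reads are
#' binomial at the per-strand error rate among the remaining reads and
#' split uniformly over the three non-major bases.  Sites with true MAF
#' 0 receive error reads only.
#'
#' @param truth A truth profile ([generateTruthCohort()] element).
#' @param config A `mitoHetConfig`.
#' @param seed Integer seed.
#' @return A [StrandCounts-class] object covering all 853 positions.
#' @export
simulateStrandCounts <- function(truth, config = generatorConfig(),
                                 seed = 1L) {
  stopifnot(inherits(config, "mitoHetConfig"))
  set.seed(seed)
  pos <- fragmentPositions()
  n <- length(pos)
  maf <- numeric(n); names(maf) <- as.character(pos)
  minorIdx <- rep(NA_integer_, n)
  if (nrow(truth$sites)) {
    at <- match(truth$sites$position, pos)
    maf[at] <- truth$sites$maf
    minorIdx[at] <- match(truth$sites$minor, BASES)
  }
  majIdx <- match(refBase(pos), BASES)
  strandDepth <- config$meanDepth / 2
  simStrand <- function(err) {
    d <- if (config$overdispersion > 0)
      rnbinom(n, mu = strandDepth, size = 1 / config$overdispersion)
    else rpois(n, strandDepth)
    nMinor <- ifelse(maf > 0, rbinom(n, d, maf), 0L)
    nErr <- rbinom(n, d - nMinor, err)
    # split errors over the three non-major bases (vectorised multinomial)
    e1 <- rbinom(n, nErr, 1 / 3)
    e2 <- rbinom(n, nErr - e1, 1 / 2)
    e3 <- nErr - e1 - e2
    cnt <- matrix(0L, n, 4L, dimnames = list(as.character(pos), BASES))
    nonMaj <- t(vapply(majIdx, function(j) setdiff(1:4, j), integer(3)))
    idx <- seq_len(n)
    cnt[cbind(idx, nonMaj[, 1])] <- e1
    cnt[cbind(idx, nonMaj[, 2])] <- e2
    cnt[cbind(idx, nonMaj[, 3])] <- e3
    has <- !is.na(minorIdx)
    cnt[cbind(idx[has], minorIdx[has])] <-
      cnt[cbind(idx[has], minorIdx[has])] + as.integer(nMinor[has])
    cnt[cbind(idx, majIdx)] <- as.integer(d - nMinor - nErr)
    cnt
  }
  StrandCounts(truth$sampleId, pos,
               plus = simStrand(config$errorRate[1L]),
               minus = simStrand(config$errorRate[2L]))
}

#' Simulate replicate PCR count realizations
#'
#' `n` independent count realizations from the same truth (fresh depth
#' and error draws per replicate).  Optional lognormal per-replicate MAF
#' perturbation models PCR drift (off by default).
#'
#' @param truth A truth profile.
#' @param n Number of replicates (at least 2; canonically 3).
#' @param config A `mitoHetConfig`.
#' @param seed Integer seed.
#' @param pcrJitterSd Lognormal sd of the per-replicate MAF
#'   perturbation (0 = off).
#' @return List of `n` [StrandCounts-class] objects.
#' @export
simulateReplicates <- function(truth, n = 3L, config = generatorConfig(),
                               seed = 1L, pcrJitterSd = 0) {
  if (n < 2L)
    stop2("need at least 2 replicates", class = "mitoHet_parameter_error")
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(j) {
    tr <- truth
    if (pcrJitterSd > 0 && nrow(tr$sites)) {
      set.seed(subSeeds[j])
      tr$sites$maf <- pmin(tr$sites$maf *
                             exp(rnorm(nrow(tr$sites), 0, pcrJitterSd)),
                           config$mafMax)
    }
    simulateStrandCounts(tr, config, seed = subSeeds[j])
  })
}

#' Simulate counts for a whole truth cohort
#'
#' @param truthCohort Result of [generateTruthCohort()].
#' @param config A `mitoHetConfig`.
#' @param seed Integer seed (per-sample sub-seeds are derived from it).
#' @return Named list of [StrandCounts-class] objects.
#' @export
simulateCohortCounts <- function(truthCohort, config = generatorConfig(),
                                 seed = 1L) {
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max,
                         length(truthCohort$profiles))
  out <- lapply(seq_along(truthCohort$profiles), function(i)
    simulateStrandCounts(truthCohort$profiles[[i]], config,
                         seed = subSeeds[i]))
  names(out) <- names(truthCohort$profiles)
  out
}

#' Build SampleProfiles for a simulated cohort
#'
#' Convenience wrapper: simulates counts for every truth profile and
#' runs QC + calling on each.
#'
#' @inheritParams simulateCohortCounts
#' @param threshold,strandMultiplier,coverageFloor Passed to
#'   [buildProfile()].
#' @return A [HetCohort-class] object.
#' @export
simulateCohort <- function(truthCohort, config = generatorConfig(),
                           seed = 1L, threshold = 0.002,
                           strandMultiplier = 1, coverageFloor = 10000) {
  counts <- simulateCohortCounts(truthCohort, config, seed)
  profs <- lapply(names(counts), function(id) {
    tr <- truthCohort$profiles[[id]]
    buildProfile(counts[[id]], group = tr$group, familyId = tr$familyId,
                 age = tr$age, threshold = threshold,
                 strandMultiplier = strandMultiplier,
                 coverageFloor = coverageFloor)
  })
  HetCohort(profs)
}
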