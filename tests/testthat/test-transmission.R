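# helper: pair set with prescribed per-sample (site -> maf) maps
makePairs <- function(momMafs, offMafs, onllMafs = list()) {
  mk <- function(id, group, mafs, fam) {
    calls <- if (length(mafs))
      data.frame(site = as.integer(names(mafs)), major = "A",
                 minor = "G", maf = unname(mafs), depth = 50000L,
                 dsValidated = TRUE, stringsAsFactors = FALSE)
    else data.frame(site = integer(), major = character(),
                    minor = character(), maf = numeric(),
                    depth = integer(), dsValidated = logical())
    SampleProfile(id, group, fam, 70, 50000, TRUE, calls)
  }
  profs <- c(
    lapply(seq_along(momMafs), function(i)
      mk(sprintf("CENT%02d", i), "CENT", momMafs[[i]], sprintf("F%02d", i))),
    lapply(seq_along(offMafs), function(i)
      mk(sprintf("CO%02d", i), "CO", offMafs[[i]], sprintf("F%02d", i))),
    lapply(seq_along(onllMafs), function(i)
      mk(sprintf("ONLL%02d", i), "ONLL", onllMafs[[i]], NA_character_)))
  pairSet(profs)
}

test_that("total heteroplasmy sums MAFs in percent", {
  p <- SampleProfile("s1", "CENT", calls = data.frame(
    site = c(146L, 204L, 16129L), major = "A", minor = "G",
    maf = c(0.005, 0.003, 0.002), depth = 50000L, dsValidated = TRUE))
  expect_equal(totalHeteroplasmy(p), 1.0)
  expect_equal(totalHeteroplasmy(SampleProfile("s2", "CO")), 0)
  bad <- SampleProfile("s3", "CO", qcPass = FALSE)
  expect_error(totalHeteroplasmy(bad), class = "mitoHet_qc_error")
})

test_that("pair correlation hits exact limits and guards degeneracy", {
  mafs <- lapply(1:5, function(i) setNames(0.002 * i, "146"))
  pairs <- makePairs(mafs, mafs)
  expect_equal(pairCorrelation(pairs)$r, 1)
  expect_error(pairCorrelation(makePairs(mafs[1:2], mafs[1:2])),
               class = "mitoHet_parameter_error")
  const <- lapply(1:5, function(i) setNames(0.004, "146"))
  expect_error(pairCorrelation(makePairs(const, const)),
               class = "mitoHet_degenerate_error")
})

test_that("TNCS counts shared sites over pairs", {
  pairs <- makePairs(
    momMafs = list(c(`146` = 0.004, `204` = 0.005, `100` = 0.003),
                   c(`150` = 0.004)),
    offMafs = list(c(`146` = 0.004, `204` = 0.006),
                   c(`151` = 0.004)))
  expect_identical(tncs(pairs), 2L)
  # every pair shares the same 3 sites, 29 pairs -> 87
  shared <- c(`146` = 0.004, `204` = 0.004, `16129` = 0.004)
  pairs29 <- makePairs(rep(list(shared), 29), rep(list(shared), 29))
  expect_identical(tncs(pairs29), 87L)
  # symmetric in pair-member order and bounded
  expect_identical(tncs(lapply(pairs29@mothers, hetSites),
                        lapply(pairs29@offspring, hetSites)),
                   tncs(lapply(pairs29@offspring, hetSites),
                        lapply(pairs29@mothers, hetSites)))
  expect_lte(tncs(pairs29), 853L * 29L)
})

test_that("the exhaustive permutation null of Pearson r has mean zero;
           self-pairing over derangements has mean -1/(n-1)", {
  set.seed(17)
  for (n in c(4, 5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    perms <- permutationsOf(n)
    # permuting one side of two fixed vectors: the numerator of r sums
    # to (n-1)! * sum(x - xbar) * sum(y - ybar) = 0 over all n! maps,
    # so the exhaustive mean is exactly zero
    rs <- apply(perms, 1, function(ix) cor(x, y[ix]))
    expect_equal(mean(rs), 0, tolerance = 1e-12)
    # the classical -1/(n-1) arises for a vector paired with a
    # derangement of itself (no element kept in place)
    der <- perms[apply(perms, 1, function(ix)
      all(ix != seq_len(n))), , drop = FALSE]
    rsSelf <- apply(der, 1, function(ix) cor(x, x[ix]))
    expect_equal(mean(rsSelf), -1 / (n - 1), tolerance = 1e-12)
  }
})

test_that("reshuffleNull reproduces the permutation-null mean and the
           add-one empirical p", {
  set.seed(23)
  x <- rnorm(29, 10, 3); y <- x + rnorm(29, 0, 2)
  nd <- reshuffleNull(x, y, "pearson", nReshuffles = 2000, seed = 99)
  expect_length(nullReplicates(nd), 2000)
  se <- sd(nullReplicates(nd)) / sqrt(2000)
  expect_lt(abs(mean(nullReplicates(nd)) - 0), 4 * se)
  expect_equal(empiricalP(nd),
               (1 + sum(nullReplicates(nd) >= observedStat(nd))) / 2001)
  # same seed -> identical distribution
  nd2 <- reshuffleNull(x, y, "pearson", nReshuffles = 2000, seed = 99)
  expect_identical(nullReplicates(nd), nullReplicates(nd2))
})

test_that("a constant TNCS null gives empirical p 1", {
  sets <- rep(list(c(146L, 204L, 16129L)), 6)
  nd <- reshuffleNull(sets, sets, "tncs", nReshuffles = 200, seed = 4)
  expect_equal(unique(nullReplicates(nd)), 18)  # 6 pairs x 3 shared sites
  expect_equal(empiricalP(nd), 1)
})

test_that("cross-group nulls are centred near zero", {
  set.seed(41)
  nd <- crossGroupNull(rnorm(29), rnorm(28), nReshuffles = 500, seed = 6)
  expect_true(is.na(observedStat(nd)))
  expect_lt(abs(mean(nullReplicates(nd))), 3 * sd(nullReplicates(nd)) /
              sqrt(500) + 0.05)
})

test_that("site distance is the normalised absolute MAF difference", {
  expect_equal(siteDistance(0.005, 0.0025), 50)
  expect_equal(siteDistance(0.004, 0.004), 0)
  expect_equal(siteDistance(0.002, 0.02), 90)
  # symmetric and bounded
  set.seed(2)
  m1 <- runif(50, 0.002, 0.5); m2 <- runif(50, 0.002, 0.5)
  expect_equal(siteDistance(m1, m2), siteDistance(m2, m1))
  expect_true(all(siteDistance(m1, m2) >= 0 & siteDistance(m1, m2) <= 100))
  expect_identical(siteDistance(m1, m1), rep(0, 50))
  expect_error(siteDistance(0.001, 0.004),
               class = "mitoHet_parameter_error")
})

test_that("the pair distance matrix covers only jointly heteroplasmic
           sites", {
  pairs <- makePairs(
    momMafs = list(c(`146` = 0.004, `204` = 0.01)),
    offMafs = list(c(`146` = 0.002, `100` = 0.01)))
  dm <- pairDistanceMatrix(pairs)
  expect_identical(dim(dm), c(1L, 853L))
  expect_equal(dm["F01", "146"], 50)
  expect_true(is.na(dm["F01", "204"]))
  expect_true(is.na(dm["F01", "100"]))
})

test_that("sites classify as public, private or absent by shared
           fraction", {
  shared <- c(`146` = 0.004)
  one <- c(`150` = 0.004)
  pairs <- makePairs(
    momMafs = c(rep(list(shared), 3), list(c(shared, one))),
    offMafs = c(rep(list(shared), 3), list(c(shared, one))))
  cls <- classifySites(pairs)
  expect_identical(unname(cls["146"]), "public")   # 4/4 pairs
  expect_identical(unname(cls["150"]), "private")  # 1/4 pairs
  expect_identical(unname(cls["100"]), "absent")
  expect_identical(sum(cls == "public"), 1L)
})
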