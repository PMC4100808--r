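# Shared fixtures and independent oracles, all built in code.

# StrandCounts with identical plus/minus strands from per-site
# (major, minor, majorCount, minorCount) specs.
makeCounts <- function(sampleId, site, major, minor, nMajor, nMinor,
                       plusOnlyMinor = FALSE) {
  n <- length(site)
  mk <- function(withMinor) {
    m <- matrix(0L, n, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    m[cbind(seq_len(n), match(major, colnames(m)))] <- as.integer(nMajor)
    if (withMinor)
      m[cbind(seq_len(n), match(minor, colnames(m)))] <-
        m[cbind(seq_len(n), match(minor, colnames(m)))] + as.integer(nMinor)
    m
  }
  StrandCounts(sampleId, site, plus = mk(TRUE), minus = mk(!plusOnlyMinor))
}

# uniform-depth monomorphic table over all fragment positions
monomorphicCounts <- function(sampleId = "s", depthPerStrand = 25000L) {
  pos <- fragmentPositions()
  makeCounts(sampleId, pos, major = rep("A", length(pos)), minor = "C",
             nMajor = depthPerStrand, nMinor = 0L)
}

# all permutations of 1..n (brute-force oracle; n <= 7)
permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# independent Fisher oracle: exact hypergeometric enumeration with
# choose(), two-sided p as the sum of table probabilities not exceeding
# the observed one (with the conventional 1 + 1e-7 slack)
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  pObs <- p[x == a]
  list(p = sum(p[p <= pObs * (1 + 1e-7)]),
       orCrossProduct = (a * d) / (b * c))
}
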