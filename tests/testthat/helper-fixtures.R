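# Shared fixture builders; everything is generated in code at test time.

randomExpr <- function(nf, ns, seed, missingRate = 0) {
  set.seed(seed)
  v <- matrix(rnorm(nf * ns, sd = 2), nf, ns,
              dimnames = list(sprintf("miR-t%03d", seq_len(nf)),
                              sprintf("S%03d", seq_len(ns))))
  m <- matrix(runif(nf * ns) < missingRate, nf, ns,
              dimnames = dimnames(v))
  v[m] <- NA_real_
  MirnaExpressionSet(v, m)
}

# small two-group cohort with one planted signature, for fast DLCV tests
smallCohort <- function(seed = 1, effect = 3, noise = 1,
                        nFeatures = 80L, nPos = 14L, nNeg = 26L,
                        sigSize = 6L) {
  generateCohort(cohortDesign(
    nFeatures = nFeatures,
    groupSizes = c(MLL = nPos, other = nNeg),
    signatureSizes = c(MLL = sigSize),
    effectLog2 = effect, noiseSd = noise, missingRate = 0,
    rngSeed = seed))
}

# pair-counting adjusted Rand index (independent of any clustering package)
pairAri <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}
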