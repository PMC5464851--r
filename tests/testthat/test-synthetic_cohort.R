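test_that("default design reproduces the study cohort geometry", {
  d <- cohortDesign(rngSeed = 11)
  coh <- generateCohort(d)
  expect_equal(dim(exprValues(coh$expression)), c(664L, 165L))
  expect_equal(as.vector(table(factor(coh$truth$sampleLabels,
                                      levels = AML_SUBTYPES))),
               c(36L, 21L, 17L, 12L, 11L, 11L, 57L))
  sizes <- vapply(coh$truth$plantedSignatures, nrow, integer(1))
  expect_equal(sizes[c("MLL", "t_8_21", "inv_16", "t_15_17",
                       "CEBPA_dm", "NPM1")],
               c(MLL = 37L, t_8_21 = 14L, inv_16 = 17L, t_15_17 = 14L,
                 CEBPA_dm = 18L, NPM1 = 5L))
  # disjoint by default
  all <- unlist(lapply(coh$truth$plantedSignatures, `[[`, "mirna"))
  expect_false(anyDuplicated(all) > 0)
})

test_that("zero-noise cohorts show the planted effect exactly", {
  coh <- generateCohort(cohortDesign(
    nFeatures = 40L, groupSizes = c(MLL = 6L, other = 10L),
    signatureSizes = c(MLL = 8L), effectLog2 = 3, noiseSd = 0,
    missingRate = 0, rngSeed = 4))
  v <- exprValues(coh$expression)
  lab <- coh$truth$sampleLabels
  ps <- coh$truth$plantedSignatures$MLL
  for (i in seq_len(nrow(ps))) {
    gap <- mean(v[ps$mirna[i], lab == "MLL"]) -
           mean(v[ps$mirna[i], lab != "MLL"])
    expect_equal(gap, ifelse(ps$direction[i] == "up", 3, -3),
                 tolerance = 1e-12)
  }
  # non-signature features carry no group difference at all
  others <- setdiff(rownames(v), ps$mirna)
  gaps <- rowMeans(v[others, lab == "MLL"]) -
          rowMeans(v[others, lab != "MLL"])
  expect_equal(unname(gaps), rep(0, length(others)), tolerance = 1e-12)
})

test_that("planted group-mean differences match the design under noise", {
  # Monte-Carlo: the pooled signed in-out gap estimates effectLog2
  diffs <- c()
  for (seed in 1:20) {
    coh <- generateCohort(cohortDesign(rngSeed = seed, noiseSd = 1))
    v <- exprValues(coh$expression)
    lab <- coh$truth$sampleLabels
    for (g in names(coh$truth$plantedSignatures)) {
      ps <- coh$truth$plantedSignatures[[g]]
      gap <- rowMeans(v[ps$mirna, lab == g, drop = FALSE]) -
             rowMeans(v[ps$mirna, lab != g, drop = FALSE])
      diffs <- c(diffs, ifelse(ps$direction == "up", 1, -1) * gap)
    }
  }
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - log2(6)), 3 * se)
})

test_that("identical designs generate identical cohorts", {
  d <- cohortDesign(rngSeed = 77, missingRate = 0.05)
  a <- generateCohort(d)
  b <- generateCohort(d)
  expect_identical(exprValues(a$expression), exprValues(b$expression))
  expect_identical(missingMask(a$expression), missingMask(b$expression))
  expect_identical(a$truth, b$truth)
})

test_that("undetected cells are floor-imputed and flagged", {
  coh <- generateCohort(cohortDesign(
    nFeatures = 120L, groupSizes = c(MLL = 12L, other = 20L),
    signatureSizes = c(MLL = 5L), missingRate = 0.1, rngSeed = 3))
  m <- missingMask(coh$expression)
  v <- exprValues(coh$expression)
  expect_gt(mean(m), 0.05)
  expect_lt(mean(m), 0.15)
  expect_true(all(v[m] == min(v[!m])))
  expect_true(all(is.finite(v)))
})

test_that("oversized signatures are rejected", {
  expect_error(generateCohort(cohortDesign(
    nFeatures = 10L, groupSizes = c(MLL = 12L, other = 20L),
    signatureSizes = c(MLL = 11L))), "exceed")
})

test_that("null cohorts show no group effect beyond Gaussian bounds", {
  hits <- 0L
  nSeeds <- 20L
  for (seed in 1:nSeeds) {
    coh <- generateCohort(cohortDesign(
      nFeatures = 200L, groupSizes = c(MLL = 14L, inv_16 = 10L,
                                       other = 26L),
      signatureSizes = c(MLL = 5L), effectLog2 = 0, noiseSd = 1,
      missingRate = 0, rngSeed = 100 + seed))
    v <- exprValues(coh$expression)
    lab <- coh$truth$sampleLabels
    groups <- c("MLL", "inv_16")
    nTests <- nrow(v) * length(groups)
    z <- qnorm(1 - 0.025 / nTests)
    ok <- TRUE
    for (g in groups) {
      n1 <- sum(lab == g); n0 <- sum(lab != g)
      gap <- rowMeans(v[, lab == g]) - rowMeans(v[, lab != g])
      bound <- z * sqrt(1 / n1 + 1 / n0)
      if (any(abs(gap) > bound)) ok <- FALSE
    }
    hits <- hits + ok
  }
  expect_gte(hits, round(0.95 * nSeeds) - 2L)  # binomial slack at n = 20
})

test_that("paired mRNA targets track their miRNA at the set coupling", {
  coh <- smallCohort(seed = 5)
  # exact linear map when noiseless
  ex <- generatePairedMrna(coh$truth, coh$expression, coupling = -1,
                           nTargetsPerMirna = 2L, noiseSd = 0, rngSeed = 1)
  for (i in seq_len(nrow(ex$targetMap))) {
    r <- cor(exprValues(coh$expression)[ex$targetMap$mirna[i], ],
             exprValues(ex$expression)[ex$targetMap$gene[i], ])
    expect_equal(r, -1, tolerance = 1e-12)
  }
  # with unit noise the correlation is negative for nearly every pair
  negShare <- c()
  for (seed in 1:20) {
    g <- generatePairedMrna(coh$truth, coh$expression, coupling = -1,
                            nTargetsPerMirna = 3L, noiseSd = 1,
                            rngSeed = seed)
    r <- vapply(seq_len(nrow(g$targetMap)), function(i)
      cor(exprValues(coh$expression)[g$targetMap$mirna[i], ],
          exprValues(g$expression)[g$targetMap$gene[i], ]), numeric(1))
    negShare <- c(negShare, mean(r < 0))
  }
  expect_gte(mean(negShare), 0.95)
  # zero coupling: no systematic correlation
  g0 <- generatePairedMrna(coh$truth, coh$expression, coupling = 0,
                           nTargetsPerMirna = 10L, rngSeed = 2)
  r0 <- vapply(seq_len(nrow(g0$targetMap)), function(i)
    cor(exprValues(coh$expression)[g0$targetMap$mirna[i], ],
        exprValues(g0$expression)[g0$targetMap$gene[i], ]), numeric(1))
  expect_lt(abs(mean(r0)), 0.1)
  expect_error(generatePairedMrna(coh$truth, coh$expression, coupling = 0.5),
               "coupling")
})

test_that("second-platform emulation keeps floor(fraction * n) features", {
  coh <- generateCohort(cohortDesign(rngSeed = 6))
  p <- generateSecondPlatform(coh$expression, keepFraction = 0.5,
                              shiftSd = 0, rngSeed = 1)
  expect_equal(nrow(p), 332L)
  expect_true(all(featureIds(p) %in% featureIds(coh$expression)))
  # identity case
  pid <- generateSecondPlatform(coh$expression, keepFraction = 1,
                                shiftSd = 0, rngSeed = 1)
  expect_identical(exprValues(pid), exprValues(coh$expression))
  # per-feature offsets have roughly the requested spread
  sds <- c()
  for (seed in 1:10) {
    ps <- generateSecondPlatform(coh$expression, keepFraction = 1,
                                 shiftSd = 5, rngSeed = seed)
    off <- rowMeans(exprValues(ps)) - rowMeans(exprValues(coh$expression))
    sds <- c(sds, sd(off))
  }
  expect_equal(mean(sds), 5, tolerance = 0.15)
  expect_error(generateSecondPlatform(coh$expression, keepFraction = 0),
               "keepFraction")
})
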