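test_that("feature ranking follows the closed-form Welch statistic", {
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  set.seed(7)
  v <- rbind(f1 = c(5.0, 5.2, 4.9, 1.0, 1.1, 0.8),
             f2 = c(2.0, 2.1, 1.9, 1.8, 2.2, 2.0),
             f3 = c(0.0, 1.0, 2.0, 4.0, 5.0, 6.0),
             f4 = rnorm(6),
             f5 = c(3.0, 3.0, 3.0, 3.0, 3.0, 3.0))
  colnames(v) <- paste0("s", 1:6)
  welch <- function(x) {
    a <- x[y]; b <- x[!y]
    abs(mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  }
  tExp <- apply(v, 1, welch)
  tExp[5] <- 0                              # zero gap, zero variance
  expect_identical(rankFeatures(v, y),
                   names(sort(-tExp)))

  # a perfect separator with zero within-class variance ranks first
  v2 <- rbind(v, sep = c(1, 1, 1, 0, 0, 0))
  expect_identical(rankFeatures(v2, y)[1], "sep")
  # an identical-in-both-classes feature ranks last
  expect_identical(rankFeatures(v, y)[5], "f5")
  expect_error(rankFeatures(v[, 1:3], y[1:3]), "two samples")
})

test_that("the linear SVM finds the maximum-margin boundary on toys", {
  v <- matrix(c(-2, -1, 1, 2), 1, 4,
              dimnames = list("f1", paste0("s", 1:4)))
  y <- c(FALSE, FALSE, TRUE, TRUE)
  model <- trainOvrSvm(v, y, "f1", cost = 10)
  expect_identical(unname(predict(model, matrix(c(-0.4, 0.4), 1, 2,
    dimnames = list("f1", c("a", "b"))))), c(FALSE, TRUE))
  # analytic hard-margin solution: boundary at 0, decision value +-1 at
  # the support vectors (x = -1 and x = 1)
  sv <- matrix(c(-1, 0, 1), 1, 3, dimnames = list("f1", c("m", "z", "p")))
  zstd <- t((sv - model$mu) / model$sd)
  dec <- as.numeric(attr(predict(model$svm, zstd,
                                 decision.values = TRUE),
                         "decision.values"))
  # e1071 orients decision values by first label (FALSE): negative side
  expect_equal(abs(dec), c(1, 0, 1), tolerance = 1e-3)
  expect_equal(dec[2], 0, tolerance = 1e-3)

  # label symmetry: flipping y flips every prediction
  flipped <- trainOvrSvm(v, !y, "f1", cost = 10)
  newx <- matrix(seq(-3, 3, by = 0.5), 1,
                 dimnames = list("f1", NULL))
  colnames(newx) <- paste0("n", seq_len(ncol(newx)))
  expect_identical(unname(predict(model, newx)),
                   !unname(predict(flipped, newx)))
  expect_error(trainOvrSvm(v, y, character(0)), "non-empty")
})

test_that("inner loop picks the single informative feature and ties small", {
  # only feature "inf" separates; all other features are exact duplicates
  # of each other, so every grid size predicts identically => tie => m* = 1
  set.seed(11)
  y <- rep(c(TRUE, FALSE), each = 10)
  sep <- ifelse(y, 4, 0) + rnorm(20, sd = 0.1)
  dup <- rnorm(20)
  v <- rbind(inf = sep, d1 = dup, d2 = dup, d3 = dup)
  colnames(v) <- paste0("s", 1:20)
  m <- innerLoopSelect(v, y, featureGrid = c(1L, 2L, 3L), innerFolds = 5L,
                       rngSeed = 1)
  expect_equal(as.integer(m), 1L)
  acc <- attr(m, "meanBalancedAccuracy")
  expect_equal(unname(acc["1"]), 1)

  # grid of one: no comparison happens
  expect_equal(as.integer(innerLoopSelect(v, y, featureGrid = 5L,
                                          innerFolds = 5L, rngSeed = 1)),
               4L)   # capped at the feature count

  # minority class smaller than the fold count triggers refolding
  ySmall <- c(rep(TRUE, 3), rep(FALSE, 17))
  expect_warning(innerLoopSelect(v, ySmall, featureGrid = c(1L, 2L),
                                 innerFolds = 5L, rngSeed = 1),
                 "reduced to 3")
})

test_that("confusion metrics match direct arithmetic and flag undefined", {
  m <- computeMetrics(tp = 9, fp = 5, tn = 85, fn = 1)
  expect_equal(unname(m), c(100 * 9 / 10, 100 * 85 / 90, 100 * 9 / 14,
                            100 * 85 / 86, 94),
               tolerance = 1e-12)
  expect_equal(unname(computeMetrics(10, 0, 20, 0)), rep(100, 5))

  degenerate <- computeMetrics(tp = 0, fp = 0, tn = 30, fn = 10)
  expect_true(is.nan(degenerate[["ppv"]]))
  expect_equal(degenerate[["sensitivity"]], 0)
  expect_error(computeMetrics(0, 0, 0, 0), "all confusion counts")

  # brute-force counting from prediction/label vectors
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    m <- computeMetrics(tp = sum(pred & truth), fp = sum(pred & !truth),
                        tn = sum(!pred & !truth), fn = sum(!pred & truth))
    seExp <- if (sum(truth) == 0) NaN else 100 * mean(pred[truth])
    spExp <- if (sum(!truth) == 0) NaN else 100 * mean(!pred[!truth])
    accExp <- 100 * mean(pred == truth)
    expect_equal(m[["sensitivity"]], seExp)
    expect_equal(m[["specificity"]], spExp)
    expect_equal(m[["accuracy"]], accExp)
  }
})

test_that("outer-fold models never see their test samples", {
  coh <- smallCohort(seed = 2)
  v <- exprValues(coh$expression)
  y <- coh$truth$sampleLabels == "MLL"
  cfg <- pipelineConfig(featureGrid = c(1L, 2L, 4L, 8L), rngSeed = 3)
  trainIdx <- which(seq_along(y) %% 3 != 0)
  fit1 <- fitFoldModel(v, y, trainIdx, cfg, rngSeed = 5)
  vPerturbed <- v
  vPerturbed[, -trainIdx] <- vPerturbed[, -trainIdx] + 1000
  fit2 <- fitFoldModel(vPerturbed, y, trainIdx, cfg, rngSeed = 5)
  expect_identical(fit1$features, fit2$features)
  expect_identical(fit1$mStar, fit2$mStar)
  expect_identical(fit1$model$mu, fit2$model$mu)
  expect_identical(fit1$model$sd, fit2$model$sd)
  expect_identical(fit1$model$svm$coefs, fit2$model$svm$coefs)
  expect_identical(fit1$model$svm$rho, fit2$model$svm$rho)
  expect_identical(fit1$model$svm$SV, fit2$model$svm$SV)
})

test_that("DLCV separates a planted subtype and stays deterministic", {
  coh <- smallCohort(seed = 4, nPos = 14L, nNeg = 26L)
  cfg <- pipelineConfig(dlcvRuns = 4L, minGroupSize = 10L,
                        featureGrid = c(1L, 2L, 3L, 5L, 8L, 12L),
                        rngSeed = 17)
  r1 <- dlcv(coh$expression, coh$annotation, "MLL", cfg)
  expect_gte(dlcvMetrics(r1)[["sensitivity"]], 85)
  expect_gte(dlcvMetrics(r1)[["specificity"]], 85)
  expect_equal(sum(r1@confusionTotals), 4 * 40)

  # every consolidated member is a planted signature miRNA, direction true
  planted <- coh$truth$plantedSignatures$MLL
  members <- signatureMembers(r1)
  expect_gt(nrow(members), 0)
  expect_true(all(members$mirna %in% planted$mirna))
  expect_identical(members$direction,
                   planted$direction[match(members$mirna, planted$mirna)])

  r2 <- dlcv(coh$expression, coh$annotation, "MLL", cfg)
  expect_identical(r1@runMetrics, r2@runMetrics)
  expect_identical(r1@selectionFrequency, r2@selectionFrequency)
  expect_identical(signatureMembers(r1), signatureMembers(r2))

  expect_error(dlcv(coh$expression, coh$annotation, "NPM1", cfg),
               "below the minimum group size")
})

test_that("signature consolidation unions members across subtypes", {
  mk <- function(st, ids) new("SubtypeSignature", subtype = st,
    members = data.frame(mirna = ids, direction = "up",
                         frequency = seq(1, 0.5, length.out = length(ids))))
  disjoint <- consolidateSignatures(list(mk("MLL", paste0("a", 1:3)),
                                         mk("NPM1", paste0("b", 1:4))))
  expect_equal(disjoint$unionSize, 7L)
  identical2 <- consolidateSignatures(list(mk("MLL", paste0("a", 1:3)),
                                           mk("NPM1", paste0("a", 1:3))))
  expect_equal(identical2$unionSize, 3L)
  overlap <- consolidateSignatures(list(mk("MLL", c("x", "y", "z")),
                                        mk("NPM1", c("z", "w"))))
  expect_equal(overlap$unionSize, 4L)
  expect_lt(overlap$unionSize, 5L)   # union smaller than the size sum
  expect_error(consolidateSignatures(list()), "at least one")
})
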