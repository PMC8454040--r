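test_that("dataset recipes satisfy their membership conditions", {
  sim <- smallSim(); db <- smallSimDB(); b <- sim$backend
  real <- buildVirtualDataset(db, b, "REAL", seed = 1)
  expect_equal(nrow(real$X), length(db))
  expect_true(all(real$label == 1))
  expect_identical(real$attachedSubstrate, real$pairSubstrate)

  v1 <- buildVirtualDataset(db, b, "VIRTUAL1", nRecords = 80, seed = 2)
  expect_true(all(v1$label == 0))
  # a real pair, but never its own registered substrate attached
  expect_true(all(v1$attachedSubstrate != v1$pairSubstrate))
  expect_true(all(paste(v1$pairSubstrate, v1$pairProduct) %in%
                    paste(db@substrateId, db@productId)))

  v2 <- buildVirtualDataset(db, b, "VIRTUAL2", nRecords = 80, seed = 3)
  expect_identical(v2$attachedSubstrate, v2$pairSubstrate)
  expect_true(all(v2$pairSubstrate != v2$pairProduct))
  # the example's reaction vector is the random pair's latent difference and
  # its substrate block is the random substrate's latents
  i <- 5
  expect_equal(v2$X[i, ],
               c(computeReactionVector(
                   encodeCompound(b, v2$pairSubstrate[i])$combinedLatent,
                   encodeCompound(b, v2$pairProduct[i])$combinedLatent),
                 encodeCompound(b, v2$pairSubstrate[i])$treeLatent,
                 encodeCompound(b, v2$pairSubstrate[i])$graphLatent))

  v3 <- buildVirtualDataset(db, b, "VIRTUAL3", nRecords = 80, seed = 4)
  expect_true(all(v3$attachedSubstrate != v3$pairSubstrate))
  expect_true(all(v3$attachedSubstrate != v3$pairProduct))
  # reproducibility per seed
  expect_identical(v3$X,
                   buildVirtualDataset(db, b, "VIRTUAL3", nRecords = 80,
                                       seed = 4)$X)
  expect_error(buildVirtualDataset(db, b, "VIRTUAL1", nRecords = 10,
                                   seed = 1, compounds = compoundIds(b)[1:2]),
               "parameter-error")
})

test_that("ensemble bookkeeping: Q datasets x R folds models, stratified folds", {
  sim <- smallSim(); db <- smallSimDB(); b <- sim$backend
  real <- buildVirtualDataset(db, b, "REAL", seed = 1)
  virt <- list(buildVirtualDataset(db, b, "VIRTUAL1", nRecords = 40, seed = 2))
  model <- trainEnsemble(real, virt, R = 2, seed = 5, epochs = 3,
                         hidden = c(8L, 4L))
  expect_length(model@models, 2)            # Q=1, R=2
  expect_equal(model@meta$combinedSizes, length(db) + 40)
  # folds are stratified by label and reproducible
  fold <- model@meta$folds[[1]]
  y <- c(real$label, virt[[1]]$label)
  for (r in 1:2)
    expect_gt(min(table(y[fold == r])), 0)
  m2 <- trainEnsemble(real, virt, R = 2, seed = 5, epochs = 3,
                      hidden = c(8L, 4L))
  expect_identical(model@meta$folds, m2@meta$folds)
  expect_equal(model@models[[1]]$layers[[1]]$W, m2@models[[1]]$layers[[1]]$W)
  expect_error(trainEnsemble(real, virt, R = 1), "parameter-error")
  expect_error(trainEnsemble(real, list(), R = 2), "parameter-error")
})

test_that("possibility values are vote fractions in [0,1]", {
  d <- 8L
  # 150 constant voters, 75 voting 1: v_r = 0.5 for any input
  half <- constantEnsemble(75, 75, d)
  X <- matrix(rnorm(5 * d), 5, d)
  expect_equal(predictPossibility(half, X), rep(0.5, 5))
  expect_equal(predictPossibility(constantEnsemble(150, 0, d), X), rep(1, 5))
  expect_equal(predictPossibility(constantEnsemble(0, 150, d), X), rep(0, 5))
  # vote-count identity: v_r * (Q*R) is an integer for a trained ensemble
  sim <- smallSim(); db <- smallSimDB(); b <- sim$backend
  real <- buildVirtualDataset(db, b, "REAL", seed = 1)
  virt <- list(buildVirtualDataset(db, b, "VIRTUAL3", nRecords = 40, seed = 2),
               buildVirtualDataset(db, b, "VIRTUAL2", nRecords = 40, seed = 3))
  model <- trainEnsemble(real, virt, R = 2, seed = 7, epochs = 5,
                         hidden = c(8L, 4L))
  v <- predictPossibility(model, real$X[1:20, ])
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(v * length(model@models), round(v * length(model@models)))
  expect_error(predictPossibility(model, matrix(0, 2, 3)), "dimension-error")
})

test_that("pathway feasibility is the product of segment possibilities", {
  toy <- identityToy(); db <- identityToyDB()
  q <- pathwayQuery(toy, "T00001", "T00004")
  pw <- pruneUnrealistic(reconstructIntermediates(q, db[c(1L, 3L)], toy))
  d <- 2L * combinedDim(toy)
  # all models vote 1: v_p = 1 and s = |e| / 1 = 0 here
  scored <- scorePathway(pw, constantEnsemble(6, 0, d), toy)
  expect_equal(scored@vR, c(1, 1))
  expect_equal(scored@vP, 1)
  expect_equal(scored@score, 0)
  # two-thirds of models vote 1: v_p = (2/3)^segments, monotone in length
  scored2 <- scorePathway(pw, constantEnsemble(4, 2, d), toy)
  expect_equal(scored2@vP, (2 / 3)^2)
  one <- pruneUnrealistic(reconstructIntermediates(
    pathwayQuery(toy, "T00001", "T00003"), db[1L], toy))
  scored1 <- scorePathway(one, constantEnsemble(4, 2, d), toy)
  expect_gt(scored1@vP, scored2@vP)
  expect_lte(scored2@vP, min(scored2@vR))
  # zero feasibility ranks last: the ratio score is infinite
  scored0 <- scorePathway(pw, constantEnsemble(0, 6, d), toy)
  expect_identical(scored0@score, Inf)
  # the product reading of the score is available behind the flag
  scoredProd <- scorePathway(pw, constantEnsemble(4, 2, d), toy,
                             scoreForm = "product")
  expect_equal(scoredProd@score, scoredProd@absError * scoredProd@vP)
})

test_that("with equal residuals the more feasible pathway ranks first", {
  # v_r = (0.9, 0.8, 1.0) gives v_p = 0.72 by direct product
  expect_equal(prod(c(0.9, 0.8, 1.0)), 0.72)
  # ratio score: same |e|, v_p 0.9 vs 0.3 -> the 0.9 pathway wins
  e <- 2.5
  expect_lt(e / 0.9, e / 0.3)
})

test_that("possibility summaries report group means and dispersions", {
  d <- 4L
  model <- constantEnsemble(3, 0, d)
  g <- list(allOnes = matrix(rnorm(10 * d), 10, d))
  s <- summarizePossibilities(model, g)
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 10)
})
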