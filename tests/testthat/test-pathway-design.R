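test_that("pathway-feature vectors are exact endpoint differences", {
  expect_equal(computePathwayVector(c(0, 0), c(1, -1)), c(1, -1))
  z <- rnorm(4)
  expect_equal(computePathwayVector(z, z), rep(0, 4))
  zs <- rnorm(4); zt <- rnorm(4)
  expect_equal(zs + computePathwayVector(zs, zt), zt, tolerance = 1e-14)
  expect_error(computePathwayVector(c(1), c(1, 2)), "dimension-error")
  # the query object carries endpoint ids and the configured part
  toy <- identityToy()
  q <- pathwayQuery(toy, "T00001", "T00004")
  expect_identical(q@startId, "T00001")
  expect_equal(q@p, c(1, 1))   # counts (2,1) - (1,0)
})

test_that("subset sampling is uniform, seeded and bounded", {
  db <- smallSimDB()
  full <- sampleSubset(db, length(db), seed = 5)
  expect_setequal(attr(full, "dbIndex"), seq_len(length(db)))
  expect_identical(attr(sampleSubset(db, 10, seed = 9), "dbIndex"),
                   attr(sampleSubset(db, 10, seed = 9), "dbIndex"))
  expect_error(sampleSubset(db, length(db) + 1), "parameter-error")
  # empirical uniformity: 10,000 draws of M=1 from a 10-feature DB
  small <- db[1:10]
  seeds <- 1:10000
  drawn <- vapply(seeds, function(s)
    attr(sampleSubset(small, 1, seed = s), "dbIndex"), integer(1))
  freq <- tabulate(drawn, 10) / length(drawn)
  expect_true(all(abs(freq - 0.1) <= 0.01))
  expect_gt(stats::chisq.test(tabulate(drawn, 10))$p.value, 1e-4)
})

test_that("fitness is squared error plus an exact over-length penalty", {
  set.seed(2)
  V <- matrix(rnorm(40), 8, 5)
  p <- rnorm(5)
  # empty selection: |p|^2 and no penalty
  ev <- evaluateFitness(rep(0, 8), V, p, K = 3, C = 1000)
  expect_equal(ev$squaredError, sum(p^2))
  expect_equal(ev$lambda, 0)
  # an exact solution within the step budget has fitness 0
  pExact <- colSums(V[c(2, 5), ])
  ev <- evaluateFitness(as.numeric(1:8 %in% c(2, 5)), V, pExact, K = 3, C = 1000)
  expect_equal(ev$fitness, 0, tolerance = 1e-20)
  # K=3, C=1000, four selected: lambda = 1000 * exp(4)^2 = 1000 * e^8
  ev <- evaluateFitness(as.numeric(1:8 %in% 1:4), V, p, K = 3, C = 1000)
  expect_equal(ev$lambda, 1000 * exp(8))
  expect_equal(ev$lambda, 2980957.987, tolerance = 1e-6)
  # alternative penalty reading C * exp(xlen^2)
  ev2 <- evaluateFitness(as.numeric(1:8 %in% 1:4), V, p, K = 3, C = 1000,
                         penaltyForm = "exp-of-square")
  expect_equal(ev2$lambda, 1000 * exp(16))
  expect_error(evaluateFitness(rep(0, 7), V, p, 3, 1000), "dimension-error")
})

test_that("penalty is exactly zero within the step budget, and exact beyond", {
  set.seed(3)
  V <- matrix(rnorm(60), 12, 5); p <- rnorm(5)
  for (len in 1:12) {
    x <- as.numeric(seq_len(12) <= len)
    ev <- evaluateFitness(x, V, p, K = 4, C = 1000)
    if (len <= 4) expect_identical(ev$fitness - ev$squaredError, 0)
    else expect_equal(ev$fitness - ev$squaredError, 1000 * exp(2 * len))
  }
})

test_that("mutant components binarize at the one-half threshold", {
  expect_identical(pathlatent:::binarize05(c(0.49, 0.5, 0.51, -1, 1.2)),
                   c(0, 1, 1, 0, 1))
})

test_that("DE finds a uniquely optimal single feature and never lies about fitness", {
  # one subset feature equals p exactly; enumeration over all selections of
  # size <= K confirms it is the unique optimum
  set.seed(11)
  V <- matrix(rnorm(8 * 6, sd = 2), 8, 6)
  p <- V[3, ]
  oracle <- enumerationOracle(V, p, K = 3, C = 1000)
  expect_identical(oracle$selected, 3L)
  expect_equal(oracle$fitness, 0, tolerance = 1e-18)
  sub <- methods::new("ReactionFeatureDB",
                      ec = sprintf("1.1.1.%d", 1:8),
                      substrateId = sprintf("s%d", 1:8),
                      productId = sprintf("p%d", 1:8),
                      vectors = V, deltaMW = rep(1, 8), part = "tree",
                      treeDim = 6L, graphDim = 6L, skipped = 0L)
  cfg <- deConfig(population = 50, maxGenerations = 50, subsetSize = 8,
                  K = 3, Th = 1e-9, repetitions = 1, seed = 21)
  res <- binaryDESelect(sub, p, cfg)
  expect_identical(res$selected, 3L)
  expect_equal(res$squaredError, 0, tolerance = 1e-18)
  # greedy replacement: the best-fitness trace never increases
  expect_true(all(diff(res$trace) <= 0))
  expect_error(binaryDESelect(sub, p, deConfig(population = 3)),
               "parameter-error")
})

test_that("DE matches the enumeration oracle on random instances", {
  # scaled version of the full oracle-equivalence suite (20 instances in the
  # acceptance checks): DE must never report a fitness below the true
  # optimum, and usually attains it
  hits <- 0L
  for (inst in 1:6) {
    set.seed(300 + inst)
    M <- sample(8:12, 1); d <- 5; K <- sample(2:3, 1)
    V <- matrix(rnorm(M * d), M, d)
    p <- colSums(V[sample(M, K), , drop = FALSE]) + rnorm(d, sd = 0.05)
    oracle <- enumerationOracle(V, p, K = K, C = 1000)
    sub <- methods::new("ReactionFeatureDB",
                        ec = sprintf("1.1.1.%d", 1:M),
                        substrateId = sprintf("s%d", 1:M),
                        productId = sprintf("p%d", 1:M),
                        vectors = V, deltaMW = rep(1, M), part = "tree",
                        treeDim = as.integer(d), graphDim = as.integer(d),
                        skipped = 0L)
    cfg <- deConfig(population = 60, maxGenerations = 50, subsetSize = M,
                    K = K, Th = 1e-9, seed = 400 + inst, earlyStop = FALSE)
    res <- binaryDESelect(sub, p, cfg)
    expect_gte(res$fitness, oracle$fitness - 1e-9)
    if (abs(res$fitness - oracle$fitness) <= 1e-9 * (1 + oracle$fitness))
      hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("orderings enumerate all permutations deterministically", {
  expect_equal(nrow(enumerateOrderings(c(4L, 7L, 9L))), 6)
  expect_equal(nrow(enumerateOrderings(5L)), 1)
  expect_equal(nrow(enumerateOrderings(1:4)), 24)
  # lexicographic by position in the selection
  o <- enumerateOrderings(c(10L, 20L, 30L))
  expect_identical(o[1, ], c(10L, 20L, 30L))
  expect_identical(o[6, ], c(30L, 20L, 10L))
  expect_equal(nrow(unique(o)), 6)
  expect_error(enumerateOrderings(integer()), "parameter-error")
})

test_that("intermediates are cumulative latent sums decoded in the toy universe", {
  toy <- identityToy()
  db <- identityToyDB()
  # pathway T00001 -> T00004 via reactions 1 then 3:
  # (1,0) +(0,1)-> (1,1) +(1,0)-> (2,1); all nodes exist in the universe
  q <- pathwayQuery(toy, "T00001", "T00004")
  ord <- db[c(1L, 3L)]
  pw <- reconstructIntermediates(q, ord, toy)
  expect_length(pw@intermediateLatents, 1)
  expect_equal(pw@intermediateLatents[[1]], c(1, 1))
  expect_identical(pw@nodeIds, c("T00001", "T00003", "T00004"))
  expect_equal(pw@absError, 0)
  # hand-computed segment MW changes (masses 10 and 14)
  expect_equal(pw@segmentDeltaMW, c(14, 10))
  expect_equal(pw@registeredDeltaMW, c(14, 10))
})

test_that("molecular-weight pruning removes deviant segments and keeps exact ones", {
  toy <- identityToy()
  db <- identityToyDB()
  q <- pathwayQuery(toy, "T00001", "T00004")
  pw <- reconstructIntermediates(q, db[c(1L, 3L)], toy)
  # exact toy arithmetic: zero deviation, kept
  kept <- pruneUnrealistic(pw)
  expect_true(kept@keep)
  # a segment whose decoded change deviates from the registered change by
  # more than the tolerance is removed (84 vs 80 with tolerance 3)
  bad <- pw
  bad@segmentDeltaMW <- c(84, 10)
  bad@registeredDeltaMW <- c(80, 10)
  rem <- pruneUnrealistic(bad)
  expect_false(rem@keep)
  expect_match(rem@removalReason, "mw-mismatch")
  # deviation exactly at the tolerance is kept
  expect_true(pruneUnrealistic(local({p <- pw
    p@segmentDeltaMW <- c(83, 10); p@registeredDeltaMW <- c(80, 10); p}))@keep)
  # undecodable segment endpoints force removal
  nod <- pw; nod@nodeIds[2] <- NA_character_
  remNod <- pruneUnrealistic(nod)
  expect_false(remNod@keep)
  expect_identical(remNod@removalReason, "decode-failure")
})

test_that("the design loop recovers a planted pathway and deduplicates", {
  sim <- smallSim()
  db <- smallSimDB()
  m <- sim$manifest[[1]]  # planted 1-step query
  q <- pathwayQuery(sim$backend, m$startId, m$targetId)
  cfg <- deConfig(population = 30, maxGenerations = 25,
                  subsetSize = length(db), K = 2, Th = 1e-6,
                  repetitions = 4, seed = 17)
  cands <- designCandidates(q, db, cfg, sim$backend)
  expect_gte(length(cands), 1)
  ecs <- vapply(cands, function(p) paste(p@ec, collapse = ">"), character(1))
  expect_true(paste(m$ec, collapse = ">") %in% ecs)
  # every kept candidate satisfies the threshold and passed pruning
  for (p in cands) {
    expect_lte(p@absError, cfg$Th)
    expect_true(p@keep)
  }
  # with the whole DB as subset each repetition finds the same solution:
  # duplicates collapse instead of accumulating
  expect_lte(length(cands), 3)
  log <- attr(cands, "log")
  expect_equal(nrow(log), 4)
})

test_that("an unattainable exactness threshold yields an empty candidate list", {
  toy <- identityToy(); db <- identityToyDB()
  # p = (-1, 2) but the registered features are (0,1), (1,0), (1,0): no
  # selection of <= 2 of them sums to p, so Th = 0 admits nothing
  q <- pathwayQuery(toy, "T00001", "T00006")
  cfg <- deConfig(population = 20, maxGenerations = 10, subsetSize = 3,
                  K = 2, Th = 0, repetitions = 3, seed = 23)
  cands <- designCandidates(q, db, cfg, toy)
  expect_length(cands, 0)
})

test_that("subset inclusion probability of a planted set grows with subset size", {
  # hypergeometric argument: drawing M of N features without replacement,
  # P(all k planted features included) = C(N-k, M-k) / C(N, M)
  N <- 400; k <- 2
  pIncl <- function(M) choose(N - k, M - k) / choose(N, M)
  Ms <- seq(50, 400, by = 50)
  expect_true(all(diff(pIncl(Ms)) > 0))
  # agrees with the product form M/N * (M-1)/(N-1)
  expect_equal(pIncl(100), (100 / 400) * (99 / 399))
})
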