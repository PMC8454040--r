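# Shared fixtures, built in code. Heavy objects are memoised for the run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# A hand-specified toy backend (known counts / masses / mixing) for exact
# arithmetic checks.
manualToy <- function(counts, masses, mixing, graphMixing = mixing,
                      ids = sprintf("T%05d", seq_len(nrow(counts)))) {
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts))
  rownames(counts) <- ids
  methods::new("ToyChemistry", name = "toy",
               fragmentMasses = masses, mixingMatrix = mixing,
               graphMixing = graphMixing, counts = counts,
               seed = 0L)
}

# Two-fragment universe under the identity embedding: latents are the counts
# themselves, so every expectation can be computed by hand.
identityToy <- function() {
  manualToy(rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(2L, 1L), c(2L, 0L),
                  c(0L, 2L)),
            masses = c(10, 14), mixing = diag(2))
}

# A reaction-feature DB over the identity toy: each reaction adds fragments.
identityToyDB <- function() {
  toy <- identityToy()
  records <- data.frame(
    ec_number    = c("1.1.1.1", "2.7.1.1", "2.7.1.2"),
    substrate_id = c("T00001", "T00002", "T00003"),
    product_id   = c("T00003", "T00003", "T00004"),
    stringsAsFactors = FALSE)
  buildReactionDB(records, toy, part = "tree")
}

# Small simulated scenario shared by several test files.
smallSim <- function() memo("smallSim", function()
  simulateUniverse(nCompounds = 60L, nReactions = 90L, nEcClasses = 4L,
                   nFragments = 6L, latentDim = 6L, seed = 401L))

smallSimDB <- function() memo("smallSimDB", function()
  buildReactionDB(smallSim()$records, smallSim()$backend, part = "tree"))

# Exhaustive oracle for reaction selection: enumerate every selection of at
# most K features (larger selections cannot win: the penalty exceeds any
# unpenalized squared error by construction) and return the minimal fitness.
enumerationOracle <- function(vectors, p, K, C, penaltyForm = "square-of-exp") {
  M <- nrow(vectors)
  best <- list(fitness = Inf, selected = integer())
  for (k in 0:K) {
    sels <- if (k == 0L) list(integer()) else
      asplit(utils::combn(M, k), 2L)
    for (sel in sels) {
      ev <- evaluateFitness(as.numeric(seq_len(M) %in% sel), vectors, p, K, C,
                            penaltyForm)
      if (ev$fitness < best$fitness)
        best <- list(fitness = ev$fitness, selected = as.integer(sel))
    }
  }
  best
}

# An ensemble of constant voters: `nOnes` models always vote 1, the rest
# always vote 0, regardless of input. Exercises the voting arithmetic
# without training.
constantEnsemble <- function(nOnes, nZeros, inputDim, Q = 1L,
                             R = nOnes + nZeros) {
  oneModel <- function(vote) {
    list(layers = list(list(W = matrix(0, inputDim, 1L),
                            b = if (vote) 10 else -10)),
         center = rep(0, inputDim), scale = rep(1, inputDim))
  }
  models <- c(replicate(nOnes, oneModel(TRUE), simplify = FALSE),
              replicate(nZeros, oneModel(FALSE), simplify = FALSE))
  methods::new("EnsembleModel", models = models, Q = as.integer(Q),
               R = as.integer(R), reactionDim = as.integer(inputDim / 2),
               treeDim = NA_integer_, graphDim = NA_integer_,
               hidden = 0L, meta = list())
}
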