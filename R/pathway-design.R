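#' Differential-evolution configuration for reaction selection
#'
#' Collects the tunable parameters of the pathway-design stage. The defaults
#' are the full-scale operating point of the method: scaling factor
#' `F = 0.5`, crossover rate `CR = 0.5`, penalty constant `C = 1000`, error
#' threshold `Th = 50`, population `2000`, at most `50` generations,
#' repetitions `2000`, molecular-weight tolerance `3`. Desk-scale analyses
#' override the sizes downward.
#'
#' @param FScale DE scaling factor applied to the parent difference.
#' @param CR crossover rate in [0,1].
#' @param population population size P (>= 4: three distinct parents plus
#'   the current individual).
#' @param maxGenerations generation budget per DE run.
#' @param subsetSize M, number of reaction features drawn from the DB per
#'   repetition.
#' @param K maximum number of reaction steps in a pathway.
#' @param Th error threshold on the residual `|e|` (latent units); candidates
#'   with `|e| > Th` are discarded and DE may stop early once the best
#'   individual satisfies it. `Th = 0` demands an exact solution.
#' @param C penalty constant for selections longer than `K`.
#' @param repetitions number of subset-draw/DE repetitions.
#' @param seed master seed; per-repetition streams are derived from it.
#' @param mwTolerance allowed deviation (u) between a segment's decoded
#'   molecular-weight change and the registered change of its reaction.
#' @param earlyStop stop a DE run as soon as the best `|e| <= Th`.
#' @param guaranteedMutant force one component of each trial vector to come
#'   from the mutant (classic binomial crossover); `FALSE` gives the plain
#'   printed loop.
#' @param penaltyForm how the over-length penalty grows: `"square-of-exp"`
#'   (default) is `C * exp(xlen)^2 = C * e^(2 xlen)`; `"exp-of-square"` is
#'   `C * exp(xlen^2)`.
#' @return a validated list of class `"DEConfig"`.
#' @export
deConfig <- function(FScale = 0.5, CR = 0.5, population = 2000L,
                     maxGenerations = 50L, subsetSize = 500L, K = 3L,
                     Th = 50, C = 1000, repetitions = 2000L, seed = 1L,
                     mwTolerance = 3, earlyStop = TRUE,
                     guaranteedMutant = TRUE,
                     penaltyForm = c("square-of-exp", "exp-of-square")) {
  cfg <- list(FScale = FScale, CR = CR, population = as.integer(population),
              maxGenerations = as.integer(maxGenerations),
              subsetSize = as.integer(subsetSize), K = as.integer(K),
              Th = Th, C = C, repetitions = as.integer(repetitions),
              seed = as.integer(seed), mwTolerance = mwTolerance,
              earlyStop = isTRUE(earlyStop),
              guaranteedMutant = isTRUE(guaranteedMutant),
              penaltyForm = match.arg(penaltyForm))
  if (cfg$population < 4L) stopParam("population must be >= 4")
  if (cfg$CR < 0 || cfg$CR > 1) stopParam("CR must be in [0,1]")
  if (cfg$subsetSize < 1L || cfg$K < 1L || cfg$Th < 0)
    stopParam("subsetSize and K must be >= 1 and Th >= 0")
  if (cfg$repetitions < 1L) stopParam("repetitions must be >= 1")
  class(cfg) <- "DEConfig"
  cfg
}

#' Pathway-feature vector of a desired transformation
#'
#' The pathway-feature vector is the latent difference between the target
#' and start compounds, `p = z_target - z_start`; a pathway whose selected
#' reaction vectors sum to `p` transforms start into target in latent space.
#'
#' @param backend an [EmbeddingBackend-class].
#' @param startId,targetId compound ids.
#' @param part latent part (default `"tree"`, the part used for design).
#' @return a [PathwayQuery-class].
#' @export
pathwayQuery <- function(backend, startId, targetId,
                         part = c("tree", "graph", "combined")) {
  part <- match.arg(part)
  pick <- function(enc) switch(part, tree = enc$treeLatent,
                               graph = enc$graphLatent,
                               combined = enc$combinedLatent)
  s <- encodeCompound(backend, startId)
  t <- encodeCompound(backend, targetId)
  methods::new("PathwayQuery", startId = s$compoundId, targetId = t$compoundId,
               p = computePathwayVector(pick(s), pick(t)), part = part)
}

#' @rdname pathwayQuery
#' @param zStart,zTarget numeric latent vectors of equal dimension.
#' @return `computePathwayVector` returns the bare numeric difference.
#' @export
computePathwayVector <- function(zStart, zTarget) {
  if (length(zStart) != length(zTarget))
    stopDim("start and target latents differ in dimension")
  zTarget - zStart
}

setMethod("show", "PathwayQuery", function(object) {
  cat("PathwayQuery ", object@startId, " -> ", object@targetId,
      " (", object@part, " part, |p| = ",
      format(sqrt(sum(object@p^2)), digits = 4), ")\n", sep = "")
})

#' Draw a random reaction subset from the DB
#'
#' Uniform sample of `M` features without replacement; working on a subset
#' rather than the whole DB bounds the DE search space and improves search
#' efficiency.
#'
#' @param db a [ReactionFeatureDB-class].
#' @param M subset size (<= `length(db)`).
#' @param seed integer seed.
#' @return a [ReactionFeatureDB-class] of the sampled rows, with attribute
#'   `"dbIndex"` giving their row indices in `db`.
#' @export
sampleSubset <- function(db, M, seed = NULL) {
  if (M > length(db)) stopParam("M exceeds the DB size")
  if (M < 1L) stopParam("M must be >= 1")
  idx <- withSeed(seed, sample.int(length(db), M))
  out <- db[idx]
  attr(out, "dbIndex") <- idx
  out
}

# Over-length penalty: 0 when xlen <= K, otherwise grows super-exponentially.
penaltyLambda <- function(xlen, K, C, penaltyForm = "square-of-exp") {
  if (xlen <= K) return(0)
  if (penaltyForm == "square-of-exp") C * exp(xlen)^2 else C * exp(xlen^2)
}

#' Fitness of a binary reaction selection
#'
#' The DE objective: the squared residual between the pathway-feature vector
#' and the sum of the selected reaction vectors, plus a penalty that is
#' exactly zero while the number of selected reactions is within the step
#' budget `K` and grows super-exponentially beyond it.
#'
#' @param x binary 0/1 vector over the subset.
#' @param vectors numeric matrix, subset rows x latent dimension.
#' @param p pathway-feature vector.
#' @param K maximum number of reaction steps.
#' @param C penalty constant.
#' @param penaltyForm see [deConfig()].
#' @return list with `squaredError`, `lambda`, `fitness` (their sum) and
#'   `xlen`.
#' @export
evaluateFitness <- function(x, vectors, p, K, C, penaltyForm = "square-of-exp") {
  if (length(x) != nrow(vectors))
    stopDim("selection vector length does not match the subset")
  if (ncol(vectors) != length(p))
    stopDim("reaction vectors and p differ in dimension")
  xlen <- sum(x != 0)
  resid <- p - as.numeric(crossprod(vectors, x))
  se <- sum(resid^2)
  lam <- penaltyLambda(xlen, K, C, penaltyForm)
  list(squaredError = se, lambda = lam, fitness = se + lam, xlen = xlen)
}

#' Binary differential evolution over a reaction subset
#'
#' Selects the subset of reaction-feature vectors whose sum best matches the
#' pathway-feature vector. Individuals are binary inclusion vectors of length
#' `M`; each is initialized with a uniformly drawn number of selected
#' reactions between 1 and `K`. Per generation and individual, three
#' mutually distinct parents (all different from the current individual) form
#' the mutant `v = x_a + F (x_b - x_c)`, each component is binarized at the
#' 0.5 threshold, uniform crossover with rate `CR` builds the trial vector,
#' and the trial replaces the current individual only when its fitness is
#' strictly lower. The run stops early once the best residual satisfies
#' `|e| <= Th` (if `cfg$earlyStop`).
#'
#' @param subset a [ReactionFeatureDB-class] of M candidate reactions
#'   (e.g. from [sampleSubset()]).
#' @param p pathway-feature vector.
#' @param cfg a [deConfig()] list.
#' @param seed optional seed overriding `cfg$seed` for this run.
#' @return list with the best individual `x`, `selected` (its indices into
#'   the subset), `squaredError`, `absError`, `fitness`, `generations`, and
#'   `trace` (best fitness per generation, non-increasing).
#' @export
binaryDESelect <- function(subset, p, cfg, seed = cfg$seed) {
  M <- length(subset)
  if (M < 1L) stopParam("subset is empty")
  V <- subset@vectors
  if (ncol(V) != length(p)) stopDim("subset vectors and p differ in dimension")
  P <- cfg$population
  fit <- function(x) evaluateFitness(x, V, p, cfg$K, cfg$C, cfg$penaltyForm)$fitness
  withSeed(seed, {
    pop <- matrix(0, P, M)
    for (i in seq_len(P)) {
      k <- sample.int(cfg$K, 1L)
      pop[i, sample.int(M, min(k, M))] <- 1
    }
    fits <- apply(pop, 1L, fit)
    trace <- numeric(0)
    gens <- 0L
    for (g in seq_len(cfg$maxGenerations)) {
      gens <- g
      for (i in seq_len(P)) {
        abc <- sample(setdiff(seq_len(P), i), 3L)
        v <- binarize05(pop[abc[1L], ] + cfg$FScale * (pop[abc[2L], ] - pop[abc[3L], ]))
        u <- pop[i, ]
        take <- stats::runif(M) < cfg$CR
        if (cfg$guaranteedMutant) take[sample.int(M, 1L)] <- TRUE
        u[take] <- v[take]
        fu <- fit(u)
        if (fu < fits[i]) { pop[i, ] <- u; fits[i] <- fu }
      }
      trace <- c(trace, min(fits))
      best <- which.min(fits)
      bestEval <- evaluateFitness(pop[best, ], V, p, cfg$K, cfg$C, cfg$penaltyForm)
      if (cfg$earlyStop && sqrt(bestEval$squaredError) <= cfg$Th &&
          bestEval$xlen <= cfg$K) break
    }
    best <- which.min(fits)
    ev <- evaluateFitness(pop[best, ], V, p, cfg$K, cfg$C, cfg$penaltyForm)
    list(x = pop[best, ], selected = which(pop[best, ] == 1),
         squaredError = ev$squaredError, absError = sqrt(ev$squaredError),
         fitness = ev$fitness, generations = gens, trace = trace)
  })
}

#' All orderings of a selected reaction set
#'
#' A set of `n` selected reactions yields `n!` ordered candidate pathways
#' (three reactions give six orders). Rows are permutations of the selection
#' indices in lexicographic order.
#'
#' @param selected integer vector of selected indices (length >= 1).
#' @return integer matrix, `n!` rows.
#' @export
enumerateOrderings <- function(selected) {
  n <- length(selected)
  if (n < 1L) stopParam("empty selection has no orderings")
  perms <- permutationsOf(n)
  matrix(selected[perms], nrow(perms), n)
}

#' Reconstruct the intermediates of one ordered candidate pathway
#'
#' Sequentially adds the ordered reaction vectors to the start compound's
#' latent; each cumulative sum is the latent of an intermediate compound and
#' is decoded by the backend. Decode failures are recorded (as `NA` node
#' ids), not raised.
#'
#' @param query a [PathwayQuery-class].
#' @param ordering a [ReactionFeatureDB-class] holding the ordered segment
#'   reactions (e.g. `subset[ordering.indices]`), with optional attribute
#'   `"dbIndex"`.
#' @param backend a decoding-capable [EmbeddingBackend-class].
#' @return a [CandidatePathway-class] with reconstruction state filled and
#'   scoring state empty.
#' @export
reconstructIntermediates <- function(query, ordering, backend) {
  if (!canDecode(backend))
    stop("capability-error: backend cannot decode", call. = FALSE)
  V <- ordering@vectors
  if (ncol(V) != length(query@p)) stopDim("ordering vectors do not match query")
  n <- nrow(V)
  z0 <- local({
    enc <- encodeCompound(backend, query@startId)
    switch(query@part, tree = enc$treeLatent, graph = enc$graphLatent,
           combined = enc$combinedLatent)
  })
  cum <- apply(V, 2L, cumsum)
  if (n == 1L) cum <- matrix(cum, 1L)
  latents <- lapply(seq_len(n), function(k) z0 + cum[k, ])
  nodes <- c(query@startId,
             vapply(latents, function(z)
               tryCatch(decodeLatent(backend, z, query@part),
                        error = function(e) NA_character_), character(1)))
  dmw <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    a <- nodes[k]; b <- nodes[k + 1L]
    if (!is.na(a) && !is.na(b))
      dmw[k] <- molecularWeight(backend, b) - molecularWeight(backend, a)
  }
  resid <- query@p - as.numeric(colSums(V))
  dbIdx <- attr(ordering, "dbIndex")
  methods::new("CandidatePathway",
               startId = query@startId, targetId = query@targetId,
               ec = ordering@ec, substrateId = ordering@substrateId,
               productId = ordering@productId,
               dbIndex = if (is.null(dbIdx)) seq_len(n) else as.integer(dbIdx),
               intermediateLatents = latents[seq_len(max(0L, n - 1L))],
               nodeIds = nodes,
               segmentDeltaMW = dmw,
               registeredDeltaMW = ordering@deltaMW,
               absError = sqrt(sum(resid^2)),
               vR = numeric(0), vP = NA_real_, score = NA_real_,
               keep = NA, removalReason = NA_character_)
}

#' Molecular-weight pruning of unrealistic pathways
#'
#' For each segment, the molecular-weight change between the decoded
#' substrate and decoded product is compared with the registered change of
#' the segment's reaction; the pathway is removed when any segment deviates
#' by more than `tolerance` mass units, or when a segment endpoint could not
#' be decoded (the rule cannot then be evaluated).
#'
#' @param pathway a [CandidatePathway-class] from [reconstructIntermediates()].
#' @param tolerance allowed deviation in u (default 3).
#' @return the pathway with `keep` and `removalReason` filled; per-segment
#'   deviations are in `segmentDeltaMW` minus `registeredDeltaMW`.
#' @export
pruneUnrealistic <- function(pathway, tolerance = 3) {
  if (anyNA(pathway@nodeIds)) {
    pathway@keep <- FALSE
    pathway@removalReason <- "decode-failure"
    return(pathway)
  }
  dev <- abs(pathway@segmentDeltaMW - pathway@registeredDeltaMW)
  if (any(dev > tolerance)) {
    pathway@keep <- FALSE
    pathway@removalReason <- sprintf("mw-mismatch: segment %d deviates by %.3f",
                                     which.max(dev), max(dev))
  } else {
    pathway@keep <- TRUE
    pathway@removalReason <- NA_character_
  }
  pathway
}

setMethod("show", "CandidatePathway", function(object) {
  cat("CandidatePathway ", object@startId, " -> ", object@targetId, "\n",
      "  EC sequence: ", paste(object@ec, collapse = " -> "), "\n",
      "  |e| = ", format(object@absError, digits = 4), sep = "")
  if (!is.na(object@vP))
    cat("  v_p = ", format(object@vP, digits = 4),
        "  s = ", format(object@score, digits = 4), sep = "")
  if (!is.na(object@keep) && !object@keep)
    cat("  [removed: ", object@removalReason, "]", sep = "")
  cat("\n")
})

pathwayKey <- function(pw)
  paste(paste(pw@ec, collapse = ">"),
        paste(pw@substrateId, collapse = ">"),
        paste(pw@productId, collapse = ">"), sep = "|")

#' Design candidate pathways for a query
#'
#' Repeats the full design loop `cfg$repetitions` times with derived seeds:
#' draw a random subset of `cfg$subsetSize` reactions, run binary DE to
#' select a reaction set, enumerate every ordering of the set, reconstruct
#' and decode the intermediates of each ordering, and prune orderings whose
#' decoded molecular-weight changes contradict the registered ones.
#' Candidates are kept only when `|e| <= Th`, and duplicates (same ordered
#' EC and substrate/product sequences) found in different repetitions are
#' collapsed.
#'
#' @param query a [PathwayQuery-class].
#' @param db a [ReactionFeatureDB-class] in the query's part.
#' @param cfg a [deConfig()] list.
#' @param backend a decoding-capable [EmbeddingBackend-class].
#' @return list of kept [CandidatePathway-class] objects (possibly empty),
#'   with attribute `"log"`: a data.frame of per-repetition best fitness,
#'   generations and counts of orderings kept/pruned.
#' @export
designCandidates <- function(query, db, cfg, backend) {
  seeds <- deriveSeeds(cfg$seed, 2L * cfg$repetitions)
  kept <- list()
  log <- vector("list", cfg$repetitions)
  for (rep in seq_len(cfg$repetitions)) {
    subset <- sampleSubset(db, min(cfg$subsetSize, length(db)), seeds[rep])
    sel <- binaryDESelect(subset, query@p, cfg, seed = seeds[cfg$repetitions + rep])
    nKept <- 0L; nPruned <- 0L
    if (length(sel$selected) >= 1L && sel$absError <= cfg$Th &&
        length(sel$selected) <= cfg$K) {
      ords <- enumerateOrderings(sel$selected)
      dbIdx <- attr(subset, "dbIndex")
      for (r in seq_len(nrow(ords))) {
        ordFeat <- subset[ords[r, ]]
        attr(ordFeat, "dbIndex") <- dbIdx[ords[r, ]]
        pw <- reconstructIntermediates(query, ordFeat, backend)
        pw <- pruneUnrealistic(pw, cfg$mwTolerance)
        if (pw@keep) {
          key <- pathwayKey(pw)
          if (is.null(kept[[key]])) kept[[key]] <- pw
          nKept <- nKept + 1L
        } else nPruned <- nPruned + 1L
      }
    }
    log[[rep]] <- data.frame(repetition = rep, bestFitness = sel$fitness,
                             absError = sel$absError,
                             generations = sel$generations,
                             orderingsKept = nKept, orderingsPruned = nPruned)
  }
  out <- unname(kept)
  attr(out, "log") <- do.call(rbind, log)
  out
}
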