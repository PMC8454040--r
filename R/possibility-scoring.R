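# Ensemble input layout: [combined reaction vector | substrate tree latent |
# substrate graph latent].
scoringInput <- function(backend, subId, prodId, substrateOfInput = subId) {
  s <- encodeCompound(backend, subId)
  p <- encodeCompound(backend, prodId)
  att <- if (identical(substrateOfInput, subId)) s
         else encodeCompound(backend, substrateOfInput)
  c(computeReactionVector(s$combinedLatent, p$combinedLatent),
    att$treeLatent, att$graphLatent)
}

#' Build a training dataset of reaction examples by recipe
#'
#' Four recipes probe the two ingredients of a plausible enzymatic reaction:
#' whether the substrate/product pair is registered, and whether the attached
#' substrate is the one that formed the pair.
#' \describe{
#'   \item{REAL}{registered pair with its own substrate (label 1).}
#'   \item{VIRTUAL1}{registered pair with a substrate \emph{not} used to form
#'     that pair (label 0).}
#'   \item{VIRTUAL2}{randomly drawn substrate/product pair (not necessarily
#'     registered) with the random pair's own substrate (label 0).}
#'   \item{VIRTUAL3}{randomly drawn pair with a third, unrelated substrate
#'     (label 0).}
#' }
#' Each example's input is the combined-part reaction vector of the pair
#' concatenated with the attached substrate's tree and graph latents.
#'
#' @param db a [ReactionFeatureDB-class] of registered reactions.
#' @param backend the [EmbeddingBackend-class] that encodes the compounds.
#' @param recipe one of `"REAL"`, `"VIRTUAL1"`, `"VIRTUAL2"`, `"VIRTUAL3"`.
#' @param nRecords number of examples; `REAL` defaults to one per DB record.
#' @param seed integer seed.
#' @param compounds compound ids to draw random substrates/pairs from
#'   (default: the backend's whole universe).
#' @return list with `X` (example matrix), `label` (0/1), `recipe`, and
#'   per-example annotation `pairSubstrate`, `pairProduct`,
#'   `attachedSubstrate`, `ec`.
#' @export
buildVirtualDataset <- function(db, backend,
                                recipe = c("REAL", "VIRTUAL1", "VIRTUAL2", "VIRTUAL3"),
                                nRecords = NULL, seed = 1L,
                                compounds = compoundIds(backend)) {
  recipe <- match.arg(recipe)
  if (length(db) < 1L) stopParam("empty reaction DB")
  if (recipe != "REAL" && length(compounds) < 3L)
    stopParam("virtual recipes need at least 3 compounds")
  if (is.null(nRecords))
    nRecords <- if (recipe == "REAL") length(db) else stopParam("nRecords required")
  withSeed(seed, {
    pairSub <- character(nRecords); pairProd <- character(nRecords)
    attached <- character(nRecords); ec <- rep(NA_character_, nRecords)
    if (recipe %in% c("REAL", "VIRTUAL1")) {
      ri <- if (recipe == "REAL" && nRecords == length(db)) seq_len(length(db))
            else sample.int(length(db), nRecords, replace = TRUE)
      pairSub <- db@substrateId[ri]; pairProd <- db@productId[ri]
      ec <- db@ec[ri]
      attached <- if (recipe == "REAL") pairSub else
        vapply(pairSub, function(s) sample(setdiff(compounds, s), 1L), character(1))
    } else {
      for (i in seq_len(nRecords)) {
        pr <- sample(compounds, 2L)           # substrate != product
        pairSub[i] <- pr[1L]; pairProd[i] <- pr[2L]
        attached[i] <- if (recipe == "VIRTUAL2") pr[1L]
                       else sample(setdiff(compounds, pr), 1L)
      }
    }
    X <- t(vapply(seq_len(nRecords), function(i)
      scoringInput(backend, pairSub[i], pairProd[i], attached[i]),
      numeric(2L * combinedDim(backend))))
    list(X = X, label = rep(as.numeric(recipe == "REAL"), nRecords),
         recipe = recipe, pairSubstrate = pairSub, pairProduct = pairProd,
         attachedSubstrate = attached, ec = ec)
  })
}

#' Train the Q x R voting ensemble
#'
#' Each of the Q combined datasets is the real examples plus one virtual
#' dataset; R-fold stratified cross-validation over a combined dataset trains
#' R networks (each on R-1 folds), for Q x R models in total.
#'
#' @param realExamples output of [buildVirtualDataset()] with recipe `REAL`.
#' @param virtualDatasets list of Q outputs of [buildVirtualDataset()] with
#'   virtual recipes.
#' @param R number of cross-validation folds (>= 2).
#' @param seed integer seed controlling folds and weight initialization.
#' @param hidden hidden-layer widths of each network.
#' @param epochs,batchSize,lr training hyperparameters (configuration, not
#'   part of the method's claims).
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(realExamples, virtualDatasets, R = 5L, seed = 1L,
                          hidden = c(64L, 32L, 8L), epochs = 100L,
                          batchSize = 128L, lr = 1e-3) {
  Q <- length(virtualDatasets)
  if (Q < 1L) stopParam("need at least one virtual dataset")
  if (R < 2L) stopParam("R must be >= 2")
  d <- ncol(realExamples$X)
  seeds <- deriveSeeds(seed, Q * (R + 1L))
  models <- vector("list", Q * R)
  folds <- vector("list", Q)
  sizes <- integer(Q)
  for (q in seq_len(Q)) {
    if (ncol(virtualDatasets[[q]]$X) != d)
      stopDim("virtual dataset dimension differs from real examples")
    X <- rbind(realExamples$X, virtualDatasets[[q]]$X)
    y <- c(realExamples$label, virtualDatasets[[q]]$label)
    sizes[q] <- length(y)
    fold <- stratifiedFolds(y, R, seeds[q])
    folds[[q]] <- fold
    for (r in seq_len(R)) {
      tr <- fold != r
      if (length(unique(y[tr])) < 2L)
        stop("fold-error: training split is single-class; re-stratify",
             call. = FALSE)
      yTr <- y[tr]
      models[[(q - 1L) * R + r]] <-
        mlpTrain(X[tr, , drop = FALSE], yTr, hidden = hidden,
                 epochs = epochs, batchSize = batchSize, lr = lr,
                 posWeight = max(1, sum(yTr == 0) / sum(yTr == 1)),
                 seed = seeds[Q + (q - 1L) * R + r])
    }
  }
  # input layout is [combined reaction vector | substrate tree | graph], so
  # the combined reaction dimension is half the input width
  methods::new("EnsembleModel", models = models, Q = as.integer(Q),
               R = as.integer(R),
               reactionDim = as.integer(d / 2L),
               treeDim = as.integer(NA), graphDim = as.integer(NA),
               hidden = as.integer(hidden),
               meta = list(seed = seed, folds = folds,
                           combinedSizes = sizes,
                           virtualRecipes = vapply(virtualDatasets,
                                                   `[[`, character(1), "recipe")))
}

stratifiedFolds <- function(y, R, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(R), length(idx))
    }
  })
  fold
}

#' Voting reaction-possibility value
#'
#' Every model in the ensemble outputs a hard 0 or 1 (its sigmoid output
#' thresholded at 0.5); the reaction-possibility value is the fraction of
#' models voting 1, so it always lies in [0,1] and `vR * (Q*R)` is an
#' integer.
#'
#' @param model an [EnsembleModel-class].
#' @param X example matrix (rows are `[reaction vector | substrate tree |
#'   substrate graph]` inputs), or a single numeric example.
#' @return numeric vector of possibility values, one per row.
#' @export
predictPossibility <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1L)
  din <- nrow(model@models[[1L]]$layers[[1L]]$W)
  if (ncol(X) != din)
    stopDim(sprintf("examples have %d columns but models expect %d",
                    ncol(X), din))
  votes <- matrix(0, nrow(X), length(model@models))
  for (m in seq_along(model@models))
    votes[, m] <- as.numeric(mlpPredict(model@models[[m]], X) >= 0.5)
  rowMeans(votes)
}

#' Score a candidate pathway with the ensemble
#'
#' For each segment, the registered reaction's combined-part vector and the
#' decoded segment substrate's latents are fed to the ensemble, giving a
#' per-segment reaction-possibility value `vR`. The pathway feasibility `vP`
#' is the product of the `vR`, and the pathway score is
#' `s = |e| / vP` (lower is better); with `scoreForm = "product"` the
#' alternative reading `s = |e| * vP` is used. `vP = 0` yields an infinite
#' ratio score, ranking the pathway last.
#'
#' @param pathway a kept [CandidatePathway-class] with decoded nodes.
#' @param model an [EnsembleModel-class].
#' @param backend the [EmbeddingBackend-class] used for encoding.
#' @param scoreForm `"ratio"` (default) or `"product"`.
#' @return the pathway with `vR`, `vP` and `score` filled.
#' @export
scorePathway <- function(pathway, model, backend,
                         scoreForm = c("ratio", "product")) {
  scoreForm <- match.arg(scoreForm)
  n <- length(pathway@ec)
  if (anyNA(pathway@nodeIds))
    stop("scoring-error: pathway has undecoded segments", call. = FALSE)
  X <- t(vapply(seq_len(n), function(k)
    scoringInput(backend, pathway@substrateId[k], pathway@productId[k],
                 substrateOfInput = pathway@nodeIds[k]),
    numeric(2L * combinedDim(backend))))
  vR <- predictPossibility(model, X)
  vP <- prod(vR)
  pathway@vR <- vR
  pathway@vP <- vP
  pathway@score <- if (scoreForm == "ratio") {
    if (vP == 0) Inf else pathway@absError / vP
  } else pathway@absError * vP
  pathway
}

#' Per-recipe summary of reaction-possibility values
#'
#' Computes the mean and standard deviation of the voting possibility over
#' example groups, the standard 2x2 view (pair real/virtual x substrate
#' in/out) used to check that the ensemble orders the four recipes
#' correctly.
#'
#' @param model an [EnsembleModel-class].
#' @param groups named list of example sets (each as returned by
#'   [buildVirtualDataset()], or a bare matrix).
#' @return data.frame with columns `group`, `n`, `mean`, `sd`.
#' @export
summarizePossibilities <- function(model, groups) {
  rows <- lapply(names(groups), function(g) {
    X <- groups[[g]]
    if (is.list(X) && !is.null(X$X)) X <- X$X
    v <- predictPossibility(model, X)
    data.frame(group = g, n = nrow(X), mean = mean(v), sd = stats::sd(v))
  })
  do.call(rbind, rows)
}

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel: ", object@Q, " datasets x ", object@R,
      "-fold CV = ", length(object@models), " models\n",
      "  hidden layers: ", paste(object@hidden, collapse = "-"),
      "  input dim: ", nrow(object@models[[1L]]$layers[[1L]]$W), "\n", sep = "")
})
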