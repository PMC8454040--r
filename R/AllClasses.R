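#' @import methods
NULL

#' Virtual base class for embedding backends
#'
#' An embedding backend maps compound structures to fixed-dimension latent
#' vectors and (when it can decode) maps latent vectors back to structures.
#' Two latent parts are exposed, \emph{tree} and \emph{graph}, mirroring the
#' two encoders of junction-tree generative models for molecules; the
#' \emph{combined} part is their concatenation. Concrete backends implement
#' [encodeCompound()], [decodeLatent()], [treeDim()], [graphDim()],
#' [canDecode()] and [molecularWeight()].
#'
#' @slot name single string identifying the backend.
#' @export
setClass("EmbeddingBackend",
         representation("VIRTUAL", name = "character"))

#' Deterministic synthetic chemistry backend
#'
#' A linear stand-in for a trained molecular autoencoder. Each compound in the
#' toy universe is a non-negative integer vector of fragment counts; encoding
#' is a fixed full-rank linear map of the count vector, so latent arithmetic
#' on toy compounds is exact, and molecular weight is the exact dot product of
#' counts with per-fragment masses. Decoding maps a latent vector through the
#' pseudo-inverse of the mixing matrix and returns the nearest universe
#' compound in fragment-count space (ties broken by lowest compound id).
#'
#' By default the tree and graph parts share one mixing matrix, so both parts
#' expose the same latent vector; a distinct `graphMixing` decouples them.
#'
#' @slot fragmentMasses positive numeric, one mass per fragment type (u).
#' @slot mixingMatrix numeric matrix, latent dimension x fragment types,
#'   full column rank; the tree-part encoder.
#' @slot graphMixing numeric matrix with the same shape; the graph-part
#'   encoder (defaults to `mixingMatrix`).
#' @slot counts integer matrix, compounds x fragment types, row names are
#'   compound ids; the universe of representable compounds.
#' @slot seed integer seed the universe was generated from (informational).
#' @export
setClass("ToyChemistry",
         contains = "EmbeddingBackend",
         representation(fragmentMasses = "numeric",
                        mixingMatrix   = "matrix",
                        graphMixing    = "matrix",
                        counts         = "matrix",
                        seed           = "integer"))

setValidity("ToyChemistry", function(object) {
  msg <- character()
  F <- length(object@fragmentMasses)
  if (F < 1L || any(!is.finite(object@fragmentMasses)) ||
      any(object@fragmentMasses <= 0))
    msg <- c(msg, "fragmentMasses must be positive and finite")
  if (ncol(object@mixingMatrix) != F)
    msg <- c(msg, "mixingMatrix must have one column per fragment type")
  if (!all(dim(object@graphMixing) == dim(object@mixingMatrix)))
    msg <- c(msg, "graphMixing must match mixingMatrix in shape")
  if (qr(object@mixingMatrix)$rank < F)
    msg <- c(msg, "mixingMatrix must have full column rank")
  if (ncol(object@counts) != F)
    msg <- c(msg, "universe counts must have one column per fragment type")
  if (nrow(object@counts) < 1L)
    msg <- c(msg, "universe must contain at least one compound")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "universe counts must be non-negative integers")
  if (is.null(rownames(object@counts)) || anyDuplicated(rownames(object@counts)))
    msg <- c(msg, "universe compounds need unique ids as row names")
  if (anyDuplicated(object@counts) > 0)
    msg <- c(msg, "universe count vectors must be distinct")
  if (length(msg)) msg else TRUE
})

#' EC-annotated database of reaction-feature vectors
#'
#' One row per registered enzymatic reaction: the main substrate/product pair,
#' the EC number, the reaction-feature vector (difference of the product and
#' substrate latents for the configured part) and the registered
#' molecular-weight change (product minus substrate). Iteration order is the
#' input record order and is stable.
#'
#' @slot ec character vector of dotted EC numbers (1-4 numeric fields).
#' @slot substrateId,productId character vectors of compound ids.
#' @slot vectors numeric matrix, reactions x latent dimension.
#' @slot deltaMW numeric vector of registered MW changes (u).
#' @slot part one of `"tree"`, `"graph"`, `"combined"` - which latent part
#'   the vectors were computed from.
#' @slot treeDim,graphDim integer latent dimensions of the source backend
#'   (used to split `"combined"` vectors back into parts).
#' @slot skipped integer count of input records dropped because a compound
#'   could not be encoded.
#' @export
setClass("ReactionFeatureDB",
         representation(ec          = "character",
                        substrateId = "character",
                        productId   = "character",
                        vectors     = "matrix",
                        deltaMW     = "numeric",
                        part        = "character",
                        treeDim     = "integer",
                        graphDim    = "integer",
                        skipped     = "integer"))

setValidity("ReactionFeatureDB", function(object) {
  n <- length(object@ec)
  msg <- character()
  if (length(object@substrateId) != n || length(object@productId) != n ||
      nrow(object@vectors) != n || length(object@deltaMW) != n)
    msg <- c(msg, "all per-reaction slots must have equal length")
  if (!object@part %in% c("tree", "graph", "combined"))
    msg <- c(msg, "part must be tree, graph or combined")
  bad <- !grepl("^[0-9]+(\\.[0-9]+){0,3}$", object@ec)
  if (any(bad))
    msg <- c(msg, sprintf("%d EC numbers do not match the dotted-digit pattern",
                          sum(bad)))
  if (any(object@substrateId == object@productId))
    msg <- c(msg, "substrate and product ids must differ within a reaction")
  if (any(!is.finite(object@vectors)))
    msg <- c(msg, "reaction vectors must be finite")
  if (length(msg)) msg else TRUE
})

#' Pathway query: desired overall transformation as a latent difference
#'
#' Holds the start and target compound ids together with the pathway-feature
#' vector `p`, the elementwise difference of the target and start latents for
#' the configured part.
#'
#' @slot startId,targetId compound ids.
#' @slot p numeric pathway-feature vector.
#' @slot part latent part the vector was computed from.
#' @export
setClass("PathwayQuery",
         representation(startId  = "character",
                        targetId = "character",
                        p        = "numeric",
                        part     = "character"))

#' A candidate pathway with reconstruction, pruning and scoring state
#'
#' An ordered sequence of registered reactions applied from the start
#' compound: cumulative latent sums give the intermediate latents, which the
#' backend decodes to structures; each segment's decoded molecular-weight
#' change is compared with the registered change of its reaction for pruning;
#' scoring fills per-segment reaction-possibility values `vR`, the pathway
#' feasibility `vP` (their product) and the final score `s`.
#'
#' @slot startId,targetId compound ids of the query endpoints.
#' @slot ec,substrateId,productId per-segment registered-reaction annotation,
#'   in pathway order.
#' @slot dbIndex integer row index of each segment's reaction in the source DB.
#' @slot intermediateLatents list of numeric latents of the strict
#'   intermediates (length = segments - 1).
#' @slot nodeIds decoded compound id at every node, length segments + 1
#'   (node 1 is the start compound itself); `NA` marks a decode failure.
#' @slot segmentDeltaMW decoded MW change per segment; `registeredDeltaMW`
#'   the registered change of the segment's reaction.
#' @slot absError residual `|e|` between the pathway vector and the vector sum.
#' @slot vR per-segment reaction-possibility values in [0,1] (scored).
#' @slot vP pathway feasibility, the product of `vR` (scored).
#' @slot score pathway score `s` (scored; lower is better).
#' @slot keep logical pruning decision; `removalReason` why it was removed.
#' @export
setClass("CandidatePathway",
         representation(startId             = "character",
                        targetId            = "character",
                        ec                  = "character",
                        substrateId         = "character",
                        productId           = "character",
                        dbIndex             = "integer",
                        intermediateLatents = "list",
                        nodeIds             = "character",
                        segmentDeltaMW      = "numeric",
                        registeredDeltaMW   = "numeric",
                        absError            = "numeric",
                        vR                  = "numeric",
                        vP                  = "numeric",
                        score               = "numeric",
                        keep                = "logical",
                        removalReason       = "character"))

#' Voting ensemble of small binary neural-network classifiers
#'
#' Q combined datasets (real reactions plus one virtual dataset each) times
#' R cross-validation folds give Q x R trained multilayer perceptrons. Each
#' model sees the concatenation of a combined-part reaction-feature vector
#' with the substrate's tree and graph latents, and outputs a hard 0/1; the
#' voting average over all models is the reaction-possibility value in [0,1].
#'
#' @slot models list of Q x R trained networks (weight/bias lists).
#' @slot Q,R ensemble bookkeeping: datasets and folds.
#' @slot reactionDim,treeDim,graphDim input layout dimensions.
#' @slot hidden integer widths of the hidden layers.
#' @slot meta list of training metadata (seeds, fold assignments, sizes).
#' @export
setClass("EnsembleModel",
         representation(models      = "list",
                        Q           = "integer",
                        R           = "integer",
                        reactionDim = "integer",
                        treeDim     = "integer",
                        graphDim    = "integer",
                        hidden      = "integer",
                        meta        = "list"))

setValidity("EnsembleModel", function(object) {
  if (length(object@models) != object@Q * object@R)
    "number of models must equal Q * R" else TRUE
})
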