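#' Reaction-feature vector: latent difference of a substrate/product pair
#'
#' The reaction-feature vector of an enzymatic reaction is the elementwise
#' difference between the latent vector of the main product and that of the
#' main substrate, `r = z_pro - z_sub`. Adding `r` back to the substrate
#' latent reproduces the product latent exactly.
#'
#' @param zSub,zPro numeric latent vectors of identical dimension.
#' @return numeric difference vector.
#' @export
computeReactionVector <- function(zSub, zPro) {
  if (length(zSub) != length(zPro))
    stopDim("substrate and product latents differ in dimension")
  zPro - zSub
}

#' Read a reaction table
#'
#' Expects columns `ec_number`, `substrate_id`, `product_id` (TSV or CSV by
#' extension). Each row is one registered reaction: the EC number and the
#' main substrate / main product pair; cofactors and co-substrates are not
#' represented.
#'
#' @param path file path.
#' @return data.frame of character columns.
#' @export
readReactionTable <- function(path) {
  df <- readDelimited(path)
  need <- c("ec_number", "substrate_id", "product_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopFormat(paste0("reaction table is missing column(s): ",
                      paste(miss, collapse = ", ")))
  df[need] <- lapply(df[need], as.character)
  df[, need, drop = FALSE]
}

#' Build the EC-annotated reaction-feature database
#'
#' Encodes every registered substrate/product pair with the backend and
#' stores one reaction-feature vector per record, in input order, together
#' with the registered molecular-weight change (product MW minus substrate
#' MW). Records whose compounds cannot be encoded are skipped; the skip
#' count is kept on the object and reported by `show()`.
#'
#' @param records data.frame with columns `ec_number`, `substrate_id`,
#'   `product_id` (see [readReactionTable()]).
#' @param backend an [EmbeddingBackend-class] object.
#' @param part latent part for the stored vectors: `"tree"` (default, the
#'   part used for pathway design), `"graph"`, or `"combined"`.
#' @return a [ReactionFeatureDB-class] object.
#' @export
buildReactionDB <- function(records, backend, part = c("tree", "graph", "combined")) {
  part <- match.arg(part)
  n <- nrow(records)
  if (is.null(n) || n < 1L) stopParam("no reaction records supplied")
  pick <- function(enc) switch(part, tree = enc$treeLatent,
                               graph = enc$graphLatent, combined = enc$combinedLatent)
  vecs <- vector("list", n); dmw <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    enc <- tryCatch(list(s = encodeCompound(backend, records$substrate_id[i]),
                         p = encodeCompound(backend, records$product_id[i])),
                    error = function(e) NULL)
    if (is.null(enc)) next
    vecs[[i]] <- computeReactionVector(pick(enc$s), pick(enc$p))
    dmw[i] <- enc$p$molecularWeight - enc$s$molecularWeight
    ok[i] <- TRUE
  }
  if (!any(ok))
    stop("empty-db: no record could be encoded", call. = FALSE)
  methods::new("ReactionFeatureDB",
               ec = records$ec_number[ok],
               substrateId = records$substrate_id[ok],
               productId = records$product_id[ok],
               vectors = do.call(rbind, vecs[ok]),
               deltaMW = dmw[ok],
               part = part,
               treeDim = as.integer(treeDim(backend)),
               graphDim = as.integer(graphDim(backend)),
               skipped = as.integer(sum(!ok)))
}

#' @describeIn buildReactionDB number of stored reaction features.
#' @param x a [ReactionFeatureDB-class] object.
#' @export
setMethod("length", "ReactionFeatureDB", function(x) length(x@ec))

#' Subset a reaction-feature DB by row index
#'
#' @param x a [ReactionFeatureDB-class].
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @return a [ReactionFeatureDB-class] with the selected rows, in the order
#'   of `i`.
#' @export
setMethod("[", "ReactionFeatureDB", function(x, i, j, ..., drop = FALSE) {
  methods::initialize(x, ec = x@ec[i], substrateId = x@substrateId[i],
                      productId = x@productId[i],
                      vectors = x@vectors[i, , drop = FALSE],
                      deltaMW = x@deltaMW[i])
})

setMethod("show", "ReactionFeatureDB", function(object) {
  cat("ReactionFeatureDB with ", length(object), " reaction features (",
      object@part, " part, dim ", ncol(object@vectors), ")\n", sep = "")
  cat("  EC classes (1 digit): ",
      paste(names(table(ecPrefix(object@ec, 1L))), collapse = " "), "\n", sep = "")
  if (object@skipped > 0L)
    cat("  skipped records (unencodable): ", object@skipped, "\n", sep = "")
})

#' Retrieve features by EC number or EC prefix
#'
#' A prefix of 1-4 dotted fields selects all features whose EC number starts
#' with those fields (`"2.7"` matches `"2.7.1.1"` but not `"2.71.1.1"`).
#'
#' @param db a [ReactionFeatureDB-class].
#' @param prefix dotted EC prefix.
#' @return integer row indices into `db`, in DB order.
#' @export
featuresByEC <- function(db, prefix) which(ecMatchesPrefix(db@ec, prefix))

#' Nearest registered reactions to a query vector
#'
#' Ranks stored reaction features by ascending Euclidean distance to the
#' query vector, optionally restricted to an EC-number prefix. Used to ask
#' which registered enzymatic transformations most resemble a novel
#' (e.g. non-registered) reaction vector. Ties keep DB order.
#'
#' @param db a [ReactionFeatureDB-class].
#' @param query numeric vector matching the DB's vector dimension.
#' @param ecPrefix optional dotted EC prefix restricting the search.
#' @param k number of neighbours to return (truncated to the matching set).
#' @return data.frame with columns `index` (row in `db`), `ec_number`,
#'   `substrate_id`, `product_id`, `distance`, ordered by distance.
#' @export
nearestReactions <- function(db, query, ecPrefix = NULL, k = 5L) {
  if (k < 1L) stopParam("k must be >= 1")
  if (length(query) != ncol(db@vectors))
    stopDim("query dimension does not match DB vectors")
  idx <- if (is.null(ecPrefix)) seq_len(length(db)) else featuresByEC(db, ecPrefix)
  if (!length(idx))
    return(data.frame(index = integer(), ec_number = character(),
                      substrate_id = character(), product_id = character(),
                      distance = numeric()))
  d <- sqrt(colSums((t(db@vectors[idx, , drop = FALSE]) - query)^2))
  ord <- order(d, seq_along(idx))[seq_len(min(k, length(idx)))]
  data.frame(index = idx[ord], ec_number = db@ec[idx[ord]],
             substrate_id = db@substrateId[idx[ord]],
             product_id = db@productId[idx[ord]],
             distance = d[ord], row.names = NULL)
}

#' Serialize / restore a reaction-feature DB as JSON
#'
#' Vectors are written at full precision so that
#' `readReactionDB(writeReactionDB(db, f))` reproduces the DB contents
#' exactly.
#'
#' @param db a non-empty [ReactionFeatureDB-class].
#' @param path file path.
#' @return `readReactionDB` returns the restored DB; `writeReactionDB`
#'   returns `path` invisibly.
#' @export
writeReactionDB <- function(db, path) {
  if (length(db) < 1L) stopParam("refusing to write an empty DB")
  obj <- list(format = "pathlatent-reaction-db", version = 1L,
              part = db@part, tree_dim = db@treeDim, graph_dim = db@graphDim,
              skipped = db@skipped,
              ec_number = db@ec, substrate_id = db@substrateId,
              product_id = db@productId, delta_mw = numToChar(db@deltaMW),
              vectors = matToChar(db@vectors))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeReactionDB
#' @export
readReactionDB <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopFormat(conditionMessage(e)))
  if (!identical(obj$format, "pathlatent-reaction-db"))
    stopFormat("not a reaction-feature DB file")
  need <- c("ec_number", "substrate_id", "product_id", "delta_mw", "vectors")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stopFormat(paste0("DB file is missing field(s): ",
                      paste(miss, collapse = ", ")))
  methods::new("ReactionFeatureDB",
               ec = as.character(obj$ec_number),
               substrateId = as.character(obj$substrate_id),
               productId = as.character(obj$product_id),
               vectors = charToMat(obj$vectors),
               deltaMW = charToNum(obj$delta_mw),
               part = obj$part,
               treeDim = as.integer(obj$tree_dim),
               graphDim = as.integer(obj$graph_dim),
               skipped = as.integer(obj$skipped))
}
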