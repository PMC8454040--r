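#' Generate a seeded toy-chemistry universe
#'
#' Builds a [ToyChemistry-class] backend: `nFragments` fragment types with
#' random masses, a full-rank random mixing matrix from fragment-count space
#' into an `latentDim`-dimensional latent space, and `nCompounds` distinct
#' random compounds (non-negative integer fragment-count vectors). Because the
#' embedding is linear in the counts, latent arithmetic over toy compounds is
#' exact, which makes every downstream stage of the pipeline testable against
#' hand computation.
#'
#' @param nCompounds number of compounds in the universe (>= 2).
#' @param nFragments number of fragment types (>= 1).
#' @param latentDim latent dimension per part (>= `nFragments`). The default
#'   28 gives a combined tree+graph dimension of 56, the conventional
#'   bottleneck size for junction-tree molecular autoencoders.
#' @param seed integer seed; the universe is reproducible given the seed.
#' @param maxCount largest fragment count drawn per compound and type.
#' @param splitParts when `TRUE`, draw an independent mixing matrix for the
#'   graph part so tree and graph latents differ; by default both parts share
#'   one matrix and expose the same latent.
#' @return a validated [ToyChemistry-class] object.
#' @examples
#' toy <- makeToyUniverse(20, 4, 6, seed = 1)
#' enc <- encodeCompound(toy, compoundIds(toy)[1])
#' decodeLatent(toy, enc$treeLatent)  # round-trips to the same id
#' @export
makeToyUniverse <- function(nCompounds, nFragments, latentDim = 28L,
                            seed = 1L, maxCount = 6L, splitParts = FALSE) {
  if (nCompounds < 2L) stopParam("nCompounds must be >= 2")
  if (nFragments < 1L) stopParam("nFragments must be >= 1")
  if (latentDim < nFragments)
    stopParam("latentDim must be >= nFragments for a full-rank embedding")
  withSeed(seed, {
    masses <- round(stats::runif(nFragments, 12, 80), 2)
    mixing <- randomFullRank(latentDim, nFragments)
    gmix <- if (splitParts) randomFullRank(latentDim, nFragments) else mixing
    counts <- matrix(0L, 0L, nFragments)
    tries <- 0L
    while (nrow(counts) < nCompounds && tries < 200L * nCompounds) {
      cand <- sample.int(maxCount + 1L, nFragments, replace = TRUE) - 1L
      if (sum(cand) == 0L) cand[sample.int(nFragments, 1L)] <- 1L
      counts <- unique(rbind(counts, cand))
      tries <- tries + 1L
    }
    if (nrow(counts) < nCompounds)
      stopParam("could not draw enough distinct compounds; raise maxCount")
    rownames(counts) <- sprintf("T%05d", seq_len(nCompounds))
    methods::new("ToyChemistry", name = "toy",
                 fragmentMasses = masses, mixingMatrix = mixing,
                 graphMixing = gmix, counts = counts,
                 seed = as.integer(seed))
  })
}

# Random latentDim x F matrix with orthonormal columns (always full rank,
# numerically stable pseudo-inverse for decoding).
randomFullRank <- function(latentDim, F) {
  repeat {
    m <- matrix(stats::rnorm(latentDim * F), latentDim, F)
    q <- qr(m)
    if (q$rank == F) return(qr.Q(q)[, seq_len(F), drop = FALSE])
  }
}

#' Compact structure notation for toy compounds
#'
#' Renders a fragment-count vector as e.g. `"f1:2+f3:1"` (fragment type and
#' count, zero counts omitted). This plays the role SMILES plays for real
#' chemistry: a canonical, parseable structure string.
#'
#' @param counts non-negative integer fragment-count vector.
#' @return single string.
#' @export
toyNotation <- function(counts) {
  nz <- which(counts > 0)
  if (!length(nz)) return("empty")
  paste(sprintf("f%d:%d", nz, as.integer(counts[nz])), collapse = "+")
}

parseToyNotation <- function(s, nFragments) {
  if (identical(s, "empty")) return(integer(nFragments))
  parts <- strsplit(s, "+", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^f([0-9]+):([0-9]+)$", parts))
  if (any(lengths(m) != 3L))
    stop("structure-error: cannot parse toy notation '", s, "'", call. = FALSE)
  counts <- integer(nFragments)
  for (p in m) {
    idx <- as.integer(p[2])
    if (idx < 1L || idx > nFragments)
      stop("structure-error: fragment index out of range in '", s, "'",
           call. = FALSE)
    counts[idx] <- counts[idx] + as.integer(p[3])
  }
  counts
}

# Resolve an id or toy-notation string to a universe row index.
toyResolve <- function(backend, x) {
  ids <- rownames(backend@counts)
  i <- match(x, ids)
  if (!is.na(i)) return(i)
  counts <- parseToyNotation(x, ncol(backend@counts))
  hit <- which(apply(backend@counts, 1L, function(r) all(r == counts)))
  if (!length(hit))
    stop("unsupported-compound: '", x, "' is not in the toy universe",
         call. = FALSE)
  hit[1L]
}

#' @describeIn treeDim tree dimension of the toy backend.
setMethod("treeDim", "ToyChemistry", function(backend) nrow(backend@mixingMatrix))

#' @describeIn treeDim graph dimension of the toy backend.
setMethod("graphDim", "ToyChemistry", function(backend) nrow(backend@graphMixing))

#' @describeIn treeDim combined (tree + graph) dimension.
setMethod("combinedDim", "EmbeddingBackend",
          function(backend) treeDim(backend) + graphDim(backend))

#' @describeIn treeDim the toy backend always decodes.
setMethod("canDecode", "ToyChemistry", function(backend) TRUE)

#' @describeIn compoundIds ids of the toy universe.
setMethod("compoundIds", "ToyChemistry",
          function(backend) rownames(backend@counts))

#' @describeIn encodeCompound exact linear encoding of a toy compound; errors
#'   with `unsupported-compound` for structures outside the universe.
setMethod("encodeCompound", "ToyChemistry", function(backend, x) {
  i <- toyResolve(backend, x)
  cnt <- backend@counts[i, ]
  list(compoundId = rownames(backend@counts)[i],
       structure = toyNotation(cnt),
       treeLatent = as.numeric(backend@mixingMatrix %*% cnt),
       graphLatent = as.numeric(backend@graphMixing %*% cnt),
       combinedLatent = c(as.numeric(backend@mixingMatrix %*% cnt),
                          as.numeric(backend@graphMixing %*% cnt)),
       molecularWeight = as.numeric(cnt %*% backend@fragmentMasses))
})

#' @describeIn molecularWeight exact toy molecular weight.
setMethod("molecularWeight", "ToyChemistry", function(backend, x) {
  as.numeric(backend@counts[toyResolve(backend, x), ] %*% backend@fragmentMasses)
})

#' @describeIn decodeLatent nearest universe compound after mapping the latent
#'   through the pseudo-inverse of the part's mixing matrix; ties broken by
#'   lowest compound id.
setMethod("decodeLatent", "ToyChemistry", function(backend, latent, part = "tree") {
  M <- switch(part,
              tree = backend@mixingMatrix,
              graph = backend@graphMixing,
              combined = rbind(backend@mixingMatrix, backend@graphMixing),
              stopParam("part must be tree, graph or combined"))
  if (length(latent) != nrow(M))
    stopDim(sprintf("latent has length %d but the %s part has dimension %d",
                    length(latent), part, nrow(M)))
  est <- as.numeric(MASS::ginv(M) %*% latent)
  d2 <- colSums((t(backend@counts) - est)^2)
  best <- which(d2 <= min(d2) + 1e-12)
  ids <- rownames(backend@counts)[best]
  ids[order(ids)][1L]
})

setMethod("show", "ToyChemistry", function(object) {
  cat("ToyChemistry backend\n",
      "  compounds: ", nrow(object@counts),
      "  fragment types: ", length(object@fragmentMasses),
      "  latent dim (tree/graph): ", treeDim(object), "/", graphDim(object),
      "  seed: ", object@seed, "\n", sep = "")
})

#' Serialize / restore a toy universe as JSON
#'
#' Full-precision round trip: `readToyUniverse(writeToyUniverse(x, f))`
#' reproduces the backend exactly.
#'
#' @param backend a [ToyChemistry-class] object.
#' @param path file path.
#' @return `readToyUniverse` returns the restored backend;
#'   `writeToyUniverse` returns `path` invisibly.
#' @export
writeToyUniverse <- function(backend, path) {
  obj <- list(format = "pathlatent-toy-universe", version = 1L,
              seed = backend@seed,
              fragment_masses = numToChar(backend@fragmentMasses),
              mixing_matrix = matToChar(backend@mixingMatrix),
              graph_mixing = matToChar(backend@graphMixing),
              compound_ids = rownames(backend@counts),
              counts = unname(backend@counts))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeToyUniverse
#' @export
readToyUniverse <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pathlatent-toy-universe"))
    stopFormat("not a toy-universe file")
  counts <- matrix(as.integer(obj$counts), nrow = length(obj$compound_ids))
  rownames(counts) <- obj$compound_ids
  methods::new("ToyChemistry", name = "toy",
               fragmentMasses = charToNum(obj$fragment_masses),
               mixingMatrix = charToMat(obj$mixing_matrix),
               graphMixing = charToMat(obj$graph_mixing),
               counts = counts, seed = as.integer(obj$seed))
}

#' Read a compound table
#'
#' Expects columns `compound_id` and `smiles` (for the toy backend the
#' `smiles` column holds toy-notation structure strings). TSV or CSV is
#' chosen by file extension.
#'
#' @param path file path.
#' @return data.frame with character columns `compound_id`, `smiles`.
#' @export
readCompoundTable <- function(path) {
  df <- readDelimited(path)
  need <- c("compound_id", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopFormat(paste0("compound table is missing column(s): ",
                      paste(miss, collapse = ", ")))
  df[need] <- lapply(df[need], as.character)
  df[, need, drop = FALSE]
}

readDelimited <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = TRUE,
                    comment.char = "")
}
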