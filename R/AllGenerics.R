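#' Backend dimensions and capabilities
#'
#' `treeDim()`, `graphDim()` and `combinedDim()` report the latent dimensions
#' a backend declares for each part; `canDecode()` reports whether the backend
#' supports decoding latent vectors back to structures.
#'
#' @param backend an [EmbeddingBackend-class] object.
#' @return an integer dimension, or a logical for `canDecode()`.
#' @aliases treeDim graphDim combinedDim canDecode
#' @export
setGeneric("treeDim", function(backend) standardGeneric("treeDim"))

#' @rdname treeDim
#' @export
setGeneric("graphDim", function(backend) standardGeneric("graphDim"))

#' @rdname treeDim
#' @export
setGeneric("combinedDim", function(backend) standardGeneric("combinedDim"))

#' @rdname treeDim
#' @export
setGeneric("canDecode", function(backend) standardGeneric("canDecode"))

#' Encode a compound to its latent representation
#'
#' @param backend an [EmbeddingBackend-class] object.
#' @param x a compound id known to the backend, or a structure string the
#'   backend can parse.
#' @return a list with elements `compoundId`, `structure`, `treeLatent`,
#'   `graphLatent`, `combinedLatent` and `molecularWeight`. Encoding is
#'   deterministic: the same input always yields identical latents.
#' @export
setGeneric("encodeCompound", function(backend, x) standardGeneric("encodeCompound"))

#' Decode a latent vector back to a compound structure
#'
#' @param backend an [EmbeddingBackend-class] object with `canDecode(backend)`
#'   `TRUE`.
#' @param latent numeric latent vector of the dimension declared for `part`.
#' @param part which latent part `latent` belongs to: `"tree"`, `"graph"` or
#'   `"combined"`.
#' @return the decoded compound id as a single string, or `NA_character_`
#'   when the backend cannot produce a structure for this latent (a decode
#'   failure is a represented outcome, not an error).
#' @export
setGeneric("decodeLatent",
           function(backend, latent, part = "tree") standardGeneric("decodeLatent"))

#' Exact molecular weight of a compound known to a backend
#'
#' @param backend an [EmbeddingBackend-class] object.
#' @param x compound id or structure string.
#' @return molecular weight in unified atomic mass units.
#' @export
setGeneric("molecularWeight", function(backend, x) standardGeneric("molecularWeight"))

#' Compound ids of a backend's representable universe
#'
#' @param backend an [EmbeddingBackend-class] object.
#' @return character vector of compound ids.
#' @export
setGeneric("compoundIds", function(backend) standardGeneric("compoundIds"))
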