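#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib plasmidMOB, .registration = TRUE
NULL

#' KmerEmbedding: skip-gram k-mer word vectors
#'
#' Container for a trained k-mer embedding: the token-by-dimension matrix of
#' word vectors (input layer of the skip-gram network) together with the
#' training configuration. Row names of `vectors` are the vocabulary tokens.
#'
#' @slot k Integer word length (k-mer size).
#' @slot dim Integer embedding dimension.
#' @slot vectors Numeric matrix, one row per vocabulary token.
#' @slot config Named list of training settings (window, epochs,
#'   negative samples, learning rate, seed, corpus size).
#'
#' @aliases KmerEmbedding-class
#' @exportClass KmerEmbedding
setClass("KmerEmbedding",
         representation(k = "integer", dim = "integer",
                        vectors = "matrix", config = "list"))

setValidity("KmerEmbedding", function(object) {
  msg <- NULL
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (ncol(object@vectors) != object@dim)
    msg <- c(msg, "vector matrix width must equal the embedding dimension")
  toks <- rownames(object@vectors)
  if (is.null(toks) || any(nchar(toks) != object@k))
    msg <- c(msg, "vocabulary tokens must all have length k")
  if (any(!is.finite(object@vectors)))
    msg <- c(msg, "word vectors must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn KmerEmbedding Number of vocabulary tokens.
#' @param x,object A `KmerEmbedding`.
#' @export
setMethod("length", "KmerEmbedding", function(x) nrow(x@vectors))

setMethod("show", "KmerEmbedding", function(object) {
  cat(sprintf("KmerEmbedding: %d-mers, %d tokens, %d dimensions\n",
              object@k, nrow(object@vectors), object@dim))
  cfg <- object@config
  if (length(cfg))
    cat(sprintf("  window=%s epochs=%s negative=%s seed=%s\n",
                cfg$window, cfg$epochs, cfg$negative, cfg$seed))
})

#' Embedding accessors
#'
#' @param x A [KmerEmbedding].
#' @return `embeddingTokens()` returns the vocabulary; `embeddingVectors()`
#'   the token-by-dimension matrix; `embeddingK()` the k-mer size;
#'   `embeddingDim()` the dimension.
#' @export
embeddingTokens <- function(x) rownames(x@vectors)

#' @rdname embeddingTokens
#' @export
embeddingVectors <- function(x) x@vectors

#' @rdname embeddingTokens
#' @export
embeddingK <- function(x) x@k

#' @rdname embeddingTokens
#' @export
embeddingDim <- function(x) x@dim

#' MobEnsemble: length-binned random-forest MOB classifier
#'
#' The trained classifier: one probability random forest per training length
#' bin, the embedding used to featurize fragments at training time, and the
#' fixed class order shared by every score vector.
#'
#' @slot forests Named list of ranger forests, one per length bin (B1..B4).
#' @slot embedding The [KmerEmbedding] used for featurization.
#' @slot classOrder Character vector, the fixed 11-class order.
#' @slot nTrees Integer, trees per forest.
#' @slot seed Integer training seed.
#'
#' @aliases MobEnsemble-class
#' @exportClass MobEnsemble
setClass("MobEnsemble",
         representation(forests = "list", embedding = "KmerEmbedding",
                        classOrder = "character", nTrees = "integer",
                        seed = "integer"))

setValidity("MobEnsemble", function(object) {
  msg <- NULL
  if (length(object@forests) != 4L ||
      !identical(sort(names(object@forests)), sort(lengthBins()$bin)))
    msg <- c(msg, "exactly four per-bin forests (B1..B4) are required")
  if (length(object@classOrder) < 2L)
    msg <- c(msg, "classOrder must list at least two classes")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MobEnsemble", function(object) {
  cat(sprintf("MobEnsemble: 4 length-binned forests (%d trees each)\n",
              object@nTrees))
  cat("  classes:", paste(object@classOrder, collapse = ", "), "\n")
  cat(sprintf("  embedding: %d-mers, %d dimensions\n",
              object@embedding@k, object@embedding@dim))
})

#' Ensemble accessors
#'
#' @param x A [MobEnsemble].
#' @return `ensembleForests()` returns the named list of per-bin forests;
#'   `ensembleEmbedding()` the training [KmerEmbedding]; `classOrder()` the
#'   fixed class order.
#' @export
ensembleForests <- function(x) x@forests

#' @rdname ensembleForests
#' @export
ensembleEmbedding <- function(x) x@embedding

#' @rdname ensembleForests
#' @export
classOrder <- function(x) x@classOrder
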