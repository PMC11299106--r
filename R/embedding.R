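#' Tokenize DNA into overlapping k-mer words
#'
#' Slides a window of width `k` along the sequence and returns the
#' overlapping words in order. Windows containing a character outside
#' `{A, C, G, T}` (ambiguity codes, gaps) are dropped; the remaining windows
#' keep their original order.
#'
#' @param sequence A single DNA string (case-insensitive).
#' @param k Word length (default 4).
#' @return Character vector of tokens, length at most `nchar(sequence) - k + 1`.
#' @examples
#' tokenizeDNA("ATCGCTGA", 4)
#' @export
tokenizeDNA <- function(sequence, k = 4L) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nchar(sequence) < k)
    stop("sequence shorter than k: no tokens can be produced")
  ids <- .tokenize_ids(sequence, k)[[1L]]
  allKmers(k)[ids + 1L]
}

#' Train skip-gram k-mer word vectors
#'
#' Learns a dense vector per k-mer with the skip-gram objective and negative
#' sampling. Each corpus sequence is one "sentence" of overlapping k-mer
#' words; the network's input-layer weights after training are the word
#' vectors. Training is single-threaded and bit-reproducible given `seed`.
#'
#' @param corpus Character vector or `DNAStringSet` of training sequences.
#' @param k Word length (default 4).
#' @param dim Embedding dimension (default 100).
#' @param window Context words per side (default 10, i.e. 20 context words
#'   total); the effective window per center word is drawn uniformly from
#'   1..`window`, as in standard skip-gram implementations.
#' @param epochs Training passes over the corpus (default 10).
#' @param negative Negative samples per context word (default 5).
#' @param alpha Initial learning rate (default 0.025, decayed linearly).
#' @param minCount Minimum occurrences for vocabulary inclusion (default 1).
#' @param seed Integer seed for initialization and sampling.
#' @return A [KmerEmbedding].
#' @examples
#' emb <- trainKmerEmbedding(c("ACGTACGTACGTACGT"), k = 4, dim = 8,
#'                           epochs = 2, seed = 1)
#' emb
#' @export
trainKmerEmbedding <- function(corpus, k = 4L, dim = 100L, window = 10L,
                               epochs = 10L, negative = 5L, alpha = 0.025,
                               minCount = 1L, seed = 1L) {
  corpus <- .asSequenceChar(corpus)
  if (length(corpus) == 0L) stop("empty corpus")
  k <- as.integer(k); dim <- as.integer(dim)
  window <- as.integer(window); epochs <- as.integer(epochs)
  stopifnot(k >= 1L, dim >= 1L, window >= 1L, epochs >= 1L, negative >= 0L)
  sentences <- .tokenize_ids(corpus, k)
  sentences <- sentences[lengths(sentences) > 0L]
  if (length(sentences) == 0L)
    stop("no sequence of length >= k with usable characters in corpus")

  counts <- tabulate(unlist(sentences) + 1L, nbins = 4L^k)
  vocabIds <- which(counts >= max(1L, minCount)) - 1L  # 0-based token ids
  if (length(vocabIds) == 0L) stop("empty vocabulary after minCount filter")
  remap <- integer(4L^k)                      # token id -> 1-based vocab row
  remap[vocabIds + 1L] <- seq_along(vocabIds)
  sentences <- lapply(sentences, function(s) {
    r <- remap[s + 1L]
    r[r > 0L] - 1L                             # 0-based rows for the trainer
  })
  sentences <- sentences[lengths(sentences) > 0L]

  vecs <- .sgns_train(sentences, length(vocabIds),
                      as.numeric(counts[vocabIds + 1L]), dim, window,
                      as.integer(negative), epochs, alpha, as.numeric(seed))
  rownames(vecs) <- allKmers(k)[vocabIds + 1L]
  new("KmerEmbedding", k = k, dim = dim, vectors = vecs,
      config = list(window = window, epochs = epochs,
                    negative = as.integer(negative), alpha = alpha,
                    minCount = as.integer(minCount), seed = as.integer(seed),
                    corpusSequences = length(corpus)))
}

#' Featurize DNA fragments as mean k-mer word vectors
#'
#' The feature vector of a fragment is the arithmetic mean of the word
#' vectors of all its in-vocabulary k-mer tokens; out-of-vocabulary tokens
#' (and windows with ambiguity characters) are skipped. Fragments with no
#' usable token get an `NA` row and a zero token count.
#'
#' @param x Character vector or `DNAStringSet` of fragments.
#' @param embedding A [KmerEmbedding].
#' @return A list with `features` (fragments x dim numeric matrix, row names
#'   from `names(x)`) and `nTokens` (usable tokens per fragment).
#' @export
featurizeFragments <- function(x, embedding) {
  stopifnot(is(embedding, "KmerEmbedding"))
  ids <- names(x)
  x <- .asSequenceChar(x)
  k <- embedding@k
  rowOf <- integer(4L^k)
  tokIds <- .kmerIds(embeddingTokens(embedding), k)
  rowOf[tokIds + 1L] <- seq_len(length(embedding))
  res <- .featurize_batch(x, embedding@vectors, rowOf, k)
  feats <- res$features
  rownames(feats) <- ids
  colnames(feats) <- paste0("V", seq_len(ncol(feats)))
  list(features = feats, nTokens = as.integer(res$n_tokens))
}

#' Featurize a single fragment
#'
#' Convenience wrapper around [featurizeFragments()] for one sequence;
#' errors if the fragment has no usable in-vocabulary token.
#'
#' @inheritParams featurizeFragments
#' @param sequence A single DNA string.
#' @return Numeric vector of length `embeddingDim(embedding)`.
#' @export
featurize <- function(sequence, embedding) {
  res <- featurizeFragments(sequence, embedding)
  if (res$nTokens[1L] == 0L)
    stop("fragment has no usable in-vocabulary token; cannot featurize")
  drop(res$features[1L, ])
}

# token string -> 0-based integer id
.kmerIds <- function(tokens, k) {
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  m <- matrix(codes[unlist(strsplit(tokens, ""))], nrow = k)
  as.integer(colSums(m * 4L^((k - 1L):0L)))
}

.asSequenceChar <- function(x) {
  if (is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("sequences must be a character vector or XStringSet")
  toupper(x)
}

#' Write / read a k-mer embedding as plain text
#'
#' Plain-text serialization: a header line `k dimension`, then one line per
#' token with the token and its whitespace-separated vector entries.
#'
#' @param embedding A [KmerEmbedding].
#' @param path File path.
#' @return `writeKmerEmbedding()` invisibly returns `path`;
#'   `readKmerEmbedding()` returns a [KmerEmbedding] (training configuration
#'   is not round-tripped).
#' @export
writeKmerEmbedding <- function(embedding, path) {
  stopifnot(is(embedding, "KmerEmbedding"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(embedding@k, embedding@dim), con)
  toks <- embeddingTokens(embedding)
  body <- vapply(seq_along(toks), function(i)
    paste(toks[i], paste(format(embedding@vectors[i, ], digits = 17,
                                scientific = TRUE, trim = TRUE),
                         collapse = " ")), character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeKmerEmbedding
#' @export
readKmerEmbedding <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed embedding header; expected 'k dimension'")
  k <- hdr[1L]; dim <- hdr[2L]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  if (any(lengths(body) != dim + 1L))
    stop("malformed embedding body: each line needs a token and ", dim,
         " values")
  toks <- vapply(body, `[`, character(1), 1L)
  vecs <- t(vapply(body, function(f) as.numeric(f[-1L]), numeric(dim)))
  rownames(vecs) <- toks
  new("KmerEmbedding", k = k, dim = dim, vectors = vecs, config = list())
}
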