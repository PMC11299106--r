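#' Assign a fragment length to its model bin
#'
#' Fragments shorter than 100 bp are served by the 100-400 bp model (B1).
#' Lengths above 1,600 bp are outside any single model's domain and must be
#' segmented first ([segmentFragment()]).
#'
#' @param length Integer vector of fragment lengths (bp).
#' @return Character vector of bin names (`B1`..`B4`).
#' @examples
#' assignLengthBin(c(50, 400, 401, 1600))
#' @export
assignLengthBin <- function(length) {
  length <- as.integer(length)
  if (any(length < 1L)) stop("lengths must be >= 1")
  if (any(length > .MAX_MODEL_LEN))
    stop("lengths above ", .MAX_MODEL_LEN,
         " bp are handled by segmentation, not a single bin")
  bins <- lengthBins()
  idx <- pmax(findInterval(length, bins$lo), 1L)
  bins$bin[idx]
}

#' Segment a long fragment into model-sized pieces
#'
#' Fragments longer than 1,600 bp are cut greedily left to right into
#' `floor(L/1600)` pieces of 1,600 bp plus one remainder piece (omitted when
#' the length is an exact multiple); e.g. a 4,000 bp fragment yields pieces
#' of 1,600, 1,600 and 800 bp. Concatenating the pieces reproduces the
#' input. Shorter inputs pass through as a single segment.
#'
#' @param sequence A single DNA string.
#' @return Character vector of segment sequences, in order.
#' @examples
#' nchar(segmentFragment(paste(rep("ACGT", 1000), collapse = "")))
#' @export
segmentFragment <- function(sequence) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  L <- nchar(sequence)
  if (L <= .MAX_MODEL_LEN) return(sequence)
  starts <- seq.int(1L, L, by = .MAX_MODEL_LEN)
  ends <- pmin(starts + .MAX_MODEL_LEN - 1L, L)
  substring(sequence, starts, ends)
}

#' Train the length-binned random-forest ensemble
#'
#' Featurizes training fragments with the embedding, groups them into the
#' four length bins and trains one probability random forest per bin
#' (500 trees by default). Forest scores are per-class vote fractions,
#' renormalized defensively to sum to 1. Training is single-threaded and
#' deterministic given `seed`.
#'
#' @param fragments `DNAStringSet` of training fragments with an `mcols`
#'   column `true_class`, or a character vector with `trueClass` supplied.
#' @param embedding A [KmerEmbedding].
#' @param trueClass Optional character vector of labels (overrides `mcols`).
#' @param nTrees Trees per forest (default 500).
#' @param seed Integer seed.
#' @param classes The fixed class order (default [mobClasses()]).
#' @return A [MobEnsemble].
#' @export
trainMobEnsemble <- function(fragments, embedding, trueClass = NULL,
                             nTrees = 500L, seed = 1L,
                             classes = mobClasses()) {
  if (is.null(trueClass)) {
    trueClass <- S4Vectors::mcols(fragments)$true_class
    if (is.null(trueClass))
      stop("supply trueClass or fragments with an mcols true_class column")
  }
  seqs <- .asSequenceChar(fragments)
  stopifnot(length(seqs) == length(trueClass))
  unknown <- setdiff(unique(trueClass), classes)
  if (length(unknown))
    stop("labels outside the class order: ", paste(unknown, collapse = ", "))
  lens <- nchar(seqs)
  if (any(lens > .MAX_MODEL_LEN))
    stop("training fragments must be at most ", .MAX_MODEL_LEN, " bp")
  feat <- featurizeFragments(seqs, embedding)
  usable <- feat$nTokens > 0L
  if (!all(usable)) {
    warning(sum(!usable), " unfeaturizable training fragment(s) dropped")
    seqs <- seqs[usable]; trueClass <- trueClass[usable]; lens <- lens[usable]
  }
  X <- feat$features[usable, , drop = FALSE]
  bin <- assignLengthBin(lens)
  forests <- list()
  for (b in lengthBins()$bin) {
    idx <- which(bin == b)
    if (length(unique(trueClass[idx])) < 2L)
      stop("length bin ", b, " has fewer than 2 classes; cannot train")
    df <- as.data.frame(X[idx, , drop = FALSE])
    # levels restricted to observed classes, in class order; scores are
    # expanded back to the full order at prediction time
    df$.class <- factor(trueClass[idx],
                        levels = intersect(classes, trueClass[idx]))
    forests[[b]] <- ranger::ranger(
      dependent.variable.name = ".class", data = df,
      num.trees = as.integer(nTrees), probability = TRUE,
      seed = as.integer(seed), num.threads = 1L, verbose = FALSE)
  }
  new("MobEnsemble", forests = forests, embedding = embedding,
      classOrder = classes, nTrees = as.integer(nTrees),
      seed = as.integer(seed))
}

# raw per-bin forest scores for a feature matrix; returns rows in the full
# class order (zero for classes absent from the forest), renormalized
.forestScores <- function(forest, X, classes) {
  df <- as.data.frame(X)
  p <- stats::predict(forest, data = df, num.threads = 1L,
                      verbose = FALSE)$predictions
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L,
                                   dimnames = list(NULL, names(p)))
  out <- matrix(0, nrow(p), length(classes),
                dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  sums <- rowSums(out)
  sums[sums == 0] <- 1
  out / sums
}

# length-weighted mean of score rows; weights need not be normalized
.weightScores <- function(scores, weights) {
  w <- weights / sum(weights)
  drop(crossprod(scores, w))
}

#' Predict MOB class scores for fragments
#'
#' Fragments up to 1,600 bp are scored by the forest of their length bin.
#' Longer fragments are segmented ([segmentFragment()]), each segment is
#' scored by its bin's forest, and the segment score vectors are combined as
#' their length-weighted mean. The predicted class is the arg-max, with ties
#' broken deterministically by class order. Fragments with no usable k-mer
#' token are reported with class `"unclassified"` and `NA` scores rather
#' than dropped.
#'
#' @param x Character vector or `DNAStringSet` of fragments.
#' @param model A [MobEnsemble].
#' @return A data.frame with `fragment_id`, `predicted_class`, and one score
#'   column per class in the fixed order; score rows sum to 1.
#' @export
predictMob <- function(x, model) {
  stopifnot(is(model, "MobEnsemble"))
  ids <- names(x)
  seqs <- .asSequenceChar(x)
  if (is.null(ids)) ids <- paste0("fragment_", seq_along(seqs))
  classes <- model@classOrder

  # explode into segments, remembering fragment membership
  segSeq <- character(0); segFrag <- integer(0)
  for (i in seq_along(seqs)) {
    segs <- segmentFragment(seqs[i])
    segSeq <- c(segSeq, segs)
    segFrag <- c(segFrag, rep(i, length(segs)))
  }
  segLen <- nchar(segSeq)
  feat <- featurizeFragments(segSeq, model@embedding)
  usable <- feat$nTokens > 0L
  segBin <- rep(NA_character_, length(segSeq))
  segBin[usable] <- assignLengthBin(segLen[usable])

  segScores <- matrix(NA_real_, length(segSeq), length(classes),
                      dimnames = list(NULL, classes))
  for (b in unique(segBin[usable])) {
    idx <- which(usable & segBin == b)
    segScores[idx, ] <- .forestScores(model@forests[[b]],
                                      feat$features[idx, , drop = FALSE],
                                      classes)
  }

  scores <- matrix(NA_real_, length(seqs), length(classes),
                   dimnames = list(NULL, classes))
  pred <- rep("unclassified", length(seqs))
  for (i in seq_along(seqs)) {
    idx <- which(segFrag == i & usable)
    if (length(idx) == 0L) next
    scores[i, ] <- .weightScores(segScores[idx, , drop = FALSE], segLen[idx])
    pred[i] <- classes[which.max(scores[i, ])]
  }
  out <- data.frame(fragment_id = ids, predicted_class = pred,
                    stringsAsFactors = FALSE)
  sdf <- as.data.frame(scores)
  names(sdf) <- classes
  cbind(out, sdf)
}

#' Predict MOB class scores for metagenomic bins
#'
#' Scores every member fragment with [predictMob()], then combines the
#' fragments of each bin as the mean of their score vectors weighted by
#' fragment length. Bins whose members are all unclassifiable are reported
#' as `"unclassified"`.
#'
#' @param x Character vector or `DNAStringSet` of fragments (names are
#'   fragment ids).
#' @param bins Two-column mapping of `fragment_id` to `bin_id`
#'   ([readBinMetatable()]), or a named character vector.
#' @param model A [MobEnsemble].
#' @return A data.frame with `bin_id`, `predicted_class`, `n_fragments`,
#'   `total_length`, and one score column per class.
#' @export
predictMobBins <- function(x, bins, model) {
  if (is.data.frame(bins))
    bins <- stats::setNames(as.character(bins[[2]]), as.character(bins[[1]]))
  ids <- names(x)
  if (is.null(ids)) stop("fragments must be named to map them to bins")
  missing <- setdiff(names(bins), ids)
  if (length(missing))
    stop("metatable fragments absent from input: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- x[names(x) %in% names(bins)]
  fragPred <- predictMob(x, model)
  lens <- nchar(.asSequenceChar(x))
  classes <- model@classOrder
  scoreCols <- as.matrix(fragPred[, classes, drop = FALSE])
  binOf <- unname(bins[fragPred$fragment_id])

  out <- NULL
  for (b in unique(binOf)) {
    idx <- which(binOf == b)
    ok <- idx[!is.na(scoreCols[idx, 1L])]
    row <- data.frame(bin_id = b, predicted_class = "unclassified",
                      n_fragments = length(idx),
                      total_length = sum(lens[idx]),
                      stringsAsFactors = FALSE)
    sc <- rep(NA_real_, length(classes))
    if (length(ok)) {
      sc <- .weightScores(scoreCols[ok, , drop = FALSE], lens[ok])
      row$predicted_class <- classes[which.max(sc)]
    }
    sm <- as.data.frame(matrix(sc, nrow = 1L))
    names(sm) <- classes
    out <- rbind(out, cbind(row, sm))
  }
  out
}

#' Save / load a trained ensemble
#'
#' The archive is a single-object serialization bundling the four forests,
#' the embedding used at training time, the class order and the training
#' configuration, behind a format version tag. Bundling the embedding makes
#' an embedding/model mismatch impossible at prediction time.
#'
#' @param model A [MobEnsemble].
#' @param path Archive path (RDS).
#' @return `saveMobEnsemble()` invisibly returns `path`;
#'   `readMobEnsemble()` returns the [MobEnsemble].
#' @export
saveMobEnsemble <- function(model, path) {
  stopifnot(is(model, "MobEnsemble"))
  saveRDS(list(format = "plasmidMOB-ensemble-1", model = model), path)
  invisible(path)
}

#' @rdname saveMobEnsemble
#' @export
readMobEnsemble <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "plasmidMOB-ensemble-1"))
    stop("not a recognized ensemble archive: ", path)
  validObject(obj$model)
  obj$model
}
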