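#' Relaxase homology confidence score
#'
#' Confidence that a plasmid genome encodes a relaxase of a given MOB family,
#' combining the query coverage and bitscore of its best protein alignment:
#' \deqn{\sqrt{0.01 \cdot qcov_{max} \cdot (1 - 1/\log_{10}(bitscore_{max}))}}
#' The score is calibrated so that the working threshold of 0.5 corresponds
#' to a minimum query coverage of 50% together with a minimum bitscore
#' of 100. Bitscores at or below 10 make the bracket nonpositive; the score
#' is defined as 0 there (such hits can never reach the threshold).
#'
#' @param qcov Query coverage of the best-scoring hit, in percent (0-100).
#' @param bitscore Bitscore of the best-scoring hit (nonnegative).
#' @return Numeric vector of scores in \[0, 1\] (for qcov <= 100).
#' @examples
#' mobScore(50, 100)   # 0.5, the working threshold
#' mobScore(70, 1000)
#' @export
mobScore <- function(qcov, bitscore) {
  if (any(!is.finite(qcov)) || any(!is.finite(bitscore)))
    stop("qcov and bitscore must be finite")
  if (any(qcov < 0)) stop("qcov must be nonnegative")
  if (any(bitscore < 0)) stop("bitscore must be nonnegative")
  n <- max(length(qcov), length(bitscore))
  qcov <- rep_len(qcov, n)
  bitscore <- rep_len(bitscore, n)
  out <- numeric(n)
  ok <- bitscore > 10
  out[ok] <- sqrt(0.01 * qcov[ok] * (1 - 1 / log10(bitscore[ok])))
  out
}

.HIT_COLUMNS <- c("query_id", "subject_id", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore", "qcovs")

#' Read a tabular protein-alignment hit file
#'
#' Parses the standard 12-column tabular alignment format extended with a
#' 13th query-coverage column (`qcovs`), as produced by
#' `blastp -outfmt "6 std qcovs"`.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return A data.frame with columns `query_id`, `subject_id`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, `qcovs`.
#' @export
readAlignmentHits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty hit file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(.HIT_COLUMNS))
  if (length(bad))
    stop("malformed hit row at line ", bad[1L], ": expected ",
         length(.HIT_COLUMNS), " tab-separated columns, found ",
         lengths(fields)[bad[1L]])
  m <- do.call(rbind, fields)
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     stringsAsFactors = FALSE)
  numcols <- .HIT_COLUMNS[-(1:2)]
  for (i in seq_along(numcols)) {
    v <- suppressWarnings(as.numeric(m[, i + 2]))
    if (anyNA(v))
      stop("malformed hit row at line ", which(is.na(v))[1L],
           ": non-numeric value in column '", numcols[i], "'")
    hits[[numcols[i]]] <- v
  }
  if (any(hits$qcovs < 0 | hits$qcovs > 100))
    stop("query coverage must lie in [0, 100]")
  if (any(hits$evalue < 0) || any(hits$bitscore < 0))
    stop("e-values and bitscores must be nonnegative")
  hits
}

#' Filter alignment hits by homology thresholds
#'
#' Keeps hits meeting all three criteria used to build an unambiguous
#' relaxase reference set: e-value at most `eValueMax`, query coverage at
#' least `qcovMin` and percent identity at least `identityMin`.
#'
#' @param hits Hit data.frame as returned by [readAlignmentHits()].
#' @param eValueMax Maximum e-value (default 1e-10).
#' @param qcovMin Minimum query coverage in percent (default 70).
#' @param identityMin Minimum percent identity (default 70).
#' @return The subset of `hits` passing all thresholds.
#' @export
filterHomologHits <- function(hits, eValueMax = 1e-10, qcovMin = 70,
                              identityMin = 70) {
  stopifnot(is.data.frame(hits),
            all(c("evalue", "qcovs", "pident") %in% names(hits)))
  if (any(c(eValueMax, qcovMin, identityMin) < 0))
    stop("thresholds must be nonnegative")
  keep <- hits$evalue <= eValueMax & hits$qcovs >= qcovMin &
    hits$pident >= identityMin
  hits[keep, , drop = FALSE]
}

# best hit per (genome, class): maximum bitscore, ties by minimum e-value,
# then lexicographic subject_id
.bestHitPerClass <- function(hits) {
  ord <- order(hits$query_id, hits$mob_class, -hits$bitscore, hits$evalue,
               hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  keep <- !duplicated(h[, c("query_id", "mob_class")])
  h[keep, , drop = FALSE]
}

#' MOB-type complete plasmid genomes from relaxase alignment hits
#'
#' Assigns each genome one of the ten MOB classes or non-MOB. Hits are mapped
#' to MOB classes via `subjectClass`; per genome and class the best hit
#' (maximum bitscore, ties broken by minimum e-value then subject id) is
#' scored with [mobScore()]. Genomes with no hits, or whose hits all have
#' e-value above 0.01, are non-MOB. Otherwise the class whose best hit
#' maximizes the score is assigned, with confidence `"sure"` when that hit
#' has score above 0.5 and e-value at most 1e-10, else `"possible"`.
#'
#' @param hits Hit data.frame ([readAlignmentHits()]); `query_id` is the
#'   genome, `subject_id` the reference relaxase protein.
#' @param subjectClass Named character vector or two-column data.frame
#'   mapping `subject_id` to a MOB class.
#' @param genomeIds Character vector of all genomes under consideration
#'   (genomes without hits are classified non-MOB).
#' @return A data.frame with one row per genome: `genome_id`,
#'   `assigned_class`, `confidence` (`sure`/`possible`/`non-MOB`),
#'   `mob_score`, best-hit fields (`subject_id`, `qcovs`, `bitscore`,
#'   `evalue`) and `sure_classes` (comma-separated classes meeting the sure
#'   rule, used to flag ambiguous genomes).
#' @export
classifyGenomes <- function(hits, subjectClass, genomeIds) {
  if (is.data.frame(subjectClass))
    subjectClass <- stats::setNames(as.character(subjectClass[[2]]),
                                    as.character(subjectClass[[1]]))
  genomeIds <- as.character(genomeIds)
  if (any(!nzchar(genomeIds))) stop("empty genome id")
  if (anyDuplicated(genomeIds)) stop("duplicate genome ids")

  out <- data.frame(genome_id = genomeIds, assigned_class = "non-MOB",
                    confidence = "non-MOB", mob_score = NA_real_,
                    subject_id = NA_character_, qcovs = NA_real_,
                    bitscore = NA_real_, evalue = NA_real_,
                    sure_classes = "", stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)

  unknown <- setdiff(unique(hits$subject_id), names(subjectClass))
  if (length(unknown))
    stop("subjects without a MOB class mapping: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  hits$mob_class <- unname(subjectClass[hits$subject_id])
  hits <- hits[hits$query_id %in% genomeIds, , drop = FALSE]
  if (nrow(hits) == 0L) return(out)

  best <- .bestHitPerClass(hits)
  best$score <- mobScore(best$qcovs, best$bitscore)
  best$sure <- best$score > 0.5 & best$evalue <= 1e-10

  for (g in unique(best$query_id)) {
    b <- best[best$query_id == g, , drop = FALSE]
    i <- match(g, out$genome_id)
    usable <- b$evalue <= 0.01
    out$sure_classes[i] <- paste(sort(b$mob_class[b$sure]), collapse = ",")
    if (!any(usable)) next  # stays non-MOB
    b <- b[usable, , drop = FALSE]
    top <- b[order(-b$score, b$evalue, b$mob_class), , drop = FALSE][1L, ]
    out$assigned_class[i] <- top$mob_class
    out$confidence[i] <- if (top$sure) "sure" else "possible"
    out$mob_score[i] <- top$score
    out$subject_id[i] <- top$subject_id
    out$qcovs[i] <- top$qcovs
    out$bitscore[i] <- top$bitscore
    out$evalue[i] <- top$evalue
  }
  out
}

#' Retain unambiguous genomes for benchmarking
#'
#' Keeps only genomes suitable as benchmark truth: non-MOB genomes and
#' genomes confidently ("sure") assigned to exactly one MOB class. Genomes
#' meeting the sure rule in more than one class, and genomes with only
#' "possible" support, are excluded.
#'
#' @param labels Data.frame from [classifyGenomes()].
#' @return The retained subset of `labels`.
#' @export
buildBenchmarkLabels <- function(labels) {
  stopifnot(all(c("confidence", "sure_classes") %in% names(labels)))
  nSure <- ifelse(nzchar(labels$sure_classes),
                  lengths(strsplit(labels$sure_classes, ",", fixed = TRUE)),
                  0L)
  keep <- labels$confidence == "non-MOB" |
    (labels$confidence == "sure" & nSure == 1L)
  labels[keep, , drop = FALSE]
}

#' Write genome MOB labels to TSV
#'
#' @param labels Data.frame from [classifyGenomes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGenomeLabels <- function(labels, path) {
  .writeTsvAtomic(labels, path)
}
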