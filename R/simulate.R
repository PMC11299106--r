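#' Default synthetic class profiles
#'
#' Composition profiles for the eleven classes of the synthetic plasmid
#' benchmark. GC contents are the per-class values observed for real
#' MOB-typed plasmid collections (ranging from ~0.27 for MOBM to ~0.57 for
#' MOBQ), so the synthetic task's difficulty qualitatively mirrors reality:
#' several classes differ by less than one GC percentage point and are
#' separable only through their dinucleotide signatures. Each class
#' additionally carries a deterministic class-specific dinucleotide bias
#' (a +/-1 signature matrix exponentiated with strength `beta`), emulating
#' the compositional divergence of the distinct host clades that carry each
#' MOB family. Mean genome lengths are desk-scale (real collections average
#' ~2.7 kb for MOBM up to ~150 kb for MOBH; defaults scale these down
#' roughly tenfold, clamped to 3-15 kb).
#'
#' @param classes Character vector of class labels (default [mobClasses()]).
#' @param gc Numeric vector of target GC contents, one per class.
#' @param meanLength Integer vector of mean genome lengths (bp), one per
#'   class.
#' @param beta Dinucleotide-bias strength; 0 removes the class signature
#'   (default 0.25, matching typical bacterial dinucleotide odds-ratio
#'   magnitudes).
#' @return A data.frame with columns `class_label`, `gc_content`,
#'   `mean_genome_length`, `beta`.
#' @export
mobClassProfiles <- function(classes = mobClasses(),
                             gc = NULL, meanLength = NULL, beta = 0.25) {
  defaults <- data.frame(
    class_label = mobClasses(),
    gc_content = c(0.5127, 0.4714, 0.5207, 0.4837, 0.3457, 0.2712,
                   0.4970, 0.5677, 0.3692, 0.3775, 0.4984),
    mean_genome_length = c(3000L, 3000L, 10380L, 15000L, 5143L, 3000L,
                           3224L, 8936L, 3000L, 3000L, 3758L),
    stringsAsFactors = FALSE)
  idx <- match(classes, defaults$class_label)
  prof <- data.frame(class_label = classes, stringsAsFactors = FALSE)
  prof$gc_content <- if (is.null(gc)) {
    ifelse(is.na(idx), 0.5, defaults$gc_content[idx])
  } else rep_len(gc, length(classes))
  prof$mean_genome_length <- if (is.null(meanLength)) {
    as.integer(ifelse(is.na(idx), 5000L, defaults$mean_genome_length[idx]))
  } else as.integer(rep_len(meanLength, length(classes)))
  prof$beta <- beta
  stopifnot(all(prof$gc_content > 0 & prof$gc_content < 1),
            all(prof$mean_genome_length >= 2000L))
  prof
}

# deterministic per-class +/-1 dinucleotide signature (independent of the
# user's simulation seed, so a class always has the same signature)
.classSignature <- function(classIndex) {
  withSeed(7001L + classIndex,
           matrix(sample(c(-1, 1), 16L, replace = TRUE), 4L, 4L))
}

#' First-order Markov transition matrix with target GC
#'
#' Builds a row-stochastic transition matrix over A, C, G, T whose stationary
#' distribution has GC content `gc`, tilted by a positive 4x4 dinucleotide
#' weight matrix. The base composition is adjusted by a fixed-point
#' iteration until the stationary GC matches `gc` to within 1e-6.
#'
#' @param gc Target stationary GC content in (0, 1).
#' @param bias Positive 4x4 matrix of dinucleotide weights (rows = current
#'   base, columns = next base), default all ones.
#' @return List with `trans` (4x4 transition matrix) and `init` (stationary
#'   distribution, used as the start distribution).
#' @export
markovTransition <- function(gc, bias = matrix(1, 4, 4)) {
  stopifnot(gc > 0, gc < 1, all(bias > 0), all(dim(bias) == c(4L, 4L)))
  f <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  for (iter in 1:500) {
    trans <- bias * rep(f, each = 4L)
    trans <- trans / rowSums(trans)
    e <- eigen(t(trans))
    i <- which.min(abs(e$values - 1))
    stat <- Re(e$vectors[, i]); stat <- stat / sum(stat)
    gcReal <- stat[2L] + stat[3L]
    if (abs(gcReal - gc) < 1e-6) break
    f[c(2L, 3L)] <- f[c(2L, 3L)] * gc / gcReal
    f[c(1L, 4L)] <- f[c(1L, 4L)] * (1 - gc) / (1 - gcReal)
    f <- f / sum(f)
  }
  list(trans = trans, init = stat)
}

#' Simulate class-labeled plasmid genomes
#'
#' Draws `nGenomes` genome sequences per class from first-order Markov
#' chains built around the class profile. Classes are heterogeneous inside,
#' as real MOB classes are (each spans several host genera): every genome
#' gets its own GC content (normal around the class GC, sd `gcJitterSd`)
#' and its own dinucleotide log-weights (the class signature plus normal
#' noise, sd `biasJitterSd`). Genome lengths are uniform in
#' `lengthJitter * mean_genome_length`. Genomes are linear for all
#' downstream coordinate arithmetic (no wrap-around across the origin of
#' the circular plasmid). Deterministic given `seed`.
#'
#' @param profiles Data.frame from [mobClassProfiles()].
#' @param nGenomes Genomes per class (default 20).
#' @param seed Integer seed.
#' @param lengthJitter Length range as a fraction of the mean, default
#'   `c(0.8, 1.2)`.
#' @param gcJitterSd Per-genome GC standard deviation around the class GC
#'   (default 0.03; 0 makes every genome hit the class GC exactly).
#' @param biasJitterSd Per-genome dinucleotide log-weight noise (default
#'   0.35; 0 gives every genome the exact class signature).
#' @return A `DNAStringSet` named `<class>_g<i>` with `mcols` columns
#'   `class_label`, `genome_id` and `genome_gc` (the genome's target GC).
#' @export
simulateMobGenomes <- function(profiles = mobClassProfiles(), nGenomes = 20L,
                               seed = 1L, lengthJitter = c(0.8, 1.2),
                               gcJitterSd = 0.03, biasJitterSd = 0.35) {
  stopifnot(nGenomes >= 0L, gcJitterSd >= 0, biasJitterSd >= 0)
  seqs <- character(0); cls <- character(0); ids <- character(0)
  gcs <- numeric(0)
  if (nGenomes > 0L) {
    for (ci in seq_len(nrow(profiles))) {
      p <- profiles[ci, ]
      sig <- .classSignature(ci)
      draws <- withSeed(seed * 1000L + ci, {
        list(lens = as.integer(round(stats::runif(
               nGenomes, lengthJitter[1L] * p$mean_genome_length,
               lengthJitter[2L] * p$mean_genome_length))),
             gc = pmin(pmax(stats::rnorm(nGenomes, p$gc_content, gcJitterSd),
                            0.1), 0.9),
             noise = matrix(stats::rnorm(16L * nGenomes, 0, biasJitterSd),
                            nrow = 16L))
      })
      for (gi in seq_len(nGenomes)) {
        bias <- exp(p$beta * sig + matrix(draws$noise[, gi], 4L, 4L))
        mk <- markovTransition(draws$gc[gi], bias)
        seqs <- c(seqs, .markov_generate(mk$trans, mk$init, draws$lens[gi],
                                         as.numeric(seed) * 1e5 + ci * 1e3 + gi))
      }
      cls <- c(cls, rep(p$class_label, nGenomes))
      gcs <- c(gcs, draws$gc)
      ids <- c(ids, paste0(gsub("[^A-Za-z0-9]", "", p$class_label), "_g",
                           seq_len(nGenomes)))
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(class_label = cls,
                                                genome_id = ids,
                                                genome_gc = gcs)
  out
}

#' Split genomes into training and test sets
#'
#' Genome-level split performed independently within each class:
#' `round(trainFraction * n)` genomes go to training, the rest to test, so
#' no genome contributes fragments to both sides.
#'
#' @param genomes `DNAStringSet` from [simulateMobGenomes()] (requires an
#'   `mcols` column `class_label`).
#' @param trainFraction Fraction of genomes per class for training
#'   (default 0.7).
#' @param seed Integer seed.
#' @return Character vector of `"train"`/`"test"`, parallel to `genomes`;
#'   also stored in `mcols(genomes)$split` of the returned attribute-free
#'   copy when assigned by the caller.
#' @export
splitGenomes <- function(genomes, trainFraction = 0.7, seed = 1L) {
  cls <- S4Vectors::mcols(genomes)$class_label
  if (is.null(cls)) stop("genomes must carry an mcols class_label column")
  split <- character(length(genomes))
  withSeed(seed, {
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      if (length(idx) < 2L)
        stop("class '", cl, "' has fewer than 2 genomes; cannot split")
      nTrain <- round(trainFraction * length(idx))
      tr <- sample(idx, nTrain)
      split[idx] <- "test"
      split[tr] <- "train"
    }
  })
  split
}

#' Sample labeled fragments from genomes
#'
#' For each class, draws `nPerClass` fragments: a source genome is chosen
#' uniformly with replacement among the class's genomes long enough for the
#' range, the fragment length is uniform over `range` (capped by genome
#' length) and the start position uniform over valid positions. Classes with
#' no genome reaching the range minimum are skipped with a warning.
#'
#' @param genomes `DNAStringSet` with `mcols` `class_label` (and optionally
#'   `split`).
#' @param range Integer length-2 vector, inclusive fragment length range (bp).
#' @param nPerClass Fragments per class.
#' @param seed Integer seed.
#' @param label Optional tag stored in the `set` column (e.g. a bin or test
#'   group name).
#' @return A `DNAStringSet` of fragments with `mcols` columns
#'   `fragment_id`, `true_class`, `source_genome`, `length`, `set`.
#' @export
sampleFragments <- function(genomes, range, nPerClass, seed = 1L,
                            label = NA_character_) {
  stopifnot(length(range) == 2L, range[1L] >= 1L, range[2L] >= range[1L],
            nPerClass >= 0L)
  cls <- S4Vectors::mcols(genomes)$class_label
  if (is.null(cls)) stop("genomes must carry an mcols class_label column")
  gl <- Biostrings::width(genomes)
  seqsOut <- character(0); meta <- NULL
  withSeed(seed, {
    for (cl in unique(cls)) {
      if (nPerClass == 0L) next
      idx <- which(cls == cl & gl >= range[1L])
      if (length(idx) == 0L) {
        warning("class '", cl, "' has no genome of length >= ", range[1L],
                "; sampled 0 of ", nPerClass, " fragments")
        next
      }
      src <- sample(idx, nPerClass, replace = TRUE)
      lens <- pmin(sample(seq.int(range[1L], range[2L]), nPerClass,
                          replace = TRUE), gl[src])
      starts <- vapply(seq_len(nPerClass), function(i)
        sample.int(gl[src[i]] - lens[i] + 1L, 1L), integer(1))
      frs <- as.character(Biostrings::subseq(genomes[src], start = starts,
                                             width = lens))
      seqsOut <- c(seqsOut, unname(frs))
      meta <- rbind(meta, data.frame(
        true_class = rep(cl, nPerClass),
        source_genome = names(genomes)[src],
        length = lens, stringsAsFactors = FALSE))
    }
  })
  out <- Biostrings::DNAStringSet(seqsOut)
  n <- length(out)
  fid <- if (n) paste0("frag_", if (is.na(label)) "" else paste0(label, "_"),
                       seq_len(n)) else character(0)
  names(out) <- fid
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    fragment_id = fid,
    true_class = if (n) meta$true_class else character(0),
    source_genome = if (n) meta$source_genome else character(0),
    length = if (n) meta$length else integer(0),
    set = rep(label, n))
  out
}

#' Write a fragment set as FASTA plus manifest
#'
#' Writes the fragments as FASTA (ids as headers) and a TSV manifest with
#' the labeling columns (`fragment_id`, `true_class`, `source_genome`,
#' `length`, `set`).
#'
#' @param fragments `DNAStringSet` from [sampleFragments()].
#' @param fastaPath,manifestPath Output paths.
#' @return Invisibly, `fastaPath`.
#' @export
writeFragmentSet <- function(fragments, fastaPath, manifestPath) {
  Biostrings::writeXStringSet(fragments, fastaPath)
  .writeTsvAtomic(as.data.frame(S4Vectors::mcols(fragments)), manifestPath)
  invisible(fastaPath)
}
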