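# shared in-code fixtures: all test data are generated here, never stored

# a tiny alignment hit table in the 13-column tabular dialect
makeHitFile <- function(path, rows) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

hitRow <- function(query, subject, pident = 90, evalue = 1e-20,
                   bitscore = 500, qcovs = 90) {
  c(query, subject, pident, 200, 5, 0, 1, 200, 1, 200, evalue, bitscore, qcovs)
}

# small three-class world for classifier tests: strongly separated profiles
# so toy forests learn them from few fragments
toyWorld <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    classes <- c("MOBF", "MOBQ", "non-MOB")
    prof <- mobClassProfiles(classes = classes, gc = c(0.30, 0.50, 0.70),
                             meanLength = 4000L)
    genomes <- simulateMobGenomes(prof, nGenomes = 6, seed = 101)
    split <- splitGenomes(genomes, seed = 102)
    train <- genomes[split == "train"]
    emb <- trainKmerEmbedding(as.character(train), dim = 16, epochs = 3,
                              seed = 103)
    bins <- lengthBins()
    frags <- do.call(c, lapply(seq_len(4), function(i)
      sampleFragments(train, c(bins$lo[i], bins$hi[i]), 40, seed = 110 + i,
                      label = bins$bin[i])))
    # full 11-class order: the three simulated classes simply occupy three
    # of the eleven score columns
    ens <- trainMobEnsemble(frags, emb, nTrees = 60, seed = 104)
    cache <<- list(classes = classes, genomes = genomes, split = split,
                   emb = emb, ens = ens)
    cache
  }
})

randomDNA <- function(n, len, seed) {
  randomDNAFrom(c("A", "C", "G", "T"), n, len, seed)
}

randomDNAFrom <- function(alphabet, n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}
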