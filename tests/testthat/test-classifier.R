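# Length-binned forest ensemble: binning, segmentation, training, prediction.

test_that("length bins follow the documented edges", {
  expect_identical(assignLengthBin(50), "B1")    # short inputs use B1's model
  expect_identical(assignLengthBin(c(100, 400)), c("B1", "B1"))
  expect_identical(assignLengthBin(c(401, 800, 801, 1200, 1201, 1600)),
                   c("B2", "B2", "B3", "B3", "B4", "B4"))
  expect_error(assignLengthBin(1601), "segmentation")
  expect_error(assignLengthBin(0), ">= 1")
})

test_that("segmentation cuts greedily into 1600 bp pieces plus remainder", {
  s4000 <- strrep("ACGT", 1000)
  segs <- segmentFragment(s4000)
  expect_equal(nchar(segs), c(1600, 1600, 800))
  expect_identical(paste(segs, collapse = ""), s4000)

  s5000 <- strrep("A", 5000)
  expect_equal(nchar(segmentFragment(s5000)), c(1600, 1600, 1600, 200))
  # exact multiples have no remainder piece; short inputs pass through
  expect_equal(nchar(segmentFragment(strrep("A", 3200))), c(1600, 1600))
  expect_identical(segmentFragment("ACGTACGT"), "ACGTACGT")
  expect_equal(nchar(segmentFragment(strrep("A", 1600))), 1600)
  # round-trip on random lengths
  set.seed(61)
  for (L in sample(1601:9000, 5)) {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    expect_identical(paste(segmentFragment(s), collapse = ""), s)
  }
})

test_that("ensemble training produces four deterministic per-bin forests", {
  w <- toyWorld()
  expect_s4_class(w$ens, "MobEnsemble")
  expect_setequal(names(ensembleForests(w$ens)), c("B1", "B2", "B3", "B4"))
  expect_true(all(vapply(ensembleForests(w$ens), function(f) f$num.trees,
                         numeric(1)) == 60))
  probe <- sampleFragments(w$genomes[w$split == "test"], c(100, 1600), 10,
                           seed = 200)
  p1 <- predictMob(probe, w$ens)
  # retraining with the same seed reproduces predictions exactly
  bins <- lengthBins()
  train <- w$genomes[w$split == "train"]
  frags <- do.call(c, lapply(seq_len(4), function(i)
    sampleFragments(train, c(bins$lo[i], bins$hi[i]), 40, seed = 110 + i,
                    label = bins$bin[i])))
  ens2 <- trainMobEnsemble(frags, w$emb, nTrees = 60, seed = 104)
  p2 <- predictMob(probe, ens2)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("training refuses a bin with a single class", {
  w <- toyWorld()
  one <- sampleFragments(w$genomes[S4Vectors::mcols(w$genomes)$class_label ==
                                     "MOBF"],
                         c(100, 400), 10, seed = 1, label = "B1")
  expect_error(trainMobEnsemble(one, w$emb, nTrees = 10, seed = 1,
                                classes = w$classes),
               "fewer than 2 classes")
})

test_that("two classes with disjoint composition are learned perfectly", {
  # poly-AT versus poly-GC worlds share no 4-mer
  at <- randomDNAFrom(c("A", "T"), 40, 300, seed = 71)
  gc <- randomDNAFrom(c("G", "C"), 40, 300, seed = 72)
  emb <- trainKmerEmbedding(c(at, gc), dim = 8, epochs = 2, seed = 73)
  seqs <- c(at, gc)
  cls <- rep(c("MOBF", "MOBQ"), each = 40)
  # spread fragments across all four bins by padding length
  lens <- rep(c(150, 600, 1000, 1400), 20)
  seqs <- vapply(seq_along(seqs), function(i)
    strrep(seqs[i], ceiling(lens[i] / 300))[1], character(1))
  seqs <- substr(seqs, 1, lens)
  ens <- trainMobEnsemble(seqs, emb, trueClass = cls, nTrees = 50, seed = 74,
                          classes = c("MOBF", "MOBQ"))
  pred <- predictMob(seqs, ens)
  expect_true(all(pred$predicted_class == cls))
})

test_that("score vectors are valid distributions at all levels", {
  w <- toyWorld()
  te <- w$genomes[w$split == "test"]
  short <- sampleFragments(te, c(100, 1600), 30, seed = 301)
  long <- sampleFragments(te, c(3000, 4800), 10, seed = 302)
  for (fr in list(short, long)) {
    pred <- predictMob(fr, w$ens)
    sc <- as.matrix(pred[, w$classes])
    expect_true(all(abs(rowSums(sc) - 1) < 1e-9))
    expect_true(all(sc >= 0))
    # predicted class attains the row maximum
    expect_identical(pred$predicted_class,
                     w$classes[max.col(sc, ties.method = "first")])
  }
  bins <- data.frame(fragment_id = names(short),
                     bin_id = rep(sprintf("bin%02d", 1:18), 5))
  bp <- predictMobBins(short, bins, w$ens)
  bs <- as.matrix(bp[, w$classes])
  expect_true(all(abs(rowSums(bs) - 1) < 1e-9))
})

test_that("short fragments equal the raw per-bin model output", {
  w <- toyWorld()
  fr <- sampleFragments(w$genomes[w$split == "test"], c(801, 1200), 5,
                        seed = 303)
  pred <- predictMob(fr, w$ens)
  feats <- featurizeFragments(fr, w$emb)$features
  raw <- plasmidMOB:::.forestScores(ensembleForests(w$ens)$B3, feats,
                                    w$classes)
  expect_equal(unname(as.matrix(pred[, w$classes])), unname(raw),
               tolerance = 1e-12)
})

test_that("segment scores combine as a length-weighted mean", {
  # stubbed arithmetic on hand-set score vectors
  s1 <- c(0.8, 0.1, 0.1); s2 <- c(0.2, 0.5, 0.3)
  comb <- plasmidMOB:::.weightScores(rbind(s1, s2), c(1600, 800))
  expect_equal(unname(comb), (1600 * s1 + 800 * s2) / 2400)
  # weighted mean of identical vectors is that vector
  expect_equal(unname(plasmidMOB:::.weightScores(rbind(s1, s1, s1),
                                                 c(5, 7, 11))), s1)
  # fragment lengths 100 and 300 with vectors p, q -> (100 p + 300 q) / 400
  p <- c(0.6, 0.4, 0); q <- c(0, 0.3, 0.7)
  expect_equal(unname(plasmidMOB:::.weightScores(rbind(p, q), c(100, 300))),
               (100 * p + 300 * q) / 400)
})

test_that("unfeaturizable fragments are reported, not dropped", {
  w <- toyWorld()
  fr <- c(bad = "NNNNNNNN", good = strrep("ACGT", 100))
  pred <- predictMob(fr, w$ens)
  expect_equal(nrow(pred), 2)
  expect_identical(pred$predicted_class[1], "unclassified")
  expect_true(all(is.na(pred[1, w$classes])))
  expect_false(anyNA(pred[2, w$classes]))
})

test_that("model archives round-trip and reject foreign files", {
  w <- toyWorld()
  tmp <- withr::local_tempfile(fileext = ".rds")
  saveMobEnsemble(w$ens, tmp)
  back <- readMobEnsemble(tmp)
  probe <- sampleFragments(w$genomes[w$split == "test"], c(401, 800), 5,
                           seed = 304)
  expect_equal(predictMob(probe, back), predictMob(probe, w$ens))
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(readMobEnsemble(other), "not a recognized ensemble archive")
})
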