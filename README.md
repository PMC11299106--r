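# plasmidMOB

MOB typing of plasmid metagenomic fragments.

Plasmids are classified into **mobilization (MOB) types** by their relaxase
gene — the protein that initiates conjugative transfer at *oriT*. The ten
relaxase families (MOBB, MOBC, MOBF, MOBH, MOBL, MOBM, MOBP, MOBQ, MOBT,
MOBV) differ in transfer mechanism and host range, which makes MOB typing
central to tracking plasmid-borne antibiotic resistance. Metagenomic
assemblies, however, deliver plasmids as short fragments that rarely carry
the relaxase gene, so alignment-based typing fails there. plasmidMOB types
such fragments from sequence composition alone, placing each fragment (or
each metagenomic bin) into one of the ten MOB classes or a nonmobilizable
`non-MOB` class. It is aimed at microbiome researchers analysing
plasmid-derived contigs and bins from shotgun metagenomes.

## Method

1. **Reference labeling.** Complete plasmid genomes are labeled from
   protein-alignment hits of their coding sequences against a relaxase
   reference set. Per genome and class, the best hit (maximum bitscore) is
   scored with

   mob_score = sqrt( 0.01 · qcov_max · (1 − 1/log₁₀(bitscore_max)) )

   calibrated so that 0.5 corresponds to 50% query coverage with bitscore
   100. Genomes with no hit at e-value ≤ 0.01 are `non-MOB`; the
   best-scoring class wins otherwise, with confidence `sure` when
   mob_score > 0.5 and e-value ≤ 1e-10. Only `non-MOB` genomes and genomes
   sure in exactly one class are kept as benchmark truth.
2. **k-mer word vectors.** Sequences are read as sentences of overlapping
   4-mers and a skip-gram model with negative sampling (window 10 per side,
   10 epochs) learns a 100-dimensional vector per 4-mer. A fragment's
   feature vector is the mean of its k-mer vectors.
3. **Length-binned forest ensemble.** Four probability random forests
   (500 trees each) serve the ranges 100–400, 401–800, 801–1200 and
   1201–1600 bp. Fragments over 1600 bp are segmented greedily into 1600 bp
   pieces plus a remainder (4000 → 1600 + 1600 + 800); piece scores are
   combined as a length-weighted mean. Bins are scored as the
   length-weighted mean of their member fragments' score vectors.
4. **Evaluation.** Overall accuracy and Cohen's kappa; per-class balanced
   accuracy (TPR+TNR)/2, harmonic mean 2·Sn·Sp/(Sn+Sp) and F1; one-vs-rest
   ROC curves with trapezoid AUC.

A synthetic benchmark generator ships with the package: class-labeled
plasmid genomes from first-order Markov chains whose GC and dinucleotide
signatures echo real per-class composition, with within-class heterogeneity
so that the task is realistically hard. See the methods vignette
(`vignettes/mob-typing-methods.Rmd`) for the model details and the
generator's limitations.

## Worked example

Simulate a three-class world, train an embedding and ensemble, and type
held-out fragments:

```r
library(plasmidMOB)

classes <- c("MOBF", "MOBQ", "non-MOB")
profiles <- mobClassProfiles(classes = classes, gc = c(0.30, 0.50, 0.70),
                             meanLength = 4000L)
genomes <- simulateMobGenomes(profiles, nGenomes = 6, seed = 101)
split <- splitGenomes(genomes, seed = 102)
train <- genomes[split == "train"]

emb <- trainKmerEmbedding(as.character(train), dim = 16, epochs = 3,
                          seed = 103)
bins <- lengthBins()
frags <- do.call(c, lapply(1:4, function(i)
  sampleFragments(train, c(bins$lo[i], bins$hi[i]), 40, seed = 110 + i,
                  label = bins$bin[i])))
ens <- trainMobEnsemble(frags, emb, nTrees = 60, seed = 104)

test <- sampleFragments(genomes[split == "test"], c(801, 1200), 25,
                        seed = 200, label = "A")
pred <- predictMob(test, ens)
head(pred[, c("fragment_id", "predicted_class", classes)], 3)
ev <- evaluatePredictions(pred, S4Vectors::mcols(test)$true_class,
                          classes = classes)
ev$overall[c("accuracy", "kappa")]
```

Output:

```
  fragment_id predicted_class      MOBF      MOBQ non-MOB
1    frag_A_1            MOBF 1.0000000 0.0000000       0
2    frag_A_2            MOBF 1.0000000 0.0000000       0
3    frag_A_3            MOBF 0.6666667 0.3333333       0
$accuracy
[1] 1

$kappa
[1] 1
```

Each row gives the fragment id, the arg-max MOB class, and the class score
vector (a probability distribution over the classes, here the three used in
the toy world; the full model uses all eleven). With three widely separated
GC profiles the held-out fragments are typed perfectly. The 11-class
defaults, whose GC profiles overlap as in real plasmid collections, are
deliberately harder: the acceptance test computes held-out fragment
accuracy on the 801–1200 bp group and asserts it exceeds 60% (chance is
1/11 ≈ 9.1%); the runs behind this README landed near 80%, with bin-level
accuracy higher still.

The command-line surface wraps the same functions:

```sh
exec/mobtool simulate --n-genomes 20 --n-fragments 500 --seed 1 --out-prefix bench
exec/mobtool classify --input fragments.fasta --model model.rds --out mob_scores.tsv
```

`mob_scores.tsv` has 13 tab-separated columns: fragment id, predicted MOB
type, and the eleven class scores in the fixed order MOBB, MOBC, MOBF,
MOBH, MOBL, MOBM, MOBP, MOBQ, MOBT, MOBV, non-MOB.

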