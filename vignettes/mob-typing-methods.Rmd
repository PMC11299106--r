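---
title: "MOB typing of plasmid fragments: models and methods"
author: "plasmidMOB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MOB typing of plasmid fragments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plasmids are classified into mobilization (MOB) types by their relaxase
gene — the protein that nicks at *oriT* to initiate conjugative transfer.
The ten recognized relaxase families (MOBB, MOBC, MOBF, MOBH, MOBL, MOBM,
MOBP, MOBQ, MOBT, MOBV) differ in transmission mechanism and host range, so
MOB typing is central to tracking plasmid-mediated spread of resistance and
virulence genes. In shotgun metagenomes, however, plasmids arrive as short
assembly fragments that usually do not carry the relaxase gene at all, so
alignment-based typing fails. plasmidMOB instead learns the *compositional*
signature of each MOB class — plasmids sharing a mobilization system tend to
share hosts, and hence GC content, codon usage, and oligonucleotide
statistics — and types fragments from sequence composition alone, treating
nonmobilizable plasmids as an eleventh class (`non-MOB`).

## Reference labeling of complete genomes

Training labels for complete plasmid genomes come from protein alignments of
their coding sequences against a relaxase reference set with known classes.
For each genome and class we keep the best hit (maximum bitscore; ties broken
by minimum e-value, then subject id — the tie-break is our choice, made for
determinism) and score it with

$$\mathrm{mob\_score} = \sqrt{0.01 \cdot qcov_{max}
  \left(1 - \frac{1}{\log_{10} bitscore_{max}}\right)},$$

where $qcov_{max}$ and $bitscore_{max}$ are the query coverage (percent) and
bitscore of that hit. The score is calibrated so 0.5 corresponds to coverage
50% with bitscore 100. Bitscores $\le 10$ make the bracket nonpositive; we
define the score as 0 there, a conservative, monotone-consistent extension
(such hits can never reach the threshold, and the square root stays real).

A genome with no hits, or none with e-value $\le 0.01$, is `non-MOB`. The
best-scoring class otherwise wins; confidence is `"sure"` when the winning
hit has score $> 0.5$ *and* e-value $\le 10^{-10}$, else `"possible"`.
Benchmarks keep only `non-MOB` genomes and genomes sure in *exactly one*
class: `possible` genomes and multi-class ("ambiguous") genomes are removed,
because their labels are not reliable enough to train on. Whether scores
should instead be compared only within the top-hit class is underdetermined;
we compute per-class best hits, take the maximum-score class, and flag
multi-sure genomes for removal, which makes the removal rule independent of
that choice.

The package does not run any alignment search itself; it consumes the
standard 13-column tabular hit format (`blastp -outfmt "6 std qcovs"`) plus
a two-column subject-to-class map.

## k-mer word vectors

Fragments are featurized through a DNA language model. A sequence is read as
a sentence of overlapping k-mers (default $k = 4$, the standard word size for
metagenomic composition models): `ATCGCTGA` becomes `ATCG, TCGC, CGCT, GCTG,
CTGA`. Windows containing ambiguity characters (N or other IUPAC codes) are
dropped individually rather than discarding the whole sequence.

A skip-gram model with negative sampling maps each k-mer to a 100-dimensional
vector. Defaults: context window 10 words per side (20 context words total),
10 training epochs, 5 negative samples per context word, initial learning
rate 0.025 decayed linearly to near zero, vocabulary minimum count 1. The
trainer is a single-threaded C++ implementation of the classic word2vec
update rules with a $\mathrm{count}^{0.75}$ negative-sampling table and a
per-center dynamic window (effective half-width uniform on $1..10$); it uses
its own seeded RNG, so training is bit-reproducible given the seed. The
negative-sampling count and learning-rate schedule are common skip-gram
defaults — we do not claim they match any particular prior implementation —
and both are exposed as arguments. Frequent-word subsampling is deliberately
omitted: with a 256-word vocabulary every word is frequent, and subsampling
would discard most of the corpus.

The feature vector of a fragment is the arithmetic mean of the word vectors
of its in-vocabulary tokens (out-of-vocabulary tokens are skipped; a fragment
with no usable token is reported unclassifiable, never silently dropped).
The mean makes features length-invariant and order-free, and every feature
coordinate lies within the min/max of that coordinate over the fragment's
tokens — a property the test suite checks.

Two leakage-related choices: the embedding is trained on **training-split
genomes only** by default (training on all genomes would leak test
composition into the features; a caller can still pass any corpus
explicitly), and no reverse-complement canonicalization is applied — both
strands can be covered by adding reverse complements to the corpus if
desired.

## Length-binned forest ensemble

Composition estimates from a 150 bp fragment and a 1,500 bp fragment have
very different variance, so one model per length range works better than a
single model. Four probability random forests (500 trees each; probabilities
are per-class vote fractions, renormalized defensively) are trained on
fragments from the ranges 100–400, 401–800, 801–1,200 and 1,201–1,600 bp.
Prediction:

* length $\le 1600$: the fragment's bin model scores it directly (fragments
  shorter than 100 bp use the 100–400 bp model);
* length $> 1600$: the fragment is cut greedily left-to-right into
  $\lfloor L/1600\rfloor$ pieces of 1,600 bp plus a remainder (a 4,000 bp
  fragment gives 1,600 + 1,600 + 800), each piece is scored by its bin's
  model, and the piece score vectors are combined as their
  **length-weighted mean**. Whether the remainder should instead be balanced
  across pieces is not determined by the design we follow; greedy-left is
  chosen and documented, and the weighting makes the result insensitive to
  that choice when composition is homogeneous.

Metagenomic bins (clusters of fragments presumed to share a replicon) are
scored as the length-weighted mean of their member fragments' score vectors.
At every level — single model output, segment ensemble, bin — the score
vector is a convex combination of probability vectors, so it is nonnegative
and sums to 1; arg-max with ties broken by the fixed class order gives the
predicted class. The fixed order (MOBB, MOBC, MOBF, MOBH, MOBL, MOBM, MOBP,
MOBQ, MOBT, MOBV, non-MOB) is exported once (`mobClasses()`) and used by
every output table.

Model archives bundle the four forests *and* the embedding used at training
time (plus the class order and configuration) behind a format version tag,
so a model can never be applied with a mismatched embedding.

## The synthetic benchmark generator

Real benchmark construction requires tens of thousands of complete plasmid
genomes. The package instead ships a generator whose defaults emulate the
study conditions at desk scale, so the full pipeline is exercisable and
testable without downloads:

* **Class composition.** Each of the 11 classes is modeled by first-order
  Markov chains over A/C/G/T. Target class GC contents are the values
  observed in real MOB-typed plasmid collections (MOBM ≈ 0.27 up to MOBQ ≈
  0.57; several classes differ by under one GC point, which keeps the task
  honest). Each class carries a deterministic dinucleotide signature: a
  fixed ±1 matrix per class (seeded by class index, independent of the
  simulation seed) scaled by `beta = 0.25`, matching the magnitude of real
  bacterial dinucleotide odds-ratio deviations (|log ρ| ≲ 0.25); `beta` is
  the class-separability knob, and 0 removes the signature.
* **Within-class heterogeneity.** Real MOB classes are not compositional
  point masses — each spans several host genera. The generator therefore
  draws, per genome, its own GC (normal around the class GC, sd 0.03) and
  its own dinucleotide log-weights (class signature plus normal noise, sd
  0.35). The within-class spread is deliberately comparable to the
  between-class gaps inside the mid-GC cluster of classes, so desk-scale
  classification accuracy is substantial but not saturated — without
  heterogeneity the 11 chains are point hypotheses and the task collapses
  to triviality. For every genome the transition matrix is renormalized by
  a fixed-point adjustment of the base composition until the chain's
  stationary GC matches that genome's target to 1e-6.
* **Genome lengths.** Real per-class average genome lengths span ~2.7 kb
  (MOBM) to ~150 kb (MOBH). Defaults scale these down roughly tenfold,
  clamped to 3–15 kb, with ±20% uniform jitter — long enough for every
  fragment range used here while keeping simulation and embedding training
  at desk scale. Genomes are generated *linear*: plasmids are circular, but
  ignoring origin wrap-around only discards one fragment start position per
  genome, negligible at these scales.
* **Split and fragments.** Genomes are split 70/30 per class at genome level
  (no genome contributes fragments to both sides). Fragments are sampled per
  class with genomes drawn uniformly with replacement, lengths uniform over
  the requested range (capped by genome length), starts uniform over valid
  positions. Whether real fragment sampling should weight genomes by length
  is unknowable from composition alone; uniform-by-genome is the simple,
  documented choice. Default per-class training counts are desk-scale
  (2,000 per bin rather than the 90,000 of a full-scale build) and
  configurable.

What the generator does **not** emulate: sequencing error, read pairs,
coverage structure, assembly artifacts, chimeras, shared mobile elements
between classes, or phylogenetic correlation within a class. Passing tests
on synthetic data therefore demonstrate that the pipeline recovers
compositional class structure when it exists; they do not certify accuracy
on real metagenomes, where class signals are weaker and confounded.

## Evaluation suite

Overall: accuracy $P_o = \mathrm{trace}/N$ and Cohen's kappa
$\kappa = (P_o - P_e)/(1 - P_e)$ with the standard expected agreement
$P_e = \sum_i r_i c_i / N^2$ ($r_i$, $c_i$ row/column sums). Per class
(one-vs-rest): TPR, TNR, precision, balanced accuracy $(TPR + TNR)/2$,
harmonic mean $2\,Sn\,Sp/(Sn + Sp)$, and F1. When a denominator vanishes
(class never true or never predicted) the affected metrics are reported as 0
with an explicit degenerate flag. ROC curves are built one-vs-rest per class
by sweeping thresholds over the unique scores; AUC is the trapezoid area,
which equals the Mann–Whitney pair statistic with ties counted ½ — the test
suite verifies this equivalence against brute-force pair counting and
against an independent ROC implementation (pROC).

A kappa of 1 occurs exactly when the off-diagonal is empty; under label
independence kappa concentrates near 0 — both are property-tested.

## Numerical and degenerate-input conventions

* Score vectors renormalized after forest prediction (guards against
  vote-fraction rounding); validity asserted to 1e-9 in tests.
* Arg-max ties broken by first-in-class-order, for determinism.
* Fragments shorter than $k$, or consisting of ambiguity characters, get the
  sentinel class `unclassified` and blank scores in output tables (13
  columns: id, predicted type, 11 scores at 4 decimals).
* All tabular outputs are written to a temporary file and atomically
  renamed, so a failed run leaves no partial output.
* Every stochastic step (simulation, split, sampling, embedding, forests)
  takes an explicit seed; single-threaded runs are byte-reproducible.

## Problem sizes used by the shipped checks

The bundled tests and the acceptance script run the full pipeline at desk
scale: 11 classes × 20 genomes, 70/30 split, 2,000 training fragments per
class per bin (88,000 total), a 100-dimension embedding trained on the
training-split genomes, 500-tree forests, and a held-out test group of 500
fragments per class at 801–1,200 bp plus 5-fragment synthetic bins. Smaller
three-class worlds back the unit tests.
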