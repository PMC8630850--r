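---
title: "Predicting transgenerational DMRs with a hybrid CNN + gradient-boosting model"
author: "hybridDMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transgenerational DMRs with a hybrid CNN + gradient-boosting model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridDMR)
```

## The problem

Environmental toxicants administered to a gestating female can alter DNA
methylation in the germ line, and some of those alterations persist into
the F3 generation — the first generation with no direct exposure. A
1000 bp genomic window whose methylation differs between exposure-lineage
and control-lineage animals is a *differentially methylated region*
(DMR), or epimutation. Only a small fraction of the genome behaves this
way, and an obvious question is whether the DNA sequence of a window
predicts its susceptibility.

`hybridDMR` frames this as binary sequence classification. The genome is
tiled into non-overlapping 1000 bp windows. Windows called DMRs at
p < 10^-5 in *any* exposure dataset are positives (the union rule: a
region significant only under, say, atrazine still counts). Negatives
are windows with *zero* CpG dinucleotides: without a cytosine followed by
a guanine there is no methylation substrate, so these windows are
unambiguous non-DMRs. Windows with CpGs but no significant p-value are
left out of training entirely — failing a significance threshold does not
make a region a non-DMR. Two further negative definitions (CpG islands,
i.e. density above a configurable 10–20% cutoff, and windows with high
p-values) are implemented behind `buildDataset()` flags but disabled by
default; they add only a percent or two of negatives and have been
observed to hurt performance.

## The model

The classifier is a hybrid of two stages.

**Stage 1 — convolutional feature learning.** Each window is one-hot
encoded as a 5 × 1000 binary matrix (rows A, C, G, T, N). The network has
two convolutional blocks. Each block applies two convolutions of kernel
size 20 (32 filters in block 1, 64 in block 2) — the first unpadded, the
second length-preserving — each followed by batch normalization and then
ReLU; the block ends with max pooling of size 2 and dropout at rate 0.4.
A classifier head (dense 256, dense 128, dense 2 with softmax) is trained
with cross-entropy, the Adam optimizer, and early stopping: a stratified
10% of the training data is held out, and training stops when the
validation loss has not improved for 5 epochs, restoring the
best-validation weights. Class imbalance is countered by per-example loss
weights n_total / (2 n_class). The first convolution layer therefore has
exactly 32 kernels with a 5 × 20 receptive field (3232 parameters) and
produces a 32 × 981 activation map per window (981 = 1000 − 20 + 1).

**Stage 2 — boosted-tree classification on learned features.** After
training, every window is *re-expressed* as a 32-vector: each kernel's
activation map (taken after its batch normalization and ReLU, before any
pooling) is collapsed to a single value. The collapse is a global *mean*
by default — a density reading that also mirrors the average-output
convention by which detector kernels are categorized — with a global
maximum available as a motif-presence alternative that is invariant to
where a motif sits in the window. The mean is the default because the
classes differ in the *density* of what the kernels respond to (CpG-free
negatives against CpG-bearing positives): measured on the synthetic
fixture with a network at validation accuracy 1.0, mean-pooled features
carry the hybrid to held-out accuracy 1.00 while max-pooled features —
an extreme-value statistic over ~10^3 positions — reach only ~0.8.

An XGBoost ensemble (200 trees, depth 6, learning rate 0.1, positive
class weighted by n_nonDMR/n_DMR) is trained
on these features and makes the final DMR/non-DMR call. Whole-genome
scans (`scanGenome()`) use this hybrid path, not the network's softmax
head, with a 0.5 decision threshold.

The two-stage split buys three things: the boosted stage needs far less
data than a deep classifier head; XGBoost's gain-based importance ranks
the learned features (`featureImportance()`); and the first-layer kernels
are directly interpretable as sequence motifs.

## Kernel motifs

Each first-layer kernel is summarized as a position weight matrix
(`kernelMotifs()`): every length-20 subsequence whose activation reaches
at least a threshold fraction (default 0.5) of that kernel's maximum
activation over the whole dataset is collected, and the per-position base
frequencies over those subsequences form a 5 × 20 column-stochastic PWM.
The threshold fraction is a package choice — only "exceeds some
threshold" is prescribed — and mirrors common conv-motif visualization
practice. Kernels are categorized by the sign of their activation
difference (mean pooled activation over DMR examples minus non-DMR
examples): positive means a DMR detector, negative a non-DMR detector,
and an exact zero is assigned non-DMR with a note. `exportMotifs()`
writes MEME minimal format for downstream motif matching (the N row's
mass is redistributed uniformly over A, C, G, T because standard motif
tools use a 4-letter alphabet; the TSV export keeps all five rows).
Whether PWMs should be computed over all examples or positives only is
not prescribed; all examples is the default, and the subsequence scan
runs over whichever dataset is passed in.

## Evaluation protocol

`crossValidate()` runs stratified k-fold (default fivefold)
cross-validation. Within each fold, *both* stages are retrained from
scratch on that fold's training partition only; reusing a single network
trained on all data would leak test windows into the features. Folds are
stratified because the real datasets are heavily imbalanced. Metrics are
accuracy, precision (TP/(TP+FP)), recall (TP/(TP+FN)), and F1 as the
harmonic mean 2PR/(P+R); reported means are arithmetic means over folds.
A zero-denominator precision or recall is reported as 0 with a note.
`summarizeChromosomeCv()` assembles per-chromosome reports and averages
their accuracies unweighted, excluding any pooled "All" row from the
mean. The shipped reference table
(`ratCvReference()`) of published per-chromosome results for the rat
transgenerational DMR task is used in the tests to validate this
arithmetic: the harmonic-mean F1 reproduces the printed per-chromosome
F1 values from their printed precision/recall to printed precision,
whereas a "half the product over the sum" reading yields half the
correct value and is rejected; and the unweighted mean of the 22
per-chromosome accuracies reproduces the published 95.14%.

## The synthetic generator

Real training data require multi-gigabyte genomes and sequencing
archives, so the package carries a generator (`generateDataset()`) that
reproduces the *statistical shape* of the task at arbitrary scale:

* **Positives** are i.i.d. background sequence (uniform A/C/G/T by
  default, configurable GC bias) carrying `motifCopies` copies of a
  consensus 20-mer planted at uniform random non-overlapping positions,
  each copy mutated per position at the spec's rate, then topped up with
  CpG dinucleotides to a Poisson target (default mean 10, minimum 1) —
  roughly the CpG density of an average mammalian 1000 bp window.
* **Negatives** are CpG-free *by construction*: they are drawn from a
  first-order Markov chain that forbids the C→G transition, with the
  remaining transition mass solved so that the chain's stationary
  distribution equals the background exactly. A naive alternative —
  resampling the G of every CG — visibly depletes G (by about 0.07 under
  a uniform background) and would make the classes separable by base
  composition alone, which is not part of the task being emulated.
* `generateStatsTable()` emits the per-exposure p-value table the
  labeling step consumes (true positives drawn below 10^-6 under one
  random exposure, everything else above 0.1), and
  `assembleToyGenome()` concatenates shuffled windows into a FASTA whose
  re-tiling reproduces the windows bit-exactly, for end-to-end scan
  tests.

The generator reproduces the task's defining confound — CpG presence
alone separates the default classes, exactly as zero-CpG negatives do in
the real data — so a high synthetic accuracy demonstrates that the
pipeline learns and applies sequence features correctly, *not* that the
real-genome accuracy would be equally high. Real windows differ in ways
the generator does not emulate: repeat structure, CpG islands,
non-stationary composition, and DMR labels that are noisy outcomes of a
sequencing experiment rather than planted motifs. The
`cpgMatchedNegatives` mode removes the CpG shortcut and forces the model
onto the planted motif, which is the harder, more diagnostic setting for
feature learning.

## Numerical choices

* The network engine is implemented in the package itself: convolutions
  are lowered to shifted accumulating GEMMs through R's BLAS, and the
  elementwise layers (batchnorm, ReLU, max pooling, inverted dropout,
  Adam) are fused single-pass C++ loops. Everything is double precision
  and single-threaded, so seeded runs are bit-reproducible on a given
  platform (documented as best-effort across platforms, as BLAS
  summation order may differ). Dropout draws from R's RNG stream, so
  `set.seed` governs every source of randomness.
* Batch normalization uses ε = 10^-3 and running-statistics momentum
  0.9 (values in the usual framework range; not prescribed). Statistics
  are per channel over positions × batch; inference uses the running
  statistics, which is what makes prediction batch-invariant.
* Kernel initialization is variance-scaling (He) with the run seed;
  biases start at zero. Learning rate 10^-3, batch size 64 and an epoch
  cap of 100 are defaults for the values the published configuration
  does not pin down; all are configurable.
* Max pooling breaks ties toward the earliest position; a trailing
  remainder shorter than the pool is dropped, and a trailing genome
  remainder shorter than a window is likewise dropped (the input shape
  is fixed at 5 × 1000).
* Coordinates are 0-based half-open in every text representation
  (window keys, TSV, BED); in memory they live as 1-based `GRanges`, as
  is native to Bioconductor. Tiling is anchored at position 0 of each
  chromosome; IUPAC ambiguity codes collapse to N on input; CpG counting
  never counts an N-containing dinucleotide.

## Problem sizes used by the tests and acceptance script

Module tests run on reduced shapes (120 bp windows, 4 kernels of width
8) where a training run takes seconds; the correctness of the engine is
established there by numerical gradient checks against central
differences and by brute-force oracles (sliding-dot-product convolution,
confusion-matrix metrics, per-position PWM counts). The end-to-end
checks run the full 5 × 1000 architecture on the generator's default
conditions — 2,000 windows, one planted 20-mer, 10% mutation — with the
network stage capped at 2 epochs per fold for cross-validation (1 for
the shuffled-label null, which tests the pipeline's honesty rather than
convergence, and 4 for the single full-data model used for motif
recovery). The boosted stage on mean-pooled features carries the final
classification, so these short network schedules already saturate the
separable fixture; accuracies are insensitive to raising the cap.

## Known limitations

* Random 20-mer kernels already separate CpG-bearing positives from
  CpG-free negatives once pooled and boosted, so the default synthetic
  task validates the pipeline end to end but does not force deep motif
  learning; use `cpgMatchedNegatives = TRUE` for that.
* Recovering the planted consensus from the top-importance kernel's PWM
  is reported, not guaranteed: with CpG-free negatives the most
  important kernel is often a CpG detector rather than a motif detector,
  and a kernel may learn a shifted or partial version of the consensus.
* The engine targets 1000 bp × small-batch workloads on one CPU; it is
  not a general deep-learning framework (no GPU, no graph autodiff —
  the backward pass is hand-derived per layer and verified by finite
  differences).
* Whole-genome scans stream in bounded memory, but scanning a
  multi-gigabyte genome remains hours of CPU work; the operation is
  supported while its full-scale outputs are not part of the test
  surface.
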