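---
title: "Per-nucleotide mutation detection with temporal convolutional networks"
author: "mutTCN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-nucleotide mutation detection with temporal convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutTCN)
```

## The problem

Somatic mutation calling is usually framed as alignment followed by
variant inference against a reference genome. mutTCN implements a
different framing: per-nucleotide *sequence labeling*. A model reads a
DNA sequence and emits, for every nucleotide, one of four classes —
0 = normal, 1 = SNV (single-nucleotide variant), 2 = inserted base,
3 = deletion breakpoint. Once a sequence can be labeled this way, both
the *type* and the *index* of each mutation fall out of the label
vector directly, with no alignment step at prediction time: whatever
reference knowledge the model needs is internalized in its weights
during training.

The package provides the full pipeline around that idea: k-mer numeric
encodings of DNA, a temporal convolutional network (TCN) for the
labeling itself, a seeded mutation simulator that generates training
data with exact ground truth, class-imbalance handling, and the
evaluation stack (confusion matrices, per-class precision/recall/F1,
one-vs-rest ROC/AUC, and run-merged mutation calls).

## Input encoding

DNA sequences over `{A, C, G, T, N}` are mapped to integer codes by a
`KmerTable`:

* **Integer (1-mer) mapping** — the fixed table T=1, C=2, A=3, G=4.
  This table predates the k-mer scheme below and deliberately does not
  follow its ordering; it is special-cased verbatim.
* **k-mer mapping (k ≥ 2)** — the word at each position is read as a
  base-4 number under the digit order A=0, T=1, G=2, C=3, plus one. For
  2-mers this yields AA=1, AT=2, AG=3, AC=4, TA=5, …, CC=16 (m = 16
  codes); for 3-mers AAA=1 … CCC=64 (m = 64).

Code 0 is reserved for padding: any window that contains an `N` (or any
non-ACGT character, which is coerced to `N` with a warning) or that
overhangs the 3' end encodes to 0. Encoding is stride-1 with the window
anchored at its first base, so the code vector has exactly one entry
per nucleotide and stays aligned with the label vector. The anchoring
convention is a design choice: a sequence-labeling model needs equal
input and output lengths, and anchoring at the first base keeps the
causal network's receptive field looking strictly backwards.

```{r}
tab <- buildKmerTable(2)
encodedCodes(encodeSequence("AATTC", tab))
```

For the network, codes are expanded one-hot into an `(m+1) x n` binary
matrix; row 0 is the padding channel.

## Windowing

Long sequences are reshaped into fixed windows of `W = 150` positions
overlapping by `O = 50` (stride 100), the geometry used throughout the
reference pipeline. Windows open at offsets `0, S, 2S, …` for
`S = W - O`, a new window opening only while the previous one has not
reached the end of the sequence; the final window is right-padded with
code 0/label 0. Consecutive interior windows share exactly `O`
positions. At prediction time, overlapping windows are reconciled by
keeping the earliest window's positions (each position is reported
exactly once); an alternative mode averages class probabilities over
all covering windows before the argmax.

## The network

The model is a TCN for sequence labeling:

* **Causal dilated convolutions.** The convolution at position `t`
  computes `sum_i f(i) * x[t - d*i]` over `K` taps with dilation `d`,
  left-zero-padded so output length equals input length and no output
  depends on positions after `t`. With `d = 1` this is standard causal
  convolution.
* **Residual blocks.** One block per dilation factor (reference
  setting `[1, 2, 4, 8, 16, 32]`), each containing two convolutions
  (the canonical TCN block; the count is configurable) with weight
  normalization, ReLU, and spatial dropout after each, and a residual
  connection `o = ReLU(skip(x) + F(x))`. The skip is the identity when
  channel counts match and a 1x1 convolution otherwise.
* **Weight normalization** re-parameterizes every dilated-convolution
  filter as `w = g * v / ||v||`, decoupling scale from direction; the
  1x1 skip projection, the post-stack 1x1 convolution and the output
  projection are plain affine maps.
* **Spatial dropout** zeroes whole feature channels (per window) with
  probability 0.1 by default, rescaling survivors by `1/(1-rate)`.
* **Output head.** After the blocks, a 1x1 convolution (channel count
  preserved) with ReLU, then a position-shared affine map to 4 classes
  with a per-position softmax — the same map applied independently at
  every position, so output length always equals input length.

The receptive field is `1 + sum_blocks convs_per_block * (K-1) * d`;
for the reference setting (K = 16, dilations up to 32, 2 convolutions
per block) this is 1891 positions, comfortably beyond the 150-position
window.

```{r}
receptiveField(tcnConfig())
```

## Training

Windows are split 90:10 into train and test, stratified by whether a
window contains any mutated position. The train set (only) is
rebalanced by random under-sampling (RUS): windows with at least one
mutated position are all kept, and all-normal windows are subsampled to
at most `rus_ratio` (default 1.0) times their count.

The loss is per-position categorical cross-entropy averaged over
non-padding positions (positions with input code 0 are masked; the
masking can be disabled). Optimization is Adam at learning rate 0.0005
with batch size 256 and 100 epochs in the reference configuration. An
optional validation fraction carved from the train set (default 0.1) is
used for per-epoch reporting only — it never drives early stopping or
model selection. All randomness (splitting, RUS, shuffling, dropout,
initialization) derives from a single master seed, and on a
single-threaded BLAS a run is bit-reproducible.

Two numerical notes. First, the training step (forward, loss, backward)
runs in compiled code with single-precision internals; parameters,
gradients and the Adam state remain double precision. The compiled step
is tested against the package's double-precision reference
implementation of the same layers (finite-difference gradient checks
and layer-composition tests). Second, ties in the output argmax are
broken toward the lower class index, and degenerate metric
denominators follow fixed conventions (precision 0 when TP+FP = 0,
recall 0 when TP+FN = 0, F1 0 when P+R = 0).

## The simulator

Real mutation-call databases and hospital read sets cannot be
redistributed, so the package ships a seeded simulator that generates
structurally analogous data with exact truth:

* A reference panel of i.i.d. uniform random DNA (`n_refs` sequences of
  `ref_len` bp).
* Mutated samples derived from the panel round-robin. Per sample the
  mutation count is a zero-truncated Poisson draw (mean
  `muts_per_sample`, default 5 — a default chosen once as a realistic
  density for a few-hundred-bp panel: a handful of events per sample,
  so that windows typically contain between zero and a few mutated
  positions); types are drawn from `(SNV, INS, DEL)` proportions,
  default `(0.7633, 0.1079, 0.1288)`, the empirical shares observed in
  curated somatic mutation-call data with duplications folded into
  insertions. SNVs substitute a uniformly chosen different base;
  insertions add a uniform random string of 1–3 bp; deletions remove a
  1–3 bp span.
* Short reads: fixed-length substrings (at most 144 bp) at uniform
  random starts, each with the identically sliced label vector, with an
  optional SNV-only filter that mirrors annotation pipelines keeping
  only normal and SNV-containing reads.

Labeling conventions for indels are a documented choice: every inserted
base is labeled 2; deleted bases are absent from the sample, so the
single sample position immediately 3' of the deleted span carries the
label 3; collisions resolve by precedence deletion > insertion > SNV.
Mutations are placed at non-overlapping reference spans (a deletion
also claims its proxy base) and applied in ascending reference order
with a running coordinate shift, so the truth labels are well defined.
Record positions are 0-based on the mutated sample in memory and
1-based in every TSV on disk.

What the simulator does *not* emulate: sequencing errors, quality
scores, coverage structure, strand, and the long-range repeat and
homopolymer structure of real genomes. Tests passing on simulated data
therefore demonstrate that the pipeline is correct and that the
network can internalize reference structure and flag deviations — not
that the trained weights transfer to real patient data.

## Scaled-down study conditions

The packaged end-to-end check trains a reduced network (32 channels,
K = 8, dilations `[1, 2, 4, 8]`, 15 epochs, batch 64, learning rate
0.0005) on 3,000 SNV-only samples from a 4 x 300 bp panel, evaluating
on a held-out 10%. These sizes keep a full run on one CPU core in the
minutes range while preserving the structure of the full-scale
protocol; the vignette-scale examples in this document are smaller
still. The reference architecture (128 channels, K = 16, six dilation
levels) is the package default for real use.

## Evaluation

`evaluateModel()` masks padding positions, assembles the 4x4 confusion
matrix (rows true, columns predicted) and reports per-class
precision/recall/F1, the pooled (micro) F1 over the three mutation
classes, one-vs-rest AUC per mutation class (trapezoidal rule, equal to
the Mann-Whitney concordance statistic), and the headline number: the
unweighted macro-F1 over the mutation classes *present* in the truth.
Averaging only over present classes is deliberate — on SNV-only data,
counting the absent insertion and deletion classes as zero would pin
the macro average below 1/3 regardless of performance, making the
metric uninformative; absent classes are reported as NA instead.
Class 0 is excluded from the headline because its dominance makes
pooled-with-normal summaries uninformative.

`extractCalls()` turns a predicted label vector into calls by merging
maximal runs of identical nonzero labels, reporting 1-based start/end,
the type, and the mean probability of the called class over the run.
Note that adjacent same-type events merge into a single call by
construction.

## A worked example

```{r, message = FALSE}
cfg <- runConfig(seed = 11, n_refs = 2, ref_len = 300, n_samples = 12,
                 muts_per_sample = 6, n_channels = 8, kernel_size = 4,
                 dilations = c(1, 2), epochs = 2, batch_size = 16,
                 val_fraction = 0)
sim <- simulateDataset(cfg$simulator)
sim
ws <- windowDataset(simSamples(sim), simLabels(sim), buildKmerTable(2))
ws
sp <- trainTestSplit(ws, cfg$train)
fit <- trainModel(buildModel(cfg$tcn), randomUnderSample(sp$train, cfg$train),
                  cfg$train, quiet = TRUE)
evaluateModel(fit$model, sp$test)
```

Two epochs of a toy model are of course not expected to detect
anything; the block above demonstrates the mechanics and the report
format. See the README for a full-scale run and
`scripts/acceptance.R` for the reproducible reference computations.

## Known limitations

* The simulator's uniform random references make mutation detection a
  pure memorization task; there is no transfer between the simulated
  panel and any real genome.
* Deletion calls mark the breakpoint-adjacent base, not the deleted
  span; the span length is recoverable only from the truth records.
* Causal (backward-looking) convolution is kept for fidelity to the
  TCN architecture even though offline labeling could use centered
  context; positions near a window's start therefore see little
  context, which is also why overlapping windows are used.
* Training is single-threaded by design for reproducibility; wall-time
  scales linearly with window count.
* As in most rare-class sequence labelers trained with cross-entropy,
  optimization first fits the dominant normal class and can sit on that
  plateau for many epochs before per-position discrimination emerges;
  with a fixed small epoch budget a run may end while still on the
  plateau even though the same configuration trained longer succeeds.
  The packaged end-to-end check reports exactly what its prescribed
  budget achieves.
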