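# mutTCN

Per-nucleotide mutation detection in DNA sequences with temporal
convolutional networks (TCNs).

## What it does

mutTCN frames mutation calling as *sequence labeling*: a model reads a
DNA sequence and assigns every nucleotide one of four classes —
0 = normal, 1 = SNV, 2 = inserted base, 3 = deletion breakpoint. The
label vector directly yields the type and 1-based index of every
mutation in the sequence, with no alignment against a reference at
prediction time.

Sequences are first mapped to integer codes. The 1-mer (integer)
mapping is the fixed table T=1, C=2, A=3, G=4; for k ≥ 2 the code of a
k-mer *s* is the positional base-4 number

    code(s) = 1 + Σ_{j=0}^{k-1} digit(s_j) · 4^(k-1-j),   digit: A=0, T=1, G=2, C=3

so 2-mers map AA=1, AT=2, …, CC=16 (m = 4^k codes; code 0 is reserved
for padding/N). Codes are one-hot expanded to (m+1) × n and fed to the
network:

* stacked residual blocks of weight-normalized **causal dilated
  convolutions** F(x)(t) = Σ_i f(i)·x_{t−d·i}, one block per dilation
  d ∈ [1, 2, 4, 8, 16, 32], with ReLU and spatial dropout,
* a 1×1 convolution, and
* a position-shared softmax head over the 4 classes (output length =
  input length; position t never sees inputs after t).

The receptive field, 1 + Σ convs_per_block·(K−1)·d = 1891 positions for
the default (K = 16), spans far beyond the 150 bp analysis windows
(overlap 50) that long sequences are cut into.

Because real mutation databases and patient read sets cannot be
redistributed, the package includes a seeded simulator that generates
reference panels, mutated samples (SNV/insertion/deletion with default
type proportions 76.33 / 10.79 / 12.88 %) and short reads (≤ 144 bp)
with exact per-base truth labels, plus the training protocol (90:10
stratified split, random under-sampling of all-normal windows, Adam,
masked per-position cross-entropy) and the evaluation stack (confusion
matrix, per-class precision/recall/F1, one-vs-rest ROC/AUC, merged
mutation calls).

## Tests

```r
testthat::test_dir("tests/testthat", package = "mutTCN",
                   load_package = "installed")
```

## A worked example

```r
library(mutTCN)

cfg <- runConfig(seed = 11, n_refs = 2, ref_len = 300, n_samples = 12,
                 muts_per_sample = 6, n_channels = 8, kernel_size = 4,
                 dilations = c(1, 2), epochs = 2, batch_size = 16,
                 val_fraction = 0)
sim <- simulateDataset(cfg$simulator)
sim
#> MutSimData: 12 samples from 2 refs (300 bp), 97 mutation events
#>   SNV=76 INS=5 DEL=16, seed 11

ws <- windowDataset(simSamples(sim), simLabels(sim), buildKmerTable(2))
ws
#> WindowSet: 36 windows of 150 positions (overlap 50, k=2, m=16)
#>   34 windows contain mutations, 2 are all-normal
```

The `MutSimData` report counts simulated mutation events by type; the
`WindowSet` line shows how many 150 bp windows carry at least one
mutated position (the unit used for splitting and under-sampling).
Training and evaluation then run off these windows:

```r
sp  <- trainTestSplit(ws, cfg$train)
fit <- trainModel(buildModel(cfg$tcn),
                  randomUnderSample(sp$train, cfg$train),
                  cfg$train, quiet = TRUE)
evaluateModel(fit$model, sp$test)
#> EvalReport over 493 positions
#>         pred
#> true     normal SNV INS DEL
#>   normal    238  49 184  15
#>   SNV         4   1   2   0
#>   INS         0   0   0   0
#>   DEL         0   0   0   0
#>   normal P=0.9835 R=0.4897 F1=0.6538 (support 486)
#>   SNV    P=0.0200 R=0.1429 F1=0.0351 (support 7)
#>   ...
#>   macro-F1 (mutation classes): 0.0351, micro-F1: 0.0078
#>   AUC: SNV=0.4759
```

(Two epochs of a toy model are barely past random — the report format
is the point here. The per-class rows show precision/recall/F1 with
support; the headline macro-F1 averages F1 over the mutation classes
present in the truth, so the empty INS/DEL rows of this SNV-poor test
split do not enter the average.)

A shell front end wrapping the same functions ships in
`inst/cli/muttcn.R`:

```sh
Rscript inst/cli/muttcn.R simulate --config cfg.txt --out data/
Rscript inst/cli/muttcn.R train    --config cfg.txt --data data/ --out run/
Rscript inst/cli/muttcn.R predict  --checkpoint run/checkpoint.txt \
                                   --fasta query.fasta --out calls.tsv
Rscript inst/cli/muttcn.R evaluate --checkpoint run/checkpoint.txt \
                                   --data data/ --out report/
```

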