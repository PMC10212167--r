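## Independent oracles and shared fixtures for the test suite. Everything
## here is deliberately written in the most literal way possible (double
## loops, explicit counting) so it cannot share a bug with the vectorized
## implementations it checks.

## The full 2-mer conversion table, hard-coded entry by entry.
TABLE_2MER <- c(
    AA = 1, AT = 2, AG = 3, AC = 4,
    TA = 5, TT = 6, TG = 7, TC = 8,
    GA = 9, GT = 10, GG = 11, GC = 12,
    CA = 13, CT = 14, CG = 15, CC = 16)

## The full 3-mer conversion table.
TABLE_3MER <- c(
    AAA = 1, AAT = 2, AAG = 3, AAC = 4,
    ATA = 5, ATT = 6, ATG = 7, ATC = 8,
    AGA = 9, AGT = 10, AGG = 11, AGC = 12,
    ACA = 13, ACT = 14, ACG = 15, ACC = 16,
    TAA = 17, TAT = 18, TAG = 19, TAC = 20,
    TTA = 21, TTT = 22, TTG = 23, TTC = 24,
    TGA = 25, TGT = 26, TGG = 27, TGC = 28,
    TCA = 29, TCT = 30, TCG = 31, TCC = 32,
    GAA = 33, GAT = 34, GAG = 35, GAC = 36,
    GTA = 37, GTT = 38, GTG = 39, GTC = 40,
    GGA = 41, GGT = 42, GGG = 43, GGC = 44,
    GCA = 45, GCT = 46, GCG = 47, GCC = 48,
    CAA = 49, CAT = 50, CAG = 51, CAC = 52,
    CTA = 53, CTT = 54, CTG = 55, CTC = 56,
    CGA = 57, CGT = 58, CGG = 59, CGC = 60,
    CCA = 61, CCT = 62, CCG = 63, CCC = 64)

## brute-force causal dilated convolution: literal double loop over the
## defining sum, x taken as zero left of position 1
brute_conv <- function(x, f, d) {
    n <- length(x)
    K <- length(f)
    y <- numeric(n)
    for (t in seq_len(n)) {
        acc <- 0
        for (i in 0:(K - 1)) {
            j <- t - d * i
            if (j >= 1)
                acc <- acc + f[i + 1] * x[j]
        }
        y[t] <- acc
    }
    y
}

## position-by-position confusion counting
brute_confusion <- function(true, pred) {
    cm <- matrix(0L, 4, 4)
    for (i in seq_along(true))
        cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
    cm
}

## precision/recall/F1 by explicit TP/FP/FN counting over raw label vectors
brute_prf <- function(true, pred, cls) {
    tp <- sum(true == cls & pred == cls)
    fp <- sum(true != cls & pred == cls)
    fn <- sum(true == cls & pred != cls)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1)
}

## Mann-Whitney pairwise concordance: P(score_pos > score_neg) + ties/2
brute_auc <- function(pos_scores, neg_scores) {
    wins <- 0
    for (a in pos_scores)
        for (b in neg_scores)
            wins <- wins + (a > b) + 0.5 * (a == b)
    wins / (length(pos_scores) * length(neg_scores))
}

## small architecture used across the model tests
small_tcn_config <- function(seed = 1L, dropoutRate = 0, inDim = 17L,
                             nChannels = 6L, kernelSize = 4L,
                             dilations = c(1L, 2L)) {
    mutTCN:::tcnConfig(nChannels = nChannels, kernelSize = kernelSize,
                       dilations = dilations, convsPerBlock = 2L,
                       dropoutRate = dropoutRate, inDim = inDim,
                       seed = seed)
}

random_dna <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
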