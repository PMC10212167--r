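#' @include utils.R
NULL

#' KmerTable: the k-mer to integer-code mapping
#'
#' Maps every length-`k` DNA word over \{A,C,G,T\} to an integer code in
#' `1..m` with `m = 4^k`; code 0 is reserved for padding (any window touching
#' an `N` or running past the end of the sequence). For `k >= 2` the code is
#' the positional base-4 number of the word under the digit order A=0, T=1,
#' G=2, C=3, plus one, so `AA..A` is 1 and `CC..C` is `4^k`. The `k = 1`
#' table does not follow that ordering: it is the fixed integer mapping
#' T=1, C=2, A=3, G=4 used for single-nucleotide encoding.
#'
#' @slot k integer(1), nucleotides per code.
#' @slot codes named integer vector, a bijection from k-mers onto `1..m`.
#' @slot m integer(1), number of distinct non-padding codes, `4^k`.
#'
#' @seealso [buildKmerTable()], [encodeSequence()], [oneHotEncode()]
#' @exportClass KmerTable
setClass("KmerTable",
    representation(k = "integer", codes = "integer", m = "integer"))

setValidity("KmerTable", function(object) {
    msg <- character(0L)
    if (length(object@k) != 1L || object@k < 1L)
        msg <- c(msg, "'k' must be a single positive integer")
    if (object@m != 4L^object@k)
        msg <- c(msg, "'m' must equal 4^k")
    cod <- object@codes
    if (length(cod) != object@m || is.null(names(cod)) ||
        anyDuplicated(names(cod)) || !setequal(cod, seq_len(object@m)))
        msg <- c(msg, "'codes' must be a bijection from 4^k k-mers onto 1..m")
    if (length(msg)) msg else TRUE
})

#' @describeIn KmerTable number of k-mers per code
#' @param x,object a `KmerTable`
#' @export
kmerSize <- function(x) x@k

#' @describeIn KmerTable count of distinct non-padding codes (`4^k`)
#' @export
codeCount <- function(x) x@m

#' @describeIn KmerTable the named code vector (k-mer -> integer)
#' @export
kmerCodes <- function(x) x@codes

setMethod("show", "KmerTable", function(object) {
    cat(sprintf("KmerTable: k=%d, m=%d codes (pad code 0 reserved)\n",
                object@k, object@m))
    n <- min(6L, object@m)
    cat("  ", paste(sprintf("%s=%d", names(object@codes)[seq_len(n)],
                            object@codes[seq_len(n)]), collapse = " "),
        if (object@m > n) "...\n" else "\n")
})

#' Build the k-mer conversion table
#'
#' Constructs the mapping from DNA k-mers to integer codes. For `k >= 2` the
#' code of a word `s` is `1 + sum_j digit(s[j]) * 4^(k-1-j)` with digit order
#' A=0, T=1, G=2, C=3 (so for 2-mers AA=1, AT=2, AG=3, AC=4, TA=5, ...,
#' CC=16, and for 3-mers AAA=1 ... CCC=64). For `k = 1` the fixed integer
#' mapping T=1, C=2, A=3, G=4 is returned; it predates the k-mer ordering and
#' deliberately does not follow it.
#'
#' @param k integer(1), k-mer size, between 1 and 6.
#' @return a [KmerTable-class].
#' @examples
#' buildKmerTable(1)            # T=1 C=2 A=3 G=4
#' kmerCodes(buildKmerTable(2))[["AT"]]  # 2
#' @export
buildKmerTable <- function(k) {
    if (length(k) != 1L || is.na(k) || k < 1)
        stop("'k' must be a single integer >= 1")
    k <- as.integer(k)
    if (k > 6L)
        stop("k-mer sizes above 6 are not supported")
    if (k == 1L) {
        codes <- c(T = 1L, C = 2L, A = 3L, G = 4L)
    } else {
        grids <- rev(expand.grid(rep(list(KMER_DIGIT_ORDER), k),
                                 stringsAsFactors = FALSE))
        kmers <- do.call(paste0, grids)
        codes <- stats::setNames(seq_along(kmers), kmers)
    }
    new("KmerTable", k = k, codes = codes, m = as.integer(4^k))
}

#' EncodedSequence: integer code vector aligned to a DNA sequence
#'
#' One integer code per nucleotide position (stride-1, window anchored at its
#' first base), so labels stay position-aligned with the input. Positions
#' whose k-window contains a non-ACGT character, or overhangs the 3' end,
#' carry the padding code 0.
#'
#' @slot sourceId character(1), id of the encoded sequence.
#' @slot codes integer vector, entries in `0..m`.
#' @slot k integer(1), k-mer size used.
#' @slot m integer(1), code count of the table used.
#' @exportClass EncodedSequence
setClass("EncodedSequence",
    representation(sourceId = "character", codes = "integer",
                   k = "integer", m = "integer"))

setValidity("EncodedSequence", function(object) {
    if (length(object@codes) &&
        (min(object@codes) < 0L || max(object@codes) > object@m))
        return("codes must lie in 0..m")
    TRUE
})

#' @describeIn EncodedSequence the integer code vector
#' @param x an `EncodedSequence`
#' @export
encodedCodes <- function(x) x@codes

setMethod("show", "EncodedSequence", function(object) {
    cat(sprintf("EncodedSequence '%s': n=%d, k=%d, m=%d\n", object@sourceId,
                length(object@codes), object@k, object@m))
})

setMethod("length", "EncodedSequence", function(x) length(x@codes))

## core: character vector of bases -> integer codes (0 = padding)
encode_chars <- function(ch, k) {
    n <- length(ch)
    if (n == 0L)
        return(integer(0L))
    if (k == 1L) {
        d <- match(ch, c("T", "C", "A", "G"))
        d[is.na(d)] <- 0L
        return(as.integer(d))
    }
    d <- match(ch, KMER_DIGIT_ORDER) - 1L          # NA outside ACGT
    dpad <- c(d, rep(NA_integer_, k - 1L))
    acc <- numeric(n)
    ok <- rep(TRUE, n)
    idx <- seq_len(n)
    for (j in 0:(k - 1L)) {
        v <- dpad[idx + j]
        ok <- ok & !is.na(v)
        v[is.na(v)] <- 0L
        acc <- acc + v * 4^(k - 1L - j)
    }
    as.integer(ifelse(ok, acc + 1, 0))
}

#' Encode a DNA sequence as integer k-mer codes
#'
#' Slides a length-`k` window at stride 1 over the sequence and emits one
#' code per position (the window anchored at that position's base), keeping
#' the code vector the same length as the sequence. Windows containing `N`
#' (or any non-ACGT character, coerced to `N` with a warning) and windows
#' overhanging the 3' end yield code 0.
#'
#' @param seq a single character string, a [Biostrings::DNAString], or a
#'   length-1 [Biostrings::DNAStringSet].
#' @param table a [KmerTable-class] from [buildKmerTable()].
#' @param id sequence id; defaults to the FASTA name when present.
#' @return an [EncodedSequence-class] of the same length as `seq`.
#' @examples
#' encodedCodes(encodeSequence("TCAG", buildKmerTable(1)))   # 1 2 3 4
#' encodedCodes(encodeSequence("AATTC", buildKmerTable(2)))  # 1 2 6 8 0
#' @export
encodeSequence <- function(seq, table, id = NULL) {
    if (is(seq, "DNAStringSet")) {
        stopifnot(length(seq) == 1L)
        if (is.null(id))
            id <- names(seq)
        seq <- as.character(seq[[1L]])
    }
    if (is.null(id) || !length(id))
        id <- "seq"
    ch <- seq_chars(seq)
    new("EncodedSequence", sourceId = as.character(id),
        codes = encode_chars(ch, table@k), k = table@k, m = table@m)
}

#' Pad a DNA sequence to a fixed length with 'N'
#'
#' Appends `N` characters to the 3' end until the sequence has length `L`.
#' `N` encodes to the padding code 0 and is excluded from training loss and
#' evaluation metrics by default.
#'
#' @param seq character string (or DNAString/DNAStringSet of length 1).
#' @param L target length; must be at least the current length.
#' @return a character string of length `L`.
#' @export
padToLength <- function(seq, L) {
    if (is(seq, "DNAStringSet")) seq <- as.character(seq[[1L]])
    seq <- toupper(as.character(seq))
    n <- nchar(seq)
    if (n > L)
        stop(sprintf("sequence length %d exceeds target length %d", n, L))
    paste0(seq, strrep("N", L - n))
}

#' One-hot expand an integer code vector
#'
#' Expands codes in `0..m` into an `(m+1) x n` binary matrix whose column `t`
#' is the unit vector with a 1 at row `codes[t] + 1`; row 1 (index 0) is the
#' padding channel. This is the fixed embedding in front of the network.
#'
#' @param codes an [EncodedSequence-class] or integer vector with entries in
#'   `0..m`.
#' @param m number of non-padding codes (`4^k` for the table used).
#' @return numeric matrix of dimension `(m+1) x n`; every column sums to 1.
#' @export
oneHotEncode <- function(codes, m) {
    if (is(codes, "EncodedSequence")) {
        if (missing(m)) m <- codes@m
        codes <- codes@codes
    }
    codes <- as.integer(codes)
    if (length(codes) && max(codes) > m)
        stop("code exceeds m; sequence was encoded with a different table")
    if (length(codes) && min(codes) < 0L)
        stop("negative code")
    X <- matrix(0, nrow = m + 1L, ncol = length(codes))
    if (length(codes))
        X[cbind(codes + 1L, seq_along(codes))] <- 1
    X
}

#' LabelSequence: per-nucleotide class labels
#'
#' Integer labels aligned position-by-position to a sample sequence:
#' 0 = normal, 1 = SNV, 2 = inserted base, 3 = deletion breakpoint (the
#' sample base immediately 3' of a deleted span, since the deleted bases
#' themselves are absent from the sample).
#'
#' @slot sourceId character(1).
#' @slot labels integer vector over \{0,1,2,3\}.
#' @exportClass LabelSequence
setClass("LabelSequence",
    representation(sourceId = "character", labels = "integer"))

setValidity("LabelSequence", function(object) {
    if (length(object@labels) &&
        (min(object@labels) < 0L || max(object@labels) > 3L))
        return("labels must lie in {0,1,2,3}")
    TRUE
})

#' @describeIn LabelSequence the integer label vector
#' @param x a `LabelSequence`
#' @export
labelValues <- function(x) x@labels

setMethod("length", "LabelSequence", function(x) length(x@labels))

setMethod("show", "LabelSequence", function(object) {
    tab <- tabulate(object@labels + 1L, 4L)
    cat(sprintf("LabelSequence '%s': n=%d (normal=%d SNV=%d INS=%d DEL=%d)\n",
                object@sourceId, length(object@labels),
                tab[1L], tab[2L], tab[3L], tab[4L]))
})

#' Build the per-nucleotide label sequence from ground-truth records
#'
#' Positions default to 0 (normal). An SNV record labels its substituted
#' position 1; an insertion labels every inserted position 2; a deletion
#' labels the single sample position immediately following the deleted span
#' 3. When records collide on a position the precedence is
#' deletion > insertion > SNV. Record positions are 0-based indices on the
#' mutated sample sequence (see [MutationRecords]).
#'
#' @param sampleLength length of the sample sequence being labeled.
#' @param records a mutation-record `data.frame` (see [MutationRecords]);
#'   may have zero rows.
#' @param id sequence id for the result.
#' @return a [LabelSequence-class] of length `sampleLength`.
#' @export
makeLabelSequence <- function(sampleLength, records, id = "seq") {
    sampleLength <- as.integer(sampleLength)
    labels <- rep(LABEL_NORMAL, sampleLength)
    if (!is.null(records) && nrow(records)) {
        validateMutationRecords(records)
        spans <- record_label_spans(records)
        bad <- spans$start < 0L | spans$end > sampleLength - 1L
        if (any(bad)) {
            i <- which(bad)[1L]
            stop(sprintf(
                "invalid record %d (sample '%s', type %s, position %d): label position outside 0..%d",
                i, records$sample_id[i], records$type[i],
                records$position[i], sampleLength - 1L))
        }
        ## ascending precedence: later assignment wins (DEL > INS > SNV)
        for (lab in c(LABEL_SNV, LABEL_INS, LABEL_DEL)) {
            sel <- which(spans$label == lab)
            for (i in sel)
                labels[(spans$start[i] + 1L):(spans$end[i] + 1L)] <- lab
        }
    }
    new("LabelSequence", sourceId = as.character(id), labels = labels)
}

## per-record labeled span (0-based, inclusive) on the sample sequence
record_label_spans <- function(records) {
    type <- toupper(records$type)
    len <- as.integer(records$length)
    start <- as.integer(records$position)
    end <- ifelse(type == "INS", start + len - 1L, start)
    label <- ifelse(type == "SNV", LABEL_SNV,
             ifelse(type == "INS", LABEL_INS, LABEL_DEL))
    list(start = start, end = as.integer(end), label = as.integer(label))
}
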