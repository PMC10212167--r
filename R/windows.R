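#' @include encoding.R
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' WindowSet: fixed-length overlapping windows of codes and labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' sliding-window reshaped data that the network trains on. Rows are window
#' positions (1..W), columns are windows. Two integer assays, `"code"` and
#' `"label"`, are cut identically from each source sequence; `colData` keeps
#' the source id and the 0-based offset of each window. Window offsets step
#' by the stride `S = W - O`; a new window is opened only while the previous
#' one has not reached the end of the sequence, and the final window is
#' right-padded with code 0 / label 0. Consecutive windows that are fully
#' inside the source share exactly `O` positions.
#'
#' Metadata slots: `window` (W), `overlap` (O), `k`, `m`.
#'
#' @seealso [windowReshape()], [trainTestSplit()], [randomUnderSample()]
#' @exportClass WindowSet
setClass("WindowSet", contains = "SummarizedExperiment")

setValidity("WindowSet", function(object) {
    msg <- character(0L)
    if (!all(c("code", "label") %in% assayNames(object)))
        msg <- c(msg, "assays 'code' and 'label' are required")
    else {
        lab <- assay(object, "label")
        if (length(lab) && (min(lab) < 0L || max(lab) > 3L))
            msg <- c(msg, "labels must lie in {0,1,2,3}")
    }
    if (!all(c("source_id", "offset") %in% colnames(colData(object))))
        msg <- c(msg, "colData must have 'source_id' and 'offset'")
    md <- metadata(object)
    for (key in c("window", "overlap", "k", "m"))
        if (is.null(md[[key]]))
            msg <- c(msg, sprintf("metadata '%s' is required", key))
    if (length(msg)) msg else TRUE
})

new_window_set <- function(codes, labels, source_id, offset, W, O, k, m) {
    se <- SummarizedExperiment(
        assays = list(code = codes, label = labels),
        colData = DataFrame(source_id = source_id, offset = as.integer(offset)))
    metadata(se) <- list(window = as.integer(W), overlap = as.integer(O),
                         k = as.integer(k), m = as.integer(m))
    new("WindowSet", se)
}

#' @describeIn WindowSet `W x n` integer matrix of codes
#' @param x,object a `WindowSet`
#' @export
windowCodes <- function(x) assay(x, "code")

#' @describeIn WindowSet `W x n` integer matrix of labels
#' @export
windowLabels <- function(x) assay(x, "label")

#' @describeIn WindowSet 0-based offset of each window on its source
#' @export
windowOffsets <- function(x) colData(x)$offset

#' @describeIn WindowSet source sequence id of each window
#' @export
windowSources <- function(x) colData(x)$source_id

#' @describeIn WindowSet logical: does the window contain any mutated position
#' @export
windowHasMutation <- function(x) colSums(assay(x, "label") > 0L) > 0L

setMethod("show", "WindowSet", function(object) {
    md <- metadata(object)
    mut <- sum(windowHasMutation(object))
    cat(sprintf(
        "WindowSet: %d windows of %d positions (overlap %d, k=%d, m=%d)\n",
        ncol(object), md$window, md$overlap, md$k, md$m))
    cat(sprintf("  %d windows contain mutations, %d are all-normal\n",
                mut, ncol(object) - mut))
})

## offsets for one source of length n: 0, S, 2S, ... opening a new window
## only while the previous window's end (offset + W) is still short of n
window_offsets <- function(n, W, O) {
    S <- W - O
    k <- max(0, ceiling((n - W) / S))
    as.integer(S * (0:k))
}

#' Reshape a code/label pair into fixed-length overlapping windows
#'
#' Cuts an encoded sequence and its aligned label sequence into windows of
#' `W` positions overlapping by `O` (stride `W - O`). Both vectors are cut
#' identically; the final window is right-padded with code 0 / label 0.
#'
#' @param codes an [EncodedSequence-class] (or integer vector).
#' @param labels a [LabelSequence-class] (or integer vector) of equal length.
#' @param W window length in positions (150 for the reference pipeline).
#' @param O overlap between consecutive windows (50 for the reference
#'   pipeline).
#' @param k,m encoding parameters, taken from `codes` when it is an
#'   `EncodedSequence`.
#' @param id source id, taken from `codes` when available.
#' @return a [WindowSet-class].
#' @examples
#' tab <- buildKmerTable(2)
#' enc <- encodeSequence(strrep("ACGT", 90), tab)          # 360 bp
#' lab <- makeLabelSequence(360, NULL)
#' ws <- windowReshape(enc, lab, W = 150, O = 50)
#' windowOffsets(ws)   # 0 100 200
#' @export
windowReshape <- function(codes, labels, W = 150L, O = 50L,
                          k = NULL, m = NULL, id = NULL) {
    if (is(codes, "EncodedSequence")) {
        if (is.null(k)) k <- codes@k
        if (is.null(m)) m <- codes@m
        if (is.null(id)) id <- codes@sourceId
        codes <- codes@codes
    }
    if (is(labels, "LabelSequence"))
        labels <- labels@labels
    if (is.null(k)) k <- NA_integer_
    if (is.null(m)) m <- max(codes, 1L)
    if (is.null(id)) id <- "seq"
    if (O >= W || O < 0L)
        stop("overlap must satisfy 0 <= O < W")
    if (length(codes) != length(labels))
        stop("codes and labels must have equal length")
    n <- length(codes)
    offs <- window_offsets(n, W, O)
    cut1 <- function(v) {
        vapply(offs, function(o) {
            idx <- (o + 1L):(o + W)
            out <- rep(0L, W)
            keep <- idx <= n
            out[keep] <- v[idx[keep]]
            out
        }, integer(W))
    }
    cmat <- cut1(as.integer(codes))
    lmat <- cut1(as.integer(labels))
    if (length(offs) == 1L) {                      # vapply drops to vector? no,
        cmat <- matrix(cmat, nrow = W)             # vapply keeps matrix; guard
        lmat <- matrix(lmat, nrow = W)             # n=0 edge anyway
    }
    new_window_set(cmat, lmat, rep(as.character(id), length(offs)), offs,
                   W, O, k, m)
}

#' Write an encoded matrix as whitespace-delimited text
#'
#' Debugging aid: dumps a code (or label) matrix — positions in rows,
#' windows in columns — as plain space-delimited integers.
#'
#' @param x a [WindowSet-class], [EncodedSequence-class] or integer matrix.
#' @param path output file.
#' @param what for a `WindowSet`: which assay to write, `"code"` or
#'   `"label"`.
#' @return `path`, invisibly.
#' @export
writeEncodedMatrix <- function(x, path, what = c("code", "label")) {
    what <- match.arg(what)
    m <- if (is(x, "WindowSet")) assay(x, what)
         else if (is(x, "EncodedSequence")) matrix(x@codes, ncol = 1L)
         else as.matrix(x)
    write.table(m, path, sep = " ", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Window every sequence of a dataset into one WindowSet
#'
#' Encodes each sample with the given k-mer table, pairs it with its label
#' vector, windows each pair with [windowReshape()] and binds the windows
#' column-wise.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   samples.
#' @param labels named list of integer label vectors aligned to `seqs`.
#' @param table a [KmerTable-class].
#' @param W,O window length and overlap.
#' @return a [WindowSet-class] with one column per window over all samples.
#' @export
windowDataset <- function(seqs, labels, table, W = 150L, O = 50L) {
    ids <- names(seqs)
    if (is.null(ids))
        stop("'seqs' must be named")
    if (is(seqs, "DNAStringSet"))
        seqs <- as.character(seqs)
    S <- W - O
    pieces_c <- vector("list", length(ids))
    pieces_l <- vector("list", length(ids))
    src <- vector("list", length(ids))
    off <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        id <- ids[[i]]
        codes <- encode_chars(seq_chars(seqs[[i]]), table@k)
        lab <- as.integer(labels[[id]])
        if (length(lab) != length(codes))
            stop("label length mismatch for sequence '", id, "'")
        n <- length(codes)
        offs <- window_offsets(n, W, O)
        cm <- matrix(0L, W, length(offs))
        lm <- matrix(0L, W, length(offs))
        for (j in seq_along(offs)) {
            idx <- (offs[j] + 1L):(offs[j] + W)
            keep <- idx <= n
            cm[keep, j] <- codes[idx[keep]]
            lm[keep, j] <- lab[idx[keep]]
        }
        pieces_c[[i]] <- cm
        pieces_l[[i]] <- lm
        src[[i]] <- rep(id, length(offs))
        off[[i]] <- offs
    }
    new_window_set(do.call(cbind, pieces_c), do.call(cbind, pieces_l),
                   unlist(src), unlist(off), W, O, table@k, table@m)
}
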