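#' @import methods
#' @importFrom stats rpois runif rnorm
#' @importFrom utils read.delim write.table modifyList
#' @importFrom tools md5sum
#' @importFrom Rcpp evalCpp
#' @useDynLib mutTCN, .registration=TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

## digit order used by the k-mer (k >= 2) positional code: A=0, T=1, G=2, C=3
KMER_DIGIT_ORDER <- c("A", "T", "G", "C")

LABEL_NORMAL <- 0L
LABEL_SNV <- 1L
LABEL_INS <- 2L
LABEL_DEL <- 3L
LABEL_NAMES <- c("normal", "SNV", "INS", "DEL")

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so library calls do not perturb user code.
with_seed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old)
        old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
        if (has_old)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    expr
}

## Derive a stream-specific child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, stream) {
    (as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647
}

## Split a sequence into single characters, uppercased; anything outside
## A,C,G,T,N is coerced to 'N' with a warning (degraded, never an error).
seq_chars <- function(x) {
    ch <- strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]]
    bad <- !(ch %in% c(DNA_BASES, "N"))
    if (any(bad)) {
        warning(sprintf("%d character(s) outside {A,C,G,T,N} coerced to 'N'",
                        sum(bad)), call. = FALSE)
        ch[bad] <- "N"
    }
    ch
}

## key=value flat-file helpers (manifests, run configs, checkpoints)
write_kv <- function(x, path) {
    stopifnot(is.list(x))
    lines <- vapply(names(x), function(nm) {
        v <- x[[nm]]
        if (is.numeric(v))
            v <- paste(sprintf("%.17g", v), collapse = ",")
        else
            v <- paste(as.character(v), collapse = ",")
        paste0(nm, "=", v)
    }, character(1L))
    writeLines(lines, path)
    invisible(path)
}

read_kv <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    eq <- regexpr("=", lines, fixed = TRUE)
    if (any(eq < 0L))
        stop("malformed key=value line in ", path)
    keys <- substr(lines, 1L, eq - 1L)
    vals <- substring(lines, eq + 1L)
    stats::setNames(as.list(vals), keys)
}

kv_num <- function(kv, key, default = NULL) {
    if (is.null(kv[[key]])) {
        if (is.null(default))
            stop("missing required key '", key, "'")
        return(default)
    }
    as.numeric(strsplit(kv[[key]], ",", fixed = TRUE)[[1L]])
}

kv_chr <- function(kv, key, default = NULL) {
    if (is.null(kv[[key]])) {
        if (is.null(default))
            stop("missing required key '", key, "'")
        return(default)
    }
    kv[[key]]
}

kv_lgl <- function(kv, key, default = NULL) {
    if (is.null(kv[[key]])) {
        if (is.null(default))
            stop("missing required key '", key, "'")
        return(default)
    }
    toupper(kv[[key]]) %in% c("TRUE", "T", "1", "YES")
}
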