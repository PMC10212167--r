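#' @include encoding.R
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
NULL

#' Mutation-record tables
#'
#' Ground-truth mutation events are carried as a `data.frame` with one row
#' per event and columns:
#' \describe{
#'   \item{sample_id}{id of the mutated sample sequence}
#'   \item{ref_id}{id of the reference the sample was derived from}
#'   \item{position}{0-based index on the \emph{mutated sample} sequence: the
#'     substituted base (SNV), the first inserted base (INS), or the base
#'     immediately 3' of the deleted span (DEL)}
#'   \item{type}{one of `"SNV"`, `"INS"`, `"DEL"`}
#'   \item{ref_allele}{reference bases affected; empty string for INS}
#'   \item{alt_allele}{sample bases introduced; empty string for DEL}
#'   \item{length}{bases affected (1 for SNV)}
#' }
#' On disk (`mutations.tsv`) positions are reported 1-based; in memory they
#' are 0-based.
#'
#' @name MutationRecords
NULL

empty_records <- function() {
    data.frame(sample_id = character(0L), ref_id = character(0L),
               position = integer(0L), type = character(0L),
               ref_allele = character(0L), alt_allele = character(0L),
               length = integer(0L), stringsAsFactors = FALSE)
}

#' Validate a mutation-record data.frame
#'
#' Checks the column contract of [MutationRecords]: SNV rows carry single,
#' differing ref/alt alleles; INS rows an alt allele matching `length`; DEL
#' rows a ref allele matching `length`.
#'
#' @param records a mutation-record `data.frame`.
#' @return `records`, invisibly; errors describe the first offending row.
#' @export
validateMutationRecords <- function(records) {
    need <- c("sample_id", "ref_id", "position", "type", "ref_allele",
              "alt_allele", "length")
    miss <- setdiff(need, names(records))
    if (length(miss))
        stop("mutation records lack column(s): ", paste(miss, collapse = ", "))
    type <- toupper(records$type)
    if (!all(type %in% c("SNV", "INS", "DEL")))
        stop("record type must be SNV, INS or DEL")
    snv <- type == "SNV"
    if (any(snv & (nchar(records$ref_allele) != 1L |
                   nchar(records$alt_allele) != 1L |
                   records$ref_allele == records$alt_allele)))
        stop("SNV records need single, differing ref and alt alleles")
    ins <- type == "INS"
    if (any(ins & nchar(records$alt_allele) != records$length))
        stop("INS records need alt_allele of the stated length")
    del <- type == "DEL"
    if (any(del & nchar(records$ref_allele) != records$length))
        stop("DEL records need ref_allele of the stated length")
    if (any(records$position < 0L))
        stop("record positions are 0-based and must be >= 0")
    invisible(records)
}

#' SimulatorConfig: parameters of the seeded mutation simulator
#'
#' The simulator generates a reference panel of uniform random DNA, derives
#' mutated samples from it with known per-base truth labels, and optionally
#' slices short reads. It stands in for mutation-database-derived gene
#' samples (long sequences, all mutation types) and hospital-style short
#' reads (at most 144 bp, SNV-only after annotation filtering).
#'
#' @slot nRefs number of reference sequences.
#' @slot refLen reference length in bp.
#' @slot nSamples number of mutated samples (assigned round-robin to
#'   references).
#' @slot mutsPerSample mean mutation count per sample; actual counts are
#'   Poisson draws truncated to be at least 1.
#' @slot typeProps probability triple over (SNV, INS, DEL); default
#'   `(0.7633, 0.1079, 0.1288)`, the observed proportions in somatic
#'   mutation-call data (duplications folded into insertions).
#' @slot indelLenRange inclusive integer range of indel lengths, default 1..3.
#' @slot readLen short-read length, at most 144 bp.
#' @slot readsPerSample reads drawn per sample by [simulateReads()].
#' @slot seed master seed; every random draw derives from it.
#' @exportClass SimulatorConfig
setClass("SimulatorConfig",
    representation(nRefs = "integer", refLen = "integer",
                   nSamples = "integer", mutsPerSample = "numeric",
                   typeProps = "numeric", indelLenRange = "integer",
                   readLen = "integer", readsPerSample = "integer",
                   seed = "integer"))

setValidity("SimulatorConfig", function(object) {
    msg <- character(0L)
    if (abs(sum(object@typeProps) - 1) > 1e-9 || length(object@typeProps) != 3L ||
        any(object@typeProps < 0))
        msg <- c(msg, "typeProps must be 3 non-negative numbers summing to 1")
    if (object@readLen > 144L)
        msg <- c(msg, "readLen must be <= 144")
    for (s in c("nRefs", "refLen", "nSamples", "readLen", "readsPerSample"))
        if (slot(object, s) < 1L)
            msg <- c(msg, sprintf("'%s' must be positive", s))
    if (object@mutsPerSample <= 0)
        msg <- c(msg, "'mutsPerSample' must be positive")
    if (length(object@indelLenRange) != 2L ||
        object@indelLenRange[1L] < 1L ||
        object@indelLenRange[2L] < object@indelLenRange[1L])
        msg <- c(msg, "indelLenRange must be an increasing positive pair")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulatorConfig
#'
#' @param nRefs,refLen,nSamples,mutsPerSample,typeProps,indelLenRange,readLen,readsPerSample,seed
#'   see [SimulatorConfig-class].
#' @return a validated [SimulatorConfig-class].
#' @examples
#' cfg <- simulatorConfig(nRefs = 2, refLen = 200, nSamples = 10, seed = 7)
#' @export
simulatorConfig <- function(nRefs = 4L, refLen = 300L, nSamples = 100L,
                            mutsPerSample = 5,
                            typeProps = c(0.7633, 0.1079, 0.1288),
                            indelLenRange = c(1L, 3L),
                            readLen = 144L, readsPerSample = 1000L,
                            seed = 1L) {
    new("SimulatorConfig", nRefs = as.integer(nRefs),
        refLen = as.integer(refLen), nSamples = as.integer(nSamples),
        mutsPerSample = as.numeric(mutsPerSample),
        typeProps = as.numeric(typeProps),
        indelLenRange = as.integer(indelLenRange),
        readLen = as.integer(readLen),
        readsPerSample = as.integer(readsPerSample), seed = as.integer(seed))
}

setMethod("show", "SimulatorConfig", function(object) {
    cat(sprintf(
        "SimulatorConfig: %d refs x %d bp, %d samples, ~%.3g muts/sample\n",
        object@nRefs, object@refLen, object@nSamples, object@mutsPerSample))
    cat(sprintf("  type props SNV/INS/DEL = %.4f/%.4f/%.4f, indel len %d..%d\n",
                object@typeProps[1L], object@typeProps[2L],
                object@typeProps[3L], object@indelLenRange[1L],
                object@indelLenRange[2L]))
    cat(sprintf("  reads: %d x %d bp per sample, seed %d\n",
                object@readsPerSample, object@readLen, object@seed))
})

#' Generate a reference panel of uniform random DNA
#'
#' Draws `nRefs` sequences of exactly `refLen` i.i.d. uniform bases,
#' reproducibly from the config seed, with ids `ref_0 .. ref_{nRefs-1}`.
#'
#' @param cfg a [SimulatorConfig-class].
#' @return a [Biostrings::DNAStringSet] of length `nRefs`.
#' @export
generateReferences <- function(cfg) {
    stopifnot(is(cfg, "SimulatorConfig"))
    validObject(cfg)
    with_seed(derive_seed(cfg@seed, 1L), {
        seqs <- vapply(seq_len(cfg@nRefs), function(i)
            paste(sample(DNA_BASES, cfg@refLen, replace = TRUE),
                  collapse = ""), character(1L))
    })
    out <- DNAStringSet(seqs)
    names(out) <- paste0("ref_", seq_len(cfg@nRefs) - 1L)
    out
}

## draw a zero-truncated Poisson count by inversion (exact, O(1) even for
## tiny means, where rejection sampling would loop unboundedly)
draw_mut_count <- function(lambda) {
    p0 <- stats::dpois(0L, lambda)
    u <- stats::runif(1L, p0, 1)
    max(1L, stats::qpois(u, lambda))
}

#' Implant random mutations into one reference sequence
#'
#' Draws a truncated-Poisson number of mutations, assigns types from
#' `typeProps`, places them at non-overlapping reference positions, applies
#' them in ascending reference order while tracking the coordinate shift, and
#' returns the mutated sample together with its ground-truth records (sample
#' coordinates, 0-based) and per-base truth labels. SNVs substitute one base
#' with a uniformly chosen different base; insertions insert a uniform random
#' string ahead of a reference base; deletions remove a span (never the last
#' reference base, so the label-3 proxy position exists).
#'
#' Uses the current RNG stream; seed it (or call via [simulateDataset()])
#' for reproducibility.
#'
#' @param ref a single reference sequence (character or DNAStringSet element).
#' @param cfg a [SimulatorConfig-class].
#' @param sampleId id for the generated sample.
#' @param refId id of `ref` recorded in the truth table.
#' @return a list with elements `sample` (character), `records`
#'   ([MutationRecords] data.frame) and `truth` ([LabelSequence-class]).
#' @export
implantMutations <- function(ref, cfg, sampleId = "sample_0",
                             refId = "ref_0") {
    stopifnot(is(cfg, "SimulatorConfig"))
    if (is(ref, "DNAStringSet")) ref <- as.character(ref[[1L]])
    ch <- seq_chars(ref)
    R <- length(ch)
    if (R <= 2L * cfg@indelLenRange[2L])
        stop("reference too short for the configured indel lengths")
    nmut <- draw_mut_count(cfg@mutsPerSample)
    types <- sample(c("SNV", "INS", "DEL"), nmut, replace = TRUE,
                    prob = cfg@typeProps)
    lens <- ifelse(types == "SNV", 1L,
                   sample(seq(cfg@indelLenRange[1L], cfg@indelLenRange[2L]),
                          nmut, replace = TRUE))
    ## greedy non-overlapping placement of reference spans; a DEL also
    ## claims the base 3' of its span (the label-3 proxy), so no other
    ## event can land on the proxy position
    taken <- logical(R)
    pos <- integer(nmut)
    tries <- 0L
    for (i in seq_len(nmut)) {
        span <- if (types[i] == "DEL") lens[i] + 1L else 1L
        maxstart <- R - span
        repeat {
            tries <- tries + 1L
            if (tries > 1000L * nmut)
                stop("simulation infeasible: cannot place ", nmut,
                     " non-overlapping mutations on a ", R, " bp reference")
            p <- sample.int(maxstart + 1L, 1L) - 1L          # 0-based
            cells <- (p + 1L):(p + span)
            if (!any(taken[cells])) {
                taken[cells] <- TRUE
                pos[i] <- p
                break
            }
        }
    }
    ord <- order(pos)
    types <- types[ord]; lens <- lens[ord]; pos <- pos[ord]
    ## apply ascending with a running shift; record sample coordinates
    segs <- character(0L)
    rec <- vector("list", nmut)
    cursor <- 0L                                             # 0-based ref pos
    shift <- 0L
    for (i in seq_len(nmut)) {
        p <- pos[i]
        if (p > cursor)
            segs <- c(segs, paste(ch[(cursor + 1L):p], collapse = ""))
        q <- p + shift                                       # sample coord
        if (types[i] == "SNV") {
            old <- ch[p + 1L]
            newb <- sample(setdiff(DNA_BASES, old), 1L)
            segs <- c(segs, newb)
            rec[[i]] <- data.frame(sample_id = sampleId, ref_id = refId,
                                   position = q, type = "SNV",
                                   ref_allele = old, alt_allele = newb,
                                   length = 1L, stringsAsFactors = FALSE)
            cursor <- p + 1L
        } else if (types[i] == "INS") {
            insseq <- paste(sample(DNA_BASES, lens[i], replace = TRUE),
                            collapse = "")
            segs <- c(segs, insseq)                          # before ref base p
            rec[[i]] <- data.frame(sample_id = sampleId, ref_id = refId,
                                   position = q, type = "INS",
                                   ref_allele = "", alt_allele = insseq,
                                   length = lens[i], stringsAsFactors = FALSE)
            shift <- shift + lens[i]
            cursor <- p                                      # ref base p kept
        } else {                                             # DEL
            delseq <- paste(ch[(p + 1L):(p + lens[i])], collapse = "")
            rec[[i]] <- data.frame(sample_id = sampleId, ref_id = refId,
                                   position = q, type = "DEL",
                                   ref_allele = delseq, alt_allele = "",
                                   length = lens[i], stringsAsFactors = FALSE)
            shift <- shift - lens[i]
            cursor <- p + lens[i]
        }
    }
    if (cursor < R)
        segs <- c(segs, paste(ch[(cursor + 1L):R], collapse = ""))
    sample_seq <- paste(segs, collapse = "")
    records <- do.call(rbind, rec)
    truth <- makeLabelSequence(nchar(sample_seq), records, id = sampleId)
    list(sample = sample_seq, records = records, truth = truth)
}

## INS before a kept ref base never consumes it, so two events can share a
## boundary; the greedy placement above forbids that by claiming cell p.

#' Slice short reads from a mutated sample
#'
#' Draws `readsPerSample` substrings of length `readLen` at uniform random
#' start positions, each paired with the identically sliced truth labels.
#' With `snvOnly = TRUE`, reads containing any insertion or deletion label
#' are dropped, mirroring short-read annotation pipelines that keep only
#' normal and SNV-containing sequences.
#'
#' Uses the current RNG stream.
#'
#' @param sample sample sequence (character).
#' @param truth its [LabelSequence-class] (or integer vector).
#' @param cfg a [SimulatorConfig-class].
#' @param snvOnly drop reads containing labels 2 or 3.
#' @param materialize when `FALSE`, return only start coordinates (useful for
#'   assembly arithmetic on read sets too large to hold in memory).
#' @return a list with `starts` (0-based), and when materialized `reads`
#'   (character vector) and `labels` (list of integer vectors).
#' @export
simulateReads <- function(sample, truth, cfg, snvOnly = FALSE,
                          materialize = TRUE) {
    if (is(truth, "LabelSequence")) truth <- truth@labels
    n <- nchar(sample)
    L <- cfg@readLen
    if (L > n)
        stop(sprintf("read length %d exceeds sample length %d", L, n))
    starts <- sample.int(n - L + 1L, cfg@readsPerSample, replace = TRUE) - 1L
    labs <- lapply(starts, function(o) truth[(o + 1L):(o + L)])
    if (snvOnly) {
        keep <- !vapply(labs, function(v) any(v >= 2L), logical(1L))
        starts <- starts[keep]
        labs <- labs[keep]
    }
    out <- list(starts = starts)
    if (materialize) {
        out$reads <- substring(sample, starts + 1L, starts + L)
        out$labels <- labs
    } else {
        out$labels <- labs
    }
    out
}

#' Planned read count of a short-read assembly
#'
#' The number of read records an assembly of `nSamples` samples at
#' `readsPerSample` reads each will produce, computable without
#' materializing any sequence.
#'
#' @param cfg a [SimulatorConfig-class].
#' @return a double (may exceed integer range).
#' @examples
#' cfg <- simulatorConfig(nSamples = 24, readsPerSample = 500000)
#' plannedReadCount(cfg)   # 12,000,000
#' @export
plannedReadCount <- function(cfg) {
    as.double(cfg@nSamples) * as.double(cfg@readsPerSample)
}

#' Draw the read-start table for a whole sample set
#'
#' Seeded assembly of short-read records across samples: for each sample,
#' `readsPerSample` uniform start positions are drawn. Sequences are not
#' materialized; the result is the record table (sample id + 0-based start),
#' sufficient to count and locate every read.
#'
#' @param samples named character vector of sample sequences (or their
#'   lengths, as a named integer vector).
#' @param cfg a [SimulatorConfig-class].
#' @return a `data.frame` with columns `sample_id`, `start`.
#' @export
assembleReadSet <- function(samples, cfg) {
    lens <- if (is.numeric(samples)) as.integer(samples) else nchar(samples)
    ids <- names(samples)
    if (is.null(ids))
        stop("'samples' must be named")
    L <- cfg@readLen
    if (any(lens < L))
        stop("read length exceeds a sample length")
    with_seed(derive_seed(cfg@seed, 3L), {
        starts <- lapply(lens, function(n)
            sample.int(n - L + 1L, cfg@readsPerSample, replace = TRUE) - 1L)
    })
    data.frame(sample_id = rep(ids, each = cfg@readsPerSample),
               start = unlist(starts, use.names = FALSE),
               stringsAsFactors = FALSE)
}

#' MutSimData: a simulated dataset with ground truth
#'
#' Container for one simulator run: the reference panel, the mutated samples,
#' per-base truth labels, the mutation-record table and the generating
#' config.
#'
#' @slot refs [Biostrings::DNAStringSet] reference panel.
#' @slot samples [Biostrings::DNAStringSet] mutated samples.
#' @slot labels named list of integer label vectors, aligned to `samples`.
#' @slot records [MutationRecords] data.frame, all samples pooled.
#' @slot config the generating [SimulatorConfig-class].
#' @exportClass MutSimData
setClass("MutSimData",
    representation(refs = "DNAStringSet", samples = "DNAStringSet",
                   labels = "list", records = "data.frame",
                   config = "SimulatorConfig"))

setValidity("MutSimData", function(object) {
    msg <- character(0L)
    if (!identical(as.character(names(object@samples)),
                   as.character(names(object@labels))))
        msg <- c(msg, "samples and labels must share names and order")
    lens <- vapply(object@labels, length, integer(1L))
    if (length(lens) && any(lens != Biostrings::width(object@samples)))
        msg <- c(msg, "each label vector must match its sample length")
    if (length(msg)) msg else TRUE
})

#' @describeIn MutSimData the mutated sample sequences
#' @param x,object a `MutSimData`
#' @export
simSamples <- function(x) x@samples

#' @describeIn MutSimData the reference panel
#' @export
simRefs <- function(x) x@refs

#' @describeIn MutSimData named list of per-base truth label vectors
#' @export
simLabels <- function(x) x@labels

#' @describeIn MutSimData the pooled mutation-record table
#' @export
simRecords <- function(x) x@records

#' @describeIn MutSimData the generating config
#' @export
simConfig <- function(x) x@config

setMethod("show", "MutSimData", function(object) {
    tab <- table(factor(object@records$type, c("SNV", "INS", "DEL")))
    cat(sprintf(
        "MutSimData: %d samples from %d refs (%d bp), %d mutation events\n",
        length(object@samples), length(object@refs), object@config@refLen,
        nrow(object@records)))
    cat(sprintf("  SNV=%d INS=%d DEL=%d, seed %d\n", tab[["SNV"]],
                tab[["INS"]], tab[["DEL"]], object@config@seed))
})

#' Simulate a full dataset: references, samples, truth
#'
#' Generates the reference panel, assigns samples to references round-robin,
#' implants mutations per sample and collects truth labels and records. All
#' randomness derives from `cfg@seed`; identical configs give identical
#' datasets.
#'
#' @param cfg a [SimulatorConfig-class].
#' @return a [MutSimData-class].
#' @examples
#' sim <- simulateDataset(simulatorConfig(nSamples = 4, seed = 42))
#' sim
#' @export
simulateDataset <- function(cfg) {
    validObject(cfg)
    refs <- generateReferences(cfg)
    refs_chr <- as.character(refs)
    with_seed(derive_seed(cfg@seed, 2L), {
        out_seq <- character(cfg@nSamples)
        out_lab <- vector("list", cfg@nSamples)
        out_rec <- vector("list", cfg@nSamples)
        ids <- sprintf("sample_%d", seq_len(cfg@nSamples) - 1L)
        for (i in seq_len(cfg@nSamples)) {
            r <- ((i - 1L) %% cfg@nRefs) + 1L
            res <- implantMutations(refs_chr[[r]], cfg, sampleId = ids[i],
                                    refId = names(refs)[r])
            out_seq[i] <- res$sample
            out_lab[[i]] <- res$truth@labels
            out_rec[[i]] <- res$records
        }
    })
    samples <- DNAStringSet(out_seq)
    names(samples) <- ids
    names(out_lab) <- ids
    new("MutSimData", refs = refs, samples = samples, labels = out_lab,
        records = do.call(rbind, out_rec), config = cfg)
}
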