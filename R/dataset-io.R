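#' @include simulator.R
NULL

#' Export a simulated dataset to plain-text files
#'
#' Writes `refs.fasta`, `samples.fasta`, `labels.tsv` (columns `sequence_id`,
#' `labels` with comma-separated integers), `mutations.tsv` (1-based
#' positions) and `manifest.txt` (key=value lines recording the config and
#' seed). [loadDataset()] reproduces the in-memory object exactly from these
#' files.
#'
#' @param x a [MutSimData-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
exportDataset <- function(x, dir) {
    stopifnot(is(x, "MutSimData"))
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory '", dir, "'")
    writeXStringSet(x@refs, file.path(dir, "refs.fasta"))
    writeXStringSet(x@samples, file.path(dir, "samples.fasta"))
    lab <- data.frame(
        sequence_id = names(x@labels),
        labels = vapply(x@labels, paste, character(1L), collapse = ","),
        stringsAsFactors = FALSE)
    write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rec <- x@records
    out <- data.frame(sample_id = rec$sample_id, ref_id = rec$ref_id,
                      position_1based = rec$position + 1L, type = rec$type,
                      ref_allele = rec$ref_allele,
                      alt_allele = rec$alt_allele, length = rec$length,
                      stringsAsFactors = FALSE)
    write.table(out, file.path(dir, "mutations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfg <- x@config
    write_kv(list(
        format = "mutTCN-dataset-1",
        n_refs = cfg@nRefs, ref_len = cfg@refLen, n_samples = cfg@nSamples,
        muts_per_sample = cfg@mutsPerSample, type_props = cfg@typeProps,
        indel_len_range = cfg@indelLenRange, read_len = cfg@readLen,
        reads_per_sample = cfg@readsPerSample, seed = cfg@seed),
        file.path(dir, "manifest.txt"))
    invisible(dir)
}

#' Load a dataset written by exportDataset
#'
#' @param dir directory containing `samples.fasta`, `labels.tsv`,
#'   `mutations.tsv` and `manifest.txt` (plus `refs.fasta` if present).
#' @return a [MutSimData-class].
#' @export
loadDataset <- function(dir) {
    need <- c("samples.fasta", "labels.tsv", "mutations.tsv", "manifest.txt")
    miss <- need[!file.exists(file.path(dir, need))]
    if (length(miss))
        stop("dataset directory lacks file(s): ", paste(miss, collapse = ", "))
    kv <- read_kv(file.path(dir, "manifest.txt"))
    cfg <- simulatorConfig(
        nRefs = kv_num(kv, "n_refs"), refLen = kv_num(kv, "ref_len"),
        nSamples = kv_num(kv, "n_samples"),
        mutsPerSample = kv_num(kv, "muts_per_sample"),
        typeProps = kv_num(kv, "type_props"),
        indelLenRange = kv_num(kv, "indel_len_range"),
        readLen = kv_num(kv, "read_len"),
        readsPerSample = kv_num(kv, "reads_per_sample"),
        seed = kv_num(kv, "seed"))
    samples <- readDNAStringSet(file.path(dir, "samples.fasta"))
    refs <- if (file.exists(file.path(dir, "refs.fasta")))
        readDNAStringSet(file.path(dir, "refs.fasta"))
    else DNAStringSet()
    labpath <- file.path(dir, "labels.tsv")
    labtab <- if (length(readLines(labpath)) <= 1L)
        data.frame(sequence_id = character(0L), labels = character(0L))
    else read.delim(labpath, colClasses = c("character", "character"))
    labels <- lapply(labtab$labels, function(s)
        as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
    names(labels) <- labtab$sequence_id
    labels <- labels[names(samples)]
    rec <- read.delim(file.path(dir, "mutations.tsv"), colClasses = c(
        sample_id = "character", ref_id = "character",
        position_1based = "integer", type = "character",
        ref_allele = "character", alt_allele = "character",
        length = "integer"))
    rec$ref_allele[is.na(rec$ref_allele)] <- ""
    rec$alt_allele[is.na(rec$alt_allele)] <- ""
    records <- data.frame(sample_id = rec$sample_id, ref_id = rec$ref_id,
                          position = rec$position_1based - 1L,
                          type = rec$type, ref_allele = rec$ref_allele,
                          alt_allele = rec$alt_allele, length = rec$length,
                          stringsAsFactors = FALSE)
    if (nrow(records) == 0L)
        records <- empty_records()
    new("MutSimData", refs = refs, samples = samples, labels = labels,
        records = records, config = cfg)
}
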