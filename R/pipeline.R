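#' @include dataset-io.R evaluation.R
NULL

#' Run configuration: one key=value file for the whole pipeline
#'
#' `readRunConfig()` parses a flat key=value text file (comments with `#`,
#' lists comma-separated) and merges it over the defaults below;
#' `runConfig()` builds the same structure programmatically. The config
#' bundles the simulator, encoding, architecture and training parameters
#' plus the master seed, and round-trips losslessly through
#' `writeRunConfig()`.
#'
#' Keys and defaults: `seed` (1), `k` (2), `window` (150), `overlap` (50);
#' simulator: `n_refs` (4), `ref_len` (300), `n_samples` (100),
#' `muts_per_sample` (5), `type_props` (0.7633,0.1079,0.1288),
#' `indel_len_range` (1,3), `read_len` (144), `reads_per_sample` (1000);
#' model: `n_channels` (128), `kernel_size` (16), `dilations`
#' (1,2,4,8,16,32), `convs_per_block` (2), `dropout_rate` (0.1); training:
#' `learning_rate` (0.0005), `batch_size` (256), `epochs` (100),
#' `split_fraction` (0.9), `rus_enabled` (TRUE), `rus_ratio` (1),
#' `mask_padding` (TRUE), `val_fraction` (0.1).
#'
#' @param path file to read.
#' @param ... named overrides of the defaults (names as above).
#' @return a named list with sub-configs `simulator`
#'   ([SimulatorConfig-class]), `tcn` ([TCNConfig-class]), `train`
#'   ([TrainConfig-class]) plus `k`, `window`, `overlap`, `seed`.
#' @export
runConfig <- function(...) {
    opts <- list(...)
    defaults <- list(
        seed = 1, k = 2, window = 150, overlap = 50,
        n_refs = 4, ref_len = 300, n_samples = 100, muts_per_sample = 5,
        type_props = c(0.7633, 0.1079, 0.1288), indel_len_range = c(1, 3),
        read_len = 144, reads_per_sample = 1000,
        n_channels = 128, kernel_size = 16,
        dilations = c(1, 2, 4, 8, 16, 32), convs_per_block = 2,
        dropout_rate = 0.1,
        learning_rate = 0.0005, batch_size = 256, epochs = 100,
        split_fraction = 0.9, rus_enabled = TRUE, rus_ratio = 1,
        mask_padding = TRUE, val_fraction = 0.1)
    unknown <- setdiff(names(opts), names(defaults))
    if (length(unknown))
        stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
    v <- modifyList(defaults, opts)
    if (!v$k %in% 1:3)
        stop("k must be 1, 2 or 3")
    m <- 4^v$k
    structure(list(
        simulator = simulatorConfig(
            nRefs = v$n_refs, refLen = v$ref_len, nSamples = v$n_samples,
            mutsPerSample = v$muts_per_sample, typeProps = v$type_props,
            indelLenRange = v$indel_len_range, readLen = v$read_len,
            readsPerSample = v$reads_per_sample, seed = v$seed),
        tcn = tcnConfig(
            nChannels = v$n_channels, kernelSize = v$kernel_size,
            dilations = v$dilations, convsPerBlock = v$convs_per_block,
            dropoutRate = v$dropout_rate, inDim = m + 1, seed = v$seed),
        train = trainConfig(
            learningRate = v$learning_rate, batchSize = v$batch_size,
            epochs = v$epochs, seed = v$seed,
            splitFraction = v$split_fraction, rusEnabled = v$rus_enabled,
            rusRatio = v$rus_ratio, maskPadding = v$mask_padding,
            valFraction = v$val_fraction),
        k = as.integer(v$k), window = as.integer(v$window),
        overlap = as.integer(v$overlap), seed = as.integer(v$seed),
        raw = v), class = "muttcn_run_config")
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    kv <- read_kv(path)
    opts <- list()
    for (nm in names(kv)) {
        opts[[nm]] <- if (nm %in% c("rus_enabled", "mask_padding"))
            kv_lgl(kv, nm)
        else kv_num(kv, nm)
    }
    do.call(runConfig, opts)
}

#' @rdname runConfig
#' @param config a run config from `runConfig()`/`readRunConfig()`.
#' @export
writeRunConfig <- function(config, path) {
    write_kv(config$raw, path)
}

log_msg <- function(...) message(sprintf(...))

#' Simulate a dataset end to end and export it
#'
#' Runs the simulator with the config's parameters and seed and writes the
#' dataset files (see [exportDataset()]) into `outDir`.
#'
#' @param config a run config (see [runConfig()]).
#' @param outDir dataset output directory.
#' @return the [MutSimData-class], invisibly.
#' @export
runSimulate <- function(config, outDir) {
    sim <- simulateDataset(config$simulator)
    exportDataset(sim, outDir)
    log_msg("simulated %d samples from %d refs (seed %d): %d mutation events -> %s",
            length(simSamples(sim)), length(simRefs(sim)), config$seed,
            nrow(simRecords(sim)), outDir)
    invisible(sim)
}

#' Encode, window, split, undersample and train on an exported dataset
#'
#' The full training protocol: k-mer encode every sample, window with the
#' configured length/overlap, stratified 90:10 split, random under-sampling
#' of the train set, then optimization. Writes `checkpoint.txt`,
#' `history.tsv` and `manifest.txt` into `outDir`. With `resume = TRUE` an
#' existing checkpoint in `outDir` is loaded and training continues from
#' its epoch counter.
#'
#' @param config a run config (see [runConfig()]).
#' @param datasetDir directory written by [runSimulate()]/[exportDataset()].
#' @param outDir output directory for checkpoint and history.
#' @param resume continue from `outDir/checkpoint.txt`.
#' @param quiet suppress progress messages.
#' @return a list with `model`, `history`, and the held-out `test`
#'   [WindowSet-class], invisibly.
#' @export
runTrain <- function(config, datasetDir, outDir, resume = FALSE,
                     quiet = FALSE) {
    sim <- loadDataset(datasetDir)
    table <- buildKmerTable(config$k)
    windows <- windowDataset(simSamples(sim), simLabels(sim), table,
                             W = config$window, O = config$overlap)
    split <- trainTestSplit(windows, config$train)
    train <- if (config$train@rusEnabled)
        randomUnderSample(split$train, config$train) else split$train
    if (!quiet)
        log_msg("windows: %d train (%d after RUS) / %d test",
                ncol(split$train), ncol(train), ncol(split$test))
    ckpt <- file.path(outDir, "checkpoint.txt")
    if (resume) {
        if (!file.exists(ckpt))
            stop("no checkpoint to resume from in ", outDir)
        model <- readModelCheckpoint(ckpt)$model
    } else {
        model <- buildModel(config$tcn)
    }
    fit <- trainModel(model, train, config$train, quiet = quiet)
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    saveModelCheckpoint(fit$model, ckpt,
                        extra = list(k = config$k, window = config$window,
                                     overlap = config$overlap))
    hpath <- file.path(outDir, "history.tsv")
    write.table(fit$history, hpath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = !(resume && file.exists(hpath)),
                append = resume && file.exists(hpath))
    write_kv(list(
        command = "train", seed = config$seed, k = config$k,
        window = config$window, overlap = config$overlap,
        dataset_dir = normalizePath(datasetDir),
        dataset_manifest_md5 =
            unname(tools::md5sum(file.path(datasetDir, "manifest.txt"))),
        samples_md5 =
            unname(tools::md5sum(file.path(datasetDir, "samples.fasta"))),
        epochs_done = fit$model@epochsDone),
        file.path(outDir, "manifest.txt"))
    invisible(list(model = fit$model, history = fit$history,
                   test = split$test))
}

#' Predict mutation calls for FASTA sequences
#'
#' Encodes each input sequence with the checkpoint's k-mer table, windows
#' long sequences with the training window/overlap, predicts per-position
#' labels, reconciles overlapping windows and writes one call row per
#' merged run of identical nonzero labels (1-based coordinates).
#'
#' Overlap reconciliation: by default each position is taken from the
#' earliest window covering it (the later window's overlapping head is
#' dropped); with `vote = TRUE` the class probabilities of all covering
#' windows are averaged before the argmax.
#'
#' @param checkpoint path to a checkpoint written by [runTrain()].
#' @param fasta input FASTA file.
#' @param outTsv output calls TSV path.
#' @param vote average probabilities over covering windows instead of
#'   keeping the earliest.
#' @return the calls `data.frame`, invisibly.
#' @export
runPredict <- function(checkpoint, fasta, outTsv, vote = FALSE) {
    ck <- readModelCheckpoint(checkpoint)
    model <- ck$model
    k <- as.integer(ck$extra$k)
    W <- as.integer(ck$extra$window)
    O <- as.integer(ck$extra$overlap)
    table <- buildKmerTable(k)
    seqs <- readDNAStringSet(fasta)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("seq_%d", seq_along(seqs) - 1L)
    calls <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        id <- names(seqs)[i]
        enc <- encodeSequence(as.character(seqs[[i]]), table, id = id)
        n <- length(enc@codes)
        offs <- window_offsets(n, W, O)
        cm <- matrix(0L, W, length(offs))
        for (j in seq_along(offs)) {
            idx <- (offs[j] + 1L):(offs[j] + W)
            keep <- idx <= n
            cm[keep, j] <- enc@codes[idx[keep]]
        }
        res <- predictLabels(model, cm)
        probs <- array(t(res$probs), dim = c(4L, W, length(offs)))
        if (vote) {
            acc <- matrix(0, 4L, n)
            cnt <- numeric(n)
            for (j in seq_along(offs)) {
                pos <- (offs[j] + 1L):min(offs[j] + W, n)
                acc[, pos] <- acc[, pos] + probs[, seq_along(pos), j]
                cnt[pos] <- cnt[pos] + 1
            }
            pm <- t(acc / rep(cnt, each = 4L))
            lab <- max.col(pm, ties.method = "first") - 1L
        } else {
            pm <- matrix(0, n, 4L)
            lab <- integer(n)
            covered <- 0L
            for (j in seq_along(offs)) {
                from <- covered - offs[j] + 1L      # window-local start
                upto <- min(W, n - offs[j])
                if (from > upto) next
                pos <- (offs[j] + from):(offs[j] + upto)
                pm[pos, ] <- t(probs[, from:upto, j])
                lab[pos] <- res$labels[from:upto, j]
                covered <- offs[j] + upto
            }
        }
        calls[[i]] <- extractCalls(lab, pm, id = id)
    }
    out <- do.call(rbind, calls)
    write.table(out, outTsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}

#' Evaluate a checkpoint against a labeled dataset
#'
#' Windows the dataset exactly as in training, runs the model over every
#' window and writes `report.tsv` and `confusion.tsv` (see
#' [writeEvalReport()]) plus a manifest into `outDir`. The headline
#' macro-F1 over mutation classes is printed.
#'
#' @param checkpoint path to a checkpoint written by [runTrain()].
#' @param datasetDir labeled dataset directory.
#' @param outDir report output directory.
#' @return the [EvalReport-class], invisibly.
#' @export
runEvaluate <- function(checkpoint, datasetDir, outDir) {
    ck <- readModelCheckpoint(checkpoint)
    k <- as.integer(ck$extra$k)
    sim <- loadDataset(datasetDir)
    table <- buildKmerTable(k)
    windows <- windowDataset(simSamples(sim), simLabels(sim), table,
                             W = as.integer(ck$extra$window),
                             O = as.integer(ck$extra$overlap))
    report <- evaluateModel(ck$model, windows)
    writeEvalReport(report, outDir)
    write_kv(list(command = "evaluate",
                  checkpoint_md5 = unname(tools::md5sum(checkpoint)),
                  dataset_manifest_md5 = unname(
                      tools::md5sum(file.path(datasetDir, "manifest.txt"))),
                  n_windows = ncol(windows)),
             file.path(outDir, "manifest.txt"))
    log_msg("macro-F1 over mutation classes: %.4f",
            macroF1Mutations(report))
    invisible(report)
}
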