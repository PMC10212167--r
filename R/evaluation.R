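#' @include training.R
NULL

## raw 4x4 confusion counts from flat integer vectors (rows = true)
confusion_counts <- function(true, pred) {
    cm <- table(factor(true, levels = 0:3), factor(pred, levels = 0:3))
    cm <- matrix(as.integer(cm), 4L, 4L,
                 dimnames = list(true = LABEL_NAMES, pred = LABEL_NAMES))
    cm
}

#' Confusion matrix over per-position labels
#'
#' Counts (true, predicted) label pairs over all non-masked positions of a
#' set of paired label sequences. Rows are true classes, columns predicted,
#' in the order normal, SNV, INS, DEL.
#'
#' @param true,pred lists of equal-length integer label vectors (or
#'   [LabelSequence-class] objects, or single vectors/matrices).
#' @param codes optional input codes aligned to the labels; when given and
#'   `maskPadding` is `TRUE`, positions with code 0 are excluded.
#' @param maskPadding exclude padding positions (requires `codes`).
#' @return a 4x4 integer matrix.
#' @export
confusionMatrix <- function(true, pred, codes = NULL, maskPadding = TRUE) {
    norm <- function(x) {
        if (is(x, "LabelSequence")) return(list(x@labels))
        if (is.list(x)) return(lapply(x, function(v)
            if (is(v, "LabelSequence")) v@labels else as.integer(v)))
        list(as.integer(x))
    }
    tl <- norm(true)
    pl <- norm(pred)
    if (length(tl) != length(pl))
        stop("true and pred must pair up")
    for (i in seq_along(tl))
        if (length(tl[[i]]) != length(pl[[i]]))
            stop(sprintf("length mismatch between true and pred in sequence %d (%d vs %d)",
                         i, length(tl[[i]]), length(pl[[i]])))
    tv <- unlist(tl, use.names = FALSE)
    pv <- unlist(pl, use.names = FALSE)
    if (!is.null(codes) && maskPadding) {
        cv <- if (is.list(codes)) unlist(codes, use.names = FALSE)
              else as.integer(codes)
        if (length(cv) != length(tv))
            stop("codes must align with the labels")
        keep <- cv > 0L
        tv <- tv[keep]
        pv <- pv[keep]
    }
    confusion_counts(tv, pv)
}

#' Precision, recall and F1 for one class
#'
#' From a 4x4 confusion matrix (rows true, columns predicted):
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Zero-denominator
#' conventions: `TP + FP = 0` gives precision 0, `TP + FN = 0` gives
#' recall 0, and `precision + recall = 0` gives F1 0.
#'
#' @param confusion 4x4 count matrix.
#' @param class class index in 0..3 (0 = normal, 1 = SNV, 2 = INS,
#'   3 = DEL).
#' @return named numeric: `precision`, `recall`, `f1`.
#' @export
precisionRecallF1 <- function(confusion, class) {
    stopifnot(class %in% 0:3)
    c <- class + 1L
    tp <- confusion[c, c]
    fp <- sum(confusion[, c]) - tp
    fn <- sum(confusion[c, ]) - tp
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1)
}

## macro-F1 over the mutation classes (1..3) that actually occur in the
## truth; returns NA when no mutation class is present
macro_f1_mutations <- function(confusion) {
    present <- which(rowSums(confusion)[2:4] > 0L)
    if (!length(present))
        return(NA_real_)
    mean(vapply(present, function(c)
        precisionRecallF1(confusion, c)[["f1"]], numeric(1L)))
}

micro_f1_mutations <- function(confusion) {
    tp <- fp <- fn <- 0
    for (c in 2:4) {
        tp <- tp + confusion[c, c]
        fp <- fp + sum(confusion[, c]) - confusion[c, c]
        fn <- fn + sum(confusion[c, ]) - confusion[c, c]
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' One-vs-rest ROC AUC for one class
#'
#' Treats `probs[, class + 1]` as the score for membership of `class`,
#' sweeps all thresholds and integrates the ROC curve by the trapezoidal
#' rule. The result equals the Mann-Whitney pairwise-concordance statistic:
#' the probability that a random positive scores above a random negative,
#' with ties counted half.
#'
#' @param true integer label vector over 0..3.
#' @param probs `n x 4` matrix of class probabilities.
#' @param class class index in 0..3.
#' @return area in `[0, 1]`.
#' @export
rocAucOvr <- function(true, probs, class) {
    stopifnot(class %in% 0:3)
    true <- as.integer(true)
    pos <- true == class
    if (!any(pos))
        stop(sprintf("class %d absent from the true labels; AUC undefined",
                     class))
    if (all(pos))
        stop("all positions belong to the class; AUC undefined")
    score <- probs[, class + 1L]
    ord <- order(score, decreasing = TRUE)
    s <- score[ord]
    y <- pos[ord]
    ## threshold sweep: cut after each distinct score value
    tps <- cumsum(y)
    fps <- cumsum(!y)
    last <- c(s[-1L] != s[-length(s)], TRUE)
    tpr <- c(0, tps[last] / sum(y))
    fpr <- c(0, fps[last] / sum(!y))
    sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

#' Extract mutation calls from a predicted label sequence
#'
#' Merges maximal runs of identical nonzero labels into single calls with
#' 1-based inclusive coordinates, the mutation type (1 = SNV, 2 = INS,
#' 3 = DEL) and, when probabilities are supplied, the mean probability of
#' the called class over the run.
#'
#' @param pred a [LabelSequence-class] or integer label vector.
#' @param probs optional `n x 4` probability matrix aligned to `pred`.
#' @param id sequence id for the output table.
#' @return a `data.frame` with columns `sequence_id`, `start_1based`,
#'   `end_1based`, `type`, `mean_prob`, sorted by start; zero rows when no
#'   position is mutated.
#' @export
extractCalls <- function(pred, probs = NULL, id = NULL) {
    if (is(pred, "LabelSequence")) {
        if (is.null(id)) id <- pred@sourceId
        pred <- pred@labels
    }
    if (is.null(id)) id <- "seq"
    pred <- as.integer(pred)
    r <- rle(pred)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values > 0L
    mp <- rep(NA_real_, sum(keep))
    if (!is.null(probs)) {
        ks <- which(keep)
        mp <- vapply(seq_along(ks), function(i) {
            j <- ks[i]
            mean(probs[starts[j]:ends[j], r$values[j] + 1L])
        }, numeric(1L))
    }
    data.frame(sequence_id = rep(id, sum(keep)),
               start_1based = starts[keep], end_1based = ends[keep],
               type = c("SNV", "INS", "DEL")[r$values[keep]],
               mean_prob = mp, stringsAsFactors = FALSE)
}

#' EvalReport: confusion matrix and per-class metrics
#'
#' @slot confusion 4x4 count matrix, rows true, columns predicted.
#' @slot perClass data.frame with per-class TP/FP/FN, precision, recall,
#'   F1 and support.
#' @slot macroF1Mutations unweighted mean F1 over the mutation classes
#'   (SNV/INS/DEL) present in the truth; `NA` if none is present.
#' @slot microF1 pooled precision/recall F1 over the mutation classes.
#' @slot auc named numeric of one-vs-rest AUCs for SNV/INS/DEL (`NA` where
#'   the class is absent).
#' @slot nPositions evaluated (non-masked) position count.
#' @exportClass EvalReport
setClass("EvalReport",
    representation(confusion = "matrix", perClass = "data.frame",
                   macroF1Mutations = "numeric", microF1 = "numeric",
                   auc = "numeric", nPositions = "integer"))

setValidity("EvalReport", function(object) {
    if (!identical(dim(object@confusion), c(4L, 4L)))
        return("confusion must be 4x4")
    if (sum(object@confusion) != object@nPositions)
        return("confusion entries must sum to nPositions")
    TRUE
})

#' @describeIn EvalReport headline metric: macro-F1 over mutation classes
#' @param x,object an `EvalReport`
#' @export
macroF1Mutations <- function(x) x@macroF1Mutations

#' @describeIn EvalReport per-class metric table
#' @export
perClassMetrics <- function(x) x@perClass

#' @describeIn EvalReport the confusion matrix
#' @export
evalConfusion <- function(x) x@confusion

setMethod("show", "EvalReport", function(object) {
    cat(sprintf("EvalReport over %d positions\n", object@nPositions))
    print(object@confusion)
    pc <- object@perClass
    for (i in seq_len(nrow(pc)))
        cat(sprintf("  %-6s P=%.4f R=%.4f F1=%.4f (support %d)\n",
                    pc$class[i], pc$precision[i], pc$recall[i], pc$f1[i],
                    pc$support[i]))
    cat(sprintf("  macro-F1 (mutation classes): %.4f, micro-F1: %.4f\n",
                object@macroF1Mutations, object@microF1))
    if (any(!is.na(object@auc)))
        cat("  AUC:", paste(sprintf("%s=%.4f", names(object@auc),
                                    object@auc)[!is.na(object@auc)],
                            collapse = " "), "\n")
})

## build an EvalReport from flat truth/pred/probs vectors
build_eval_report <- function(true, pred, probs = NULL) {
    cm <- confusion_counts(true, pred)
    pc <- do.call(rbind, lapply(0:3, function(c) {
        prf <- precisionRecallF1(cm, c)
        data.frame(class = LABEL_NAMES[c + 1L],
                   tp = cm[c + 1L, c + 1L],
                   fp = sum(cm[, c + 1L]) - cm[c + 1L, c + 1L],
                   fn = sum(cm[c + 1L, ]) - cm[c + 1L, c + 1L],
                   precision = prf[["precision"]], recall = prf[["recall"]],
                   f1 = prf[["f1"]], support = sum(cm[c + 1L, ]),
                   stringsAsFactors = FALSE)
    }))
    auc <- stats::setNames(rep(NA_real_, 3L), LABEL_NAMES[2:4])
    if (!is.null(probs)) {
        for (c in 1:3) {
            if (any(true == c) && !all(true == c))
                auc[[LABEL_NAMES[c + 1L]]] <- rocAucOvr(true, probs, c)
        }
    }
    new("EvalReport", confusion = cm, perClass = pc,
        macroF1Mutations = macro_f1_mutations(cm),
        microF1 = micro_f1_mutations(cm), auc = auc,
        nPositions = length(true))
}

#' Evaluate a model on a test WindowSet
#'
#' Predicts every window, masks padding positions (input code 0) when
#' `maskPadding` is on, and assembles the confusion matrix, per-class
#' precision/recall/F1, macro- and micro-F1 over the mutation classes, and
#' one-vs-rest AUC per mutation class present.
#'
#' @param model a [TCNModel-class].
#' @param test a [WindowSet-class].
#' @param maskPadding exclude padding positions from all metrics.
#' @param batchSize forward-pass batch size.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, test, maskPadding = TRUE,
                          batchSize = 256L) {
    stopifnot(ncol(test) > 0L)
    res <- predictLabels(model, test, batchSize = batchSize)
    true <- as.integer(windowLabels(test))
    pred <- as.integer(res$labels)
    keep <- if (maskPadding) as.integer(windowCodes(test)) > 0L
            else rep(TRUE, length(true))
    build_eval_report(true[keep], pred[keep], res$probs[keep, , drop = FALSE])
}

#' Write / read an EvalReport as TSV
#'
#' `writeEvalReport` writes two files into `dir`: `report.tsv` (long table
#' metric/class/value) and `confusion.tsv` (labeled 4x4 grid).
#' `readEvalReport` reconstructs the report from them.
#'
#' @param report an [EvalReport-class].
#' @param dir output directory.
#' @return `dir` (write) / an [EvalReport-class] (read).
#' @export
writeEvalReport <- function(report, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    pc <- report@perClass
    long <- rbind(
        data.frame(metric = "precision", class = pc$class,
                   value = pc$precision),
        data.frame(metric = "recall", class = pc$class, value = pc$recall),
        data.frame(metric = "f1", class = pc$class, value = pc$f1),
        data.frame(metric = "support", class = pc$class,
                   value = pc$support),
        data.frame(metric = "auc", class = names(report@auc),
                   value = unname(report@auc)),
        data.frame(metric = "macro_f1_mutations", class = "-",
                   value = report@macroF1Mutations),
        data.frame(metric = "micro_f1_mutations", class = "-",
                   value = report@microF1),
        data.frame(metric = "n_positions", class = "-",
                   value = report@nPositions))
    write.table(format(long, digits = 17, scientific = FALSE, trim = TRUE),
                file.path(dir, "report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cm <- as.data.frame(report@confusion)
    cm <- cbind(true = rownames(report@confusion),
                as.data.frame(matrix(report@confusion, 4L, 4L,
                                     dimnames = list(NULL, LABEL_NAMES))))
    write.table(cm, file.path(dir, "confusion.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeEvalReport
#' @export
readEvalReport <- function(dir) {
    cm_tab <- read.delim(file.path(dir, "confusion.tsv"))
    cm <- as.matrix(cm_tab[, LABEL_NAMES])
    dimnames(cm) <- list(true = LABEL_NAMES, pred = LABEL_NAMES)
    storage.mode(cm) <- "integer"
    long <- read.delim(file.path(dir, "report.tsv"))
    getv <- function(metric, class = NULL) {
        sel <- long$metric == metric
        if (!is.null(class))
            sel <- sel & long$class == class
        as.numeric(long$value[sel])
    }
    pc <- do.call(rbind, lapply(0:3, function(c) {
        cls <- LABEL_NAMES[c + 1L]
        prf <- precisionRecallF1(cm, c)
        data.frame(class = cls, tp = cm[c + 1L, c + 1L],
                   fp = sum(cm[, c + 1L]) - cm[c + 1L, c + 1L],
                   fn = sum(cm[c + 1L, ]) - cm[c + 1L, c + 1L],
                   precision = getv("precision", cls),
                   recall = getv("recall", cls), f1 = getv("f1", cls),
                   support = as.integer(getv("support", cls)),
                   stringsAsFactors = FALSE)
    }))
    auc <- stats::setNames(vapply(LABEL_NAMES[2:4], function(cls) {
        v <- getv("auc", cls)
        if (length(v)) v else NA_real_
    }, numeric(1L)), LABEL_NAMES[2:4])
    new("EvalReport", confusion = cm, perClass = pc,
        macroF1Mutations = getv("macro_f1_mutations"),
        microF1 = getv("micro_f1_mutations"), auc = auc,
        nPositions = as.integer(getv("n_positions")))
}
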