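#' @include tcn-model.R windows.R
NULL

#' TrainConfig: optimization and data-handling parameters
#'
#' @slot learningRate Adam step size (reference value 0.0005).
#' @slot batchSize windows per optimization step (reference value 256).
#' @slot epochs passes over the training set (reference value 100).
#' @slot seed master seed for splitting, undersampling, shuffling and
#'   dropout.
#' @slot splitFraction train fraction of the train/test split (0.9).
#' @slot rusEnabled apply random under-sampling to the train set.
#' @slot rusRatio majority:minority window ratio after sampling (1.0 keeps
#'   at most one all-normal window per mutation-containing window).
#' @slot maskPadding exclude positions with input code 0 from the loss and
#'   the metrics.
#' @slot valFraction fraction of the train set carved off for per-epoch
#'   validation reporting (never used for model selection); 0 disables it.
#' @exportClass TrainConfig
setClass("TrainConfig",
    representation(learningRate = "numeric", batchSize = "integer",
                   epochs = "integer", seed = "integer",
                   splitFraction = "numeric", rusEnabled = "logical",
                   rusRatio = "numeric", maskPadding = "logical",
                   valFraction = "numeric"))

setValidity("TrainConfig", function(object) {
    msg <- character(0L)
    if (object@learningRate <= 0)
        msg <- c(msg, "learningRate must be positive")
    if (object@batchSize < 1L)
        msg <- c(msg, "batchSize must be >= 1")
    if (object@splitFraction <= 0 || object@splitFraction >= 1)
        msg <- c(msg, "splitFraction must lie in (0, 1)")
    if (object@valFraction < 0 || object@valFraction >= 1)
        msg <- c(msg, "valFraction must lie in [0, 1)")
    if (object@rusRatio <= 0)
        msg <- c(msg, "rusRatio must be positive")
    if (object@epochs < 0L)
        msg <- c(msg, "epochs must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#'
#' @param learningRate,batchSize,epochs,seed,splitFraction,rusEnabled,rusRatio,maskPadding,valFraction
#'   see [TrainConfig-class].
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 0.0005, batchSize = 256L,
                        epochs = 100L, seed = 1L, splitFraction = 0.9,
                        rusEnabled = TRUE, rusRatio = 1.0,
                        maskPadding = TRUE, valFraction = 0.1) {
    new("TrainConfig", learningRate = as.numeric(learningRate),
        batchSize = as.integer(batchSize), epochs = as.integer(epochs),
        seed = as.integer(seed), splitFraction = as.numeric(splitFraction),
        rusEnabled = as.logical(rusEnabled), rusRatio = as.numeric(rusRatio),
        maskPadding = as.logical(maskPadding),
        valFraction = as.numeric(valFraction))
}

setMethod("show", "TrainConfig", function(object) {
    cat(sprintf(
        "TrainConfig: lr %.4g, batch %d, %d epochs, split %.2f, seed %d\n",
        object@learningRate, object@batchSize, object@epochs,
        object@splitFraction, object@seed))
    cat(sprintf("  RUS %s (ratio %.2g), mask padding %s, val fraction %.2g\n",
                if (object@rusEnabled) "on" else "off", object@rusRatio,
                if (object@maskPadding) "on" else "off",
                object@valFraction))
})

#' Stratified train/test split of a WindowSet
#'
#' Seeded random partition stratified by whether a window contains any
#' mutated position, so mutation-bearing windows appear in both sets at the
#' global rate. The train set receives `round(splitFraction * N)` windows.
#'
#' @param windows a [WindowSet-class] with at least 10 windows.
#' @param cfg a [TrainConfig-class] (uses `splitFraction` and `seed`).
#' @return a list with elements `train` and `test`, both [WindowSet-class].
#' @export
trainTestSplit <- function(windows, cfg) {
    N <- ncol(windows)
    if (N < 10L)
        stop("need at least 10 windows to split")
    strata <- windowHasMutation(windows)
    target <- round(cfg@splitFraction * N)
    with_seed(derive_seed(cfg@seed, 21L), {
        take <- logical(N)
        for (s in unique(strata)) {
            idx <- which(strata == s)
            n_s <- round(cfg@splitFraction * length(idx))
            n_s <- max(0L, min(length(idx), n_s))
            take[sample(idx, n_s)] <- TRUE
        }
        ## largest-remainder adjustment so |train| = round(f * N) exactly
        delta <- target - sum(take)
        if (delta > 0L)
            take[sample(which(!take), delta)] <- TRUE
        else if (delta < 0L)
            take[sample(which(take), -delta)] <- FALSE
    })
    list(train = windows[, which(take)], test = windows[, which(!take)])
}

#' Random under-sampling of all-normal windows
#'
#' Keeps every window containing at least one mutated position and randomly
#' subsamples the all-normal windows so that their count is at most
#' `rusRatio` times the mutation-containing count. Intended for the train
#' set only; the test set must never be resampled.
#'
#' @param train a [WindowSet-class].
#' @param cfg a [TrainConfig-class] (uses `rusRatio` and `seed`).
#' @return a [WindowSet-class] (original window order preserved).
#' @export
randomUnderSample <- function(train, cfg) {
    mut <- windowHasMutation(train)
    n_mut <- sum(mut)
    if (n_mut == 0L) {
        warning("no mutation-containing windows; under-sampling skipped")
        return(train)
    }
    normal_idx <- which(!mut)
    keep_n <- min(length(normal_idx), floor(cfg@rusRatio * n_mut))
    if (keep_n == length(normal_idx))
        return(train)
    with_seed(derive_seed(cfg@seed, 22L), {
        kept <- sample(normal_idx, keep_n)
    })
    train[, sort(c(which(mut), kept))]
}

## ---- backward pass -------------------------------------------------------

relu_grad <- function(d, pre) relu_bwd_cpp(d, pre)

## gradient of the weight-norm re-parameterization w = g * v / ||v||,
## per filter row
weight_norm_grad <- function(dW, V, g) {
    nr <- sqrt(rowSums(V^2))
    dg <- rowSums(dW * V) / nr
    dV <- (g / nr) * dW - ((g * dg) / nr^2) * V
    list(dV = dV, dg = dg)
}

## full backward pass; returns grads with the same nesting as params
tcn_backward <- function(params, cfg, cache, labels_flat, mask_flat) {
    W <- cache$W; B <- cache$B; K <- cfg@kernelSize
    nmask <- sum(mask_flat)
    dlogits <- cache$probs
    dlogits[cbind(labels_flat + 1L, seq_along(labels_flat))] <-
        dlogits[cbind(labels_flat + 1L, seq_along(labels_flat))] - 1
    dlogits[, !mask_flat] <- 0
    dlogits <- dlogits / nmask
    g <- list(blocks = vector("list", length(cfg@dilations)), post = list())
    ## output projection
    g$post$out <- list(W = tcrossprod(dlogits, cache$a1),
                       b = rowSums(dlogits))
    da1 <- crossprod(params$post$out$W, dlogits)
    da1 <- relu_grad(da1, cache$a1_pre)
    g$post$conv1x1 <- list(W = tcrossprod(da1, cache$h_blocks_out),
                           b = rowSums(da1))
    dh <- crossprod(params$post$conv1x1$W, da1)
    for (bi in rev(seq_along(cfg@dilations))) {
        d <- cfg@dilations[bi]
        blk <- params$blocks[[bi]]
        bc <- cache$blocks[[bi]]
        ds <- relu_grad(dh, bc$sum)
        ## skip path
        if (is.null(blk$proj)) {
            dx_skip <- ds
            gproj <- NULL
        } else {
            gproj <- list(W = tcrossprod(ds, bc$x_in), b = rowSums(ds))
            dx_skip <- crossprod(blk$proj$W, ds)
        }
        ## conv stack, last to first
        dout <- ds
        gconvs <- vector("list", length(blk$convs))
        for (j in rev(seq_along(blk$convs))) {
            cv <- blk$convs[[j]]
            cc <- bc$convs[[j]]
            dact <- if (is.null(cc$mask)) dout else dout * cc$mask
            dpre <- relu_grad(dact, cc$pre)
            Wmat <- weightNormApply(cv$V, cv$g)
            bk <- conv_backward_cpp(cc$cols, Wmat, dpre, cc$cin, W, B, d, K)
            wn <- weight_norm_grad(bk$dW, cv$V, cv$g)
            gconvs[[j]] <- list(V = wn$dV, g = wn$dg,
                                b = as.numeric(bk$db))
            dout <- bk$dX
        }
        g$blocks[[bi]] <- list(convs = gconvs, proj = gproj)
        dh <- dx_skip + dout
    }
    g
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
    if (is.numeric(params))
        return(list(m = params * 0, v = params * 0))
    lapply(params, function(p) if (is.null(p)) NULL else adam_init(p))
}

## walk params/grads/state in lockstep; returns list(params, state)
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    walk <- function(p, g, s) {
        if (is.numeric(p)) {
            s$m <- beta1 * s$m + (1 - beta1) * g
            s$v <- beta2 * s$v + (1 - beta2) * g * g
            mhat <- s$m / (1 - beta1^t)
            vhat <- s$v / (1 - beta2^t)
            p <- p - lr * mhat / (sqrt(vhat) + eps)
            return(list(p = p, s = s))
        }
        keys <- if (is.null(names(p))) seq_along(p) else names(p)
        for (nm in keys) {
            if (is.null(p[[nm]]))
                next
            res <- walk(p[[nm]], g[[nm]], s[[nm]])
            p[[nm]] <- res$p
            s[[nm]] <- res$s
        }
        list(p = p, s = s)
    }
    walk(params, grads, state)
}

## ---- training loop -------------------------------------------------------

masked_ce_loss <- function(probs, labels_flat, mask_flat) {
    p <- probs[cbind(labels_flat + 1L, seq_along(labels_flat))]
    -mean(log(pmax(p[mask_flat], 1e-12)))
}

#' Train a model on a WindowSet
#'
#' Minimizes per-position categorical cross-entropy between the softmax
#' outputs and the labels with Adam, averaging over non-masked positions
#' (positions with input code 0 are excluded while `maskPadding` is on).
#' Window order is reshuffled every epoch from the config seed; on a
#' single-threaded BLAS the whole run is bit-reproducible. An optional
#' validation fraction is carved from the train set for per-epoch reporting
#' only — it never drives parameter selection or early stopping.
#'
#' @param model a [TCNModel-class] (fresh from [buildModel()] or resumed
#'   from a checkpoint; epoch numbering continues from `model@epochsDone`).
#' @param train a [WindowSet-class].
#' @param cfg a [TrainConfig-class].
#' @param quiet suppress per-epoch messages.
#' @return a list with `model` (trained [TCNModel-class]) and `history`
#'   (data.frame with columns `epoch`, `loss`, `val_macro_f1`).
#' @export
trainModel <- function(model, train, cfg, quiet = FALSE) {
    stopifnot(is(model, "TCNModel"), is(train, "WindowSet"),
              is(cfg, "TrainConfig"))
    validObject(cfg)
    tcfg <- model@config
    if (metadata(train)$m + 1L != tcfg@inDim)
        stop(sprintf("window codes use m=%d but model in_dim=%d",
                     metadata(train)$m, tcfg@inDim))
    if (cfg@epochs == 0L)
        return(list(model = model,
                    history = data.frame(epoch = integer(0L),
                                         loss = numeric(0L),
                                         val_macro_f1 = numeric(0L))))
    codes <- windowCodes(train)
    labels <- windowLabels(train)
    Wlen <- nrow(codes)
    params <- model@params
    state <- adam_init(params)
    hist_loss <- numeric(cfg@epochs)
    hist_val <- rep(NA_real_, cfg@epochs)
    step <- 0L
    with_seed(derive_seed(cfg@seed, 23L), {
        N <- ncol(codes)
        val_idx <- integer(0L)
        if (cfg@valFraction > 0 && N >= 20L) {
            nval <- max(1L, floor(cfg@valFraction * N))
            val_idx <- sample(N, nval)
        }
        fit_idx <- setdiff(seq_len(N), val_idx)
        for (ep in seq_len(cfg@epochs)) {
            ord <- sample(fit_idx)
            tot_loss <- 0
            tot_n <- 0
            for (b0 in seq(1L, length(ord), by = cfg@batchSize)) {
                idx <- ord[b0:min(b0 + cfg@batchSize - 1L, length(ord))]
                cb <- codes[, idx, drop = FALSE]
                lb <- as.integer(labels[, idx, drop = FALSE])
                mask <- if (cfg@maskPadding) as.integer(cb) > 0L
                        else rep(TRUE, length(lb))
                if (!any(mask))
                    next
                dmasks <- draw_dropout_masks(tcfg, ncol(cb))
                res <- tcn_train_step_cpp(params, cb, lb, mask, dmasks,
                                          tcfg@dilations, tcfg@kernelSize,
                                          tcfg@inDim, tcfg@nClasses)
                loss <- res$loss
                if (!is.finite(loss))
                    stop(sprintf("training diverged (non-finite loss) at epoch %d",
                                 model@epochsDone + ep))
                grads <- res$grads
                step <- step + 1L
                upd <- adam_step(params, grads, state, cfg@learningRate, step)
                params <- upd$p
                state <- upd$s
                tot_loss <- tot_loss + loss * sum(mask)
                tot_n <- tot_n + sum(mask)
            }
            hist_loss[ep] <- tot_loss / tot_n
            if (length(val_idx)) {
                hist_val[ep] <- val_macro_f1(params, tcfg, codes, labels,
                                             val_idx, cfg@maskPadding)
            }
            if (!quiet)
                message(sprintf("epoch %d/%d: loss %.5f%s",
                                model@epochsDone + ep,
                                model@epochsDone + cfg@epochs, hist_loss[ep],
                                if (is.na(hist_val[ep])) ""
                                else sprintf(", val macro-F1 %.4f",
                                             hist_val[ep])))
        }
    })
    out <- new("TCNModel", config = tcfg, params = params,
               epochsDone = model@epochsDone + cfg@epochs)
    list(model = out,
         history = data.frame(epoch = model@epochsDone + seq_len(cfg@epochs),
                              loss = hist_loss, val_macro_f1 = hist_val))
}

## one scaled channel mask per convolution, drawn from R's RNG so the whole
## run reproduces from the master seed; empty list disables dropout
draw_dropout_masks <- function(tcfg, B) {
    rate <- tcfg@dropoutRate
    if (rate <= 0)
        return(list())
    C <- tcfg@nChannels
    n <- length(tcfg@dilations) * tcfg@convsPerBlock
    lapply(seq_len(n), function(i)
        matrix((runif(C * B) >= rate) / (1 - rate), C, B))
}

## validation macro-F1 over mutation classes present in the truth
val_macro_f1 <- function(params, tcfg, codes, labels, idx, mask_padding) {
    cb <- codes[, idx, drop = FALSE]
    lb <- as.integer(labels[, idx, drop = FALSE])
    mask <- if (mask_padding) as.integer(cb) > 0L else rep(TRUE, length(lb))
    fw <- tcn_forward(params, tcfg, cb, training = FALSE)
    pred <- max.col(t(fw$probs), ties.method = "first") - 1L
    cm <- confusion_counts(lb[mask], pred[mask])
    macro_f1_mutations(cm)
}

#' Predict per-position labels and class probabilities
#'
#' Runs the network and takes, at every position, the argmax of the four
#' class probabilities (ties broken toward the lower class index). Padding
#' positions are predicted like any other; downstream metrics mask them.
#'
#' @param model a [TCNModel-class].
#' @param x what to predict on: a [WindowSet-class], an
#'   [EncodedSequence-class], or an integer code matrix
#'   (positions x windows).
#' @param batchSize windows per forward pass (memory control).
#' @return for a `WindowSet`/matrix: a list with `probs` (positions*windows
#'   x 4 matrix, window-major order) and `labels` (positions x windows
#'   integer matrix). For an `EncodedSequence`: a list with `probs`
#'   (n x 4) and `labels` (a [LabelSequence-class]).
#' @export
setGeneric("predictLabels", function(model, x, batchSize = 256L)
    standardGeneric("predictLabels"))

#' @rdname predictLabels
#' @export
setMethod("predictLabels", signature("TCNModel", "matrix"),
    function(model, x, batchSize = 256L) {
        W <- nrow(x); B <- ncol(x)
        probs <- matrix(0, W * B, 4L)
        for (b0 in seq(1L, B, by = batchSize)) {
            idx <- b0:min(b0 + batchSize - 1L, B)
            fw <- tcn_forward(model@params, model@config,
                              x[, idx, drop = FALSE], training = FALSE)
            rows <- ((idx[1L] - 1L) * W + 1L):(idx[length(idx)] * W)
            probs[rows, ] <- t(fw$probs)
        }
        labels <- matrix(max.col(probs, ties.method = "first") - 1L, W, B)
        list(probs = probs, labels = labels)
    })

#' @rdname predictLabels
#' @export
setMethod("predictLabels", signature("TCNModel", "WindowSet"),
    function(model, x, batchSize = 256L) {
        if (metadata(x)$m + 1L != model@config@inDim)
            stop(sprintf("window codes use m=%d but model in_dim=%d",
                         metadata(x)$m, model@config@inDim))
        predictLabels(model, windowCodes(x), batchSize)
    })

#' @rdname predictLabels
#' @export
setMethod("predictLabels", signature("TCNModel", "EncodedSequence"),
    function(model, x, batchSize = 256L) {
        if (x@m + 1L != model@config@inDim)
            stop(sprintf("sequence encoded with m=%d but model in_dim=%d",
                         x@m, model@config@inDim))
        res <- predictLabels(model, matrix(x@codes, ncol = 1L), batchSize)
        list(probs = res$probs,
             labels = new("LabelSequence", sourceId = x@sourceId,
                          labels = as.integer(res$labels)))
    })
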