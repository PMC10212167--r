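#' @include tcn-layers.R
NULL

#' TCNConfig: architecture hyperparameters
#'
#' @slot nChannels filters per convolution (reference value 128).
#' @slot kernelSize taps per filter K (reference value 16).
#' @slot dilations increasing positive integers, one residual block per
#'   entry (reference value `c(1, 2, 4, 8, 16, 32)`).
#' @slot convsPerBlock convolutions per residual block (default 2, the
#'   canonical TCN block).
#' @slot dropoutRate spatial dropout probability (reference value 0.1).
#' @slot inDim input one-hot dimension, `m + 1` for the k-mer table used.
#' @slot nClasses output classes, fixed at 4 (normal/SNV/INS/DEL).
#' @slot seed parameter-initialization seed.
#' @exportClass TCNConfig
setClass("TCNConfig",
    representation(nChannels = "integer", kernelSize = "integer",
                   dilations = "integer", convsPerBlock = "integer",
                   dropoutRate = "numeric", inDim = "integer",
                   nClasses = "integer", seed = "integer"))

setValidity("TCNConfig", function(object) {
    msg <- character(0L)
    if (any(object@dilations < 1L))
        msg <- c(msg, "dilations must be strictly positive")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
        msg <- c(msg, "dropoutRate must lie in [0, 1)")
    if (object@nClasses != 4L)
        msg <- c(msg, "nClasses is fixed at 4")
    if (object@kernelSize < 1L || object@nChannels < 1L ||
        object@convsPerBlock < 1L || object@inDim < 2L)
        msg <- c(msg, "nChannels, kernelSize, convsPerBlock, inDim must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a TCNConfig
#'
#' Defaults are the reference architecture: 128 kernels of size 16,
#' dilations `[1, 2, 4, 8, 16, 32]`, two convolutions per residual block,
#' spatial dropout 0.1.
#'
#' @param nChannels,kernelSize,dilations,convsPerBlock,dropoutRate,inDim,nClasses,seed
#'   see [TCNConfig-class]. `inDim` defaults to `m + 1` for 2-mer encoding.
#' @return a validated [TCNConfig-class].
#' @export
tcnConfig <- function(nChannels = 128L, kernelSize = 16L,
                      dilations = c(1L, 2L, 4L, 8L, 16L, 32L),
                      convsPerBlock = 2L, dropoutRate = 0.1,
                      inDim = 17L, nClasses = 4L, seed = 1L) {
    new("TCNConfig", nChannels = as.integer(nChannels),
        kernelSize = as.integer(kernelSize),
        dilations = as.integer(dilations),
        convsPerBlock = as.integer(convsPerBlock),
        dropoutRate = as.numeric(dropoutRate), inDim = as.integer(inDim),
        nClasses = as.integer(nClasses), seed = as.integer(seed))
}

setMethod("show", "TCNConfig", function(object) {
    cat(sprintf(
        "TCNConfig: %d channels, K=%d, dilations [%s], %d convs/block\n",
        object@nChannels, object@kernelSize,
        paste(object@dilations, collapse = ","), object@convsPerBlock))
    cat(sprintf("  dropout %.3g, in_dim %d, %d classes, seed %d\n",
                object@dropoutRate, object@inDim, object@nClasses,
                object@seed))
    cat(sprintf("  receptive field: %d positions\n", receptiveField(object)))
})

#' Receptive field of the network
#'
#' The number of trailing input positions that can influence one output
#' position: `1 + sum_over_blocks convsPerBlock * (K - 1) * d`. Each
#' dilated convolution reaches `(K-1)*d` positions back, and reaches add up
#' across stacked convolutions.
#'
#' @param cfg a [TCNConfig-class].
#' @return integer number of positions.
#' @examples
#' receptiveField(tcnConfig(kernelSize = 16,
#'                          dilations = c(1, 2, 4, 8, 16, 32)))  # 1891
#' @export
receptiveField <- function(cfg) {
    as.integer(1L + sum(cfg@convsPerBlock * (cfg@kernelSize - 1L) *
                        cfg@dilations))
}

#' TCNModel: a temporal convolutional network for per-base labeling
#'
#' Pipeline: fixed one-hot embedding of the integer code sequence
#' (`inDim = m + 1` channels) -> one residual block per dilation factor, in
#' order -> 1x1 convolution -> position-shared affine map to 4 classes with
#' a per-position softmax. Output length always equals input length, and no
#' position attends to later positions (causality).
#'
#' @slot config the [TCNConfig-class].
#' @slot params nested parameter list (see [residualBlock()] for the block
#'   layout; `post` holds the 1x1 convolution and the output projection).
#' @slot epochsDone training epochs already applied (0 for a fresh model).
#' @seealso [buildModel()], [trainModel()], [predictLabels()]
#' @exportClass TCNModel
setClass("TCNModel",
    representation(config = "TCNConfig", params = "list",
                   epochsDone = "integer"))

#' @describeIn TCNModel the architecture config
#' @param x,object a `TCNModel`
#' @export
modelConfig <- function(x) x@config

#' @describeIn TCNModel the parameter list
#' @export
modelParams <- function(x) x@params

setMethod("show", "TCNModel", function(object) {
    cfg <- object@config
    np <- sum(rapply(object@params, length, how = "unlist"))
    cat(sprintf(
        "TCNModel: %d residual blocks, %d channels, K=%d (%d parameters)\n",
        length(cfg@dilations), cfg@nChannels, cfg@kernelSize, np))
    cat(sprintf("  in_dim %d -> %d classes, receptive field %d, epochs done %d\n",
                cfg@inDim, cfg@nClasses, receptiveField(cfg),
                object@epochsDone))
})

## He-style initialization; V is stored flat (Cout x Cin*K) and g is set to
## the row norms of V so the effective initial weight equals V itself.
init_conv <- function(Cout, Cin, K) {
    V <- matrix(rnorm(Cout * Cin * K, sd = sqrt(2 / (Cin * K))), Cout)
    list(V = V, g = sqrt(rowSums(V^2)), b = numeric(Cout))
}

init_affine <- function(Cout, Cin) {
    list(W = matrix(rnorm(Cout * Cin, sd = sqrt(2 / Cin)), Cout),
         b = numeric(Cout))
}

#' Build a freshly initialized model
#'
#' Parameters are drawn from the config seed, so two builds from the same
#' config are identical.
#'
#' @param cfg a [TCNConfig-class].
#' @return a [TCNModel-class].
#' @export
buildModel <- function(cfg) {
    validObject(cfg)
    C <- cfg@nChannels; K <- cfg@kernelSize
    with_seed(derive_seed(cfg@seed, 11L), {
        blocks <- vector("list", length(cfg@dilations))
        Cin <- cfg@inDim
        for (b in seq_along(cfg@dilations)) {
            convs <- vector("list", cfg@convsPerBlock)
            cin <- Cin
            for (j in seq_len(cfg@convsPerBlock)) {
                convs[[j]] <- init_conv(C, cin, K)
                cin <- C
            }
            proj <- if (Cin != C) init_affine(C, Cin) else NULL
            blocks[[b]] <- list(convs = convs, proj = proj)
            Cin <- C
        }
        post <- list(conv1x1 = init_affine(C, C),
                     out = init_affine(cfg@nClasses, C))
    })
    new("TCNModel", config = cfg,
        params = list(blocks = blocks, post = post), epochsDone = 0L)
}

## ---- batched forward pass ------------------------------------------------
## Feature maps are C x (W*B) matrices; window b occupies columns
## ((b-1)*W + 1):(b*W). The causal dilated convolution is an im2col gather
## (zeros left of each window's first position, so windows never leak into
## each other) followed by one BLAS matmul; both live in compiled code
## (src/conv_kernels.cpp) and are tested against the composition of the
## exported reference primitives.

## spatial dropout mask for a batched map: one Bernoulli per channel per
## window, expanded across the W positions of that window
dropout_mask <- function(C, W, B, rate) {
    keep <- matrix(runif(C * B) >= rate, C, B) / (1 - rate)
    keep[, rep(seq_len(B), each = W), drop = FALSE]
}

softmax_cols <- function(Z) {
    Z <- Z - rep(apply(Z, 2L, max), each = nrow(Z))
    E <- exp(Z)
    E / rep(colSums(E), each = nrow(E))
}

## Forward pass over a batch of windows.
## codes: W x B integer matrix. Returns probs (nClasses x (W*B)) and, when
## keep_cache, the intermediates needed by the backward pass.
tcn_forward <- function(params, cfg, codes, training = FALSE,
                        keep_cache = FALSE) {
    W <- nrow(codes); B <- ncol(codes)
    if (length(codes) && max(codes) > cfg@inDim - 1L)
        stop("code exceeds model input dimension; wrong k-mer table for this model")
    K <- cfg@kernelSize
    X <- matrix(0, cfg@inDim, W * B)
    X[cbind(as.integer(codes) + 1L, seq_len(W * B))] <- 1
    cache <- if (keep_cache) list(X = X, blocks = list()) else NULL
    h <- X
    for (bi in seq_along(cfg@dilations)) {
        d <- cfg@dilations[bi]
        blk <- params$blocks[[bi]]
        x_in <- h
        bcache <- list(x_in = x_in, convs = list())
        for (j in seq_along(blk$convs)) {
            cv <- blk$convs[[j]]
            Wmat <- weightNormApply(cv$V, cv$g)
            if (keep_cache) {
                cf <- conv_forward_train_cpp(h, Wmat, cv$b, W, B, d, K)
                pre <- cf$Y
            } else {
                pre <- conv_forward_cpp(h, Wmat, cv$b, W, B, d, K)
            }
            act <- relu_fwd_cpp(pre)
            mask <- NULL
            if (training && cfg@dropoutRate > 0) {
                mask <- dropout_mask(nrow(act), W, B, cfg@dropoutRate)
                out <- act * mask
            } else out <- act
            if (keep_cache)
                bcache$convs[[j]] <- list(cols = cf$cols, cin = nrow(h),
                                          pre = pre, mask = mask)
            h <- out
        }
        skip <- if (is.null(blk$proj)) x_in
                else blk$proj$W %*% x_in + blk$proj$b
        s <- skip + h
        o <- relu_fwd_cpp(s)
        if (keep_cache) {
            bcache$sum <- s
            cache$blocks[[bi]] <- bcache
        }
        h <- o
    }
    a1_pre <- params$post$conv1x1$W %*% h + params$post$conv1x1$b
    a1 <- relu_fwd_cpp(a1_pre)
    logits <- params$post$out$W %*% a1 + params$post$out$b
    probs <- softmax_cols(logits)
    if (keep_cache) {
        cache$h_blocks_out <- h
        cache$a1_pre <- a1_pre
        cache$a1 <- a1
        cache$probs <- probs
        cache$W <- W; cache$B <- B
    }
    list(probs = probs, cache = cache)
}

## ---- checkpoint I/O (portable plain text) --------------------------------

flatten_params <- function(params, prefix = "") {
    out <- list()
    for (nm in names(params)) {
        v <- params[[nm]]
        key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
        if (is.list(v)) {
            if (is.null(names(v)))
                names(v) <- sprintf("%d", seq_along(v))
            out <- c(out, flatten_params(v, key))
        } else if (!is.null(v)) {
            out[[key]] <- v
        }
    }
    out
}

#' Save a model to a plain-text checkpoint
#'
#' Writes the architecture config and every parameter array to a single
#' text file; numbers are printed with enough digits (\code{\%.17g}) to
#' round-trip doubles exactly, so [readModelCheckpoint()] reproduces the
#' model bit for bit.
#'
#' @param model a [TCNModel-class].
#' @param path output file.
#' @param extra optional named list of additional scalar metadata (e.g. the
#'   k-mer size and window geometry the model was trained with).
#' @return `path`, invisibly.
#' @export
saveModelCheckpoint <- function(model, path, extra = list()) {
    cfg <- model@config
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# mutTCN checkpoint v1", con)
    hdr <- c(list(
        n_channels = cfg@nChannels, kernel_size = cfg@kernelSize,
        dilations = paste(cfg@dilations, collapse = ","),
        convs_per_block = cfg@convsPerBlock,
        dropout_rate = sprintf("%.17g", cfg@dropoutRate),
        in_dim = cfg@inDim, n_classes = cfg@nClasses, seed = cfg@seed,
        epochs_done = model@epochsDone), extra)
    for (nm in names(hdr))
        writeLines(sprintf("@%s=%s", nm, as.character(hdr[[nm]])), con)
    flat <- flatten_params(model@params)
    for (nm in names(flat)) {
        v <- flat[[nm]]
        dims <- if (is.null(dim(v))) length(v) else dim(v)
        writeLines(sprintf(">%s dims=%s", nm,
                           paste(dims, collapse = ",")), con)
        writeLines(paste(sprintf("%.17g", as.numeric(v)), collapse = " "),
                   con)
    }
    invisible(path)
}

#' Load a model from a plain-text checkpoint
#'
#' @param path file written by [saveModelCheckpoint()].
#' @return a list with `model` (a [TCNModel-class]) and `extra` (named
#'   character list of the additional metadata stored alongside it).
#' @export
readModelCheckpoint <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    hdr_lines <- lines[startsWith(lines, "@")]
    hdr <- read_kv_lines(sub("^@", "", hdr_lines))
    known <- c("n_channels", "kernel_size", "dilations", "convs_per_block",
               "dropout_rate", "in_dim", "n_classes", "seed", "epochs_done")
    cfg <- tcnConfig(
        nChannels = as.integer(hdr$n_channels),
        kernelSize = as.integer(hdr$kernel_size),
        dilations = as.integer(strsplit(hdr$dilations, ",")[[1L]]),
        convsPerBlock = as.integer(hdr$convs_per_block),
        dropoutRate = as.numeric(hdr$dropout_rate),
        inDim = as.integer(hdr$in_dim), nClasses = as.integer(hdr$n_classes),
        seed = as.integer(hdr$seed))
    flat <- list()
    i <- which(startsWith(lines, ">"))
    for (ix in i) {
        m <- regmatches(lines[ix],
                        regexec("^>([^ ]+) dims=([0-9,]+)$", lines[ix]))[[1L]]
        nm <- m[2L]
        dims <- as.integer(strsplit(m[3L], ",")[[1L]])
        vals <- as.numeric(strsplit(lines[ix + 1L], " ", fixed = TRUE)[[1L]])
        if (length(dims) > 1L)
            dim(vals) <- dims
        flat[[nm]] <- vals
    }
    params <- unflatten_params(flat)
    ## identity skips have no stored parameters; restore the empty slot so
    ## the structure matches buildModel() exactly
    params$blocks <- lapply(params$blocks, function(blk)
        list(convs = blk$convs, proj = blk[["proj"]]))
    model <- new("TCNModel", config = cfg, params = params,
                 epochsDone = as.integer(hdr$epochs_done))
    list(model = model, extra = hdr[setdiff(names(hdr), known)])
}

read_kv_lines <- function(lines) {
    eq <- regexpr("=", lines, fixed = TRUE)
    stats::setNames(as.list(substring(lines, eq + 1L)),
                    substr(lines, 1L, eq - 1L))
}

unflatten_params <- function(flat) {
    params <- list()
    for (nm in names(flat)) {
        parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
        parts <- lapply(parts, function(p)
            if (grepl("^[0-9]+$", p)) as.integer(p) else p)
        params <- assign_nested(params, parts, flat[[nm]])
    }
    params
}

assign_nested <- function(x, parts, value) {
    p <- parts[[1L]]
    if (length(parts) == 1L) {
        x[[p]] <- value
        return(x)
    }
    cur <- if (is.numeric(p) && length(x) >= p) x[[p]]
           else if (!is.numeric(p)) x[[p]] else NULL
    if (is.null(cur)) cur <- list()
    x[[p]] <- assign_nested(cur, parts[-1L], value)
    x
}
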