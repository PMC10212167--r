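test_that("receptive field formula gives the documented values", {
    expect_identical(receptiveField(small_tcn_config(kernelSize = 2L,
                                                     dilations = 1L)), 3L)
    expect_identical(
        receptiveField(mutTCN:::tcnConfig(kernelSize = 16,
                                          dilations = c(1, 2, 4, 8, 16, 32))),
        1891L)
    expect_identical(
        receptiveField(mutTCN:::tcnConfig(kernelSize = 1,
                                          dilations = c(1, 2, 4))), 1L)
})

test_that("a built model emits per-position probability rows summing to one", {
    cfg <- small_tcn_config(seed = 3L)
    model <- buildModel(cfg)
    expect_identical(length(modelParams(model)$blocks),
                     length(cfg@dilations))
    set.seed(4)
    codes <- matrix(sample(0:16, 150, replace = TRUE), ncol = 1)
    res <- predictLabels(model, codes)
    expect_identical(dim(res$probs), c(150L, 4L))
    expect_true(all(abs(rowSums(res$probs) - 1) < 1e-6))
    expect_identical(dim(res$labels), c(150L, 1L))
})

test_that("model building is deterministic in the seed", {
    cfg <- small_tcn_config(seed = 42L)
    m1 <- buildModel(cfg)
    m2 <- buildModel(cfg)
    expect_identical(modelParams(m1), modelParams(m2))
    set.seed(1)
    codes <- matrix(sample(0:16, 80, replace = TRUE), ncol = 1)
    expect_identical(predictLabels(m1, codes)$probs,
                     predictLabels(m2, codes)$probs)
    m3 <- buildModel(small_tcn_config(seed = 43L))
    expect_false(identical(modelParams(m1), modelParams(m3)))
})

test_that("no output position depends on any later input position", {
    cfg <- small_tcn_config(seed = 7L, dilations = c(1L, 2L, 4L))
    model <- buildModel(cfg)
    n <- 64L
    set.seed(8)
    codes <- sample(0:16, n, replace = TRUE)
    base <- mutTCN:::tcn_forward(modelParams(model), cfg,
                                 matrix(codes, ncol = 1))$probs
    for (t in seq_len(n - 1L)) {
        mod <- codes
        mod[(t + 1L):n] <- sample(0:16, n - t, replace = TRUE)
        out <- mutTCN:::tcn_forward(modelParams(model), cfg,
                                    matrix(mod, ncol = 1))$probs
        expect_equal(out[, seq_len(t)], base[, seq_len(t)],
                     tolerance = 1e-9)
    }
})

test_that("the receptive-field formula matches the observed influence horizon", {
    ## all-ones filters on a single channel keep every path active, so an
    ## input perturbation propagates exactly receptive_field - 1 positions
    set.seed(15)
    configs <- list(
        list(K = 2L, dil = c(1L), cpb = 2L),
        list(K = 3L, dil = c(1L, 2L), cpb = 1L),
        list(K = 2L, dil = c(1L, 2L, 4L), cpb = 2L),
        list(K = 4L, dil = c(1L, 2L), cpb = 2L),
        list(K = 3L, dil = c(1L, 4L), cpb = 2L))
    for (cc in configs) {
        rf <- 1L + sum(cc$cpb * (cc$K - 1L) * cc$dil)
        ones <- function() list(V = matrix(1, 1, cc$K), g = sqrt(cc$K),
                                b = 0)
        n <- rf + 5L
        x <- runif(n) + 0.5
        fwd <- function(x) {
            h <- matrix(x, 1)
            for (d in cc$dil)
                h <- residualBlock(h, list(convs = replicate(cc$cpb,
                                                             ones(),
                                                             simplify = FALSE)),
                                   d = d, kernelSize = cc$K)
            as.numeric(h)
        }
        y <- fwd(x)
        t <- n
        ## perturbing at distance rf - 1 changes the output at t ...
        x2 <- x
        x2[t - rf + 1L] <- x2[t - rf + 1L] + 1
        expect_gt(abs(fwd(x2)[t] - y[t]), 1e-9)
        ## ... and at distance rf it cannot
        x3 <- x
        x3[t - rf] <- x3[t - rf] + 1
        expect_equal(fwd(x3)[t], y[t], tolerance = 1e-12)
        ## the formula agrees with receptiveField() on the same geometry
        cfg <- mutTCN:::tcnConfig(nChannels = 1, kernelSize = cc$K,
                                  dilations = cc$dil,
                                  convsPerBlock = cc$cpb, inDim = 2)
        expect_identical(receptiveField(cfg), rf)
    }
})

test_that("the batched forward pass equals the composition of the reference primitives", {
    cfg <- small_tcn_config(seed = 21L, dilations = c(1L, 2L, 4L))
    model <- buildModel(cfg)
    p <- modelParams(model)
    set.seed(22)
    codes <- matrix(sample(0:16, 90 * 2, replace = TRUE), 90)
    fw <- mutTCN:::tcn_forward(p, cfg, codes)
    for (w in 1:2) {
        h <- oneHotEncode(codes[, w], 16)
        for (bi in seq_along(cfg@dilations))
            h <- residualBlock(h, p$blocks[[bi]], cfg@dilations[bi],
                               kernelSize = cfg@kernelSize)
        a1 <- reluActivation(p$post$conv1x1$W %*% h + p$post$conv1x1$b)
        logits <- p$post$out$W %*% a1 + p$post$out$b
        probs <- apply(logits, 2, function(z) {
            e <- exp(z - max(z)); e / sum(e)
        })
        expect_equal(fw$probs[, (w - 1) * 90 + seq_len(90)], probs,
                     tolerance = 1e-6)
    }
})

test_that("the fused training kernel reproduces the reference loss and gradients", {
    cfg <- small_tcn_config(seed = 31L, dilations = c(1L, 2L))
    model <- buildModel(cfg)
    set.seed(32)
    codes <- matrix(sample(0:16, 50 * 4, replace = TRUE), 50)
    labels <- sample(0:3, 200, replace = TRUE)
    mask <- as.integer(codes) > 0L
    fw <- mutTCN:::tcn_forward(modelParams(model), cfg, codes,
                               keep_cache = TRUE)
    loss_ref <- mutTCN:::masked_ce_loss(fw$probs, labels, mask)
    grads_ref <- mutTCN:::tcn_backward(modelParams(model), cfg, fw$cache,
                                       labels, mask)
    res <- mutTCN:::tcn_train_step_cpp(modelParams(model), codes, labels,
                                       mask, list(), cfg@dilations,
                                       cfg@kernelSize, cfg@inDim, 4L)
    expect_equal(res$loss, loss_ref, tolerance = 1e-5)
    cmp <- function(a, b) {
        keys <- if (is.null(names(a))) seq_along(a) else names(a)
        for (k in keys) {
            if (is.null(a[[k]])) next
            if (is.numeric(a[[k]])) {
                scale <- max(1e-6, max(abs(a[[k]])))
                expect_lt(max(abs(a[[k]] - b[[k]])) / scale, 2e-3)
            } else cmp(a[[k]], b[[k]])
        }
    }
    cmp(grads_ref, res$grads)
})

test_that("analytic gradients match finite differences", {
    cfg <- mutTCN:::tcnConfig(nChannels = 4L, kernelSize = 3L,
                              dilations = c(1L, 2L), convsPerBlock = 2L,
                              dropoutRate = 0, inDim = 6L, seed = 44L)
    model <- buildModel(cfg)
    set.seed(45)
    codes <- matrix(sample(0:5, 12 * 3, replace = TRUE), 12)
    labels <- sample(0:3, 36, replace = TRUE)
    mask <- as.integer(codes) > 0L
    fw <- mutTCN:::tcn_forward(modelParams(model), cfg, codes,
                               keep_cache = TRUE)
    grads <- mutTCN:::tcn_backward(modelParams(model), cfg, fw$cache,
                                   labels, mask)
    lossfun <- function(params)
        mutTCN:::masked_ce_loss(mutTCN:::tcn_forward(params, cfg,
                                                     codes)$probs,
                                labels, mask)
    setv <- function(x, path, i, v) {
        if (!length(path)) { x[i] <- v; return(x) }
        x[[path[[1]]]] <- setv(x[[path[[1]]]], path[-1], i, v)
        x
    }
    paths <- list(list("blocks", 1L, "convs", 1L, "V"),
                  list("blocks", 2L, "convs", 2L, "g"),
                  list("blocks", 1L, "proj", "W"),
                  list("blocks", 2L, "convs", 1L, "b"),
                  list("post", "conv1x1", "W"),
                  list("post", "out", "W"))
    eps <- 1e-6
    for (path in paths) {
        p <- modelParams(model)
        g <- grads
        for (k in path) { p <- p[[k]]; g <- g[[k]] }
        for (i in sample(length(p), min(4, length(p)))) {
            up <- lossfun(setv(modelParams(model), path, i, p[i] + eps))
            dn <- lossfun(setv(modelParams(model), path, i, p[i] - eps))
            fd <- (up - dn) / (2 * eps)
            expect_lt(abs(fd - g[i]), 1e-5 * max(1, abs(fd)))
        }
    }
})

test_that("checkpoints round-trip models exactly", {
    cfg <- small_tcn_config(seed = 51L)
    model <- buildModel(cfg)
    path <- withr::local_tempfile(fileext = ".txt")
    saveModelCheckpoint(model, path, extra = list(k = 2, window = 150,
                                                  overlap = 50))
    back <- readModelCheckpoint(path)
    expect_identical(back$model@params, model@params)
    expect_identical(back$model@config@dilations, cfg@dilations)
    expect_identical(back$extra$k, "2")
    set.seed(52)
    codes <- matrix(sample(0:16, 100, replace = TRUE), ncol = 1)
    expect_identical(predictLabels(model, codes)$probs,
                     predictLabels(back$model, codes)$probs)
})
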