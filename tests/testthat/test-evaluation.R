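test_that("confusion matrices count every (true, predicted) pair over non-masked positions", {
    expect_identical(confusionMatrix(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L)),
                     matrix(diag(1L, 4), 4,
                            dimnames = list(true = mutTCN:::LABEL_NAMES,
                                            pred = mutTCN:::LABEL_NAMES)))
    cm <- confusionMatrix(c(0L, 1L), c(1L, 0L))
    expect_identical(sum(diag(cm)), 0L)
    expect_identical(cm[1, 2], 1L)
    expect_identical(cm[2, 1], 1L)
    ## brute-force counting oracle over many random pairs
    set.seed(31)
    for (rep in 1:20) {
        n <- sample(50:200, 1)
        true <- sample(0:3, n, replace = TRUE)
        pred <- sample(0:3, n, replace = TRUE)
        expect_identical(unname(confusionMatrix(true, pred)),
                         brute_confusion(true, pred))
    }
    ## masking removes padding positions
    cm <- confusionMatrix(c(0L, 1L, 0L), c(0L, 1L, 1L),
                          codes = c(1L, 5L, 0L))
    expect_identical(sum(cm), 2L)
    expect_error(confusionMatrix(list(c(0L, 1L)), list(c(0L, 1L, 2L))),
                 "mismatch")
})

test_that("precision, recall and F1 follow their defining formulas with the zero conventions", {
    cm <- matrix(0L, 4, 4)
    cm[2, 2] <- 9L; cm[1, 2] <- 1L; cm[2, 1] <- 3L
    prf <- precisionRecallF1(cm, 1)
    expect_equal(prf[["precision"]], 0.9)
    expect_equal(prf[["recall"]], 0.75)
    expect_equal(prf[["f1"]], 2 * 0.9 * 0.75 / 1.65, tolerance = 1e-12)
    ## empty class: all zero by convention
    expect_identical(unname(precisionRecallF1(matrix(0L, 4, 4), 2)),
                     c(0, 0, 0))
    ## perfect class
    cm2 <- diag(5L, 4)
    expect_identical(unname(precisionRecallF1(cm2, 3)), c(1, 1, 1))
})

test_that("metric implementations agree with explicit counting on 1000 random label pairs", {
    set.seed(32)
    for (rep in 1:50) {
        n <- 1000L
        true <- sample(0:3, n, replace = TRUE,
                       prob = c(0.85, 0.07, 0.05, 0.03))
        pred <- sample(0:3, n, replace = TRUE,
                       prob = c(0.85, 0.07, 0.05, 0.03))
        cm <- confusionMatrix(true, pred)
        for (cls in 0:3)
            expect_equal(precisionRecallF1(cm, cls),
                         brute_prf(true, pred, cls), tolerance = 1e-12)
    }
})

test_that("F1 lies between min and max of precision and recall (harmonic mean)", {
    set.seed(33)
    for (rep in 1:50) {
        cm <- matrix(sample(0:30, 16, replace = TRUE), 4)
        for (cls in 0:3) {
            prf <- precisionRecallF1(cm, cls)
            if (prf[["precision"]] + prf[["recall"]] > 0) {
                expect_gte(prf[["f1"]],
                           min(prf[["precision"]], prf[["recall"]]) - 1e-12)
                expect_lte(prf[["f1"]],
                           max(prf[["precision"]], prf[["recall"]]) + 1e-12)
            }
        }
    }
})

test_that("one-vs-rest AUC equals the pairwise concordance statistic", {
    ## perfectly separating scores
    true <- c(rep(1L, 5), rep(0L, 5))
    probs <- cbind(0, c(runif(5, 0.8, 1), runif(5, 0, 0.2)), 0, 0)
    expect_equal(rocAucOvr(true, probs, 1), 1.0)
    ## uninformative scores
    probs0 <- cbind(0, rep(0.5, 10), 0, 0)
    expect_equal(rocAucOvr(true, probs0, 1), 0.5)
    ## Mann-Whitney oracle on random 20-point instances, ties included
    set.seed(34)
    for (rep in 1:20) {
        true <- sample(0:1, 20, replace = TRUE)
        if (!any(true == 1L) || all(true == 1L)) next
        score <- round(runif(20), 1)           # coarse grid forces ties
        probs <- cbind(0, score, 0, 0)
        expect_equal(rocAucOvr(true, probs, 1),
                     brute_auc(score[true == 1L], score[true == 0L]),
                     tolerance = 1e-12)
    }
})

test_that("AUC is invariant under monotone transformations of the scores", {
    set.seed(35)
    true <- sample(0:1, 30, replace = TRUE)
    score <- runif(30)
    a1 <- rocAucOvr(true, cbind(0, score, 0, 0), 1)
    a2 <- rocAucOvr(true, cbind(0, exp(3 * score), 0, 0), 1)
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_error(rocAucOvr(rep(0L, 10), cbind(1, 0, 0, 0)[rep(1, 10), ], 2),
                 "absent")
})

test_that("AUC agrees with an established ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(36)
    true <- sample(0:1, 50, replace = TRUE)
    score <- runif(50)
    ours <- rocAucOvr(true, cbind(0, score, 0, 0), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(true == 1L, score,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("extractCalls merges label runs into typed 1-based calls", {
    expect_identical(nrow(extractCalls(rep(0L, 10))), 0L)
    calls <- extractCalls(c(0L, 0L, 1L, 0L))
    expect_identical(calls$start_1based, 3L)
    expect_identical(calls$end_1based, 3L)
    expect_identical(calls$type, "SNV")
    calls <- extractCalls(c(0L, 2L, 2L, 0L))
    expect_identical(calls$start_1based, 2L)
    expect_identical(calls$end_1based, 3L)
    expect_identical(calls$type, "INS")
    ## adjacent runs of different labels stay separate; probabilities average
    probs <- matrix(0.1, 6, 4)
    probs[2:3, 3] <- c(0.6, 0.8)
    probs[4, 4] <- 0.9
    calls <- extractCalls(c(0L, 2L, 2L, 3L, 0L, 1L), probs)
    expect_identical(calls$type, c("INS", "DEL", "SNV"))
    expect_equal(calls$mean_prob[1], 0.7)
    expect_equal(calls$mean_prob[2], 0.9)
})

test_that("call extraction recovers every simulated SNV position exactly", {
    cfg <- simulatorConfig(nRefs = 1, refLen = 400, nSamples = 10,
                           mutsPerSample = 6, typeProps = c(1, 0, 0),
                           seed = 91)
    sim <- simulateDataset(cfg)
    recs <- simRecords(sim)
    for (id in names(simLabels(sim))) {
        calls <- extractCalls(simLabels(sim)[[id]], id = id)
        ## adjacent SNVs merge into one run, so compare covered positions
        covered <- unlist(lapply(seq_len(nrow(calls)), function(i)
            calls$start_1based[i]:calls$end_1based[i]))
        expect_identical(sort(covered),
                         sort(recs$position[recs$sample_id == id]) + 1L)
        expect_true(all(calls$type == "SNV"))
    }
})

test_that("evaluateModel is self-consistent and handles degenerate predictors", {
    ws <- local({
        set.seed(41)
        W <- 30L; N <- 20L
        codes <- matrix(sample(1:16, W * N, replace = TRUE), W)
        labels <- matrix(sample(0:3, W * N, replace = TRUE,
                                prob = c(0.8, 0.1, 0.06, 0.04)), W)
        mutTCN:::new_window_set(codes, labels, sprintf("w%d", 1:N),
                                rep(0L, N), W, 5L, 2L, 16L)
    })
    model <- buildModel(small_tcn_config(seed = 42L))
    rep1 <- evaluateModel(model, ws)
    expect_identical(sum(evalConfusion(rep1)), rep1@nPositions)
    ## metrics recompute identically from the serialized confusion matrix
    pc <- perClassMetrics(rep1)
    for (cls in 0:3)
        expect_equal(unname(precisionRecallF1(evalConfusion(rep1), cls)),
                     unname(unlist(pc[cls + 1, c("precision", "recall",
                                                 "f1")])),
                     tolerance = 1e-12)
    ## an untrained model predicting (almost surely) all-normal has zero
    ## recall on mutation classes present in the truth
    dominant <- as.integer(names(which.max(table(
        max.col(predictLabels(model, ws)$probs, "first") - 1L))))
    if (dominant == 0L && all(predictLabels(model, ws)$labels == 0L))
        expect_identical(perClassMetrics(rep1)$recall[2:4], rep(0, 3))
})

test_that("a perfect predictor scores macro-F1 1 on every class present", {
    true <- list(c(0L, 1L, 0L, 2L, 2L, 0L, 3L))
    cm <- confusionMatrix(true, true)
    expect_equal(mutTCN:::macro_f1_mutations(cm), 1)
    expect_equal(mutTCN:::micro_f1_mutations(cm), 1)
    ## absent mutation classes leave the macro average NA, not 0
    cm0 <- confusionMatrix(rep(0L, 5), rep(0L, 5))
    expect_true(is.na(mutTCN:::macro_f1_mutations(cm0)))
})

test_that("evaluation reports round-trip through their TSV serialization", {
    ws <- local({
        set.seed(43)
        W <- 25L; N <- 12L
        codes <- matrix(sample(0:16, W * N, replace = TRUE), W)
        labels <- matrix(sample(0:3, W * N, replace = TRUE,
                                prob = c(0.7, 0.1, 0.1, 0.1)), W)
        mutTCN:::new_window_set(codes, labels, sprintf("w%d", 1:N),
                                rep(0L, N), W, 5L, 2L, 16L)
    })
    report <- evaluateModel(buildModel(small_tcn_config(seed = 44L)), ws)
    d <- withr::local_tempdir()
    writeEvalReport(report, d)
    back <- readEvalReport(d)
    expect_identical(evalConfusion(back), evalConfusion(report))
    expect_equal(back@macroF1Mutations, report@macroF1Mutations,
                 tolerance = 1e-12)
    expect_equal(back@microF1, report@microF1, tolerance = 1e-12)
    expect_equal(back@auc, report@auc, tolerance = 1e-12)
    expect_equal(perClassMetrics(back)$f1, perClassMetrics(report)$f1,
                 tolerance = 1e-12)
})
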