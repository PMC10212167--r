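test_that("reference panels have the requested shape and are seed-reproducible", {
    cfg <- simulatorConfig(nRefs = 3, refLen = 100, nSamples = 5, seed = 42)
    refs <- generateReferences(cfg)
    expect_identical(length(refs), 3L)
    expect_true(all(Biostrings::width(refs) == 100L))
    expect_identical(names(refs), c("ref_0", "ref_1", "ref_2"))
    refs2 <- generateReferences(cfg)
    expect_identical(as.character(refs), as.character(refs2))
    other <- generateReferences(simulatorConfig(nRefs = 3, refLen = 100,
                                                nSamples = 5, seed = 43))
    expect_false(identical(as.character(refs), as.character(other)))
})

test_that("generated bases are uniform: each frequency within 0.25 +/- 0.01 at a million bases", {
    cfg <- simulatorConfig(nRefs = 10, refLen = 100000, nSamples = 1,
                           seed = 7)
    refs <- generateReferences(cfg)
    counts <- colSums(Biostrings::alphabetFrequency(refs)[, c("A", "C", "G",
                                                              "T")])
    freqs <- counts / sum(counts)
    expect_true(all(abs(freqs - 0.25) < 0.01))
})

test_that("a single SNV preserves length and labels exactly one position", {
    cfg <- simulatorConfig(nRefs = 1, refLen = 200, nSamples = 1,
                           mutsPerSample = 1e-9, typeProps = c(1, 0, 0),
                           seed = 5)
    ref <- random_dna(200, seed = 5)
    set.seed(8)
    res <- implantMutations(ref, cfg)
    expect_identical(nchar(res$sample), 200L)
    expect_identical(nrow(res$records), 1L)
    expect_identical(res$records$type, "SNV")
    expect_identical(sum(labelValues(res$truth) == 1L), 1L)
    expect_identical(sum(labelValues(res$truth) > 0L), 1L)
    ## Hamming distance to the reference is exactly 1
    a <- strsplit(ref, "")[[1]]
    b <- strsplit(res$sample, "")[[1]]
    expect_identical(sum(a != b), 1L)
    q <- res$records$position + 1L
    expect_identical(a[q] != b[q], TRUE)
    expect_identical(res$records$ref_allele, a[q])
    expect_identical(res$records$alt_allele, b[q])
})

test_that("a single deletion shortens the sample and labels the breakpoint position", {
    cfg <- simulatorConfig(nRefs = 1, refLen = 200, nSamples = 1,
                           mutsPerSample = 1e-9, typeProps = c(0, 0, 1),
                           indelLenRange = c(2, 2), seed = 5)
    ref <- random_dna(200, seed = 6)
    set.seed(9)
    res <- implantMutations(ref, cfg)
    expect_identical(nchar(res$sample), 198L)
    expect_identical(res$records$type, "DEL")
    expect_identical(res$records$length, 2L)
    expect_identical(sum(labelValues(res$truth) == 3L), 1L)
    expect_identical(which(labelValues(res$truth) == 3L),
                     res$records$position + 1L)
})

test_that("length bookkeeping and label/record consistency hold across many samples", {
    cfg <- simulatorConfig(nRefs = 2, refLen = 300, nSamples = 60,
                           mutsPerSample = 6, seed = 33)
    sim <- simulateDataset(cfg)
    recs <- simRecords(sim)
    for (id in names(simSamples(sim))) {
        r <- recs[recs$sample_id == id, ]
        lab <- simLabels(sim)[[id]]
        ins_total <- sum(r$length[r$type == "INS"])
        del_total <- sum(r$length[r$type == "DEL"])
        ## sample length = ref length + inserted - deleted
        expect_identical(Biostrings::width(simSamples(sim)[id]),
                         300L + ins_total - del_total)
        ## SNV positions <-> label 1; inserted bases <-> label 2;
        ## DEL events <-> label 3
        expect_identical(sort(which(lab == 1L) - 1L),
                         sort(r$position[r$type == "SNV"]))
        expect_identical(sum(lab == 2L), ins_total)
        expect_identical(sum(lab == 3L), sum(r$type == "DEL"))
        ## the sample carries each SNV's alt allele at the recorded position
        ch <- strsplit(as.character(simSamples(sim)[[id]]), "")[[1]]
        snv <- r[r$type == "SNV", ]
        expect_identical(ch[snv$position + 1L], snv$alt_allele)
    }
})

test_that("mutation type draws converge to the configured proportions (3-sigma envelope)", {
    cfg <- simulatorConfig(nRefs = 1, refLen = 300, nSamples = 2000,
                           mutsPerSample = 5, seed = 77)
    sim <- simulateDataset(cfg)
    recs <- simRecords(sim)
    n <- nrow(recs)
    expect_gt(n, 1e4)
    props <- c(0.7633, 0.1079, 0.1288)
    freqs <- c(mean(recs$type == "SNV"), mean(recs$type == "INS"),
               mean(recs$type == "DEL"))
    tol <- 3 * sqrt(props * (1 - props) / n)
    expect_true(all(abs(freqs - props) < tol))
})

test_that("identical config and seed give identical datasets; infeasible configs error", {
    cfg <- simulatorConfig(nRefs = 2, refLen = 150, nSamples = 8, seed = 9)
    a <- simulateDataset(cfg)
    b <- simulateDataset(cfg)
    expect_identical(as.character(simSamples(a)), as.character(simSamples(b)))
    expect_identical(simRecords(a), simRecords(b))
    ## more non-overlapping mutations than positions available
    bad <- simulatorConfig(nRefs = 1, refLen = 30, nSamples = 1,
                           mutsPerSample = 200, seed = 1)
    set.seed(1)
    expect_error(implantMutations(random_dna(30, seed = 2), bad),
                 "infeasible")
})

test_that("simulated reads slice sequence and labels identically", {
    cfg <- simulatorConfig(nRefs = 1, refLen = 300, nSamples = 1,
                           mutsPerSample = 8, readLen = 50,
                           readsPerSample = 40, seed = 21)
    set.seed(3)
    res <- implantMutations(random_dna(300, seed = 4), cfg)
    rd <- simulateReads(res$sample, res$truth, cfg)
    expect_identical(length(rd$reads), 40L)
    expect_true(all(nchar(rd$reads) == 50L))
    truth <- labelValues(res$truth)
    for (i in seq_along(rd$starts)) {
        o <- rd$starts[i]
        expect_identical(rd$reads[i], substr(res$sample, o + 1, o + 50))
        expect_identical(rd$labels[[i]], truth[(o + 1):(o + 50)])
    }
})

test_that("the SNV-only read filter drops reads containing indel labels", {
    cfg <- simulatorConfig(nRefs = 1, refLen = 300, nSamples = 1,
                           mutsPerSample = 6, typeProps = c(0, 0.5, 0.5),
                           readLen = 60, readsPerSample = 60, seed = 22)
    set.seed(14)
    res <- implantMutations(random_dna(300, seed = 15), cfg)
    rd <- simulateReads(res$sample, res$truth, cfg, snvOnly = TRUE)
    ## a sample with only indels yields only all-normal reads
    expect_true(all(vapply(rd$labels, function(v) all(v == 0L),
                           logical(1))))
    expect_error(simulateReads(res$sample, res$truth,
                               simulatorConfig(readLen = 144, seed = 1),
                               materialize = FALSE),
                 NA)
    short_cfg <- simulatorConfig(nRefs = 1, refLen = 300, nSamples = 1,
                                 readLen = 100, readsPerSample = 5,
                                 seed = 2)
    expect_error(simulateReads("ACGT", c(0L, 0L, 0L, 0L), short_cfg),
                 "exceeds")
})

test_that("read-set assembly counts records without materializing sequences", {
    cfg <- simulatorConfig(nRefs = 1, refLen = 300, nSamples = 24,
                           readLen = 144, readsPerSample = 1000, seed = 19)
    lens <- stats::setNames(rep(300L, 24), sprintf("s%d", 1:24))
    rs <- assembleReadSet(lens, cfg)
    expect_identical(nrow(rs), 24000L)
    expect_true(all(rs$start >= 0 & rs$start <= 300 - 144))
    expect_identical(plannedReadCount(cfg), 24000)
    big <- simulatorConfig(nRefs = 1, refLen = 300, nSamples = 24,
                           readLen = 144, readsPerSample = 500000, seed = 1)
    expect_identical(plannedReadCount(big), 12e6)
})

test_that("export and load round-trip a dataset exactly, including determinism on disk", {
    cfg <- simulatorConfig(nRefs = 2, refLen = 200, nSamples = 6, seed = 12)
    sim <- simulateDataset(cfg)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    exportDataset(sim, d1)
    back <- loadDataset(d1)
    expect_identical(as.character(simSamples(back)),
                     as.character(simSamples(sim)))
    expect_identical(simLabels(back), simLabels(sim))
    expect_identical(simRecords(back), simRecords(sim))
    expect_identical(nrow(simRecords(back)),
                     nrow(read.delim(file.path(d1, "mutations.tsv"))))
    ## byte-identical files from a rerun of the same config
    exportDataset(simulateDataset(cfg), d2)
    for (f in c("refs.fasta", "samples.fasta", "labels.tsv",
                "mutations.tsv", "manifest.txt"))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))))
})

test_that("an empty dataset exports to valid files and loads back", {
    cfg <- simulatorConfig(nRefs = 1, refLen = 100, nSamples = 1, seed = 3)
    empty <- new("MutSimData", refs = Biostrings::DNAStringSet(),
                 samples = Biostrings::DNAStringSet(), labels = list(),
                 records = mutTCN:::empty_records(), config = cfg)
    d <- withr::local_tempdir()
    exportDataset(empty, d)
    expect_true(all(file.exists(file.path(d, c("samples.fasta",
                                               "labels.tsv",
                                               "mutations.tsv",
                                               "manifest.txt")))))
    back <- loadDataset(d)
    expect_identical(length(simSamples(back)), 0L)
    expect_identical(nrow(simRecords(back)), 0L)
})
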