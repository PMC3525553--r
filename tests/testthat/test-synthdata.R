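test_that("genome generation honours sizing, determinism and locus invariants", {
    g0 <- generateGenome(10000, 0, seed = 1)
    expect_identical(nrow(plantedLoci(g0$truth)), 0L)
    expect_identical(Biostrings::width(g0$genome), 10000L)
    expect_error(generateGenome(1000, 10, seed = 1), "too small")
    g1 <- generateGenome(50000, 10, seed = 7)
    g2 <- generateGenome(50000, 10, seed = 7)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    expect_identical(plantedLoci(g1$truth), plantedLoci(g2$truth))
    L <- plantedLoci(g1$truth)
    expect_identical(nrow(L), 10L)
    expect_true(all(L$mature_len >= 20 & L$mature_len <= 24))
    expect_true(all(L$start >= 0 & L$end <= 50000))
    ov <- order(L$start)
    expect_true(all(L$start[ov][-1] >= L$end[ov][-10]))   # pairwise disjoint
    # every planted hairpin window folds to an accepted hairpin
    for (i in seq_len(nrow(L))) {
        x <- L[i, ]
        st <- if (x$strand == "+") x$start + x$mature_start else
            x$start + (x$end - x$start) - x$mature_start - x$mature_len
        w <- extractHairpinWindow(g1$genome, "chr1", st, x$mature_len,
            x$strand)
        expect_true(isHairpin(foldHairpin(w$window, w$matureOffset,
            x$mature_len)))
    }
})

test_that("read simulation conserves counts and plants recoverable inserts", {
    g <- generateGenome(5000, 3, seed = 2)
    r <- generateReferences(g$genome, g$truth, seed = 3)
    empty <- simulateReads(r$truth, r$refs$decoys, 0, seed = 1)
    expect_length(empty$reads, 0)
    rr <- simulateReads(r$truth, r$refs$decoys, 997, fracMirna = 0.7,
        fracContaminant = 0.1, seed = 5)
    expect_length(rr$reads, 997)
    tab <- table(rr$categories)
    expect_lte(abs(tab[["mirna"]] - round(0.7 * 997)), 1)
    expect_lte(abs(tab[["contaminant"]] - round(0.1 * 997)), 1)
    # determinism
    rr2 <- simulateReads(r$truth, r$refs$decoys, 997, fracMirna = 0.7,
        fracContaminant = 0.1, seed = 5)
    expect_identical(rr$reads, rr2$reads)
    # empty truth with miRNA reads requested is a configuration error
    g0 <- generateGenome(1000, 0, seed = 1)
    expect_error(simulateReads(g0$truth, r$refs$decoys, 10,
        fracMirna = 0.5, seed = 1), "no planted matures")
    expect_error(simulateReads(r$truth, r$refs$decoys, 10, fracMirna = 0.8,
        fracContaminant = 0.4, seed = 1), "<= 1")
})

test_that("a single planted mature dominates a pure-miRNA read set", {
    truth <- new("GroundTruth",
        loci = data.frame(id = "L1", start = 0L, end = 60L, strand = "+",
            hairpin_seq = strrep("A", 60),
            mature_seq = "ACGTACGTACGTACGTACGTAC", mature_start = 3L,
            mature_len = 22L, role = "unassigned"),
        foreign = data.frame(id = character(), hairpin_seq = character(),
            mature_seq = character(), class = character()),
        decoys = data.frame(id = character(), category = character()),
        profileAssignments = integer(),
        trueLog2Means = matrix(numeric(), 0, 0),
        genomeLength = 100L, seed = 1L)
    rr <- simulateReads(truth, list(), 100, fracMirna = 1,
        fracContaminant = 0, seed = 3)
    adapter <- rr$adapter
    inserts <- stripAdapter(rr$reads, adapter, 0)
    expect_false(anyNA(inserts))
    expect_true(all(nchar(inserts) >= 20 & nchar(inserts) <= 24))
    expect_gte(sum(inserts == "ACGTACGTACGTACGTACGTAC"), 1)
})

test_that("signal simulation plants exact cumulative-doubling stage means", {
    pr <- enumerateProfiles()
    up <- which(apply(pr$steps, 1, function(s) all(s == 1)))
    sim <- simulateSignalMatrix(c("p1", "p2"),
        c(p1 = up, p2 = 0L), pr, baseIntensity = 500, noiseSd = 0,
        seed = 4)
    m <- stageMeans(sim$se)
    expect_equal(unname(m["p1", ]), c(500, 1000, 2000, 4000),
        tolerance = 1e-9)
    # flat probe: all 12 values identical
    expect_equal(diff(range(
        SummarizedExperiment::assay(sim$se, "signal")["p2", ])), 0)
    expect_error(simulateSignalMatrix("p1", c(p1 = 0L), pr,
        noiseSd = -1, seed = 1), "noiseSd")
})

test_that("generators are byte-identical under a fixed seed", {
    g <- generateGenome(8000, 6, seed = 9)
    r1 <- generateReferences(g$genome, g$truth, seed = 10)
    r2 <- generateReferences(g$genome, g$truth, seed = 10)
    expect_identical(lapply(r1$refs[1:6], as.character),
        lapply(r2$refs[1:6], as.character))
    f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(r1$refs$genome, f1)
    Biostrings::writeXStringSet(r2$refs$genome, f2)
    expect_identical(readLines(f1), readLines(f2))
    s1 <- simulateSignalMatrix("p1", c(p1 = 3L), noiseSd = 0.2, seed = 6)
    s2 <- simulateSignalMatrix("p1", c(p1 = 3L), noiseSd = 0.2, seed = 6)
    expect_identical(SummarizedExperiment::assay(s1$se),
        SummarizedExperiment::assay(s2$se))
    q1 <- simulateQpcr(matrix(c(1, 2, 4, 8), 1,
        dimnames = list("m", NULL)), jitterSd = 0.3, seed = 2)
    q2 <- simulateQpcr(matrix(c(1, 2, 4, 8), 1,
        dimnames = list("m", NULL)), jitterSd = 0.3, seed = 2)
    expect_identical(q1, q2)
})

test_that("simulated target data plants conserved sites and no-target miRNAs", {
    set.seed(1)
    mir <- setNames(vapply(1:10, function(i) rand_dna(22), character(1)),
        sprintf("m%02d", 1:10))
    td <- generateTargetData(mir, nGenes = 40, seed = 3)
    edges <- do.call(rbind, lapply(names(td$utrs), function(sp)
        predictTargets(mir, td$utrs[[sp]], sp)))
    cons <- conservedTargets(edges, 3)
    # every planted pair is recovered as conserved
    planted_keys <- paste(td$trueTargets$mirna, td$trueTargets$gene)
    expect_true(all(planted_keys %in% paste(cons$mirna, cons$gene)))
    # the no-target miRNAs have no planted pairs
    no_t <- setdiff(names(mir), unique(td$trueTargets$mirna))
    expect_length(no_t, 3)
})
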