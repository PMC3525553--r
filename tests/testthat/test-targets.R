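test_that("seed matches are found wherever the 7-mer site occurs", {
    set.seed(41)
    mir <- c(m1 = "TGAGGTAGTAGGTTGTATAGTT")       # let-7-like, DNA alphabet
    site <- unname(rc(substr(mir, 2, 8)))
    utr_hit <- paste0(rand_dna(50), site, rand_dna(30))
    utr_miss <- rand_dna(100)
    edges <- predictTargets(mir, c(gA = utr_hit, gB = utr_miss))
    expect_identical(nrow(edges), 1L)
    expect_identical(edges$gene, "gA")
    expect_identical(edges$position, 50L)
    expect_identical(substr(utr_hit, edges$position + 1,
        edges$position + 7), site)
    # all occurrences reported; equality with a naive scan
    utr2 <- paste0(site, rand_dna(20), site)
    e2 <- predictTargets(mir, c(g2 = utr2))
    naive <- gregexpr(site, utr2, fixed = TRUE)[[1]]
    expect_identical(e2$position, as.integer(naive) - 1L)
    # short miRNAs are skipped with a warning
    expect_warning(e3 <- predictTargets(c(bad = "ACGTA"), c(g = utr2)),
        "shorter")
    expect_identical(nrow(e3), 0L)
})

test_that("conservation keeps pairs supported in enough species", {
    edges <- rbind(
        data.frame(mirna = "m1", gene = "g1", species = c("pig", "mouse",
            "human"), position = 0L, site_type = "seed_2_8"),
        data.frame(mirna = "m1", gene = "g2", species = "pig",
            position = 0L, site_type = "seed_2_8"))
    kept <- conservedTargets(edges, 3)
    expect_setequal(unique(kept$gene), "g1")
    expect_identical(conservedTargets(edges, 1), edges)
    # brute-force recount on random edge sets
    set.seed(6)
    re <- data.frame(
        mirna = sample(c("m1", "m2"), 60, TRUE),
        gene = sample(sprintf("g%d", 1:6), 60, TRUE),
        species = sample(c("pig", "mouse", "human"), 60, TRUE),
        position = 0L, site_type = "seed_2_8")
    kept2 <- conservedTargets(re, 2)
    for (i in seq_len(nrow(re))) {
        nsp <- length(unique(re$species[re$mirna == re$mirna[i] &
            re$gene == re$gene[i]]))
        expect_identical(i %in% as.integer(rownames(kept2)), nsp >= 2)
    }
})

test_that("enrichment p-values equal exact hypergeometric tails", {
    universe <- sprintf("g%02d", 1:20)
    ann <- rbind(
        data.frame(term = "T1", gene = universe[1:5], category = "GO"),
        data.frame(term = "T2", gene = universe[11:16], category = "GO"),
        data.frame(term = "P1", gene = universe[1:6], category = "pathway"))
    geneSet <- universe[1:5]
    res <- enrichTerms(geneSet, ann, universe)
    t1 <- res[res$term == "T1", ]
    expect_equal(t1$p_value, oracle_hyper_tail(5, 5, 20, 5),
        tolerance = 1e-12)
    # a term matching the whole query in a large universe passes both filters
    expect_true(t1$p_value < 1e-4)
    expect_identical(res$p_value[res$term == "T2"], 1)   # disjoint term
    # random toy instances against the combinatorial oracle
    set.seed(9)
    for (i in 1:20) {
        N <- sample(10:30, 1)
        uni <- sprintf("u%02d", seq_len(N))
        tg <- sample(uni, sample(3:N, 1))
        qs <- sample(uni, sample(3:N, 1))
        r <- enrichTerms(qs, data.frame(term = "t", gene = tg,
            category = "GO"), uni)
        expect_equal(r$p_value,
            oracle_hyper_tail(length(intersect(tg, qs)), length(tg), N,
                length(qs)), tolerance = 1e-12)
    }
    expect_error(enrichTerms(c("zzz"), ann, universe), "subset")
})

test_that("the bipartite network restricts to the intersection genes and ranks by degree", {
    edges <- data.frame(mirna = rep("m1", 5),
        gene = sprintf("g%d", 1:5), stringsAsFactors = FALSE)
    net <- buildNetwork(edges, goGenes = sprintf("g%d", 1:5),
        pathwayGenes = sprintf("g%d", 1:5))
    expect_identical(unname(mirnaDegree(net)["m1"]), 5L)
    expect_true(all(geneDegree(net) == 1L))
    # empty intersection gives an empty, valid network
    net0 <- buildNetwork(edges, "g1", "g2")
    expect_identical(nrow(networkEdges(net0)), 0L)
    # degree sums equal the edge count on random networks
    set.seed(14)
    re <- unique(data.frame(mirna = sample(sprintf("m%d", 1:6), 40, TRUE),
        gene = sample(sprintf("g%d", 1:8), 40, TRUE)))
    netr <- buildNetwork(re, sprintf("g%d", 1:8), sprintf("g%d", 1:8))
    expect_identical(sum(mirnaDegree(netr)), nrow(networkEdges(netr)))
    expect_identical(sum(geneDegree(netr)), nrow(networkEdges(netr)))
    for (m in names(mirnaDegree(netr)))
        expect_identical(unname(mirnaDegree(netr)[m]),
            sum(networkEdges(netr)$mirna == m))
})

test_that("key-miRNA selection applies the degree and signal filters disjointly", {
    cands <- sprintf("m%02d", 1:38)
    connected <- cands[1:26]
    edges <- data.frame(mirna = connected, gene = sprintf("g%02d", 1:26))
    net <- buildNetwork(edges, edges$gene, edges$gene)
    signals <- setNames(rep(600, 38), cands)
    signals[connected[1:8]] <- 300               # low-signal among connected
    res <- selectKeyMirnas(cands, net, signals)
    expect_identical(res$nCandidates, 38L)
    expect_identical(res$nAfterDegree, 26L)
    expect_identical(res$nKey, 18L)
    rep_ <- res$report
    expect_identical(sum(rep_$removed_no_target), 12L)
    expect_identical(sum(rep_$removed_low_signal), 8L)
    expect_false(any(rep_$removed_no_target & rep_$removed_low_signal))
    expect_identical(res$nKey,
        res$nCandidates - sum(rep_$removed_no_target) -
            sum(rep_$removed_low_signal))
    # permissive thresholds keep everything
    all_in <- selectKeyMirnas(cands, net, signals, minDegree = 0,
        minSignal = 0)
    expect_identical(all_in$nKey, 38L)
})
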