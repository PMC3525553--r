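ADAPTER <- "TCGTATGCCGTCTTCTGCTTG"

test_that("adapter stripping finds the leftmost occurrence and rejects dimers", {
    expect_equal(stripAdapter(paste0("ACGTACGT", ADAPTER), ADAPTER, 0),
        "ACGTACGT")
    # adapter alone is an adapter dimer: empty insert, rejected
    expect_true(is.na(stripAdapter(ADAPTER, ADAPTER, 0)))
    # no adapter at all: unligated, rejected
    expect_true(is.na(stripAdapter("ACGTACGTACGTACGTACGT", ADAPTER, 0)))
    # partial adapter at the 3' end with >= 6 nt overlap is enough
    expect_equal(
        stripAdapter(paste0("GGGTTTCCC", substr(ADAPTER, 1, 7)), ADAPTER, 0),
        "GGGTTTCCC")
    # adapter shorter than the minimum overlap is a configuration error
    expect_error(stripAdapter("ACGT", "ACG", 0), "overlap")
})

test_that("planted inserts are recovered from 1000 reads with <= 1 adapter mismatch", {
    set.seed(11)
    inserts <- vapply(sample(18:24, 1000, replace = TRUE), rand_dna,
        character(1))
    mutate1 <- function(a) {
        p <- sample.int(nchar(a), 1)
        substr(a, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
            substr(a, p, p)), 1)
        a
    }
    adapters <- ifelse(seq_len(1000) %% 2 == 0, ADAPTER,
        vapply(seq_len(500), function(i) mutate1(ADAPTER), character(1)))
    got <- stripAdapter(paste0(inserts, adapters), ADAPTER, maxMismatch = 1)
    expect_identical(got, inserts)
})

test_that("collapsing unique tags conserves reads and orders deterministically", {
    tags <- collapseUnique(c("AAA", "AAA", "CCC"))
    expect_identical(as.character(tagSequences(tags)),
        c(tag1 = "AAA", tag2 = "CCC"))
    expect_identical(tagCounts(tags), c(2L, 1L))
    expect_length(collapseUnique(character()), 0)
    # conservation on random input, order-independence
    set.seed(3)
    reads <- sample(c("ACGT", "TTTT", "GGCC", "ACGA"), 200, replace = TRUE)
    tags <- collapseUnique(reads)
    expect_identical(sum(tagCounts(tags)), 200L)
    expect_identical(as.data.frame(collapseUnique(rev(reads))),
        as.data.frame(tags))
})

test_that("length/copy filter matches its set-comprehension oracle", {
    params <- filterParams()
    expect_length(filterTags(UniqueTagSet(strrep("A", 14), 10L), params), 0)
    expect_length(filterTags(UniqueTagSet(strrep("A", 22), 2L), params), 0)
    expect_length(filterTags(UniqueTagSet(strrep("A", 22), 3L), params), 1)
    set.seed(7)
    tags <- UniqueTagSet(
        vapply(sample(10:30, 50, replace = TRUE), rand_dna, character(1)),
        sample(1:6, 50, replace = TRUE))
    kept <- filterTags(tags, params)
    w <- nchar(as.character(tagSequences(tags)))
    keep <- w >= 15 & w <= 26 & tagCounts(tags) >= 3
    expect_identical(as.data.frame(kept),
        as.data.frame(tags[keep]))
    # idempotence
    expect_identical(as.data.frame(filterTags(kept, params)),
        as.data.frame(kept))
})

test_that("contaminant removal is exact-substring, both strands, first category wins", {
    set.seed(5)
    mrna <- rand_dna(200)
    rfam <- rand_dna(120)
    decoys <- list(mRNA = c(m1 = mrna), Rfam = c(r1 = rfam),
        Repbase = c(p1 = rand_dna(150)))
    inside <- substr(mrna, 40, 61)              # 22-nt slice of an mRNA decoy
    inside_rc <- rc(substr(rfam, 10, 31))       # minus-strand Rfam slice
    outside <- rand_dna(22)
    tags <- UniqueTagSet(c(inside, inside_rc, outside), c(5L, 5L, 5L))
    res <- removeContaminants(tags, decoys)
    expect_identical(as.character(tagSequences(res$kept)),
        c(tag3 = outside))
    expect_identical(res$report$removed, c(1L, 1L, 0L))
    expect_identical(sum(res$report$removed) + length(res$kept),
        length(tags))
    # idempotence
    again <- removeContaminants(res$kept, decoys)
    expect_identical(as.data.frame(again$kept), as.data.frame(res$kept))
    expect_true(all(again$report$removed == 0L))
})

test_that("contaminant removal agrees with a naive substring scan", {
    set.seed(13)
    decoys <- list(mRNA = setNames(vapply(1:3, function(i) rand_dna(80),
        character(1)), paste0("m", 1:3)))
    pool <- c(vapply(1:10, function(i) rand_dna(18), character(1)),
        vapply(1:10, function(i) {
            d <- decoys$mRNA[[sample.int(3, 1)]]
            p <- sample.int(80 - 18, 1)
            substr(d, p, p + 17)
        }, character(1)))
    tags <- UniqueTagSet(unique(pool), rep(3L, length(unique(pool))))
    res <- removeContaminants(tags, decoys)
    naive_hit <- vapply(as.character(tagSequences(tags)), function(s)
        any(grepl(s, decoys$mRNA, fixed = TRUE)) ||
        any(grepl(rc(s), decoys$mRNA, fixed = TRUE)), logical(1))
    expect_identical(unname(as.character(tagSequences(res$kept))),
        unname(as.character(tagSequences(tags))[!naive_hit]))
})

test_that("the cleaning funnel is monotone and conserves tag accounting", {
    st <- simulateStudy(seed = 5, nReads = 2000)
    res <- cleanReads(st$reads$reads, st$refs$decoys)
    n <- res$stats$n
    expect_true(all(diff(n[2:5]) <= 0))          # tags only ever shrink
    expect_identical(n[1], 2000L)
})

test_that("a fully contaminant read set leaves zero tags", {
    st <- simulateStudy(seed = 9, nLoci = 4, genomeLength = 2000,
        nReads = 10)
    reads <- simulateReads(st$truth, st$refs$decoys, 300, fracMirna = 0,
        fracContaminant = 1, seed = 4)
    expect_true(all(reads$categories == "contaminant"))
    res <- cleanReads(reads$reads, st$refs$decoys,
        filterParams(minCount = 1L))
    expect_length(res$tags, 0)
})
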