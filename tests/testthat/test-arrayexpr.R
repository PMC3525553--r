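make_se <- function(values) SignalMatrix(values)

test_that("quantile normalization fixes columns to a common distribution", {
    set.seed(19)
    base <- 2^rnorm(100, 8, 2)
    # identical columns are (numerically) a fixed point
    m <- matrix(rep(base, 12), ncol = 12)
    nm <- SummarizedExperiment::assay(normalizeSignal(make_se(m)), "signal")
    expect_equal(unname(nm), unname(m), tolerance = 1e-12)
    # columns that permute each other end with identical sorted values
    m2 <- cbind(matrix(rep(base, 11), ncol = 11), sample(base))
    nm2 <- SummarizedExperiment::assay(normalizeSignal(make_se(m2)), "signal")
    expect_equal(unname(apply(nm2, 2, function(x) sort(unname(x)))),
        unname(apply(nm2[, rep(1, 12)], 2, function(x) sort(unname(x)))))
    # property: every column's quantiles equal the reference quantiles
    m3 <- matrix(2^rnorm(1200, 8, 2), ncol = 12)
    nm3 <- SummarizedExperiment::assay(normalizeSignal(make_se(m3)), "signal")
    ref <- sort(unname(nm3[, 1]))
    for (j in 2:12) expect_equal(sort(unname(nm3[, j])), ref,
        tolerance = 1e-8)
    expect_equal(diff(range(apply(nm3, 2, stats::median))), 0,
        tolerance = 1e-8)
    # degenerate all-zero column errors
    m4 <- m3; m4[, 3] <- 0
    expect_error(normalizeSignal(make_se(m4)), "degenerate")
})

test_that("detectability calls follow stage means against the floor", {
    m <- rbind(p1 = rep(c(100, 10, 100, 10), each = 3),
               p2 = rep(5, 12))
    det <- callDetectable(make_se(m), 32)
    expect_identical(unname(det$detectable["p1", ]),
        c(TRUE, FALSE, TRUE, FALSE))
    expect_false(det$global["p2"])
    expect_identical(det$nDetectable, 1L)
    all_det <- callDetectable(make_se(m), 0)
    expect_true(all(all_det$detectable))
})

test_that("stage ANOVA matches the closed-form computation and conventions", {
    # all values equal: zero between-group variance, p = 1 by convention
    expect_identical(unname(anovaStageTest(make_se(matrix(64, 1, 12)))), 1)
    # zero within-group variance but stage means differ: p = 0
    m0 <- matrix(rep(c(4, 5, 6, 7), each = 3), 1)
    expect_identical(unname(anovaStageTest(make_se(2^m0))), 0)
    # worked 4x3 example against the explicit sum-of-squares formula
    y <- c(7.1, 7.3, 7.0, 8.2, 8.0, 8.4, 7.9, 8.1, 8.3, 9.0, 9.2, 8.8)
    p_pkg <- unname(anovaStageTest(make_se(matrix(2^y, 1))))
    g <- rep(1:4, each = 3)
    gm <- tapply(y, g, mean)
    ss_b <- sum(3 * (gm - mean(y))^2)
    ss_w <- sum((y - gm[g])^2)
    f <- (ss_b / 3) / (ss_w / 8)
    expect_equal(p_pkg, stats::pf(f, 3, 8, lower.tail = FALSE),
        tolerance = 1e-10)
})

test_that("pairwise Welch test matches the textbook formula", {
    a <- c(7.9, 8.1, 8.0); b <- c(8.9, 9.2, 9.1)
    se <- make_se(matrix(2^c(a, b, a, b), 1))
    p_pkg <- unname(pairwiseStageTest(se, "E35", "E45"))
    sa <- stats::var(a) / 3; sb <- stats::var(b) / 3
    t_stat <- (mean(a) - mean(b)) / sqrt(sa + sb)
    df <- (sa + sb)^2 / (sa^2 / 2 + sb^2 / 2)
    expect_equal(p_pkg, 2 * stats::pt(-abs(t_stat), df), tolerance = 1e-10)
    # identical triplicates in both stages: p = 1
    se2 <- make_se(matrix(2^rep(8, 12), 1))
    expect_identical(unname(pairwiseStageTest(se2, "E35", "E60")), 1)
})

test_that("DE thresholds nest and baseline fold change is 1", {
    st <- simulateStudy(seed = 12)
    de <- deTable(normalizeSignal(st$signal$se))
    p01 <- de$probe[de$p_anova < 0.01]
    p05 <- de$probe[de$p_anova < 0.05]
    p10 <- de$probe[de$p_anova < 0.1]
    expect_true(all(p01 %in% p05) && all(p05 %in% p10))
    fc_base <- de$mean_E35 / de$mean_E35
    expect_true(all(fc_base == 1))
    expect_equal(de$signal,
        pmax(de$mean_E35, de$mean_E45, de$mean_E50, de$mean_E60))
})

test_that("average-linkage clustering matches a brute-force agglomeration", {
    # two identical probes merge at height 0; anti-correlated one joins last
    m <- rbind(a = 2^c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4),
               b = 2^c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4),
               c = 2^c(4, 4, 4, 3, 3, 3, 2, 2, 2, 1, 1, 1))
    cl <- hierarchicalCluster(make_se(m))
    expect_equal(cl$heights[1], 0, tolerance = 1e-12)
    expect_identical(sort(cl$hclust$merge[1, ]), c(-2L, -1L))
    expect_match(cl$newick, "^\\(")
    set.seed(23)
    m8 <- matrix(2^rnorm(96, 8, 1), nrow = 8,
        dimnames = list(sprintf("p%d", 1:8), NULL))
    cl8 <- hierarchicalCluster(make_se(m8))
    lg <- log2(stageMeans(make_se(m8)))
    d <- 1 - stats::cor(t(lg))
    expect_equal(sort(cl8$heights), oracle_upgma_heights(stats::as.dist(d)),
        tolerance = 1e-10)
})

test_that("strength filter keeps probes at or above the signal floor", {
    de <- data.frame(probe = c("a", "b"), signal = c(499, 501))
    expect_identical(strengthFilter(de, 500)$probe, "b")
    expect_identical(strengthFilter(de, 0), de)
    set.seed(2)
    de2 <- data.frame(probe = sprintf("p%d", 1:50),
        signal = stats::runif(50, 0, 1000))
    expect_identical(strengthFilter(de2, 500),
        de2[de2$signal >= 500, , drop = FALSE])
})
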