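# Independent oracles used across the suite. These are deliberately naive
# re-computations (exhaustive scans, textbook formulas, quadratic DPs)
# kept separate from the package's own code paths.

rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rand_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Weighted Nussinov optimal score, pure-R iterative DP (score only).
oracle_nussinov_score <- function(seq, min_loop = 3L) {
    w <- function(a, b) {
        key <- paste0(a, b)
        if (key %in% c("GC", "CG")) return(3L)
        if (key %in% c("AT", "TA")) return(2L)
        if (key %in% c("GT", "TG")) return(1L)
        0L
    }
    s <- strsplit(seq, "")[[1]]
    n <- length(s)
    S <- matrix(0L, n, n)
    if (n < min_loop + 2L) return(0L)
    for (len in (min_loop + 2L):n) {
        for (i in seq_len(n - len + 1L)) {
            j <- i + len - 1L
            best <- max(S[i + 1L, j], S[i, j - 1L])
            wij <- w(s[i], s[j])
            if (wij > 0L && j - i > min_loop)
                best <- max(best, S[i + 1L, j - 1L] + wij)
            if (j - i >= 2L) {
                for (k in (i + 1L):(j - 1L))
                    best <- max(best, S[i, k] + S[k + 1L, j])
            }
            S[i, j] <- best
        }
    }
    S[1L, n]
}

# Structure sanity: pairs must be nested, pairable, respect the minimum
# loop, and their weights must sum to the reported score.
oracle_check_structure <- function(seq, pairs, score, min_loop = 3L) {
    s <- strsplit(seq, "")[[1]]
    wt <- c(GC = 3L, CG = 3L, AT = 2L, TA = 2L, GT = 1L, TG = 1L)
    if (nrow(pairs) == 0L) return(score == 0L)
    if (any(duplicated(as.vector(pairs)))) return(FALSE)
    if (any(pairs[, 2] - pairs[, 1] <= min_loop)) return(FALSE)
    keys <- paste0(s[pairs[, 1]], s[pairs[, 2]])
    if (any(!keys %in% names(wt))) return(FALSE)
    if (sum(wt[keys]) != score) return(FALSE)
    for (a in seq_len(nrow(pairs))) for (b in seq_len(nrow(pairs))) {
        if (a == b) next
        i <- pairs[a, 1]; j <- pairs[a, 2]
        k <- pairs[b, 1]; l <- pairs[b, 2]
        crossing <- i < k && k < j && j < l
        if (crossing) return(FALSE)
    }
    TRUE
}

# All occurrences of `tag` in `ref` with <= mm substitutions (one strand).
oracle_hamming_scan <- function(tag, ref, mm) {
    nt <- nchar(tag); nr <- nchar(ref)
    if (nr < nt) return(integer())
    tv <- utf8ToInt(tag)
    hits <- integer()
    for (p in 0:(nr - nt)) {
        sub <- utf8ToInt(substr(ref, p + 1L, p + nt))
        if (sum(sub != tv) <= mm) hits <- c(hits, p)
    }
    hits
}

# Exact hypergeometric upper tail P(X >= k) via choose() sums.
oracle_hyper_tail <- function(k, K, N, n) {
    xs <- k:min(K, n)
    sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Brute-force UPGMA (average linkage on the original distance matrix);
# returns sorted merge heights.
oracle_upgma_heights <- function(d) {
    d <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(d)))
    heights <- numeric()
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestd <- Inf
        for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
            if (a >= b) next
            avg <- mean(d[clusters[[a]], clusters[[b]]])
            if (avg < bestd) { bestd <- avg; best <- c(a, b) }
        }
        heights <- c(heights, bestd)
        merged <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters <- clusters[-best]
        clusters[[length(clusters) + 1L]] <- merged
    }
    sort(heights)
}

# Literal re-evaluation of the six classification rules from the hit
# predicates, used to cross-check classifyTags on small instances.
oracle_classify <- function(ids, widths, hits, pre_gm, hairpin_ids) {
    in_hits <- function(tag, h) tag %in% h$tag_id
    loci_of <- function(tag, h, w) {
        x <- h[h$tag_id == tag, , drop = FALSE]
        if (nrow(x)) cbind(x[, c("target_id", "start")], end = x$start + w)
        else x
    }
    overlaps <- function(a, b) {
        if (!nrow(a) || !nrow(b)) return(rep(FALSE, nrow(a)))
        sapply(seq_len(nrow(a)), function(i) any(
            a$target_id[i] == b$target_id & a$start[i] < b$end &
            b$start < a$end[i]))
    }
    res <- setNames(rep("unclassified", length(ids)), ids)
    claims <- list(gp1a = NULL, gp1b = NULL, gp1c = NULL)
    cl <- function(g) {
        x <- do.call(rbind, claims[g])
        if (is.null(x)) data.frame(target_id = character(),
            start = integer(), end = integer()) else x
    }
    for (rule in c("gp1a", "gp1b", "gp1c", "gp2", "gp3", "gp4")) {
        for (tag in ids) {
            if (res[tag] != "unclassified") next
            w <- widths[[tag]]
            ssc <- in_hits(tag, hits$ssc_mirna)
            oth <- in_hits(tag, hits$other_mirna)
            gen <- in_hits(tag, hits$genome)
            est <- in_hits(tag, hits$est)
            oth_pre_gm <- any(hits$other_mirna$target_id[
                hits$other_mirna$tag_id == tag] %in% pre_gm)
            hp <- tag %in% hairpin_ids
            loci <- rbind(loci_of(tag, hits$genome, w),
                loci_of(tag, hits$est, w))
            ok <- switch(rule,
                gp1a = ssc && (gen || est),
                gp1b = oth && (gen || est) && oth_pre_gm &&
                    any(!overlaps(loci, cl("gp1a"))),
                gp1c = !ssc && !oth && est && hp &&
                    any(!overlaps(loci, cl(c("gp1a", "gp1b")))),
                gp2 = oth && gen && !oth_pre_gm,
                gp3 = oth && !gen && !oth_pre_gm,
                gp4 = !ssc && !oth && gen && hp &&
                    any(!overlaps(loci_of(tag, hits$genome, w),
                        cl(c("gp1a", "gp1b", "gp1c")))))
            if (isTRUE(ok)) {
                res[tag] <- rule
                if (rule %in% names(claims)) {
                    free <- loci[!overlaps(loci, cl(switch(rule,
                        gp1a = character(), gp1b = "gp1a",
                        gp1c = c("gp1a", "gp1b")))), , drop = FALSE]
                    if (rule == "gp1a") free <- loci
                    claims[[rule]] <- rbind(claims[[rule]], free)
                }
            }
        }
    }
    res
}
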