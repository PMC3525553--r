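# Read-cleaning funnel: adapter stripping, collapsing raw reads into unique
# tags, length/copy-number filtering and contaminant removal. Each stage's
# output tag set is a subset of its input (funnel monotonicity), and
# collapsing conserves the total read count.

#' Filter parameters for the read-cleaning funnel
#'
#' Defaults follow the study design this pipeline models: clean reads are
#' 15-26 nt and only high-copy tags (count >= 3) are retained.
#'
#' @param minLen,maxLen Length window in nt for clean tags.
#' @param minCount Copy-number cut-off; kept when
#'   `count (countComparator) minCount`.
#' @param adapter 3' adapter sequence (used by [stripAdapter()]).
#' @param maxAdapterMismatch Substitutions tolerated in the adapter match.
#' @param countComparator `">="` (default) or `">"`.
#' @return A named list of validated parameters.
#' @export
filterParams <- function(minLen = 15L, maxLen = 26L, minCount = 3L,
                         adapter = "TCGTATGCCGTCTTCTGCTTG",
                         maxAdapterMismatch = 1L, countComparator = ">=") {
    if (minLen > maxLen) stopf("minLen (%d) must be <= maxLen (%d)", minLen, maxLen)
    if (minCount < 1L) stopf("minCount must be >= 1")
    countComparator <- match.arg(countComparator, c(">=", ">"))
    list(minLen = as.integer(minLen), maxLen = as.integer(maxLen),
        minCount = as.integer(minCount), adapter = toupper(adapter),
        maxAdapterMismatch = as.integer(maxAdapterMismatch),
        countComparator = countComparator)
}

#' Strip the 3' adapter from raw reads
#'
#' Finds the leftmost adapter occurrence in each read allowing up to
#' `maxMismatch` substitutions over the aligned adapter prefix, requiring at
#' least `minOverlap` aligned bases at the read's 3' end, and returns the
#' insert preceding it. Reads without an adapter hit are rejected (unligated
#' molecules), as are empty inserts (adapter dimers).
#'
#' @param reads Character vector or `DNAStringSet` of raw reads.
#' @param adapter 3' adapter sequence (>= `minOverlap` nt).
#' @param maxMismatch Substitutions tolerated (default 1).
#' @param minOverlap Minimum aligned adapter bases (default 6).
#' @return Character vector of inserts, `NA` where the read was rejected.
#' @examples
#' stripAdapter(c("ACGTACGTTCGTATGCCG"), "TCGTATGCCGTCTTCTGCTTG", 0)
#' @export
stripAdapter <- function(reads, adapter, maxMismatch = 1L, minOverlap = 6L) {
    adapter <- toupper(adapter)
    if (nchar(adapter) < minOverlap)
        stopf("adapter (%d nt) is shorter than the minimum overlap (%d nt)",
            nchar(adapter), minOverlap)
    reads <- toupper(as.character(reads))
    pos <- .find_adapter_start(reads, adapter, as.integer(maxMismatch),
        as.integer(minOverlap))
    insert <- ifelse(pos > 0L, substr(reads, 1L, pos - 1L), NA_character_)
    insert[!is.na(insert) & nchar(insert) == 0L] <- NA_character_
    insert
}

#' Collapse reads into unique tags
#'
#' One tag per distinct sequence; counts sum to the number of input reads.
#' Output is sorted by descending count, ties broken lexicographically, so
#' downstream results are order-independent.
#'
#' @param reads Character vector of (adapter-stripped) read sequences;
#'   `NA` entries (rejected reads) are dropped.
#' @return A [UniqueTagSet-class].
#' @examples
#' collapseUnique(c("AAA", "AAA", "CCC"))
#' @export
collapseUnique <- function(reads) {
    reads <- as.character(reads)
    reads <- reads[!is.na(reads)]
    if (!length(reads)) return(UniqueTagSet())
    tab <- table(reads)
    ord <- order(-as.integer(tab), names(tab))
    UniqueTagSet(names(tab)[ord], as.integer(tab)[ord])
}

#' Length and copy-number filter
#'
#' Keeps tags with `minLen <= length <= maxLen` and count passing the
#' copy-number cut-off; input order is preserved. Idempotent.
#'
#' @param tags A [UniqueTagSet-class].
#' @param params A [filterParams()] list.
#' @return The filtered `UniqueTagSet`.
#' @export
filterTags <- function(tags, params = filterParams()) {
    w <- Biostrings::width(tagSequences(tags))
    ok_len <- w >= params$minLen & w <= params$maxLen
    ok_cnt <- if (params$countComparator == ">=") {
        tagCounts(tags) >= params$minCount
    } else {
        tagCounts(tags) > params$minCount
    }
    tags[ok_len & ok_cnt]
}

#' Remove tags matching contaminant databases
#'
#' A tag is removed iff it occurs as an exact substring of any decoy record
#' on either strand. Categories are checked in the order mRNA, Rfam,
#' Repbase; the first match determines the reported category. Idempotent.
#'
#' @param tags A [UniqueTagSet-class].
#' @param decoys Named list of decoy sets (character vectors or
#'   `DNAStringSet`s); names are the category labels, checked in list order.
#' @return List with `kept` (a `UniqueTagSet`) and `report` (data.frame of
#'   per-category removal counts; removed + kept = input).
#' @export
removeContaminants <- function(tags, decoys) {
    stopifnot(is.list(decoys), !is.null(names(decoys)))
    haystacks <- vapply(decoys, function(d)
        paste(toupper(as.character(d)), collapse = "N"), character(1))
    seqs <- as.character(tagSequences(tags))
    rcs <- if (length(seqs)) revcomp(seqs) else character()
    category <- rep(NA_character_, length(tags))
    for (cat_i in names(decoys)) {
        hs <- haystacks[[cat_i]]
        todo <- which(is.na(category))
        hit <- vapply(todo, function(i)
            grepl(seqs[i], hs, fixed = TRUE) || grepl(rcs[i], hs, fixed = TRUE),
            logical(1))
        category[todo[hit]] <- cat_i
    }
    removed <- table(factor(category, levels = names(decoys)))
    list(kept = tags[is.na(category)],
        report = data.frame(category = names(decoys),
            removed = as.integer(removed), row.names = NULL))
}

#' Run the full read-cleaning funnel
#'
#' Adapter stripping, collapsing, length/copy filtering, contaminant
#' removal — in the order the discovery pipeline applies them.
#'
#' @param reads Raw reads (character or `DNAStringSet`).
#' @param decoys Named decoy list as in [removeContaminants()].
#' @param params A [filterParams()] list.
#' @return List with `tags` (clean `UniqueTagSet`), `stats` (per-stage read
#'   and tag counts) and `contaminantReport`.
#' @export
cleanReads <- function(reads, decoys, params = filterParams()) {
    inserts <- stripAdapter(reads, params$adapter, params$maxAdapterMismatch)
    collapsed <- collapseUnique(inserts)
    filtered <- filterTags(collapsed, params)
    decon <- removeContaminants(filtered, decoys)
    list(tags = decon$kept,
        stats = data.frame(
            stage = c("raw_reads", "adapter_stripped", "unique_tags",
                "length_count_filtered", "decontaminated"),
            n = c(length(reads), sum(!is.na(inserts)), length(collapsed),
                length(filtered), length(decon$kept))),
        contaminantReport = decon$report)
}
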