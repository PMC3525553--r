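# Six-group novelty classification of clean tags. Tags are mapped against
# same-species (ssc) pre-miRNA/mature sets, other-species sets, the genome
# and ESTs; unannotated genome-mapped tags are folded for hairpin evidence.
# Each mapped tag is assigned to exactly one group by the first matching
# rule, giving a partition of the mapped tag set:
#   gp1a known   ssc miRNA + genome/EST locus
#   gp1b known   other-species homolog + distinct genome/EST locus
#   gp1c PC     EST-supported hairpin locus, no miRNA-set hit
#   gp2  PC     other-species homolog whose precursor is absent from the
#               genome, while the tag itself maps to the genome
#   gp3  PN     homology-only evidence (nothing maps to the genome)
#   gp4  PC     genome-only hairpin locus (species-specific novel)

#' Map tags against a reference sequence set
#'
#' Reports every occurrence of each tag in the reference with at most
#' `maxMismatch` substitutions (no indels). Pre-miRNA/mature reference sets
#' are searched on the forward strand only; genome and EST sets on both
#' strands. Hits are ordered by tag, target id, start and strand.
#'
#' @param tags A [UniqueTagSet-class] (or named character vector).
#' @param reference Named `DNAStringSet` (or character vector).
#' @param maxMismatch Substitutions tolerated (default 0).
#' @param bothStrands Search the minus strand too (default `FALSE`).
#' @return data.frame of hits: `tag_id`, `target_id`, `start` (0-based on
#'   the reference plus strand), `strand`, `mismatches`.
#' @export
mapTags <- function(tags, reference, maxMismatch = 0L, bothStrands = FALSE) {
    if (is(tags, "UniqueTagSet")) {
        seqs <- as.character(tagSequences(tags))
        ids <- names(tags)
    } else {
        seqs <- toupper(as.character(tags))
        ids <- names(tags)
        if (is.null(ids)) ids <- sprintf("tag%d", seq_along(seqs))
    }
    reference <- Biostrings::DNAStringSet(reference)
    if (!length(reference)) stopf("reference set is empty")
    if (is.null(names(reference)))
        names(reference) <- sprintf("ref%d", seq_along(reference))
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
        warning(sprintf("skipping %d tag(s) with degenerate bases", sum(bad)))
        seqs <- seqs[!bad]; ids <- ids[!bad]
    }
    out <- list()
    ref_chr <- as.character(reference)
    for (t in seq_along(seqs)) {
        queries <- c("+" = seqs[t])
        if (bothStrands) queries <- c(queries, "-" = revcomp(seqs[t]))
        for (strand in names(queries)) {
            m <- Biostrings::vmatchPattern(queries[[strand]], reference,
                max.mismatch = maxMismatch, fixed = TRUE)
            for (r in seq_along(reference)) {
                st <- Biostrings::startIndex(m)[[r]]
                if (is.null(st) || !length(st)) next
                sub <- substring(ref_chr[r], st, st + nchar(seqs[t]) - 1L)
                mm <- vapply(sub, function(s) {
                    sum(utf8ToInt(s) != utf8ToInt(queries[[strand]]))
                }, integer(1), USE.NAMES = FALSE)
                out[[length(out) + 1L]] <- data.frame(
                    tag_id = ids[t], target_id = names(reference)[r],
                    start = st - 1L, strand = strand, mismatches = mm,
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(tag_id = character(), target_id = character(),
            start = integer(), strand = character(), mismatches = integer(),
            stringsAsFactors = FALSE))
    hits <- do.call(rbind, out)
    hits <- hits[order(hits$tag_id, hits$target_id, hits$start, hits$strand), ]
    rownames(hits) <- NULL
    hits
}

.empty_hits <- function() {
    data.frame(tag_id = character(), target_id = character(),
        start = integer(), strand = character(), mismatches = integer(),
        stringsAsFactors = FALSE)
}

# Does any of `loci` (rows with target_id, start, end) overlap a claimed one?
.overlaps_claimed <- function(loci, claimed) {
    if (!nrow(claimed) || !nrow(loci)) return(rep(FALSE, nrow(loci)))
    vapply(seq_len(nrow(loci)), function(i) {
        any(intervals_overlap(loci$target_id[i], loci$start[i], loci$end[i],
            claimed$target_id, claimed$start, claimed$end))
    }, logical(1))
}

#' Assign mapped tags to the six novelty groups
#'
#' Applies the classification rules in fixed order (gp1a, gp1b, gp1c, gp2,
#' gp3, gp4). "Distinct location" means the tag's genomic/EST locus does
#' not overlap (0-based half-open) any locus claimed by an earlier group.
#' gp1b requires that a hit other-species record's precursor itself maps
#' to the genome; homologs whose precursor is absent from the genome fall
#' through to gp2 (tag genome-mapped) or gp3 (tag not genome-mapped).
#' gp1c and gp4 both require a folded hairpin at an unclaimed locus and are
#' distinguished by EST support (gp1c) versus genome-only evidence (gp4).
#' Tags matching no rule are reported `unclassified`.
#'
#' @param tags A [UniqueTagSet-class].
#' @param hits Named list of hit data.frames from [mapTags()]:
#'   `ssc_mirna` (ssc pre-miRNA + mature, forward strand), `other_mirna`
#'   (other-species sets, forward strand), `genome` and `est`
#'   (both strands).
#' @param premirnaGenomeMapped Character vector of other-species reference
#'   record ids (precursors and their matures) whose precursor maps to the
#'   genome.
#' @param hairpins Named list (by tag id) of [HairpinStructure-class]
#'   results for the tags' best genome/EST window, as produced by
#'   [runClassification()]; tags absent from the list count as having no
#'   hairpin.
#' @return List with `candidates` (data.frame: tag id, sequence, count,
#'   group, novelty, locus and hairpin columns) and `summary` (group counts
#'   including `unclassified`; the groups partition the mapped tags).
#' @export
classifyTags <- function(tags, hits, premirnaGenomeMapped = character(),
                         hairpins = list()) {
    ids <- names(tags)
    df <- as.data.frame(tags)
    hit_ids <- function(h) if (nrow(h)) unique(h$tag_id) else character()
    has_ssc <- ids %in% hit_ids(hits$ssc_mirna)
    has_other <- ids %in% hit_ids(hits$other_mirna)
    has_genome <- ids %in% hit_ids(hits$genome)
    has_est <- ids %in% hit_ids(hits$est)
    mapped <- has_ssc | has_other | has_genome | has_est

    widths <- Biostrings::width(tagSequences(tags))
    names(widths) <- ids
    tag_loci <- function(tag, src) {
        h <- src[src$tag_id == tag, , drop = FALSE]
        if (!nrow(h)) return(h)
        h$end <- h$start + widths[[tag]]
        h
    }
    # pre-miRNAs hit by a tag, restricted to the other-species set
    other_targets <- function(tag) {
        h <- hits$other_mirna
        unique(h$target_id[h$tag_id == tag])
    }
    hairpin_ok <- function(tag) {
        hp <- hairpins[[tag]]
        !is.null(hp) && isHairpin(hp)
    }

    group <- rep("unclassified", length(ids))
    novelty <- rep(NA_character_, length(ids))
    locus <- rep(NA_character_, length(ids))
    empty_claims <- data.frame(target_id = character(), start = integer(),
        end = integer(), stringsAsFactors = FALSE)
    # loci claimed by each group; "distinct location" is checked against
    # the claims of strictly earlier groups, so several tags (sequence
    # variants) may share one locus within a group
    claims <- list(gp1a = empty_claims, gp1b = empty_claims,
        gp1c = empty_claims)
    claim <- function(claimed, loci) {
        if (!nrow(loci)) return(claimed)
        rbind(claimed, loci[, c("target_id", "start", "end")])
    }
    fmt_locus <- function(loci) {
        if (!nrow(loci)) return(NA_character_)
        sprintf("%s:%d-%d(%s)", loci$target_id[1], loci$start[1],
            loci$end[1], loci$strand[1])
    }

    # Rules are evaluated group by group in fixed order so "location
    # distinct from earlier assignments" is well defined.
    for (rule in c("gp1a", "gp1b", "gp1c", "gp2", "gp3", "gp4")) {
        claimed <- switch(rule,
            gp1b = claims$gp1a,
            gp1c = rbind(claims$gp1a, claims$gp1b),
            gp4 = rbind(claims$gp1a, claims$gp1b, claims$gp1c),
            empty_claims)
        for (i in seq_along(ids)) {
            if (group[i] != "unclassified") next
            tag <- ids[i]
            gl <- tag_loci(tag, hits$genome)
            el <- tag_loci(tag, hits$est)
            assigned <- FALSE
            if (rule == "gp1a" && has_ssc[i] && (has_genome[i] || has_est[i])) {
                group[i] <- "gp1a"; novelty[i] <- "known"
                claims$gp1a <- claim(claims$gp1a, rbind(gl, el))
                locus[i] <- fmt_locus(rbind(gl, el))
                assigned <- TRUE
            } else if (rule == "gp1b" && has_other[i] &&
                       (has_genome[i] || has_est[i]) &&
                       any(other_targets(tag) %in% premirnaGenomeMapped)) {
                free <- rbind(gl, el)
                free <- free[!.overlaps_claimed(free, claimed), , drop = FALSE]
                if (nrow(free)) {
                    group[i] <- "gp1b"; novelty[i] <- "known"
                    claims$gp1b <- claim(claims$gp1b, free)
                    locus[i] <- fmt_locus(free)
                    assigned <- TRUE
                }
            } else if (rule == "gp1c" && !has_ssc[i] && !has_other[i] &&
                       has_est[i] && hairpin_ok(tag)) {
                free <- rbind(gl, el)
                free <- free[!.overlaps_claimed(free, claimed), , drop = FALSE]
                if (nrow(free)) {
                    group[i] <- "gp1c"; novelty[i] <- "PC"
                    claims$gp1c <- claim(claims$gp1c, free)
                    locus[i] <- fmt_locus(free)
                    assigned <- TRUE
                }
            } else if (rule == "gp2" && has_other[i] && has_genome[i] &&
                       !any(other_targets(tag) %in% premirnaGenomeMapped)) {
                group[i] <- "gp2"; novelty[i] <- "PC"
                locus[i] <- fmt_locus(gl)
                assigned <- TRUE
            } else if (rule == "gp3" && has_other[i] && !has_genome[i] &&
                       !any(other_targets(tag) %in% premirnaGenomeMapped)) {
                group[i] <- "gp3"; novelty[i] <- "PN"
                assigned <- TRUE
            } else if (rule == "gp4" && !has_ssc[i] && !has_other[i] &&
                       has_genome[i] && hairpin_ok(tag)) {
                free <- gl[!.overlaps_claimed(gl, claimed), , drop = FALSE]
                if (nrow(free)) {
                    group[i] <- "gp4"; novelty[i] <- "PC"
                    locus[i] <- fmt_locus(free)
                    assigned <- TRUE
                }
            }
            invisible(assigned)
        }
    }

    candidates <- data.frame(tag_id = ids, sequence = df$sequence,
        count = df$count, mapped = mapped, group = group, novelty = novelty,
        locus = locus,
        hairpin = vapply(ids, hairpin_ok, logical(1), USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    lvls <- c("gp1a", "gp1b", "gp1c", "gp2", "gp3", "gp4", "unclassified")
    summary <- as.data.frame(table(
        group = factor(group[mapped], levels = lvls)),
        responseName = "n_tags")
    list(candidates = candidates, summary = summary)
}

#' Map, fold and classify in one call
#'
#' Orchestrates [mapTags()] over all reference categories, maps
#' other-species pre-miRNAs to the genome (needed to separate gp2/gp3 from
#' gp1b), folds the 60-nt-extended window of every genome/EST hit of tags
#' without miRNA-set annotation, and calls [classifyTags()].
#'
#' @param tags A [UniqueTagSet-class] of clean tags.
#' @param refs Named list of reference `DNAStringSet`s: `ssc_premirna`,
#'   `ssc_mature`, `other_premirna`, `other_mature`, `genome`, `est`;
#'   optionally `other_families`, a named character vector mapping
#'   other-species record ids to precursor families so matures inherit
#'   their precursor's genome-mapping status.
#' @param maxMismatch Mapping mismatch tolerance (default 0).
#' @param extension Hairpin window flank (default 60 nt).
#' @param hairpin A [hairpinParams()] list.
#' @return As [classifyTags()], plus `hits` and `hairpins`.
#' @export
runClassification <- function(tags, refs, maxMismatch = 0L, extension = 60L,
                              hairpin = hairpinParams()) {
    need <- c("ssc_premirna", "ssc_mature", "other_premirna", "other_mature",
        "genome", "est")
    missing <- setdiff(need, names(refs))
    if (length(missing))
        stopf("missing reference set(s): %s", paste(missing, collapse = ", "))
    cat_hits <- function(sets, both) {
        parts <- lapply(sets, function(s) {
            if (length(refs[[s]]))
                mapTags(tags, refs[[s]], maxMismatch, bothStrands = both)
            else .empty_hits()
        })
        do.call(rbind, parts)
    }
    hits <- list(
        ssc_mirna = cat_hits(c("ssc_premirna", "ssc_mature"), FALSE),
        other_mirna = cat_hits(c("other_premirna", "other_mature"), FALSE),
        genome = cat_hits("genome", TRUE),
        est = cat_hits("est", TRUE))

    pre_gm <- if (length(refs$other_premirna)) {
        h <- mapTags(as.character(refs$other_premirna), refs$genome,
            maxMismatch, bothStrands = TRUE)
        unique(h$tag_id)
    } else character()
    # Propagate precursor genome-mapping to the whole record family (a
    # mature inherits its precursor's status). refs$other_families maps
    # record id -> family id; by default each record is its own family.
    fams <- refs$other_families
    if (!is.null(fams)) {
        mapped_fams <- unique(fams[pre_gm])
        pre_gm <- names(fams)[fams %in% mapped_fams]
    }

    ids <- names(tags)
    annotated <- unique(c(hits$ssc_mirna$tag_id, hits$other_mirna$tag_id))
    widths <- Biostrings::width(tagSequences(tags)); names(widths) <- ids
    hairpins <- list()
    for (tag in setdiff(ids, annotated)) {
        for (src in c("genome", "est")) {
            h <- hits[[src]]
            h <- h[h$tag_id == tag, , drop = FALSE]
            if (!nrow(h)) next
            ref <- refs[[src]]
            for (r in seq_len(nrow(h))) {
                win <- extractHairpinWindow(ref, h$target_id[r], h$start[r],
                    widths[[tag]], h$strand[r], extension)
                hp <- foldHairpin(win$window, win$matureOffset, widths[[tag]],
                    hairpin)
                if (is.null(hairpins[[tag]]) || isHairpin(hp))
                    hairpins[[tag]] <- hp
                if (isHairpin(hp)) break
            }
            if (!is.null(hairpins[[tag]]) && isHairpin(hairpins[[tag]])) break
        }
    }
    res <- classifyTags(tags, hits, pre_gm, hairpins)
    c(res, list(hits = hits, hairpins = hairpins))
}
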