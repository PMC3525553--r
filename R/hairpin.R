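# Stem-loop candidate evaluation. A mapped tag's genomic neighbourhood
# (60 nt each side by default) is folded with a weighted Nussinov dynamic
# program (no pseudoknots, minimum loop 3 nt, pairs AU/GC/GU weighted
# 2/3/1) and accepted as a pre-miRNA-like hairpin when the dominant helix
# is long enough, the terminal loop is plausible, the mature arm sits
# entirely on one stem side, and the total pairing score clears a floor.

#' Hairpin acceptance parameters
#'
#' @param stemMin Minimum pairs in the dominant helix (default 18).
#' @param loopMin,loopMax Terminal loop bounds in nt (defaults 4 and 20).
#' @param scoreMin Minimum weighted pairing score (default 35).
#' @param minLoop Minimum hairpin loop enforced by the folding DP
#'   (default 3 nt).
#' @return Named list of parameters.
#' @export
hairpinParams <- function(stemMin = 18L, loopMin = 4L, loopMax = 20L,
                          scoreMin = 35, minLoop = 3L) {
    list(stemMin = as.integer(stemMin), loopMin = as.integer(loopMin),
        loopMax = as.integer(loopMax), scoreMin = scoreMin,
        minLoop = as.integer(minLoop))
}

#' Extract the extended genomic window around a mapping hit
#'
#' Returns the genome slice `[start - extension, start + width + extension)`
#' clipped at the sequence ends; minus-strand hits are reverse-complemented
#' so the mature tag always reads 5'->3' in the window.
#'
#' @param genome A `DNAStringSet` (or single sequence) of genome contigs.
#' @param targetId Contig name of the hit.
#' @param start 0-based start of the tag match on the plus strand.
#' @param width Tag length in nt.
#' @param strand `"+"` or `"-"`.
#' @param extension Flank added on each side (default 60 nt).
#' @return List: `window` (character), `start`, `end` (0-based half-open
#'   window coordinates on the contig), `matureOffset` (0-based offset of
#'   the tag within the returned window).
#' @export
extractHairpinWindow <- function(genome, targetId, start, width, strand = "+",
                                 extension = 60L) {
    genome <- Biostrings::DNAStringSet(genome)
    if (is.null(names(genome))) names(genome) <- as.character(seq_along(genome))
    chr <- genome[[as.character(targetId)]]
    glen <- length(chr)
    w0 <- max(0L, start - extension)
    w1 <- min(glen, start + width + extension)
    win <- as.character(Biostrings::subseq(chr, start = w0 + 1L, end = w1))
    if (strand == "-") {
        win <- revcomp(win)
        offset <- w1 - (start + width)
    } else {
        offset <- start - w0
    }
    list(window = win, start = as.integer(w0), end = as.integer(w1),
        matureOffset = as.integer(offset))
}

# Dominant helix: longest run of pairs in which consecutive pairs are
# stacked or separated by a single-nt bulge on one side.
.dominant_helix <- function(pairs) {
    if (nrow(pairs) == 0) return(NULL)
    ord <- order(pairs[, 1])
    p <- pairs[ord, , drop = FALSE]
    runs <- list()
    cur <- 1L
    for (r in seq_len(nrow(p))[-1]) {
        di <- p[r, 1] - p[r - 1L, 1]
        dj <- p[r - 1L, 2] - p[r, 2]
        contiguous <- p[r, 2] < p[r - 1L, 2] &&
            ((di == 1L && dj == 1L) || (di == 2L && dj == 1L) ||
             (di == 1L && dj == 2L))
        if (!contiguous) {
            runs[[length(runs) + 1L]] <- cur
            cur <- integer()
        }
        cur <- c(cur, r)
    }
    runs[[length(runs) + 1L]] <- cur
    sizes <- lengths(runs)
    p[runs[[which.max(sizes)]], , drop = FALSE]
}

.dotbracket <- function(n, pairs) {
    db <- rep(".", n)
    if (nrow(pairs)) {
        db[pairs[, 1]] <- "("
        db[pairs[, 2]] <- ")"
    }
    paste(db, collapse = "")
}

.hairpin_fail <- function(window, reason, matureStart = NA_integer_,
                          matureEnd = NA_integer_) {
    new("HairpinStructure", window = window,
        pairs = matrix(integer(), 0, 2), score = 0, pairedBases = 0L,
        stemLength = 0L, loopLength = 0L,
        matureStart = as.integer(matureStart),
        matureEnd = as.integer(matureEnd), isHairpin = FALSE,
        reason = reason, dotbracket = strrep(".", nchar(window)))
}

#' Fold a candidate window and apply the hairpin acceptance rules
#'
#' Computes the maximum weighted base-pairing structure of the window
#' (Nussinov-style dynamic program; pairs GC/AU/GU scored 3/2/1, minimum
#' loop 3 nt, no pseudoknots), then accepts the window as a hairpin iff
#' (a) the dominant helix has at least `stemMin` pairs, (b) its terminal
#' loop length is within `[loopMin, loopMax]`, (c) the mature arm lies
#' entirely within one side of that helix, and (d) the weighted score is at
#' least `scoreMin`.
#'
#' @param window Window sequence (character; DNA or RNA alphabet).
#' @param matureOffset 0-based offset of the mature tag in the window.
#' @param matureLength Mature tag length in nt.
#' @param params A [hairpinParams()] list.
#' @return A [HairpinStructure-class]. Windows shorter than 40 nt are
#'   reported `isHairpin = FALSE` with reason `"window_too_short"`.
#' @examples
#' stem <- "GCAGCGGTTGCAGTCCAGCTGAACG"
#' rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(stem)))
#' foldHairpin(paste0(stem, "TTTCGA", rc), 0, 22)
#' @export
foldHairpin <- function(window, matureOffset, matureLength,
                        params = hairpinParams()) {
    window <- toupper(chartr("U", "T", as.character(window)))
    m0 <- as.integer(matureOffset) + 1L           # 1-based closed
    m1 <- as.integer(matureOffset) + as.integer(matureLength)
    if (nchar(window) < 40L)
        return(.hairpin_fail(window, "window_too_short", m0, m1))
    fold <- .nussinov_fold(window, params$minLoop)
    pairs <- fold$pairs
    if (nrow(pairs) == 0L)
        return(.hairpin_fail(window, "no_pairs", m0, m1))
    helix <- .dominant_helix(pairs)
    stem_len <- nrow(helix)
    inner <- helix[stem_len, ]
    loop_len <- inner[2] - inner[1] - 1L
    five_side <- c(min(helix[, 1]), max(helix[, 1]))
    three_side <- c(min(helix[, 2]), max(helix[, 2]))
    on_one_arm <- (m0 >= five_side[1] && m1 <= five_side[2]) ||
        (m0 >= three_side[1] && m1 <= three_side[2])
    reason <- if (stem_len < params$stemMin) "stem_too_short"
        else if (loop_len < params$loopMin || loop_len > params$loopMax)
            "loop_out_of_range"
        else if (!on_one_arm) "mature_not_in_stem"
        else if (fold$score < params$scoreMin) "score_below_min"
        else "ok"
    new("HairpinStructure", window = window, pairs = pairs,
        score = as.numeric(fold$score), pairedBases = nrow(pairs),
        stemLength = as.integer(stem_len), loopLength = as.integer(loop_len),
        matureStart = m0, matureEnd = m1, isHairpin = reason == "ok",
        reason = reason, dotbracket = .dotbracket(nchar(window), pairs))
}
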