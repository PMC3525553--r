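#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' UniqueTagSet: collapsed unique small-RNA tags with read counts
#'
#' The unit flowing through the read-cleaning funnel and the six-group
#' classifier: one record per distinct small-RNA sequence, carrying the
#' number of raw reads collapsed into it.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of distinct tag sequences
#'   (uppercase DNA alphabet; RNA inputs are stored as DNA).
#' @slot count Integer vector of read counts, parallel to `sequences`,
#'   each >= 1.
#'
#' @seealso [collapseUnique()], [filterTags()], [removeContaminants()]
#' @export
setClass("UniqueTagSet",
    slots = c(sequences = "DNAStringSet", count = "integer"))

setValidity("UniqueTagSet", function(object) {
    msg <- character()
    if (length(object@sequences) != length(object@count))
        msg <- c(msg, "sequences and count must have equal length")
    if (length(object@count) && any(object@count < 1L))
        msg <- c(msg, "all counts must be >= 1")
    if (length(object@sequences)) {
        af <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
        if (any(af[, "other"] > 0))
            msg <- c(msg, "tag sequences must use the {A,C,G,T} alphabet")
        if (any(Biostrings::width(object@sequences) == 0))
            msg <- c(msg, "tag sequences must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a UniqueTagSet
#'
#' @param sequences Character vector or `DNAStringSet` of tag sequences.
#' @param count Integer vector of read counts (default all 1).
#' @return A [UniqueTagSet-class] object.
#' @examples
#' UniqueTagSet(c("ACGTACGTACGTACGTACGTA", "TTTTACGTACGTACGTACGTA"), c(5L, 3L))
#' @export
UniqueTagSet <- function(sequences = character(), count = rep(1L, length(sequences))) {
    seqs <- DNAStringSet(toupper(chartr("U", "T", as.character(sequences))))
    if (is.null(names(seqs)) && length(seqs))
        names(seqs) <- sprintf("tag%d", seq_along(seqs))
    new("UniqueTagSet", sequences = seqs, count = as.integer(count))
}

#' @describeIn UniqueTagSet Tag sequences as a `DNAStringSet`.
#' @param x,object A `UniqueTagSet`.
#' @export
tagSequences <- function(x) x@sequences

#' @describeIn UniqueTagSet Read counts.
#' @export
tagCounts <- function(x) x@count

#' @export
setMethod("length", "UniqueTagSet", function(x) length(x@sequences))

#' @export
setMethod("names", "UniqueTagSet", function(x) names(x@sequences))

#' @param i Index vector.
#' @rdname UniqueTagSet
#' @export
setMethod("[", "UniqueTagSet", function(x, i) {
    initialize(x, sequences = x@sequences[i], count = x@count[i])
})

#' @export
setMethod("show", "UniqueTagSet", function(object) {
    cat(sprintf("UniqueTagSet with %d tags (%d reads)\n",
        length(object), sum(object@count)))
    if (length(object)) {
        k <- min(5L, length(object))
        for (i in seq_len(k))
            cat(sprintf("  %s  x%d  %s\n", names(object)[i], object@count[i],
                as.character(object@sequences[[i]])))
        if (length(object) > k) cat("  ...\n")
    }
})

#' Convert a UniqueTagSet to a data.frame
#' @param x A `UniqueTagSet`.
#' @param ... Unused.
#' @return data.frame with columns `id`, `sequence`, `count`.
#' @export
setMethod("as.data.frame", "UniqueTagSet", function(x, ...) {
    data.frame(id = names(x), sequence = as.character(x@sequences),
        count = x@count, stringsAsFactors = FALSE, row.names = NULL)
})

#' HairpinStructure: result of folding a candidate stem-loop window
#'
#' Produced by [foldHairpin()]. Records the optimal weighted base-pairing
#' structure of a genomic window around a mapped tag and whether it passes
#' the pre-miRNA hairpin acceptance rules.
#'
#' @slot window The folded window sequence (DNA alphabet).
#' @slot pairs Two-column integer matrix of 1-based paired positions.
#' @slot score Weighted pairing score of the optimal structure.
#' @slot pairedBases Number of base pairs in the optimal structure.
#' @slot stemLength Number of pairs in the dominant helix (longest
#'   contiguous stem allowing 1-nt bulges).
#' @slot loopLength Terminal loop length of the dominant helix, in nt.
#' @slot matureStart,matureEnd 1-based closed interval of the mature arm
#'   within the window.
#' @slot isHairpin Logical: all acceptance rules satisfied.
#' @slot reason `"ok"` or the first failed rule.
#' @slot dotbracket Dot-bracket string of the structure.
#' @export
setClass("HairpinStructure",
    slots = c(window = "character", pairs = "matrix", score = "numeric",
        pairedBases = "integer", stemLength = "integer",
        loopLength = "integer", matureStart = "integer",
        matureEnd = "integer", isHairpin = "logical", reason = "character",
        dotbracket = "character"))

setValidity("HairpinStructure", function(object) {
    n <- nchar(object@window)
    if (object@pairedBases > floor(n / 2))
        return("paired-base count exceeds floor(window length / 2)")
    TRUE
})

#' @describeIn HairpinStructure Whether the window passed the hairpin rules.
#' @param x,object A `HairpinStructure`.
#' @export
isHairpin <- function(x) x@isHairpin

#' @export
setMethod("show", "HairpinStructure", function(object) {
    cat(sprintf(paste0("HairpinStructure (%d nt): score %.0f, %d pairs, ",
        "stem %d bp, loop %d nt -> %s%s\n"),
        nchar(object@window), object@score, object@pairedBases,
        object@stemLength, object@loopLength,
        if (object@isHairpin) "hairpin" else "not a hairpin",
        if (object@reason == "ok") "" else paste0(" (", object@reason, ")")))
})

#' GroundTruth: hidden state of the synthetic study
#'
#' Carries everything the simulators planted — hairpin loci and their
#' roles, foreign (reference-only) miRNAs, decoy records, temporal profile
#' assignments and true stage means — so recovery tests can compare
#' pipeline output against known truth.
#'
#' @slot loci data.frame of planted loci: `id`, `start`/`end` (0-based
#'   half-open genome coordinates), `strand`, `hairpin_seq`, `mature_seq`,
#'   `mature_start` (0-based within hairpin), `mature_len`, `role`
#'   (`known_ssc`, `known_other`, `novel` or `unassigned`).
#' @slot foreign data.frame of miRNAs present only in reference sets:
#'   `id`, `hairpin_seq`, `mature_seq`, `class` (`gp2_like`: mature in the
#'   genome, hairpin not; `gp3_like`: neither in the genome).
#' @slot decoys data.frame of decoy record ids and categories.
#' @slot profileAssignments Named integer vector probe id -> model profile
#'   id (0 = flat).
#' @slot trueLog2Means Matrix probe x stage of planted log2 stage means.
#' @slot genomeLength Integer length of the synthetic genome.
#' @slot seed Integer seed the generators were called with.
#' @export
setClass("GroundTruth",
    slots = c(loci = "data.frame", foreign = "data.frame",
        decoys = "data.frame", profileAssignments = "integer",
        trueLog2Means = "matrix", genomeLength = "integer",
        seed = "integer"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (nrow(object@loci)) {
        if (any(object@loci$start < 0) ||
            any(object@loci$end > object@genomeLength))
            msg <- c(msg, "planted loci must lie within genome bounds")
        if (any(object@loci$mature_len < 20) ||
            any(object@loci$mature_len > 24))
            msg <- c(msg, "mature lengths must be in [20, 24] nt")
        ov <- order(object@loci$start)
        s <- object@loci$start[ov]; e <- object@loci$end[ov]
        if (nrow(object@loci) > 1 && any(s[-1] < e[-length(e)]))
            msg <- c(msg, "planted loci must be pairwise disjoint")
    }
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GroundTruth", function(object) {
    cat(sprintf(paste0("GroundTruth: %d planted loci (%s) in a %d-nt genome, ",
        "%d foreign miRNAs, %d decoys, seed %d\n"),
        nrow(object@loci),
        paste(sprintf("%d %s", table(object@loci$role),
            names(table(object@loci$role))), collapse = ", "),
        object@genomeLength, nrow(object@foreign), nrow(object@decoys),
        object@seed))
})

#' @describeIn GroundTruth data.frame of planted hairpin loci.
#' @param x,object A `GroundTruth`.
#' @export
plantedLoci <- function(x) x@loci

#' MirGeneNetwork: bipartite miRNA-target network with node degrees
#'
#' Built by [buildNetwork()] from seed-match target edges restricted to the
#' GO-and-pathway intersection gene set. Degree (the number of incident
#' edges) ranks miRNAs for key-miRNA selection.
#'
#' @slot edges data.frame of unique (miRNA, gene) edges.
#' @slot mirnaDegree,geneDegree Named integer degree vectors, sorted by
#'   decreasing degree then id.
#' @export
setClass("MirGeneNetwork",
    slots = c(edges = "data.frame", mirnaDegree = "integer",
        geneDegree = "integer"))

setValidity("MirGeneNetwork", function(object) {
    if (sum(object@mirnaDegree) != nrow(object@edges) ||
        sum(object@geneDegree) != nrow(object@edges))
        return("node degree sums must each equal the edge count")
    TRUE
})

#' @describeIn MirGeneNetwork Named miRNA degree vector (decreasing).
#' @param x,object A `MirGeneNetwork`.
#' @export
mirnaDegree <- function(x) x@mirnaDegree

#' @describeIn MirGeneNetwork Named gene degree vector (decreasing).
#' @export
geneDegree <- function(x) x@geneDegree

#' @describeIn MirGeneNetwork Edge data.frame.
#' @export
networkEdges <- function(x) x@edges

#' @export
setMethod("show", "MirGeneNetwork", function(object) {
    cat(sprintf("MirGeneNetwork: %d miRNAs, %d genes, %d edges\n",
        length(object@mirnaDegree), length(object@geneDegree),
        nrow(object@edges)))
})
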