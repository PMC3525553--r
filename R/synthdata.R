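# Synthetic-study generators. Every input the pipeline needs — genome with
# planted hairpin loci, reference sets, small-RNA reads, the 4-stage x
# 3-replicate signal matrix, target/annotation data and qPCR CT tables —
# is generated with known ground truth so recovery can be tested. All
# generators are deterministic given their seed and leave the caller's RNG
# stream untouched.

.new_truth <- function(loci = NULL, genomeLength = 0L, seed = 0L) {
    if (is.null(loci))
        loci <- data.frame(id = character(), start = integer(),
            end = integer(), strand = character(), hairpin_seq = character(),
            mature_seq = character(), mature_start = integer(),
            mature_len = integer(), role = character(),
            stringsAsFactors = FALSE)
    empty_foreign <- data.frame(id = character(), hairpin_seq = character(),
        mature_seq = character(), class = character(), stringsAsFactors = FALSE)
    empty_decoys <- data.frame(id = character(), category = character(),
        stringsAsFactors = FALSE)
    new("GroundTruth", loci = loci, foreign = empty_foreign,
        decoys = empty_decoys, profileAssignments = integer(),
        trueLog2Means = matrix(numeric(), 0, 0),
        genomeLength = as.integer(genomeLength), seed = as.integer(seed))
}

# One planted hairpin: perfect-complement stem around a 4-15 nt loop,
# mature embedded in the 5' arm with a 3-nt margin to each arm end. Built
# to satisfy the package's own hairpin acceptance rules with margin so
# classifier recovery is not flaky: the loop is non-self-pairing (all A)
# and the margins keep the mature inside the dominant helix even when
# random flanks perturb pairing at the helix boundaries.
.make_hairpin <- function() {
    mature_len <- sample(20:24, 1L)
    stem_len <- mature_len + 6L
    loop_len <- sample(4:15, 1L)
    arm5 <- random_dna(stem_len)
    loop <- strrep("A", loop_len)
    hairpin <- paste0(arm5, loop, revcomp(arm5))
    mstart <- 3L                                   # 0-based within the arm
    list(hairpin = hairpin, mature = substr(arm5, mstart + 1L,
        mstart + mature_len), mature_start = mstart, mature_len = mature_len)
}

#' Generate a synthetic genome with planted hairpin loci
#'
#' Uniform-random A/C/G/T background with `nLoci` planted stem-loop loci.
#' Each locus is stem-loop-stem (perfectly complementary stem of 22-30 bp,
#' loop 4-15 nt) with a 20-24 nt mature arm embedded in one stem side;
#' loci alternate strands and are pairwise disjoint. Deterministic given
#' `seed`.
#'
#' @param lengthNt Genome length (>= 200 x `nLoci`).
#' @param nLoci Number of loci to plant.
#' @param seed Integer seed.
#' @return List: `genome` (named `DNAStringSet`, one contig `chr1`),
#'   `truth` (a [GroundTruth-class] with `role = "unassigned"` loci).
#' @export
generateGenome <- function(lengthNt, nLoci, seed) {
    lengthNt <- as.integer(lengthNt); nLoci <- as.integer(nLoci)
    if (lengthNt < 200L * nLoci)
        stopf("genome of %d nt is too small for %d loci (need >= %d)",
            lengthNt, nLoci, 200L * nLoci)
    with_seed(seed, {
        bg <- strsplit(random_dna(lengthNt), "")[[1]]
        loci <- list()
        if (nLoci > 0L) {
            slot_w <- lengthNt %/% nLoci
            for (i in seq_len(nLoci)) {
                hp <- .make_hairpin()
                hlen <- nchar(hp$hairpin)
                lo <- (i - 1L) * slot_w
                start <- lo + sample.int(slot_w - hlen - 20L, 1L) + 10L
                strand <- if (i %% 3L == 0L) "-" else "+"
                planted <- if (strand == "+") hp$hairpin else revcomp(hp$hairpin)
                bg[(start + 1L):(start + hlen)] <- strsplit(planted, "")[[1]]
                loci[[i]] <- data.frame(id = sprintf("locus%02d", i),
                    start = start, end = start + hlen, strand = strand,
                    hairpin_seq = hp$hairpin, mature_seq = hp$mature,
                    mature_start = hp$mature_start,
                    mature_len = hp$mature_len, role = "unassigned",
                    stringsAsFactors = FALSE)
            }
        }
        genome <- Biostrings::DNAStringSet(c(chr1 = paste(bg, collapse = "")))
        truth <- .new_truth(if (length(loci)) do.call(rbind, loci) else NULL,
            lengthNt, seed)
        list(genome = genome, truth = truth)
    })
}

#' Generate reference sets and assign locus roles
#'
#' Splits the planted loci into same-species known (`known_ssc` -> ssc
#' pre-miRNA/mature sets), other-species known (`known_other` -> the
#' other-species sets, precursor present in the genome), EST-covered novel
#' (`novel_est`) and genome-only novel (`novel`). Adds foreign miRNAs that
#' exist only in the other-species sets: `gp3_like` (nothing maps to the
#' genome) and `gp2_like` (the mature is a genome slice but the precursor
#' is foreign). ESTs cover known and `novel_est` loci; decoy sets (mRNA,
#' Rfam, Repbase) are random records.
#'
#' @param genome `DNAStringSet` from [generateGenome()].
#' @param truth The matching [GroundTruth-class].
#' @param fracSsc,fracOther,fracNovelEst Role fractions of the planted
#'   loci (remainder is genome-only novel).
#' @param nGp3,nGp2 Foreign miRNAs of each class.
#' @param nDecoys Records per decoy category.
#' @param seed Integer seed.
#' @return List: `refs` (reference bundle for [runClassification()], plus
#'   `decoys` for [removeContaminants()]), `truth` (roles and foreign
#'   records filled in).
#' @export
generateReferences <- function(genome, truth, fracSsc = 0.4, fracOther = 0.25,
                               fracNovelEst = 0.1, nGp3 = 3L, nGp2 = 2L,
                               nDecoys = 5L, seed = truth@seed + 1L) {
    loci <- truth@loci
    n <- nrow(loci)
    with_seed(seed, {
        ord <- sample.int(max(n, 1L))[seq_len(n)]
        n_ssc <- round(fracSsc * n); n_oth <- round(fracOther * n)
        n_nest <- round(fracNovelEst * n)
        role <- rep("novel", n)
        role[ord[seq_len(n_ssc)]] <- "known_ssc"
        if (n_oth > 0) role[ord[n_ssc + seq_len(n_oth)]] <- "known_other"
        if (n_nest > 0)
            role[ord[n_ssc + n_oth + seq_len(n_nest)]] <- "novel_est"
        loci$role <- role

        mk_set <- function(seqs, ids) {
            s <- Biostrings::DNAStringSet(seqs); names(s) <- ids; s
        }
        ssc <- loci[loci$role == "known_ssc", , drop = FALSE]
        oth <- loci[loci$role == "known_other", , drop = FALSE]
        ssc_pre <- mk_set(ssc$hairpin_seq, sprintf("ssc-pre-%s", ssc$id))
        ssc_mat <- mk_set(ssc$mature_seq, sprintf("ssc-miR-%s", ssc$id))

        # Foreign records: gp3-like (fully foreign) and gp2-like (mature
        # lifted from un-planted genome background, precursor foreign).
        foreign <- list()
        for (i in seq_len(nGp3)) {
            hp <- .make_hairpin()
            foreign[[length(foreign) + 1L]] <- data.frame(
                id = sprintf("foreign-gp3-%02d", i), hairpin_seq = hp$hairpin,
                mature_seq = hp$mature, class = "gp3_like",
                stringsAsFactors = FALSE)
        }
        gseq <- as.character(genome[[1]])
        glen <- nchar(gseq)
        in_locus <- function(p, w) any(p < loci$end + 30L & loci$start - 30L < p + w)
        for (i in seq_len(nGp2)) {
            repeat {
                p <- sample.int(glen - 60L, 1L)
                if (n == 0L || !in_locus(p, 21L)) break
            }
            mat <- substr(gseq, p, p + 20L)
            arm5 <- paste0(mat, random_dna(4L))
            hp <- paste0(arm5, random_dna(6L), revcomp(arm5))
            foreign[[length(foreign) + 1L]] <- data.frame(
                id = sprintf("foreign-gp2-%02d", i), hairpin_seq = hp,
                mature_seq = mat, class = "gp2_like", stringsAsFactors = FALSE)
        }
        foreign <- if (length(foreign)) do.call(rbind, foreign) else
            truth@foreign
        oth_ids <- c(sprintf("oth-%s", oth$id),
            if (nrow(foreign)) sprintf("oth-%s", foreign$id))
        other_pre <- mk_set(c(oth$hairpin_seq, foreign$hairpin_seq),
            sprintf("%s-pre", oth_ids))
        other_mat <- mk_set(c(oth$mature_seq, foreign$mature_seq),
            sprintf("%s-miR", oth_ids))
        other_families <- stats::setNames(rep(oth_ids, 2L),
            c(names(other_pre), names(other_mat)))

        est_loci <- loci[loci$role %in% c("known_ssc", "known_other",
            "novel_est"), , drop = FALSE]
        est <- if (nrow(est_loci)) {
            s0 <- pmax(0L, est_loci$start - 40L)
            s1 <- pmin(glen, est_loci$end + 40L)
            mk_set(substring(gseq, s0 + 1L, s1), sprintf("est-%s", est_loci$id))
        } else Biostrings::DNAStringSet()

        decoy_len <- c(mRNA = 500L, Rfam = 120L, Repbase = 300L)
        decoys <- lapply(names(decoy_len), function(cat_i) {
            s <- vapply(seq_len(nDecoys), function(i)
                random_dna(decoy_len[[cat_i]]), character(1))
            mk_set(s, sprintf("%s-%02d", tolower(cat_i), seq_len(nDecoys)))
        })
        names(decoys) <- names(decoy_len)

        truth@loci <- loci
        truth@foreign <- foreign
        truth@decoys <- data.frame(
            id = unlist(lapply(decoys, names), use.names = FALSE),
            category = rep(names(decoys), each = nDecoys),
            stringsAsFactors = FALSE)
        validObject(truth)
        list(refs = list(ssc_premirna = ssc_pre, ssc_mature = ssc_mat,
            other_premirna = other_pre, other_mature = other_mat,
            genome = genome, est = est, other_families = other_families,
            decoys = decoys), truth = truth)
    })
}

#' Simulate a small-RNA read set
#'
#' miRNA-derived reads are planted matures (long-tailed zipf-like copy
#' distribution, exponent 1.5) with up to 2 nt trimmed from the 3' end and
#' the 3' adapter appended; contaminant reads are decoy substrings with
#' adapter; the remainder is random junk, half of it without an adapter
#' (unligated). Emits exactly `nReads` records, category totals within one
#' read of the requested fractions. Deterministic given `seed`.
#'
#' @param truth A [GroundTruth-class] (planted + foreign matures are the
#'   miRNA pool).
#' @param decoys Named list of decoy `DNAStringSet`s.
#' @param nReads Total reads.
#' @param fracMirna,fracContaminant Category fractions (sum <= 1).
#' @param adapter 3' adapter sequence.
#' @param seed Integer seed.
#' @return List: `reads` (character, named), `categories` (factor:
#'   mirna/contaminant/junk), `adapter`.
#' @export
simulateReads <- function(truth, decoys, nReads, fracMirna = 0.7,
                          fracContaminant = 0.1,
                          adapter = "TCGTATGCCGTCTTCTGCTTG", seed = 1L) {
    if (fracMirna + fracContaminant > 1 + 1e-9)
        stopf("fracMirna + fracContaminant must be <= 1")
    pool <- c(truth@loci$mature_seq, truth@foreign$mature_seq)
    if (fracMirna > 0 && !length(pool))
        stopf("ground truth has no planted matures but fracMirna > 0")
    nReads <- as.integer(nReads)
    n_mir <- round(fracMirna * nReads)
    n_con <- round(fracContaminant * nReads)
    if (n_mir + n_con > nReads) n_con <- nReads - n_mir
    n_junk <- nReads - n_mir - n_con
    with_seed(seed, {
        reads <- character(0); cats <- character(0)
        if (n_mir > 0L) {
            # zipf-like abundance; ranks are shuffled so no mature class is
            # systematically rare
            rank <- sample.int(length(pool))
            w <- rank^-1.5
            idx <- sample(seq_along(pool), n_mir, replace = TRUE,
                prob = w / sum(w))
            trim <- sample(0:2, n_mir, replace = TRUE,
                prob = c(0.6, 0.3, 0.1))
            ins <- substr(pool[idx], 1L, nchar(pool[idx]) - trim)
            reads <- c(reads, paste0(ins, adapter))
            cats <- c(cats, rep("mirna", n_mir))
        }
        if (n_con > 0L) {
            dec <- unlist(lapply(decoys, as.character), use.names = FALSE)
            src <- sample(seq_along(dec), n_con, replace = TRUE)
            len <- sample(18:28, n_con, replace = TRUE)
            st <- vapply(seq_len(n_con), function(i)
                sample.int(nchar(dec[src[i]]) - len[i], 1L), integer(1))
            reads <- c(reads, paste0(substr(dec[src], st, st + len - 1L),
                adapter))
            cats <- c(cats, rep("contaminant", n_con))
        }
        if (n_junk > 0L) {
            len <- sample(10:30, n_junk, replace = TRUE)
            jr <- vapply(len, random_dna, character(1))
            with_adapter <- seq_len(n_junk) %% 2L == 0L
            jr[with_adapter] <- paste0(jr[with_adapter], adapter)
            reads <- c(reads, jr)
            cats <- c(cats, rep("junk", n_junk))
        }
        if (length(reads)) {
            ord <- sample.int(length(reads))
            reads <- reads[ord]; cats <- cats[ord]
            names(reads) <- sprintf("read%06d", seq_along(reads))
        }
        list(reads = reads,
            categories = factor(cats, levels = c("mirna", "contaminant",
                "junk")), adapter = adapter)
    })
}

#' Write simulated reads as FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
    s <- Biostrings::DNAStringSet(reads)
    q <- Biostrings::BStringSet(vapply(nchar(reads), strrep,
        character(1), x = "I"))
    Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
    invisible(path)
}

#' Simulate the 4-stage x 3-replicate signal matrix
#'
#' Per probe, log2 intensity = log2(`baseIntensity`) + the assigned model
#' profile's cumulative template at that stage + Normal(0, `noiseSd`).
#' Flat probes (assignment 0) have a constant mean across stages.
#'
#' @param probeIds Character vector of probe ids.
#' @param profileAssignments Named integer vector probe -> profile id
#'   (0 = flat), over [enumerateProfiles()] ids.
#' @param profiles An [enumerateProfiles()] list.
#' @param baseIntensity Linear baseline intensity: a scalar, or one value
#'   per probe (e.g. log-normal across probes, as on a real array).
#' @param noiseSd Log2-scale noise SD (>= 0).
#' @param seed Integer seed.
#' @return List: `se` (a [SignalMatrix()] `SummarizedExperiment`),
#'   `trueLog2Means` (probes x 4 matrix of planted stage means).
#' @export
simulateSignalMatrix <- function(probeIds, profileAssignments,
                                 profiles = enumerateProfiles(),
                                 baseIntensity = 500, noiseSd = 0.25,
                                 seed = 1L) {
    if (noiseSd < 0) stopf("noiseSd must be >= 0")
    if (any(baseIntensity <= 0)) stopf("baseIntensity must be positive")
    if (!length(baseIntensity) %in% c(1L, length(probeIds)))
        stopf("baseIntensity must be scalar or one value per probe")
    pa <- profileAssignments[probeIds]
    pa[is.na(pa)] <- 0L
    tmpl <- rbind(rep(0L, 4L), profiles$templates)  # row 1 = flat
    mu <- log2(baseIntensity) + tmpl[pa + 1L, , drop = FALSE]
    rownames(mu) <- probeIds
    colnames(mu) <- STAGES
    with_seed(seed, {
        noise <- matrix(stats::rnorm(length(probeIds) * 12L, 0, noiseSd),
            nrow = length(probeIds))
        lg <- mu[, rep(seq_len(4L), each = 3L), drop = FALSE] + noise
        colnames(lg) <- paste(rep(STAGES, each = 3L), rep(1:3, 4L), sep = "_")
        se <- SignalMatrix(2^lg)
        rownames(se) <- probeIds
        list(se = se, trueLog2Means = mu)
    })
}

#' Simulate a qPCR CT table consistent with array fold changes
#'
#' Target CT at a stage is `controlCt - log2(foldChange) +
#' Normal(0, jitterSd)` per replicate well; the internal control's CT is
#' constant at `controlCt` in every stage. Triplicate wells per stage.
#'
#' @param arrayFoldChanges Matrix miRNA x stage of positive linear fold
#'   changes relative to the baseline stage (baseline column 1).
#' @param controlCt Control CT in cycles (default 20).
#' @param jitterSd Per-well CT jitter SD (default 0.1).
#' @param seed Integer seed.
#' @param control Control id (default `"miR-24"`).
#' @return data.frame: `mirna`, `stage`, `replicate`, `ct`.
#' @export
simulateQpcr <- function(arrayFoldChanges, controlCt = 20, jitterSd = 0.1,
                         seed = 1L, control = "miR-24") {
    fc <- as.matrix(arrayFoldChanges)
    if (any(fc <= 0)) stopf("fold changes must be positive")
    if (is.null(colnames(fc))) colnames(fc) <- STAGES
    mirnas <- rownames(fc)
    with_seed(seed, {
        rows <- list()
        for (m in mirnas) for (s in colnames(fc)) for (r in 1:3) {
            rows[[length(rows) + 1L]] <- data.frame(mirna = m, stage = s,
                replicate = r,
                ct = controlCt - log2(fc[m, s]) +
                    stats::rnorm(1L, 0, jitterSd), stringsAsFactors = FALSE)
        }
        for (s in colnames(fc)) for (r in 1:3) {
            rows[[length(rows) + 1L]] <- data.frame(mirna = control,
                stage = s, replicate = r, ct = controlCt,
                stringsAsFactors = FALSE)
        }
        do.call(rbind, rows)
    })
}

#' Synthetic target-prediction and annotation data
#'
#' Builds per-species UTR sets with planted seed-match sites (the same
#' target genes across all species, so those pairs are conserved), a
#' fraction of miRNAs with no targets at all, and flat GO/pathway
#' term-to-gene annotations whose passing terms overlap, so the
#' GO-and-pathway intersection gene set is non-empty.
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param nGenes Universe size (default 60).
#' @param targetsPerMirna Conserved target genes per targeted miRNA.
#' @param fracNoTarget Fraction of miRNAs left without any target site.
#' @param species Species tags (default pig/mouse/human).
#' @param seed Integer seed.
#' @return List: `utrs` (named list of per-species named character
#'   vectors), `annotation` (data.frame term/gene/category), `universe`,
#'   `trueTargets` (data.frame mirna/gene of planted conserved pairs).
#' @export
generateTargetData <- function(mirnas, nGenes = 60L, targetsPerMirna = 3L,
                               fracNoTarget = 0.3,
                               species = c("pig", "mouse", "human"),
                               seed = 1L) {
    mir <- toupper(chartr("U", "T", as.character(mirnas)))
    names(mir) <- if (is.null(names(mirnas)))
        sprintf("mir%d", seq_along(mir)) else names(mirnas)
    genes <- sprintf("g%03d", seq_len(nGenes))
    with_seed(seed, {
        n_no <- round(fracNoTarget * length(mir))
        no_target <- names(mir)[sample.int(length(mir))[seq_len(n_no)]]
        planted <- list()
        utrs <- lapply(species, function(sp)
            stats::setNames(vapply(genes, function(g) random_dna(300L),
                character(1)), genes))
        names(utrs) <- species
        slot_used <- list()   # per gene: next non-overlapping site slot
        for (m in names(mir)) {
            if (m %in% no_target) next
            site <- revcomp(substr(mir[[m]], 2L, 8L))
            tg <- sample(genes, targetsPerMirna)
            for (g in tg) {
                k <- if (is.null(slot_used[[g]])) 0L else slot_used[[g]]
                slot_used[[g]] <- k + 1L
                pos <- 10L + 12L * k   # disjoint slots so sites never collide
                for (sp in species) {
                    u <- utrs[[sp]][[g]]
                    substr(u, pos, pos + 6L) <- site
                    utrs[[sp]][[g]] <- u
                }
            }
            planted[[length(planted) + 1L]] <- data.frame(mirna = m,
                gene = tg, stringsAsFactors = FALSE)
        }
        planted <- if (length(planted)) do.call(rbind, planted) else
            data.frame(mirna = character(), gene = character(),
                stringsAsFactors = FALSE)
        targeted <- unique(planted$gene)
        # One strongly enriched GO term and pathway over the targeted
        # genes (overlapping sets -> non-empty intersection), plus random
        # background terms.
        ann <- rbind(
            data.frame(term = "GO:dev", gene = targeted, category = "GO",
                stringsAsFactors = FALSE),
            data.frame(term = "path:dev",
                gene = targeted, category = "pathway",
                stringsAsFactors = FALSE),
            data.frame(term = "GO:bg", gene = sample(genes, 10L),
                category = "GO", stringsAsFactors = FALSE),
            data.frame(term = "path:bg", gene = sample(genes, 10L),
                category = "pathway", stringsAsFactors = FALSE))
        list(utrs = utrs, annotation = ann, universe = genes,
            trueTargets = planted)
    })
}
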