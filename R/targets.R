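# Seed-match target prediction, cross-species conservation filtering,
# GO/pathway hypergeometric enrichment, the GO-and-pathway intersection
# gene set, the bipartite miRNA-gene network with degree ranking, and the
# key-miRNA selection chain (candidates -> degree >= 1 -> signal >= 500).

#' Predict miRNA targets by exact seed match
#'
#' An edge exists iff the reverse complement of miRNA positions 2-8 (the
#' 7-mer seed) occurs verbatim in a gene's UTR; every occurrence is
#' reported. This transparent rule replaces score-based engines so that
#' downstream network construction is fully reproducible.
#'
#' @param mirnas Named character vector or `DNAStringSet` of mature miRNA
#'   sequences (DNA or RNA alphabet). miRNAs shorter than 8 nt are skipped
#'   with a warning.
#' @param utrs Named character vector or `DNAStringSet` of UTR sequences.
#' @param species Species tag stored on each edge (default `"pig"`).
#' @return data.frame of edges: `mirna`, `gene`, `species`, `position`
#'   (0-based site offset in the UTR), `site_type`.
#' @export
predictTargets <- function(mirnas, utrs, species = "pig") {
    mir <- toupper(chartr("U", "T", as.character(mirnas)))
    names(mir) <- if (is.null(names(mirnas)))
        sprintf("mir%d", seq_along(mir)) else names(mirnas)
    utr <- toupper(as.character(utrs))
    names(utr) <- if (is.null(names(utrs)))
        sprintf("gene%d", seq_along(utr)) else names(utrs)
    short <- nchar(mir) < 8L
    if (any(short)) {
        warning(sprintf("skipping %d miRNA(s) shorter than 8 nt", sum(short)))
        mir <- mir[!short]
    }
    out <- list()
    for (m in names(mir)) {
        site <- revcomp(substr(mir[[m]], 2L, 8L))
        for (g in names(utr)) {
            hits <- gregexpr(site, utr[[g]], fixed = TRUE)[[1]]
            if (hits[1] == -1L) next
            out[[length(out) + 1L]] <- data.frame(mirna = m, gene = g,
                species = species, position = as.integer(hits) - 1L,
                site_type = "seed_2_8", stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(mirna = character(), gene = character(),
            species = character(), position = integer(),
            site_type = character(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Keep target pairs conserved across species
#'
#' A (miRNA, gene) pair is retained iff it is supported in at least
#' `minSpecies` distinct species edge sets; orthology is by shared gene id.
#'
#' @param edges data.frame of edges from [predictTargets()] (rbind the
#'   per-species calls), with a `species` column.
#' @param minSpecies Minimum supporting species (default 3).
#' @return The edge subset whose (miRNA, gene) pair passes.
#' @export
conservedTargets <- function(edges, minSpecies = 3L) {
    if (!nrow(edges)) return(edges)
    key <- paste(edges$mirna, edges$gene, sep = "\r")
    nsp <- tapply(edges$species, key, function(s) length(unique(s)))
    edges[nsp[key] >= minSpecies, , drop = FALSE]
}

#' Hypergeometric term enrichment with BH correction
#'
#' Upper-tail hypergeometric p per term (probability of an overlap at least
#' as large as observed), BH FDR across the terms of each category, and
#' pass flags at the configured thresholds (defaults: GO terms p and FDR
#' below 1e-5; pathways p and FDR below 0.05). Terms with no universe
#' genes are skipped.
#'
#' @param geneSet Character vector of query genes (subset of `universe`).
#' @param annotation data.frame with columns `term`, `gene` and optionally
#'   `category` (`"GO"` or `"pathway"`; default `"GO"`).
#' @param universe Character vector of all genes.
#' @param goP,goFdr,pathwayP,pathwayFdr Filter thresholds.
#' @return data.frame: `term`, `category`, `overlap`, `term_size`,
#'   `expected`, `p_value`, `fdr`, `pass`.
#' @export
enrichTerms <- function(geneSet, annotation, universe,
                        goP = 1e-5, goFdr = 1e-5,
                        pathwayP = 0.05, pathwayFdr = 0.05) {
    if (!all(geneSet %in% universe))
        stopf("gene set must be a subset of the universe")
    if (is.null(annotation$category)) annotation$category <- "GO"
    annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
    N <- length(unique(universe))
    n <- length(unique(geneSet))
    terms <- unique(annotation[, c("term", "category")])
    res <- lapply(seq_len(nrow(terms)), function(i) {
        tg <- unique(annotation$gene[annotation$term == terms$term[i] &
            annotation$category == terms$category[i]])
        K <- length(tg)
        if (K == 0L) return(NULL)
        k <- length(intersect(tg, geneSet))
        data.frame(term = terms$term[i], category = terms$category[i],
            overlap = k, term_size = K, expected = n * K / N,
            p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res))
        return(data.frame(term = character(), category = character(),
            overlap = integer(), term_size = integer(), expected = numeric(),
            p_value = numeric(), fdr = numeric(), pass = logical(),
            stringsAsFactors = FALSE))
    res$fdr <- NA_real_
    for (cat_i in unique(res$category)) {
        sel <- res$category == cat_i
        res$fdr[sel] <- stats::p.adjust(res$p_value[sel], "BH")
    }
    res$pass <- ifelse(res$category == "pathway",
        res$p_value < pathwayP & res$fdr < pathwayFdr,
        res$p_value < goP & res$fdr < goFdr)
    rownames(res) <- NULL
    res
}

#' Build the bipartite miRNA-gene network
#'
#' Restricts the target edges to genes present in both the GO-enriched and
#' pathway-enriched gene sets (the intersection set), deduplicates to
#' unique (miRNA, gene) pairs, and computes per-node degrees, ranked by
#' decreasing degree with ties broken by id.
#'
#' @param edges Target edge data.frame (`mirna`, `gene`).
#' @param goGenes,pathwayGenes Character vectors of genes covered by the
#'   passing GO terms and pathways.
#' @return A [MirGeneNetwork-class]; empty intersection gives an empty
#'   (valid) network.
#' @export
buildNetwork <- function(edges, goGenes, pathwayGenes) {
    core <- intersect(goGenes, pathwayGenes)
    e <- unique(edges[edges$gene %in% core, c("mirna", "gene"), drop = FALSE])
    rownames(e) <- NULL
    if (nrow(e)) {
        g <- igraph::graph_from_data_frame(e, directed = FALSE)
        deg <- igraph::degree(g)
        md <- deg[unique(e$mirna)]
        gd <- deg[unique(e$gene)]
    } else {
        md <- gd <- stats::setNames(integer(), character())
    }
    ord <- function(d) d[order(-d, names(d))]
    new("MirGeneNetwork", edges = e,
        mirnaDegree = as.integer(ord(md)) |> stats::setNames(names(ord(md))),
        geneDegree = as.integer(ord(gd)) |> stats::setNames(names(ord(gd))))
}

#' Key-miRNA selection chain
#'
#' From the candidate list, first drops miRNAs without any target gene in
#' the intersection network (degree below `minDegree`), then drops those
#' with signal strength below `minSignal`; the removals are disjoint and
#' the survivors are the key miRNAs.
#'
#' @param candidates Character vector of candidate miRNA ids.
#' @param network A [MirGeneNetwork-class]; candidates absent from its node
#'   set have degree 0.
#' @param signals Named numeric vector of signal strengths (maximum linear
#'   stage mean) covering every candidate.
#' @param minDegree Minimum network degree (default 1).
#' @param minSignal Minimum signal strength (default 500).
#' @return List: `report` (per-candidate data.frame with `degree`,
#'   `signal`, `removed_no_target`, `removed_low_signal`, `key`),
#'   `key` (ids), `nCandidates`, `nAfterDegree`, `nKey`.
#' @export
selectKeyMirnas <- function(candidates, network, signals,
                            minDegree = 1L, minSignal = 500) {
    missing <- setdiff(candidates, names(signals))
    if (length(missing))
        stopf("no signal value for candidate(s): %s",
            paste(missing, collapse = ", "))
    deg <- mirnaDegree(network)
    degree <- ifelse(candidates %in% names(deg), deg[candidates], 0L)
    signal <- signals[candidates]
    no_target <- degree < minDegree
    low_signal <- !no_target & signal < minSignal
    key <- !no_target & !low_signal
    report <- data.frame(mirna = candidates, degree = as.integer(degree),
        signal = as.numeric(signal), removed_no_target = no_target,
        removed_low_signal = low_signal, key = key,
        stringsAsFactors = FALSE, row.names = NULL)
    list(report = report, key = candidates[key],
        nCandidates = length(candidates),
        nAfterDegree = sum(!no_target), nKey = sum(key))
}
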