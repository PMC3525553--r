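# End-to-end orchestration: reads -> clean tags -> six-group candidates ->
# probe manifest -> expression -> STC -> targets/network -> key miRNAs,
# plus optional qPCR concordance. Deterministic under fixed seeds.

#' Default run configuration
#'
#' Collects every tunable parameter of the pipeline with its default, so a
#' run is fully described by one (JSON-serializable) list.
#'
#' @param ... Overrides for individual entries.
#' @return Named list of parameters.
#' @export
runConfig <- function(...) {
    cfg <- list(
        filter = filterParams(),
        maxMismatch = 0L,
        extension = 60L,
        hairpin = hairpinParams(),
        normalize = TRUE,
        detectFloor = 32,
        pThresholds = c(0.1, 0.05, 0.01),
        minSignal = 500,
        stcDeadZone = 0.25,
        stcPerm = 1000L,
        profileAlpha = 0.01,
        minDegree = 1L,
        minSpecies = 3L,
        seed = 1L)
    override <- list(...)
    cfg[names(override)] <- override
    cfg
}

#' Probe manifest: candidates plus the known same-species set
#'
#' The microarray probe set is the union of the discovered candidate
#' sequences and the separately known same-species miRNAs; with disjoint
#' inputs its size is the sum of the two counts.
#'
#' @param candidateIds Character vector of candidate ids.
#' @param knownIds Character vector of known same-species miRNA ids.
#' @return Character vector of probe ids (the union, candidates first).
#' @export
buildProbeManifest <- function(candidateIds, knownIds) {
    union(candidateIds, knownIds)
}

#' Discovery pipeline: reads to classified candidates
#'
#' Runs the cleaning funnel and the six-group classifier, then builds the
#' probe manifest (candidates plus the known same-species mature set).
#'
#' @param reads Raw reads (character vector or `DNAStringSet`).
#' @param refs Reference bundle from [generateReferences()] (or
#'   equivalent): the [runClassification()] sets plus `decoys`.
#' @param config A [runConfig()] list.
#' @return List: `tags` (clean tags), `candidates`, `summary` (group
#'   counts), `probeManifest`, `funnelStats`, `contaminantReport`.
#' @export
runDiscovery <- function(reads, refs, config = runConfig()) {
    need <- c("genome", "decoys")
    missing <- setdiff(need, names(refs))
    if (length(missing))
        stopf("reference bundle lacks: %s", paste(missing, collapse = ", "))
    clean <- cleanReads(reads, refs$decoys, config$filter)
    cls <- runClassification(clean$tags, refs, config$maxMismatch,
        config$extension, config$hairpin)
    cand <- cls$candidates[cls$candidates$group != "unclassified", ,
        drop = FALSE]
    manifest <- buildProbeManifest(cand$sequence,
        as.character(refs$ssc_mature))
    list(tags = clean$tags, candidates = cls$candidates,
        summary = cls$summary, probeManifest = manifest,
        funnelStats = clean$stats,
        contaminantReport = clean$contaminantReport)
}

#' Profiling pipeline: signal matrix to key miRNAs
#'
#' Normalizes the array, calls detectability, computes the DE table and the
#' p-value threshold cascade, clusters the significant probes, runs STC
#' profile assignment and permutation significance, and — when target data
#' are supplied — the target/enrichment/network chain down to the
#' key-miRNA report; with a CT table, also qPCR concordance.
#'
#' @param se A [SignalMatrix()] `SummarizedExperiment` (raw intensities).
#' @param config A [runConfig()] list.
#' @param targetData Optional list as from [generateTargetData()]
#'   (`utrs`, `annotation`, `universe`) plus `mirnas` (named mature
#'   sequences for the DE candidate probes).
#' @param ctTable Optional qPCR CT data.frame (see [deltaDeltaCt()]).
#' @return List with elements `normalized`, `detect`, `de`, `cascade`,
#'   `clustering`, `profiles`, `assignments`, `profileP`, and when inputs
#'   allow, `edges`, `enrichment`, `network`, `keyReport`, `concordance`.
#' @export
runProfiling <- function(se, config = runConfig(), targetData = NULL,
                         ctTable = NULL) {
    nse <- if (isTRUE(config$normalize)) normalizeSignal(se) else se
    detect <- callDetectable(nse, config$detectFloor)
    de <- deTable(nse)
    th <- sort(config$pThresholds, decreasing = TRUE)
    cascade <- data.frame(threshold = sprintf("p<%g", th),
        n = vapply(th, function(t) sum(de$p_anova < t), integer(1)))
    strong <- strengthFilter(de[de$p_anova < min(th), , drop = FALSE],
        config$minSignal)
    cascade <- rbind(cascade, data.frame(
        threshold = sprintf("p<%g & signal>=%g", min(th), config$minSignal),
        n = nrow(strong)))
    sig <- de$probe[de$p_anova < 0.05]
    out <- list(normalized = nse, detect = detect, de = de,
        cascade = cascade)
    if (length(sig) >= 2L)
        out$clustering <- hierarchicalCluster(nse, sig)
    profiles <- enumerateProfiles()
    de_sig <- de[de$probe %in% sig, , drop = FALSE]
    out$profiles <- profiles
    if (nrow(de_sig)) {
        out$assignments <- assignProfiles(de_sig, profiles,
            config$stcDeadZone)
        out$profileP <- profileSignificance(de_sig, profiles,
            config$stcPerm, config$seed, config$stcDeadZone)
    }
    if (!is.null(targetData) && !is.null(out$assignments)) {
        sig_profiles <- out$profileP$profile_id[
            out$profileP$p_value < config$profileAlpha]
        cand <- out$assignments$probe[
            out$assignments$profile_id %in% sig_profiles]
        mir <- targetData$mirnas[intersect(cand, names(targetData$mirnas))]
        edges <- do.call(rbind, lapply(names(targetData$utrs), function(sp)
            predictTargets(mir, targetData$utrs[[sp]], sp)))
        cons <- conservedTargets(edges, config$minSpecies)
        enr <- enrichTerms(unique(cons$gene), targetData$annotation,
            targetData$universe)
        genes_of <- function(cat_i) {
            pass <- enr[enr$pass & enr$category == cat_i, , drop = FALSE]
            ann <- targetData$annotation
            unique(ann$gene[ann$term %in% pass$term &
                ann$category == cat_i])
        }
        net <- buildNetwork(cons, genes_of("GO"), genes_of("pathway"))
        signals <- stats::setNames(de$signal, de$probe)
        out$edges <- cons
        out$enrichment <- enr
        out$network <- net
        out$keyReport <- selectKeyMirnas(names(mir), net, signals,
            config$minDegree, config$minSignal)
    }
    if (!is.null(ctTable)) {
        folds <- deltaDeltaCt(ctTable)
        qm <- foldMatrix(folds)
        am <- as.matrix(de[match(rownames(qm), de$probe),
            paste0("fc_", setdiff(STAGES, "E35")), drop = FALSE])
        am <- cbind(1, am)
        dimnames(am) <- dimnames(qm)
        out$qpcrFolds <- folds
        out$concordance <- validateConcordance(qm, am)
    }
    out
}

#' One-call synthetic study
#'
#' Generates a complete synthetic data set — genome with planted loci,
#' reference bundle, reads, signal matrix with planted temporal profiles,
#' target/annotation data and a CT table — under a single seed, sized for
#' quick end-to-end runs.
#'
#' @param seed Integer master seed.
#' @param genomeLength,nLoci Genome size and planted locus count.
#' @param nReads Simulated read count.
#' @param noiseSd Array noise SD (log2 scale).
#' @param nFlatProbes Extra flat (null) probes added to the array.
#' @return List: `genome`, `truth`, `refs`, `reads`, `signal` (list with
#'   `se`, `trueLog2Means`), `profiles`, `assignments` (planted), `ct`,
#'   `targetData`.
#' @export
simulateStudy <- function(seed = 1L, genomeLength = 20000L, nLoci = 24L,
                          nReads = 5000L, noiseSd = 0.15,
                          nFlatProbes = 60L) {
    gen <- generateGenome(genomeLength, nLoci, seed)
    ref <- generateReferences(gen$genome, gen$truth, seed = seed + 1L)
    reads <- simulateReads(ref$truth, ref$refs$decoys, nReads,
        seed = seed + 2L)
    profiles <- enumerateProfiles()
    matures <- stats::setNames(ref$truth@loci$mature_seq,
        ref$truth@loci$id)
    probe_ids <- c(names(matures),
        sprintf("flat%02d", seq_len(nFlatProbes)))
    # Temporal structure: 40% of miRNA probes follow the monotone-up
    # profile, 20% the monotone-down one (so STC has genuinely enriched
    # profiles), the rest are scattered; background probes are flat.
    planted <- with_seed(seed + 3L, {
        n <- length(matures)
        up <- which(rowSums(profiles$steps == 1L) == ncol(profiles$steps))
        down <- which(rowSums(profiles$steps == -1L) == ncol(profiles$steps))
        pid <- sample(profiles$id, n, replace = TRUE)
        pid[seq_len(round(0.4 * n))] <- up
        pid[round(0.4 * n) + seq_len(round(0.2 * n))] <- down
        stats::setNames(c(pid[sample.int(n)], rep(0L, nFlatProbes)),
            probe_ids)
    })
    # log-normal base intensities across probes (median 500), as on a
    # real single-channel array
    bases <- with_seed(seed + 7L,
        500 * 2^stats::rnorm(length(probe_ids), 0, 1.5))
    signal <- simulateSignalMatrix(probe_ids, planted, profiles,
        baseIntensity = bases, noiseSd = noiseSd, seed = seed + 4L)
    true_fc <- 2^(signal$trueLog2Means - signal$trueLog2Means[, "E35"])
    # validate miRNAs with at least 4-fold planted spread across stages
    spread <- apply(log2(true_fc[names(matures), , drop = FALSE]), 1L,
        function(x) diff(range(x)))
    val <- utils::head(names(sort(spread, decreasing = TRUE)), 9L)
    ct <- simulateQpcr(true_fc[val, , drop = FALSE], jitterSd = 0.1,
        seed = seed + 5L)
    td <- generateTargetData(matures, seed = seed + 6L)
    td$mirnas <- matures
    list(genome = gen$genome, truth = ref$truth, refs = ref$refs,
        reads = reads, signal = signal, profiles = profiles,
        assignments = planted, ct = ct, targetData = td)
}
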