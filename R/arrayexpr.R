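# Four-stage probe-signal analysis: quantile normalization, detectability
# calls, one-way ANOVA across stages and Welch pairwise tests on log2
# intensities, average-linkage clustering on 1 - Pearson correlation of
# stage-mean profiles, fold changes versus the bud stage (E35), and the
# signal-strength filter. The signal matrix is a SummarizedExperiment with
# 4 stages x 3 replicates.

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Build a four-stage signal matrix
#'
#' @param values Numeric matrix, probes x 12 samples (linear intensities).
#' @param stage Character/factor of stage labels per column
#'   (E35/E45/E50/E60); defaults to 3 replicates per stage in order.
#' @param replicate Integer replicate index per column.
#' @return A `SummarizedExperiment` with assay `"signal"` and colData
#'   `stage`, `replicate`.
#' @export
SignalMatrix <- function(values,
                         stage = rep(STAGES, each = 3L),
                         replicate = rep(1:3, times = 4L)) {
    values <- as.matrix(values)
    if (ncol(values) != 12L)
        stopf("expected 12 samples (4 stages x 3 replicates), got %d",
            ncol(values))
    stage <- factor(stage, levels = STAGES)
    if (any(table(stage) != 3L))
        stopf("each of %s needs exactly 3 replicates",
            paste(STAGES, collapse = "/"))
    if (is.null(colnames(values)))
        colnames(values) <- paste(stage, replicate, sep = "_")
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("probe%d", seq_len(nrow(values)))
    SummarizedExperiment(assays = list(signal = values),
        colData = S4Vectors::DataFrame(stage = stage,
            replicate = as.integer(replicate),
            row.names = colnames(values)))
}

.signal <- function(se) assay(se, "signal")
.stage <- function(se) colData(se)$stage

#' Quantile-normalize the signal matrix
#'
#' Floors intensities at 1, log2-transforms, quantile-normalizes the 12
#' sample columns and returns to the linear scale; afterwards every
#' column shares the same empirical distribution (equal medians).
#'
#' @param se A [SignalMatrix()] `SummarizedExperiment`.
#' @return The normalized `SummarizedExperiment`.
#' @export
normalizeSignal <- function(se) {
    x <- .signal(se)
    if (any(colSums(x) == 0)) stopf("degenerate array: all-zero sample column")
    lg <- log2(pmax(x, 1))
    nz <- limma::normalizeQuantiles(lg)
    out <- se
    SummarizedExperiment::assay(out, "signal") <- 2^nz
    out
}

#' Per-probe, per-stage linear stage means
#'
#' @param se A signal `SummarizedExperiment`.
#' @param log2 Return log2 of the stage means instead.
#' @return Matrix probes x 4 stages.
#' @export
stageMeans <- function(se, log2 = FALSE) {
    x <- .signal(se)
    st <- .stage(se)
    m <- vapply(STAGES, function(s)
        rowMeans(x[, st == s, drop = FALSE]), numeric(nrow(x)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1,
        dimnames = list(rownames(x), STAGES))
    if (log2) base::log2(m) else m
}

#' Detectability calls per probe and stage
#'
#' A probe is detectable in a stage iff its mean linear intensity across
#' that stage's replicates reaches `floorThreshold`; globally detectable
#' iff detectable in at least one stage.
#'
#' @param se A (normalized) signal `SummarizedExperiment`.
#' @param floorThreshold Detection floor on the linear scale (default 32).
#' @return List: `detectable` (logical probes x 4 matrix), `perStage`
#'   (named counts), `global` (logical vector), `nDetectable`.
#' @export
callDetectable <- function(se, floorThreshold = 32) {
    m <- stageMeans(se)
    det <- m >= floorThreshold
    list(detectable = det, perStage = colSums(det),
        global = rowSums(det) > 0, nDetectable = sum(rowSums(det) > 0))
}

.log2_rows <- function(se) log2(pmax(.signal(se), 1))

#' One-way ANOVA across the four stages
#'
#' Fixed-effects one-way ANOVA on log2 intensities, 4 groups x 3
#' replicates, per probe. When every group has zero within-group variance
#' the p-value is 0 if the group means differ and 1 otherwise.
#'
#' @param se A (normalized) signal `SummarizedExperiment`.
#' @return Named numeric vector of p-values.
#' @export
anovaStageTest <- function(se) {
    lg <- .log2_rows(se)
    st <- .stage(se)
    apply(lg, 1L, function(y) {
        within_var <- tapply(y, st, stats::var)
        between <- stats::var(tapply(y, st, mean))
        if (all(within_var < .Machine$double.eps^0.5)) {
            return(if (between > .Machine$double.eps^0.5) 0 else 1)
        }
        stats::oneway.test(y ~ st, var.equal = TRUE)$p.value
    })
}

#' Welch two-sample test between two stages
#'
#' Welch t-test on log2 intensities, 3 vs 3 replicates, per probe. Zero
#' variance in both groups gives p = 1 for equal means and p = 0 otherwise.
#'
#' @param se A (normalized) signal `SummarizedExperiment`.
#' @param stageA,stageB Stage labels to compare.
#' @return Named numeric vector of p-values.
#' @export
pairwiseStageTest <- function(se, stageA, stageB) {
    st <- .stage(se)
    stopifnot(stageA %in% st, stageB %in% st)
    lg <- .log2_rows(se)
    a <- lg[, st == stageA, drop = FALSE]
    b <- lg[, st == stageB, drop = FALSE]
    vapply(seq_len(nrow(lg)), function(i) {
        tryCatch(stats::t.test(a[i, ], b[i, ])$p.value,
            error = function(e)
                if (isTRUE(all.equal(mean(a[i, ]), mean(b[i, ])))) 1 else 0)
    }, numeric(1)) |> stats::setNames(rownames(lg))
}

#' Differential-expression result table
#'
#' Combines the across-stage ANOVA (with BH-adjusted q-values), the four
#' consecutive/extreme pairwise tests, linear stage means, the signal
#' strength (maximum stage mean) and fold changes versus the E35 baseline
#' (fold change at E35 is identically 1).
#'
#' @param se A (normalized) signal `SummarizedExperiment`.
#' @param baseline Baseline stage (default `"E35"`).
#' @return data.frame, one row per probe.
#' @export
deTable <- function(se, baseline = "E35") {
    m <- stageMeans(se)
    p_anova <- anovaStageTest(se)
    pairs <- list(c("E35", "E45"), c("E45", "E50"), c("E50", "E60"),
        c("E35", "E60"))
    pw <- lapply(pairs, function(p) pairwiseStageTest(se, p[1], p[2]))
    names(pw) <- vapply(pairs, paste, character(1), collapse = "_")
    fc <- m / m[, baseline]
    out <- data.frame(probe = rownames(m), p_anova = p_anova,
        q_anova = stats::p.adjust(p_anova, "BH"), stringsAsFactors = FALSE)
    for (nm in names(pw)) out[[paste0("p_", nm)]] <- pw[[nm]]
    for (s in STAGES) out[[paste0("mean_", s)]] <- m[, s]
    out$signal <- apply(m, 1L, max)
    for (s in setdiff(STAGES, baseline)) out[[paste0("fc_", s)]] <- fc[, s]
    rownames(out) <- NULL
    out
}

#' Average-linkage hierarchical clustering of probe profiles
#'
#' Clusters probes on 1 - Pearson correlation of their stage-mean log2
#' vectors (average linkage). A zero-variance probe vector has distance 1
#' to every other probe. Probes are ordered by id first so ties resolve
#' deterministically.
#'
#' @param se A (normalized) signal `SummarizedExperiment`.
#' @param probes Optional probe-id subset (>= 2 probes).
#' @return List: `hclust` (the merge tree), `leafOrder` (probe ids in
#'   dendrogram order), `heights`, `newick` (Newick string).
#' @export
hierarchicalCluster <- function(se, probes = NULL) {
    lg <- stageMeans(se, log2 = TRUE)
    if (!is.null(probes)) lg <- lg[probes, , drop = FALSE]
    if (nrow(lg) < 2L) stopf("need at least 2 probes to cluster")
    lg <- lg[order(rownames(lg)), , drop = FALSE]
    sds <- apply(lg, 1L, stats::sd)
    cm <- suppressWarnings(stats::cor(t(lg)))
    cm[is.na(cm)] <- 0                      # zero-variance convention
    d <- 1 - cm
    diag(d) <- 0
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    phy <- ape::as.phylo(hc)
    list(hclust = hc, leafOrder = hc$labels[hc$order],
        heights = hc$height, newick = ape::write.tree(phy))
}

#' Signal-strength filter
#'
#' Keeps probes whose maximum linear stage mean (`signal`) is at least
#' `minSignal` (default 500, the strong-signal cut-off).
#'
#' @param results A [deTable()] data.frame (needs a `signal` column).
#' @param minSignal Minimum signal strength.
#' @return The filtered data.frame.
#' @export
strengthFilter <- function(results, minSignal = 500) {
    results[results$signal >= minSignal, , drop = FALSE]
}
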