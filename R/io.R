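# Plain-text interchange: collapsed FASTA for tags, TSV for the signal
# matrix and result tables, JSON for the ground-truth sidecar. Every stage
# of the pipeline reads/writes these so modules are independently runnable.

#' Write a UniqueTagSet as collapsed FASTA
#'
#' Headers follow the `tag{n}_x{count}` convention.
#'
#' @param tags A [UniqueTagSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTagsFasta <- function(tags, path) {
    s <- tagSequences(tags)
    names(s) <- sprintf("tag%d_x%d", seq_along(s), tagCounts(tags))
    Biostrings::writeXStringSet(s, path)
    invisible(path)
}

#' Read a collapsed FASTA written by [writeTagsFasta()]
#'
#' @param path FASTA path with `..._x{count}` headers.
#' @return A [UniqueTagSet-class].
#' @export
readTagsFasta <- function(path) {
    s <- Biostrings::readDNAStringSet(path)
    counts <- as.integer(sub(".*_x(\\d+)$", "\\1", names(s)))
    UniqueTagSet(as.character(s), counts)
}

#' Write the signal matrix as TSV
#'
#' One `probe_id` column plus 12 sample columns named `stage_replicate`.
#'
#' @param se A [SignalMatrix()] `SummarizedExperiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSignalTsv <- function(se, path) {
    x <- SummarizedExperiment::assay(se, "signal")
    df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read a signal-matrix TSV written by [writeSignalTsv()]
#'
#' @param path TSV path.
#' @return A `SummarizedExperiment`.
#' @export
readSignalTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$probe_id
    stage <- sub("_.*$", "", colnames(m))
    replicate <- as.integer(sub("^.*_", "", colnames(m)))
    SignalMatrix(m, stage, replicate)
}

#' Write the ground-truth sidecar as JSON
#'
#' @param truth A [GroundTruth-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruthJson <- function(truth, path) {
    jsonlite::write_json(list(loci = truth@loci, foreign = truth@foreign,
        decoys = truth@decoys,
        profile_assignments = as.list(truth@profileAssignments),
        genome_length = truth@genomeLength, seed = truth@seed),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
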