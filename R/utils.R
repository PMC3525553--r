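# Internal helpers shared across modules.

#' @useDynLib mirnaome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

STAGES <- c("E35", "E45", "E50", "E60")

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    force(code)
}

# Reverse complement of a plain character vector (DNA alphabet).
revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 0-based half-open interval overlap on the same target sequence.
intervals_overlap <- function(target1, start1, end1, target2, start2, end2) {
    target1 == target2 & start1 < end2 & start2 < end1
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
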