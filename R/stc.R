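# Series Test of Cluster (STC): short time-series clustering against
# pre-defined unit-change model profiles. For T timepoints and unit change
# c, every step vector in {-c..c}^(T-1) except the all-zero one is a model
# profile; with T = 4, c = 1 this gives the canonical 26 profiles. Each
# probe's log2-ratio series (relative to the first stage) is assigned to
# the profile minimizing the Euclidean distance to the least-squares-scaled
# cumulative template, and per-profile significance is scored by permuting
# the timepoint columns.

#' Enumerate unit-change model profiles
#'
#' All step vectors of length `T - 1` with entries in `{-c, ..., c}`,
#' excluding the flat (all-zero) vector, in lexicographic order of steps.
#' Cumulative templates start at 0.
#'
#' @param T Number of timepoints (default 4).
#' @param c Maximum per-interval unit change (default 1).
#' @return List: `steps` (profiles x (T-1) matrix), `templates`
#'   (profiles x T matrix), `id` (1-based integer ids).
#' @examples
#' nrow(enumerateProfiles(4, 1)$steps)   # 26
#' @export
enumerateProfiles <- function(T = 4L, c = 1L) {
    stopifnot(T >= 2L, c >= 1L)
    vals <- seq.int(-c, c)
    grid <- as.matrix(expand.grid(replicate(T - 1L, vals, simplify = FALSE),
        KEEP.OUT.ATTRS = FALSE))
    grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]
    grid <- grid[rowSums(grid != 0L) > 0L, , drop = FALSE]
    dimnames(grid) <- list(NULL, paste0("step", seq_len(T - 1L)))
    cs <- grid
    if (ncol(grid) > 1L)
        for (j in 2:ncol(grid)) cs[, j] <- cs[, j - 1L] + grid[, j]
    templates <- cbind(0L, cs)
    colnames(templates) <- paste0("t", seq_len(T) - 1L)
    list(steps = grid, templates = templates, id = seq_len(nrow(grid)))
}

.profile_distances <- function(series, templates) {
    # series: n x T (first column 0); templates: P x T
    n <- nrow(series)
    d <- matrix(NA_real_, n, nrow(templates))
    for (p in seq_len(nrow(templates))) {
        t <- templates[p, ]
        tt <- sum(t * t)
        s <- pmax(0, as.numeric(series %*% t) / tt)  # non-negative LS scale
        resid <- series - outer(s, t)
        d[, p] <- sqrt(rowSums(resid^2))
    }
    d
}

#' Assign probe series to their closest model profile
#'
#' Each series (log2 ratios versus the first stage, so element 1 is 0) gets
#' the profile whose least-squares-scaled cumulative template is nearest in
#' Euclidean distance; the scale is constrained non-negative so a profile
#' and its mirror image are distinguishable. Ties go to the lower profile
#' id. Per-interval steps are also discretized to sign(delta) with a
#' dead-zone `|delta| < deadZone` and reported alongside.
#'
#' @param series Numeric matrix, probes x T, first column 0; or a
#'   [deTable()] data.frame (log2 fold-change columns are used).
#' @param profiles An [enumerateProfiles()] list.
#' @param deadZone Dead-zone for step discretization in log2 units
#'   (default 0.25).
#' @return data.frame: `probe`, `profile_id`, `distance`,
#'   `tentative_steps` (comma string of -1/0/+1).
#' @export
assignProfiles <- function(series, profiles = enumerateProfiles(),
                           deadZone = 0.25) {
    series <- .as_series_matrix(series)
    keep <- stats::complete.cases(series)
    if (!all(keep)) {
        warning(sprintf("skipping %d probe(s) with missing stage values",
            sum(!keep)))
        series <- series[keep, , drop = FALSE]
    }
    if (!nrow(series))
        return(data.frame(probe = character(), profile_id = integer(),
            distance = numeric(), tentative_steps = character(),
            stringsAsFactors = FALSE))
    d <- .profile_distances(series, profiles$templates)
    best <- apply(d, 1L, which.min)       # which.min takes the lowest index
    steps <- t(apply(series, 1L, function(x) {
        dl <- diff(x)
        ifelse(abs(dl) < deadZone, 0L, sign(dl))
    }))
    data.frame(probe = rownames(series), profile_id = profiles$id[best],
        distance = d[cbind(seq_len(nrow(d)), best)],
        tentative_steps = apply(steps, 1L, paste, collapse = ","),
        stringsAsFactors = FALSE, row.names = NULL)
}

.as_series_matrix <- function(series) {
    if (is.data.frame(series) && "probe" %in% names(series)) {
        fc_cols <- grep("^fc_", names(series), value = TRUE)
        m <- cbind(0, log2(as.matrix(series[, fc_cols, drop = FALSE])))
        rownames(m) <- series$probe
        return(m)
    }
    m <- as.matrix(series)
    if (is.null(rownames(m))) rownames(m) <- sprintf("probe%d", seq_len(nrow(m)))
    m
}

#' Permutation significance of model profiles
#'
#' For each profile, p is the smoothed fraction of permutations whose
#' member count reaches the observed count: `(1 + exceedances) /
#' (1 + nPerm)`. Each permutation round shuffles the timepoint columns of
#' every probe independently and re-anchors each series to its new first
#' element, so the tested hypothesis is temporal patterning. (Per-probe
#' rather than shared permutations: with 4 timepoints there are only 24
#' shared column orders, which caps attainable significance at about
#' 1/24 and cannot resolve profile enrichment at conventional levels.)
#'
#' @param series Probes x T matrix of log2 ratios (or [deTable()]).
#' @param profiles An [enumerateProfiles()] list.
#' @param nPerm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param deadZone Passed to [assignProfiles()].
#' @return data.frame: `profile_id`, `n_members`, `p_value`.
#' @export
profileSignificance <- function(series, profiles = enumerateProfiles(),
                                nPerm = 1000L, seed = 1L, deadZone = 0.25) {
    if (nPerm < 100L)
        warning("nPerm < 100 gives poor p-value resolution")
    series <- .as_series_matrix(series)
    T <- ncol(series)
    P <- nrow(profiles$templates)
    count_members <- function(m) {
        a <- assignProfiles(m, profiles, deadZone)
        tabulate(a$profile_id, nbins = P)
    }
    obs <- count_members(series)
    exceed <- integer(P)
    n <- nrow(series)
    with_seed(seed, {
        for (b in seq_len(nPerm)) {
            ord <- t(apply(matrix(stats::runif(n * T), n, T), 1L, order))
            pm <- matrix(series[cbind(rep(seq_len(n), times = T),
                as.vector(ord))], n, T)
            pm <- pm - pm[, 1L]           # re-anchor to the permuted baseline
            exceed <- exceed + (count_members(pm) >= obs)
        }
    })
    data.frame(profile_id = profiles$id, n_members = obs,
        p_value = (1 + exceed) / (1 + nPerm))
}
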