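# Relative qPCR quantification by the delta-delta-CT method against an
# internal control (miR-24 analogue) with the bud stage (E35) as baseline,
# and Pearson concordance between qPCR and array fold changes.

#' Delta-delta-CT relative quantification
#'
#' Replicate CTs are averaged per (miRNA, stage); then
#' `dCT(m, s) = meanCT(m, s) - meanCT(control, s)`,
#' `ddCT(m, s) = dCT(m, s) - dCT(m, baseline)` and
#' `fold = 2^(-ddCT)`, so the baseline fold is identically 1.
#'
#' @param ct data.frame with columns `mirna`, `stage`, `replicate`, `ct`.
#' @param control Internal-control miRNA id (default `"miR-24"`).
#' @param baseline Baseline stage (default `"E35"`).
#' @return data.frame: `mirna`, `stage`, `delta_ct`, `delta_delta_ct`,
#'   `fold`. Stages missing the control are flagged `NA` with a warning.
#' @export
deltaDeltaCt <- function(ct, control = "miR-24", baseline = "E35") {
    stopifnot(all(c("mirna", "stage", "ct") %in% names(ct)))
    mean_ct <- stats::aggregate(ct ~ mirna + stage, data = ct, FUN = mean)
    ctrl <- mean_ct[mean_ct$mirna == control, , drop = FALSE]
    if (!nrow(ctrl)) stopf("control '%s' not found in the CT table", control)
    targets <- mean_ct[mean_ct$mirna != control, , drop = FALSE]
    if (!baseline %in% targets$stage)
        stopf("baseline stage '%s' absent from the CT table", baseline)
    ctrl_by_stage <- stats::setNames(ctrl$ct, ctrl$stage)
    no_ctrl <- setdiff(unique(targets$stage), names(ctrl_by_stage))
    if (length(no_ctrl))
        warning(sprintf("control missing in stage(s) %s; values set NA",
            paste(no_ctrl, collapse = ", ")))
    targets$delta_ct <- targets$ct - ctrl_by_stage[targets$stage]
    base_dct <- targets$delta_ct[targets$stage == baseline]
    names(base_dct) <- targets$mirna[targets$stage == baseline]
    targets$delta_delta_ct <- targets$delta_ct - base_dct[targets$mirna]
    targets$fold <- 2^(-targets$delta_delta_ct)
    out <- targets[order(targets$mirna, targets$stage),
        c("mirna", "stage", "delta_ct", "delta_delta_ct", "fold")]
    rownames(out) <- NULL
    out
}

#' qPCR / array concordance by Pearson correlation
#'
#' Both platforms' fold changes are expressed relative to the baseline
#' stage; the correlation is computed per miRNA over the 4 stage values, on
#' the log2 scale by default (which symmetrizes up- and down-regulation).
#' A miRNA passes when R exceeds `minR`; the two-sided p-value from the
#' t-transform (n = 4) is reported.
#'
#' @param qpcrFolds,arrayFolds Matrices (miRNA x stage) of linear fold
#'   changes with identical dimnames, e.g. from [deltaDeltaCt()] reshaped
#'   and [deTable()] `fc_*` columns.
#' @param minR Pass threshold on R (default 0.9).
#' @param log2Scale Correlate log2 fold changes (default `TRUE`).
#' @return data.frame: `mirna`, `r`, `p_value`, `pass`, `reason`
#'   (`"zero_variance"` when R is undefined, in which case pass is FALSE).
#' @export
validateConcordance <- function(qpcrFolds, arrayFolds, minR = 0.9,
                                log2Scale = TRUE) {
    qpcrFolds <- as.matrix(qpcrFolds)
    arrayFolds <- as.matrix(arrayFolds)
    stopifnot(identical(dim(qpcrFolds), dim(arrayFolds)))
    arrayFolds <- arrayFolds[rownames(qpcrFolds), colnames(qpcrFolds),
        drop = FALSE]
    if (log2Scale) {
        qpcrFolds <- log2(qpcrFolds)
        arrayFolds <- log2(arrayFolds)
    }
    res <- lapply(rownames(qpcrFolds), function(m) {
        x <- qpcrFolds[m, ]; y <- arrayFolds[m, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
            return(data.frame(mirna = m, r = NA_real_, p_value = NA_real_,
                pass = FALSE, reason = "zero_variance",
                stringsAsFactors = FALSE))
        ct <- stats::cor.test(x, y)
        data.frame(mirna = m, r = unname(ct$estimate),
            p_value = ct$p.value, pass = unname(ct$estimate) > minR,
            reason = "", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Reshape a deltaDeltaCt result into a miRNA x stage fold matrix
#'
#' @param folds A [deltaDeltaCt()] data.frame.
#' @return Numeric matrix, miRNAs x stages.
#' @export
foldMatrix <- function(folds) {
    stats::xtabs(fold ~ mirna + stage, data = folds) |>
        unclass() |> as.matrix()
}
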