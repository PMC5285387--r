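#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged first. Per biological replicate,
#' dCt = Ct_target - Ct_reference; ddCt = dCt - mean(dCt of the
#' calibrator group); per-replicate ratio = 2^(-ddCt). The group summary
#' is the geometric mean of per-replicate ratios (ratios are
#' multiplicative; an arithmetic mean is available behind
#' \code{summary}), with the standard error computed over the
#' per-replicate ratios.
#'
#' @param ct Ct table: data.frame with columns sample_id, mode, stage,
#'   gene, tech_rep, ct (as produced by
#'   \code{\link{generateQpcrFixture}} or \code{\link{readCtTable}}).
#' @param target target gene name.
#' @param reference housekeeping gene (default "HpTIP4").
#' @param calibrator calibrator group as "mode:stage" (default
#'   "sexual:11").
#' @param summary "geometric" (default) or "arithmetic" group mean.
#' @return data.frame: gene, group, ratio, se, n (biological replicates).
#' @export
deltaDeltaCt <- function(ct, target, reference = "HpTIP4",
                         calibrator = "sexual:11",
                         summary = c("geometric", "arithmetic")) {
    summary <- match.arg(summary)
    if (any(ct$ct <= 0)) stop("Ct values must be positive")
    ct$group <- paste0(ct$mode, ":", ct$stage)
    if (!calibrator %in% ct$group)
        stop("calibrator group ", calibrator, " absent from the Ct table")
    # average technical replicates per (sample, gene)
    agg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct,
                            FUN = mean)
    tgt <- agg[agg$gene == target, ]
    ref <- agg[agg$gene == reference, ]
    if (!nrow(tgt)) stop("no Ct rows for target gene ", target)
    m <- match(tgt$sample_id, ref$sample_id)
    if (anyNA(m))
        stop("missing reference (", reference, ") Ct for replicate(s): ",
             paste(tgt$sample_id[is.na(m)], collapse = ", "))
    dct <- tgt$ct - ref$ct[m]
    calMean <- mean(dct[tgt$group == calibrator])
    ratio <- 2^(-(dct - calMean))
    out <- do.call(rbind, lapply(split(seq_along(ratio), tgt$group),
        function(idx) {
            r <- ratio[idx]
            est <- if (summary == "geometric") exp(mean(log(r)))
                   else mean(r)
            data.frame(gene = target, group = tgt$group[idx[1]],
                       ratio = est,
                       se = stats::sd(r) / sqrt(length(r)),
                       n = length(r), stringsAsFactors = FALSE)
        }))
    rownames(out) <- NULL
    out
}

#' Efficiency-corrected (Pfaffl) relative expression ratio
#'
#' ratio = E_target^dCt_target / E_reference^dCt_reference, with each
#' dCt = Ct(calibrator) - Ct(sample). With both efficiencies equal to 2
#' this reduces exactly to 2^(-ddCt).
#'
#' @param eTarget,eReference amplification efficiencies in [1, 2]
#'   (2 = perfect doubling).
#' @param dctTarget,dctReference Ct differences (calibrator - sample).
#' @return the expression ratio.
#' @export
pfafflRatio <- function(eTarget, dctTarget, eReference, dctReference) {
    if (any(c(eTarget, eReference) < 1) || any(c(eTarget, eReference) > 2))
        stop("amplification efficiencies must lie in [1, 2]")
    eTarget^dctTarget / eReference^dctReference
}

#' Read a Ct table from TSV
#'
#' Columns: sample_id, mode, stage, gene, tech_rep, ct.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "mode", "stage", "gene", "tech_rep", "ct")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(is.na(df$ct)) || any(df$ct <= 0))
        stop("Ct values must be positive and non-missing")
    df$stage <- as.character(df$stage)
    df
}
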