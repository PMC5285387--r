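#' The four canonical comparisons and their up/down clusters
#'
#' Each comparison contrasts a test group against a reference group of
#' (mode, stage) samples; the reference is the sexual sample or, within a
#' mode, the earlier floral stage. Genes up-regulated in the test group go
#' to the comparison's up cluster, down-regulated genes to its down
#' cluster, giving the eight clusters C1..C8:
#' sexual 11 -> 14 (C1/C2), apomictic 11 -> 14 (C3/C4),
#' sexual vs apomictic at stage 11 (C5/C6) and at stage 14 (C7/C8).
#'
#' @return data.frame with columns name, ref_mode, ref_stage, test_mode,
#'   test_stage, up, down.
#' @export
canonicalComparisons <- function() {
    data.frame(
        name = c("Sex11_vs_Sex14", "Apo11_vs_Apo14",
                 "Sex11_vs_Apo11", "Sex14_vs_Apo14"),
        ref_mode = c("sexual", "apomictic", "sexual", "sexual"),
        ref_stage = c("11", "11", "11", "14"),
        test_mode = c("sexual", "apomictic", "apomictic", "apomictic"),
        test_stage = c("14", "14", "11", "14"),
        up = c("C1", "C3", "C5", "C7"),
        down = c("C2", "C4", "C6", "C8"),
        stringsAsFactors = FALSE)
}

#' Normalise each sample to its 75th percentile
#'
#' Each sample column is divided by its own 75th percentile (linear
#' interpolation between order statistics, the stats::quantile type-7
#' default) and rescaled by the median of all samples' 75th percentiles so
#' the output stays on the intensity scale. After normalisation every
#' sample's 75th percentile equals that shared constant; fold changes are
#' unaffected by the constant.
#'
#' @param mat genes x samples non-negative matrix.
#' @param percentile percentile to normalise on (default 75).
#' @return normalised matrix of the same shape.
#' @export
percentileNormalize <- function(mat, percentile = 75) {
    q <- apply(mat, 2, stats::quantile, probs = percentile / 100,
               names = FALSE, type = 7)
    if (any(q == 0))
        stop("zero ", percentile, "th percentile in sample(s): ",
             paste(colnames(mat)[q == 0], collapse = ", "))
    sweep(mat, 2, q, "/") * stats::median(q)
}

#' Pooled-variance unpaired two-sample t-test
#'
#' Classic equal-variance two-sample t with df = n_a + n_b - 2 and
#' two-sided p. Degenerate zero-pooled-variance inputs follow a documented
#' convention: equal means give t = 0, p = 1; unequal means give
#' t = +/-Inf, p = 0. A Welch variant is available behind \code{welch}.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) statistic instead.
#' @return named numeric c(t, df, p).
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
    na <- length(a); nb <- length(b)
    if (na < 2 || nb < 2) stop("each group needs >= 2 values")
    ma <- mean(a); mb <- mean(b)
    va <- stats::var(a); vb <- stats::var(b)
    if (welch) {
        seSq <- va / na + vb / nb
        if (seSq == 0)
            return(c(t = if (ma == mb) 0 else sign(ma - mb) * Inf,
                     df = na + nb - 2, p = as.numeric(ma == mb)))
        t <- (ma - mb) / sqrt(seSq)
        df <- seSq^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    } else {
        sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
        df <- na + nb - 2
        if (sp2 == 0)
            return(c(t = if (ma == mb) 0 else sign(ma - mb) * Inf,
                     df = df, p = as.numeric(ma == mb)))
        t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    }
    c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Signed fold change between two positive means
#'
#' The ratio r = test/reference is reported as r when r >= 1 and as -1/r
#' when r < 1, so up- and down-regulation are symmetric around +/-1 and a
#' threshold of 2 reads as "at least two-fold in either direction";
#' |result| >= 1 always.
#'
#' @param testMean,refMean positive group means (normalised linear
#'   intensities).
#' @return signed fold change.
#' @export
signedFoldChange <- function(testMean, refMean) {
    if (any(testMean <= 0) || any(refMean <= 0))
        stop("group means must be positive")
    r <- testMean / refMean
    ifelse(r >= 1, r, -1 / r)
}

#' Call differentially expressed genes and assign C1..C8 clusters
#'
#' For every gene and comparison, an unpaired t-test contrasts the test
#' group against the reference group and the signed fold change is the
#' ratio of the groups' arithmetic means of normalised linear intensities.
#' A gene enters the comparison's up (down) cluster when p < pThreshold
#' (strict) and signed FC >= fcThreshold (<= -fcThreshold, inclusive). No
#' multiple-testing correction is applied to the calls; BH q-values are
#' reported alongside for information.
#'
#' @param x a \linkS4class{PistilSE} of normalised intensities.
#' @param comparisons data.frame as \code{\link{canonicalComparisons}}.
#' @param pThreshold raw p-value cutoff (default 0.01, strict inequality).
#' @param fcThreshold signed fold-change magnitude cutoff (default 2,
#'   inclusive).
#' @param welch use the Welch t statistic.
#' @param logScale if TRUE the t-test is computed on log2 intensities
#'   (fold changes are always ratios of linear-scale means).
#' @return data.frame with one row per gene x comparison: gene,
#'   comparison, t, df, p, q, signed_fc, cluster (NA when not called).
#' @export
callDEGs <- function(x, comparisons = canonicalComparisons(),
                     pThreshold = 0.01, fcThreshold = 2,
                     welch = FALSE, logScale = FALSE) {
    stopifnot(methods::is(x, "PistilSE"))
    if (pThreshold <= 0 || pThreshold >= 1) stop("pThreshold must be in (0,1)")
    if (fcThreshold < 1) stop("fcThreshold must be >= 1")
    mat <- intensities(x)
    groups <- sampleGroups(x)
    res <- lapply(seq_len(nrow(comparisons)), function(j) {
        cmp <- comparisons[j, ]
        rg <- paste0(cmp$ref_mode, ":", cmp$ref_stage)
        tg <- paste0(cmp$test_mode, ":", cmp$test_stage)
        refIdx <- which(groups == rg); testIdx <- which(groups == tg)
        if (length(refIdx) < 2)
            stop("group ", rg, " has fewer than 2 replicates")
        if (length(testIdx) < 2)
            stop("group ", tg, " has fewer than 2 replicates")
        refM <- mat[, refIdx, drop = FALSE]
        testM <- mat[, testIdx, drop = FALSE]
        tm <- if (logScale) log2(testM) else testM
        rm_ <- if (logScale) log2(refM) else refM
        stats_ <- t(vapply(seq_len(nrow(mat)), function(i)
            unpairedTTest(tm[i, ], rm_[i, ], welch = welch),
            numeric(3)))
        fc <- signedFoldChange(rowMeans(testM), rowMeans(refM))
        p <- stats_[, "p"]
        cluster <- ifelse(p < pThreshold & fc >= fcThreshold, cmp$up,
                   ifelse(p < pThreshold & fc <= -fcThreshold, cmp$down,
                          NA_character_))
        data.frame(gene = rownames(mat), comparison = cmp$name,
                   t = stats_[, "t"], df = stats_[, "df"], p = p,
                   q = stats::p.adjust(p, "BH"), signed_fc = fc,
                   cluster = cluster, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "thresholds") <- c(p = pThreshold, fc = fcThreshold)
    out
}

#' Gene sets of the eight clusters from a DEG table
#'
#' @param degs output of \code{\link{callDEGs}}.
#' @return named list C1..C8 of gene-id character vectors.
#' @export
clusterSets <- function(degs) {
    called <- degs[!is.na(degs$cluster), c("gene", "cluster")]
    sets <- split(called$gene, factor(called$cluster, levels = .CLUSTERS))
    lapply(sets, unique)
}

#' Union counts of up- and down-regulated genes across comparisons
#'
#' Reproduces the "in at least one comparison" summary: the number of genes
#' assigned to any up cluster (C1, C3, C5, C7) and to any down cluster
#' (C2, C4, C6, C8).
#'
#' @param degs output of \code{\link{callDEGs}}.
#' @return named numeric c(up, down).
#' @export
degUnionCounts <- function(degs) {
    sets <- clusterSets(degs)
    up <- unique(unlist(sets[c("C1", "C3", "C5", "C7")]))
    down <- unique(unlist(sets[c("C2", "C4", "C6", "C8")]))
    c(up = length(up), down = length(down))
}

#' Union of cluster gene sets by label
#'
#' @param sets named list of cluster gene sets (see
#'   \code{\link{clusterSets}}).
#' @param labels cluster labels to union; an unknown label is an error.
#' @return character vector of gene ids.
#' @export
clusterUnion <- function(sets, labels) {
    bad <- setdiff(labels, names(sets))
    if (length(bad))
        stop("unknown cluster label(s): ", paste(bad, collapse = ", "))
    unique(unlist(sets[labels], use.names = FALSE))
}

#' Venn region counts over families of gene sets
#'
#' Enumerates, for the given named sets, every non-empty combination of
#' membership and reports the number of elements exclusive to that region
#' (the counts a Venn diagram displays).
#'
#' @param sets named list of character vectors. Composite sets such as
#'   C1 U C2 are built by the caller (e.g. \code{union(s$C1, s$C2)}).
#' @return data.frame with columns region (set names joined by "&") and
#'   count; regions with zero elements are included.
#' @export
vennOverlaps <- function(sets) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("sets must be named")
    k <- length(sets)
    elements <- unique(unlist(sets))
    member <- vapply(sets, function(s) elements %in% s,
                     logical(length(elements)))
    if (length(elements) == 1) member <- matrix(member, nrow = 1)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
    region <- apply(combos, 1, function(inc)
        paste(names(sets)[unlist(inc)], collapse = "&"))
    count <- apply(combos, 1, function(inc) {
        inc <- unlist(inc)
        if (!length(elements)) return(0L)
        sum(apply(member, 1, function(m) all(m == inc)))
    })
    data.frame(region = region, count = as.integer(count),
               stringsAsFactors = FALSE)
}
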