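#' Pairwise Manhattan distances between samples
#'
#' d(s, t) = sum over the selected genes of |x_gs - x_gt|.
#'
#' @param mat genes x samples matrix.
#' @param genes gene subset (default: all rows); unknown ids are an error.
#' @return symmetric matrix of sample-sample distances.
#' @export
manhattanDistances <- function(mat, genes = rownames(mat)) {
    bad <- setdiff(genes, rownames(mat))
    if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
    if (!length(genes)) stop("gene subset is empty")
    as.matrix(stats::dist(t(mat[genes, , drop = FALSE]),
                          method = "manhattan"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres -d^2/2, eigendecomposes, and scales eigenvectors by the
#' square root of their eigenvalues. Per-axis explained variance is the
#' eigenvalue over the sum of positive eigenvalues; negative eigenvalues
#' (possible for non-Euclidean metrics such as Manhattan) are truncated to
#' zero and their total magnitude reported.
#'
#' @param d symmetric distance matrix (or dist).
#' @param k number of axes (must be < number of samples).
#' @return list of class "OrdinationResult": \code{points} (samples x k),
#'   \code{explained} (fractions per returned axis), \code{eig} (all
#'   eigenvalues) and \code{negative_magnitude}.
#' @export
classicalMDS <- function(d, k = 2) {
    dm <- as.matrix(d)
    ns <- nrow(dm)
    if (k >= ns) stop("k must be smaller than the number of samples")
    if (all(dm == 0)) {
        pts <- matrix(0, ns, k, dimnames = list(rownames(dm), NULL))
        return(structure(list(points = pts, explained = numeric(0),
                              eig = rep(0, ns), negative_magnitude = 0),
                         class = "OrdinationResult"))
    }
    fit <- stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE)
    eig <- fit$eig
    pos <- sum(eig[eig > 0])
    pts <- fit$points
    if (ncol(pts) < k)       # cmdscale drops axes with ~zero eigenvalue
        pts <- cbind(pts, matrix(0, ns, k - ncol(pts)))
    explained <- pmax(eig[seq_len(k)], 0) / pos
    structure(list(points = pts, explained = explained, eig = eig,
                   negative_magnitude = -sum(eig[eig < 0])),
              class = "OrdinationResult")
}

#' @export
print.OrdinationResult <- function(x, ...) {
    cat("OrdinationResult:", nrow(x$points), "samples,",
        ncol(x$points), "axes;",
        if (length(x$explained))
            paste0("explained: ",
                   paste(sprintf("%.1f%%", 100 * x$explained),
                         collapse = ", "))
        else "explained variance undefined (all distances zero)", "\n")
    invisible(x)
}

#' Sample ordination on Manhattan distances, with optional group centroids
#'
#' Realises "principal component analysis using Manhattan distances" as
#' principal coordinates (classical MDS) on the Manhattan distance matrix
#' over a gene subset — typically all DEGs, or the reproduction-related
#' DEGs. With \code{centroids = TRUE}, samples are first averaged within
#' each (mode, stage) group and the centroid profiles are ordinated.
#'
#' @param x a \linkS4class{PistilSE}.
#' @param genes gene subset.
#' @param k axes.
#' @param centroids ordinate group centroids instead of samples.
#' @return an "OrdinationResult" (see \code{\link{classicalMDS}}).
#' @export
ordinateSamples <- function(x, genes = rownames(x), k = 2,
                            centroids = FALSE) {
    stopifnot(methods::is(x, "PistilSE"))
    mat <- intensities(x)
    if (centroids) {
        groups <- sampleGroups(x)
        mat <- vapply(unique(groups), function(g)
            rowMeans(mat[, groups == g, drop = FALSE]),
            numeric(nrow(mat)))
    }
    classicalMDS(manhattanDistances(mat, genes), k = k)
}

#' Plain covariance PCA of samples
#'
#' Standard principal components on the samples (genes as variables),
#' provided alongside the distance-based ordination.
#'
#' @param mat genes x samples matrix.
#' @param genes gene subset.
#' @param k components.
#' @return list: points (samples x k), explained (variance fractions).
#' @export
pcaSamples <- function(mat, genes = rownames(mat), k = 2) {
    bad <- setdiff(genes, rownames(mat))
    if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
    pr <- stats::prcomp(t(mat[genes, , drop = FALSE]), center = TRUE,
                        scale. = FALSE)
    k <- min(k, ncol(pr$x))
    list(points = pr$x[, seq_len(k), drop = FALSE],
         explained = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)])
}
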