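#' Build a thresholded Pearson co-expression network
#'
#' Pearson correlation is computed across all samples for every pair of
#' the requested genes (typically the differentially expressed set); an
#' edge is kept iff r >= \code{high} or r <= \code{low} (inclusive by
#' default; \code{strict = TRUE} uses open inequalities). Genes with zero
#' variance across samples are excluded with a warning rather than
#' producing undefined correlations.
#'
#' @param mat genes x samples normalised intensity matrix.
#' @param genes gene ids to include (default: all rows).
#' @param low,high correlation thresholds (defaults -0.98, +0.98).
#' @param strict use open inequalities (r > high / r < low).
#' @return a \linkS4class{CorrelationNetwork}; its node set is the
#'   included genes (isolated nodes are kept).
#' @export
buildCorrelationNetwork <- function(mat, genes = rownames(mat),
                                    low = -0.98, high = 0.98,
                                    strict = FALSE) {
    if (ncol(mat) < 3) stop("need >= 3 samples to correlate")
    bad <- setdiff(genes, rownames(mat))
    if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
    if (!length(genes)) stop("gene list is empty")
    sub <- mat[genes, , drop = FALSE]
    v <- apply(sub, 1, stats::var)
    if (any(v == 0)) {
        warning("excluding zero-variance gene(s): ",
                paste(genes[v == 0], collapse = ", "))
        sub <- sub[v > 0, , drop = FALSE]
        genes <- rownames(sub)
    }
    edges <- data.frame(from = character(), to = character(),
                        r = numeric(), stringsAsFactors = FALSE)
    if (nrow(sub) >= 2) {
        cm <- stats::cor(t(sub))
        keep <- if (strict) (cm > high | cm < low) else
                            (cm >= high | cm <= low)
        keep[lower.tri(keep, diag = TRUE)] <- FALSE
        idx <- which(keep, arr.ind = TRUE)
        if (nrow(idx))
            edges <- data.frame(from = rownames(cm)[idx[, 1]],
                                to = colnames(cm)[idx[, 2]],
                                r = cm[idx], stringsAsFactors = FALSE)
    }
    methods::new("CorrelationNetwork", nodes = genes, edges = edges,
                 thresholds = c(low, high))
}

# parse a cluster predicate like "(C1|C2)&(C5|C6)" into an R expression
# over logical membership variables C1..C8; any other token is rejected.
.parsePredicate <- function(predicate) {
    stripped <- gsub("C[1-8]|[()&|! ]", "", predicate)
    if (nzchar(stripped))
        stop("predicate contains unresolvable token(s): ", stripped,
             " (atoms must be C1..C8)")
    str2lang(predicate)
}

#' Extract the first-neighbour sub-network of a cluster predicate
#'
#' Seed nodes are the genes whose cluster memberships satisfy the boolean
#' predicate (atoms C1..C8, operators & | ! and parentheses, e.g.
#' \code{"(C1|C2)&(C5|C6)"}). The sub-network consists of every edge of
#' the input network incident to at least one seed, together with both
#' endpoints of those edges; seeds without any incident edge are dropped.
#'
#' @param net a \linkS4class{CorrelationNetwork}.
#' @param degs DEG table from \code{\link{callDEGs}} (gene, cluster).
#' @param predicate predicate string.
#' @return a \linkS4class{CorrelationNetwork} subgraph.
#' @export
extractSubnetwork <- function(net, degs, predicate) {
    expr <- .parsePredicate(predicate)
    called <- degs[!is.na(degs$cluster), c("gene", "cluster")]
    genes <- unique(called$gene)
    env <- new.env(parent = baseenv())
    for (cl in .CLUSTERS)
        assign(cl, genes %in% called$gene[called$cluster == cl],
               envir = env)
    sat <- eval(expr, envir = env)
    seeds <- intersect(genes[sat], networkNodes(net))
    e <- networkEdges(net)
    keep <- e$from %in% seeds | e$to %in% seeds
    sub <- e[keep, , drop = FALSE]
    rownames(sub) <- NULL
    methods::new("CorrelationNetwork",
                 nodes = unique(c(sub$from, sub$to)), edges = sub,
                 thresholds = net@thresholds)
}

#' Summary statistics of a correlation network
#'
#' @param net a \linkS4class{CorrelationNetwork}.
#' @return list: n_nodes, n_edges, degree (named, sorted decreasing — the
#'   hub report) and n_components (isolated nodes count as components).
#' @export
networkStats <- function(net) {
    n <- length(networkNodes(net)); e <- networkEdges(net)
    if (!n)
        return(list(n_nodes = 0L, n_edges = 0L,
                    degree = stats::setNames(integer(), character()),
                    n_components = 0L))
    g <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = networkNodes(net))
    deg <- sort(igraph::degree(g), decreasing = TRUE)
    list(n_nodes = n, n_edges = nrow(e), degree = deg,
         n_components = igraph::components(g)$no)
}

#' Export / import a correlation network
#'
#' Formats: \code{"sif"} (lines \code{a pc b}; write-only isolated nodes
#' appear as single-field lines), \code{"edge_tsv"} (from, to, r) and
#' \code{"graphml"} with r as an edge attribute (full double precision).
#' \code{importNetwork} round-trips \code{edge_tsv} and \code{graphml}.
#'
#' @param net a \linkS4class{CorrelationNetwork}.
#' @param path output file.
#' @param format one of "sif", "edge_tsv", "graphml".
#' @export
exportNetwork <- function(net, path, format = c("sif", "edge_tsv",
                                                "graphml")) {
    format <- match.arg(format)
    e <- networkEdges(net)
    if (format == "sif") {
        lines <- if (nrow(e)) sprintf("%s\tpc\t%s", e$from, e$to)
                 else character()
        iso <- setdiff(networkNodes(net), c(e$from, e$to))
        writeLines(c(lines, iso), path)
    } else if (format == "edge_tsv") {
        out <- e
        out$r <- sprintf("%.17g", e$r)
        .writeTSV(out, path)
    } else {
        doc <- c(
            '<?xml version="1.0" encoding="UTF-8"?>',
            '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
            '<key id="r" for="edge" attr.name="r" attr.type="double"/>',
            '<graph edgedefault="undirected">',
            sprintf('<node id="%s"/>', networkNodes(net)),
            if (nrow(e)) sprintf(
                '<edge source="%s" target="%s"><data key="r">%.17g</data></edge>',
                e$from, e$to, e$r),
            '</graph>', '</graphml>')
        writeLines(doc, path)
    }
    invisible(path)
}

#' @rdname exportNetwork
#' @param thresholds thresholds to stamp on the imported network.
#' @export
importNetwork <- function(path, format = c("edge_tsv", "graphml"),
                          thresholds = c(-0.98, 0.98)) {
    format <- match.arg(format)
    if (format == "edge_tsv") {
        df <- utils::read.delim(path, stringsAsFactors = FALSE,
                                colClasses = c("character", "character",
                                               "numeric"))
        methods::new("CorrelationNetwork",
                     nodes = unique(c(df$from, df$to)), edges = df,
                     thresholds = thresholds)
    } else {
        doc <- xml2::read_xml(path)
        ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
        nodes <- xml2::xml_attr(
            xml2::xml_find_all(doc, ".//g:node", ns), "id")
        eN <- xml2::xml_find_all(doc, ".//g:edge", ns)
        edges <- data.frame(
            from = xml2::xml_attr(eN, "source"),
            to = xml2::xml_attr(eN, "target"),
            r = as.numeric(xml2::xml_text(
                xml2::xml_find_first(eN, "./g:data", ns))),
            stringsAsFactors = FALSE)
        if (!length(eN))
            edges <- data.frame(from = character(), to = character(),
                                r = numeric(), stringsAsFactors = FALSE)
        methods::new("CorrelationNetwork", nodes = nodes, edges = edges,
                     thresholds = thresholds)
    }
}
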