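#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.MODES  <- c("sexual", "apomictic")
.STAGES <- c("11", "14")
.CLUSTERS <- paste0("C", 1:8)

#' Pistil expression experiment
#'
#' A \linkS4class{SummarizedExperiment} holding a genes x samples matrix of
#' non-negative fluorescence intensities (assay \code{"intensity"}) together
#' with the per-sample design of the study: reproductive \code{mode}
#' (\code{"sexual"} or \code{"apomictic"}), floral \code{stage} (\code{"11"}
#' or \code{"14"}) and a \code{replicate} label.
#'
#' @slot .. inherited from SummarizedExperiment; no additional slots.
#' @export
setClass("PistilSE", contains = "SummarizedExperiment")

setValidity("PistilSE", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    else {
        x <- SummarizedExperiment::assay(object, "intensity")
        if (anyNA(x))
            msg <- c(msg, "intensities must not contain missing values")
        else if (any(x < 0))
            msg <- c(msg, "intensities must be non-negative")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    cd <- SummarizedExperiment::colData(object)
    need <- c("mode", "stage", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        if (!all(cd$mode %in% .MODES))
            msg <- c(msg, "mode must be 'sexual' or 'apomictic'")
        if (!all(as.character(cd$stage) %in% .STAGES))
            msg <- c(msg, "stage must be '11' or '14'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PistilSE from an intensity matrix and sample metadata
#'
#' @param intensity numeric genes x samples matrix, non-negative, with row
#'   and column names.
#' @param metadata data.frame with columns \code{sample_id}, \code{mode},
#'   \code{stage}, \code{replicate}; \code{sample_id} must match the matrix
#'   columns exactly (order is taken from the matrix).
#' @return a \linkS4class{PistilSE}.
#' @export
PistilSE <- function(intensity, metadata) {
    stopifnot(is.matrix(intensity), !is.null(rownames(intensity)),
              !is.null(colnames(intensity)))
    metadata <- as.data.frame(metadata)
    need <- c("sample_id", "mode", "stage", "replicate")
    miss <- setdiff(need, colnames(metadata))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    if (!setequal(metadata$sample_id, colnames(intensity)))
        stop("metadata sample_ids do not match the matrix columns")
    metadata <- metadata[match(colnames(intensity), metadata$sample_id), ]
    cd <- S4Vectors::DataFrame(mode = as.character(metadata$mode),
                               stage = as.character(metadata$stage),
                               replicate = as.character(metadata$replicate),
                               row.names = metadata$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensity), colData = cd)
    methods::new("PistilSE", se)
}

#' @describeIn PistilSE the intensity matrix
#' @param x a PistilSE
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn PistilSE per-sample group label \code{"<mode>:<stage>"}
#' @export
sampleGroups <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    paste0(cd$mode, ":", cd$stage)
}

setMethod("show", "PistilSE", function(object) {
    cat("PistilSE:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("groups:",
        paste(names(table(sampleGroups(object))),
              table(sampleGroups(object)), sep = "=", collapse = " "), "\n")
})

#' Thresholded Pearson co-expression network
#'
#' Undirected graph over gene identifiers whose edges carry the Pearson
#' correlation \code{r}; every edge satisfies \code{r <= low} or
#' \code{r >= high} for the thresholds used at construction.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{r};
#'   pairs are stored with \code{from < to}.
#' @slot thresholds numeric length-2 \code{c(low, high)}.
#' @export
setClass("CorrelationNetwork",
    representation(nodes = "character", edges = "data.frame",
                   thresholds = "numeric"),
    prototype(nodes = character(),
              edges = data.frame(from = character(), to = character(),
                                 r = numeric(), stringsAsFactors = FALSE),
              thresholds = c(-0.98, 0.98)))

setValidity("CorrelationNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("from", "to", "r") %in% colnames(e)))
        return("edges must have columns from, to, r")
    if (nrow(e)) {
        if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
        key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
        if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
        if (any(abs(e$r) > 1 + 1e-12)) msg <- c(msg, "r must lie in [-1, 1]")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "edge endpoints missing from node set")
    }
    if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationNetwork", function(object) {
    cat("CorrelationNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges; |r| thresholds",
        sprintf("[%g, %g]\n", object@thresholds[1], object@thresholds[2]))
})

#' @describeIn CorrelationNetwork node identifiers
#' @param net a CorrelationNetwork
#' @export
networkNodes <- function(net) net@nodes

#' @describeIn CorrelationNetwork edge table (from, to, r)
#' @export
networkEdges <- function(net) net@edges

#' Gene Ontology DAG
#'
#' Minimal typed ontology: term table plus directed child-to-parent edges of
#' relation \code{is_a} or \code{part_of}. Acyclicity is enforced at
#' construction; obsolete terms are excluded by the OBO reader.
#'
#' @slot terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation}.
#' @export
setClass("GOOntology",
    representation(terms = "data.frame", edges = "data.frame"))

setValidity("GOOntology", function(object) {
    msg <- character()
    t <- object@terms; e <- object@edges
    if (!all(c("id", "name", "namespace") %in% colnames(t)))
        return("terms must have columns id, name, namespace")
    if (!all(c("child", "parent", "relation") %in% colnames(e)))
        return("edges must have columns child, parent, relation")
    if (anyDuplicated(t$id)) msg <- c(msg, "duplicate term ids")
    if (nrow(e)) {
        bad <- !(e$child %in% t$id & e$parent %in% t$id)
        if (any(bad))
            msg <- c(msg, "edge endpoints must be declared terms")
        if (!all(e$relation %in% c("is_a", "part_of")))
            msg <- c(msg, "relations must be is_a or part_of")
        cyc <- .findCycle(e)
        if (!is.null(cyc))
            msg <- c(msg, paste0("ontology contains a cycle: ",
                                 paste(cyc, collapse = " -> ")))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "GOOntology", function(object) {
    cat("GOOntology:", nrow(object@terms), "terms,",
        nrow(object@edges), "edges\n")
})

#' @describeIn GOOntology term table
#' @param ontology a GOOntology
#' @export
ontologyTerms <- function(ontology) ontology@terms

#' @describeIn GOOntology edge table
#' @export
ontologyEdges <- function(ontology) ontology@edges

# Kahn topological sort over child->parent edges; returns NULL when acyclic,
# otherwise one explicit cycle as a vector of term ids.
.findCycle <- function(edges) {
    nodes <- unique(c(edges$child, edges$parent))
    out <- split(edges$parent, factor(edges$child, levels = nodes))
    indeg <- vapply(nodes, function(n) sum(edges$parent == n), integer(1))
    queue <- nodes[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
        n <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
        for (p in out[[n]]) {
            indeg[p] <- indeg[p] - 1L
            if (indeg[p] == 0L) queue <- c(queue, p)
        }
    }
    if (seen == length(nodes)) return(NULL)
    # walk parents from any remaining node until a repeat closes the cycle
    rest <- nodes[indeg > 0L]
    cur <- rest[1]; path <- cur
    repeat {
        nxt <- edges$parent[edges$child == cur & edges$parent %in% rest][1]
        if (is.na(nxt)) { cur <- rest[match(cur, rest) %% length(rest) + 1]
                          path <- cur; next }
        if (nxt %in% path) {
            i <- match(nxt, path)
            return(c(path[i:length(path)], nxt))
        }
        path <- c(path, nxt); cur <- nxt
    }
}
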