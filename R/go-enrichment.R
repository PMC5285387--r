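#' Read a minimal OBO v1.2 ontology
#'
#' Parses \code{[Term]} stanzas for id, name, namespace, \code{is_a}
#' parents and \code{relationship: part_of} parents. Obsolete terms (and
#' edges touching them) are skipped. The resulting graph must be acyclic;
#' a cycle is an error that names one offending cycle.
#'
#' @param path OBO file.
#' @return a \linkS4class{GOOntology}.
#' @export
readOBO <- function(path) {
    lines <- readLines(path)
    starts <- grep("^\\[", lines)
    termIdx <- which(lines[starts] == "[Term]")
    terms <- list(); edges <- list()
    for (k in seq_along(termIdx)) {
        i <- starts[termIdx[k]]
        j <- if (termIdx[k] < length(starts)) starts[termIdx[k] + 1] - 1
             else length(lines)
        block <- lines[(i + 1):j]
        getv <- function(key) sub(paste0("^", key, ": *"), "",
                                  grep(paste0("^", key, ":"), block,
                                       value = TRUE))
        if (any(grepl("^is_obsolete: *true", block))) next
        id <- getv("id")[1]
        if (is.na(id)) next
        terms[[length(terms) + 1L]] <- data.frame(
            id = id, name = getv("name")[1],
            namespace = if (length(getv("namespace"))) getv("namespace")[1]
                        else NA_character_,
            stringsAsFactors = FALSE)
        isa <- sub(" *!.*$", "", getv("is_a"))
        for (p in isa)
            edges[[length(edges) + 1L]] <- data.frame(
                child = id, parent = trimws(p), relation = "is_a",
                stringsAsFactors = FALSE)
        rel <- grep("^relationship: *part_of ", block, value = TRUE)
        for (r in rel) {
            p <- trimws(sub(" *!.*$", "",
                            sub("^relationship: *part_of ", "", r)))
            edges[[length(edges) + 1L]] <- data.frame(
                child = id, parent = p, relation = "part_of",
                stringsAsFactors = FALSE)
        }
    }
    terms <- if (length(terms)) do.call(rbind, terms)
             else data.frame(id = character(), name = character(),
                             namespace = character())
    edges <- if (length(edges)) do.call(rbind, edges)
             else data.frame(child = character(), parent = character(),
                             relation = character())
    # drop edges to undeclared or obsolete endpoints
    edges <- edges[edges$child %in% terms$id & edges$parent %in% terms$id, ,
                   drop = FALSE]
    methods::new("GOOntology", terms = terms, edges = edges)
}

#' Write a GOOntology as OBO v1.2 text
#'
#' @param ontology a \linkS4class{GOOntology}.
#' @param path output path.
#' @export
writeOBO <- function(ontology, path) {
    t <- ontologyTerms(ontology); e <- ontologyEdges(ontology)
    out <- c("format-version: 1.2", "")
    for (i in seq_len(nrow(t))) {
        out <- c(out, "[Term]", paste0("id: ", t$id[i]),
                 paste0("name: ", t$name[i]))
        if (!is.na(t$namespace[i]))
            out <- c(out, paste0("namespace: ", t$namespace[i]))
        ei <- e[e$child == t$id[i], , drop = FALSE]
        for (j in seq_len(nrow(ei)))
            out <- c(out, if (ei$relation[j] == "is_a")
                paste0("is_a: ", ei$parent[j])
                else paste0("relationship: part_of ", ei$parent[j]))
        out <- c(out, "")
    }
    writeLines(out, path)
    invisible(path)
}

# all ancestors (inclusive of the term itself) via is_a/part_of parents
.ancestorsOf <- function(ontology, term) {
    e <- ontologyEdges(ontology)
    seen <- character(); frontier <- term
    while (length(frontier)) {
        seen <- union(seen, frontier)
        frontier <- setdiff(e$parent[e$child %in% frontier], seen)
    }
    seen
}

#' Close annotations under the true-path rule
#'
#' Every gene directly annotated to a term is also annotated to all of the
#' term's ancestors via is_a and part_of, each ancestor counted once.
#'
#' @param annotations data.frame with columns gene, term (direct
#'   annotations).
#' @param ontology a \linkS4class{GOOntology}.
#' @return data.frame gene, term, closed under ancestry, unique rows.
#' @export
propagateAnnotations <- function(annotations, ontology) {
    unknown <- setdiff(annotations$term, ontologyTerms(ontology)$id)
    if (length(unknown))
        stop("annotation to unknown term(s): ",
             paste(unknown, collapse = ", "))
    anc <- lapply(stats::setNames(nm = unique(annotations$term)),
                  .ancestorsOf, ontology = ontology)
    out <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i)
        data.frame(gene = annotations$gene[i],
                   term = anc[[annotations$term[i]]],
                   stringsAsFactors = FALSE)))
    unique(out)
}

#' Hypergeometric GO over-representation with BH correction
#'
#' For every term with at least one study hit after true-path
#' propagation, the upper-tail hypergeometric probability
#' P(X >= k | N, K, n) is computed, where N is the universe size
#' (all population genes carrying at least one propagated annotation,
#' unless \code{universe} is supplied), K the term's population hits, n
#' the study size and k the term's study hits. Benjamini-Hochberg
#' q-values are computed over the tested terms; results are sorted by p.
#'
#' @param study,population character vectors of gene ids; study must be a
#'   subset of population.
#' @param annotations direct annotations (gene, term).
#' @param ontology a \linkS4class{GOOntology}.
#' @param universe optional explicit universe; defaults to the annotated
#'   population.
#' @param propagate apply \code{\link{propagateAnnotations}} first
#'   (default TRUE).
#' @return data.frame: term, name, study_hits, study_size,
#'   population_hits, population_size, p_value, q_value; sorted by
#'   p_value.
#' @export
hypergeometricEnrichment <- function(study, population, annotations,
                                     ontology, universe = NULL,
                                     propagate = TRUE) {
    if (!length(population)) stop("population is empty")
    extra <- setdiff(study, population)
    if (length(extra))
        stop("study genes outside the population: ",
             paste(utils::head(extra, 5), collapse = ", "))
    ann <- if (propagate) propagateAnnotations(annotations, ontology)
           else annotations
    ann <- ann[ann$gene %in% population, , drop = FALSE]
    if (is.null(universe)) universe <- unique(ann$gene)
    ann <- ann[ann$gene %in% universe, , drop = FALSE]
    studyU <- intersect(study, universe)
    N <- length(universe); n <- length(studyU)
    byTerm <- split(ann$gene, ann$term)
    k <- vapply(byTerm, function(g) length(intersect(g, studyU)),
                integer(1))
    K <- lengths(byTerm)
    tested <- names(byTerm)[k >= 1L]
    if (!length(tested))
        return(data.frame(term = character(), name = character(),
                          study_hits = integer(), study_size = integer(),
                          population_hits = integer(),
                          population_size = integer(),
                          p_value = numeric(), q_value = numeric()))
    p <- vapply(tested, function(tm)
        stats::phyper(k[tm] - 1L, K[tm], N - K[tm], n,
                      lower.tail = FALSE), numeric(1))
    nm <- ontologyTerms(ontology)
    res <- data.frame(term = tested,
                      name = nm$name[match(tested, nm$id)],
                      study_hits = as.integer(k[tested]), study_size = n,
                      population_hits = as.integer(K[tested]),
                      population_size = N,
                      p_value = p,
                      q_value = stats::p.adjust(p, "BH"),
                      stringsAsFactors = FALSE)
    res <- res[order(res$p_value, res$term), ]
    rownames(res) <- NULL
    res
}
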