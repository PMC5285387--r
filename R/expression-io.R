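#' Read a genes x samples intensity matrix
#'
#' Two dialects are supported: \code{"plain_tsv"} (header row of sample
#' ids, first column gene ids) and \code{"series_matrix"}, the GEO series
#' matrix layout in which metadata lines begin with \code{"!"} and the
#' expression table is bracketed by the
#' \code{!series_matrix_table_begin} / \code{!series_matrix_table_end}
#' sentinels. Validation enforces the matrix invariants: unique ids, no
#' ragged rows, numeric non-negative values, no missing values.
#'
#' @param path file path.
#' @param dialect \code{"plain_tsv"} or \code{"series_matrix"}.
#' @param log2Input if TRUE, values are taken as log2 intensities and
#'   exponentiated on import (whether a deposited matrix is linear or log
#'   scale must be decided by the caller).
#' @return numeric matrix with gene row names and sample column names.
#' @export
readExpressionMatrix <- function(path,
                                 dialect = c("plain_tsv", "series_matrix"),
                                 log2Input = FALSE) {
    dialect <- match.arg(dialect)
    lines <- readLines(path)
    if (dialect == "series_matrix") {
        beg <- grep("^!series_matrix_table_begin", lines)
        end <- grep("^!series_matrix_table_end", lines)
        if (length(beg) == 1 && length(end) == 1 && end > beg + 1)
            lines <- lines[(beg + 1):(end - 1)]
        else
            lines <- lines[!startsWith(lines, "!")]
        lines <- gsub("\"", "", lines)
    }
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2) stop("no data rows in ", path)
    cells <- strsplit(lines, "\t", fixed = TRUE)
    header <- cells[[1]]
    sampleIds <- header[-1]
    ncol_ <- length(header)
    body <- cells[-1]
    widths <- lengths(body)
    if (any(widths != ncol_))
        stop("ragged row ", which(widths != ncol_)[1] + 1L, ": expected ",
             ncol_, " fields, found ", widths[widths != ncol_][1])
    geneIds <- vapply(body, `[`, character(1), 1L)
    if (anyDuplicated(geneIds))
        stop("duplicate gene id: ", geneIds[duplicated(geneIds)][1])
    if (anyDuplicated(sampleIds))
        stop("duplicate sample id: ", sampleIds[duplicated(sampleIds)][1])
    vals <- suppressWarnings(
        matrix(as.numeric(unlist(lapply(body, `[`, -1L))),
               nrow = length(body), byrow = TRUE,
               dimnames = list(geneIds, sampleIds)))
    if (anyNA(vals)) {
        idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
        stop("non-numeric or missing value at gene '", geneIds[idx[1]],
             "', sample '", sampleIds[idx[2]], "'")
    }
    if (log2Input) vals <- 2^vals
    if (any(vals < 0)) {
        idx <- which(vals < 0, arr.ind = TRUE)[1, ]
        stop("negative intensity at gene '", geneIds[idx[1]],
             "', sample '", sampleIds[idx[2]], "'")
    }
    vals
}

#' Write an intensity matrix as plain TSV (genes in rows)
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn header for the gene-id column.
#' @export
writeExpressionMatrix <- function(mat, path, idColumn = "gene_id") {
    out <- cbind(stats::setNames(data.frame(rownames(mat),
                                            stringsAsFactors = FALSE),
                                 idColumn),
                 as.data.frame(mat, check.names = FALSE))
    .writeTSV(out, path)
}

#' Read per-sample metadata (sample_id, mode, stage, replicate)
#'
#' @param path TSV path.
#' @return data.frame with character columns.
#' @export
readSampleMetadata <- function(path) {
    md <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("sample_id", "mode", "stage", "replicate")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(md$mode, .MODES)
    if (length(bad)) stop("unknown mode label(s): ",
                          paste(bad, collapse = ", "))
    md
}

#' Collapse probe-level rows to gene-level rows
#'
#' The array carries more than one probe per unigene; probe rows mapping to
#' the same gene are summarised per sample by their median (robust to a
#' single misbehaving probe). Probes absent from the mapping are dropped;
#' genes whose probe set is empty are omitted with a warning.
#'
#' @param mat probes x samples numeric matrix.
#' @param probeToGene named character vector, probe id -> gene id. Every
#'   named probe must exist in the matrix.
#' @return genes x samples matrix, one row per gene, in first-appearance
#'   order of the genes.
#' @export
collapseProbes <- function(mat, probeToGene) {
    missing <- setdiff(names(probeToGene), rownames(mat))
    if (length(missing))
        stop("probe(s) not in matrix: ", paste(missing, collapse = ", "))
    genes <- unique(unname(probeToGene))
    rows <- lapply(genes, function(g) {
        probes <- names(probeToGene)[probeToGene == g]
        if (!length(probes)) return(NULL)
        apply(mat[probes, , drop = FALSE], 2, stats::median)
    })
    empty <- vapply(rows, is.null, logical(1))
    if (any(empty)) {
        warning("omitting gene(s) with empty probe set: ",
                paste(genes[empty], collapse = ", "))
        rows <- rows[!empty]; genes <- genes[!empty]
    }
    out <- do.call(rbind, rows)
    dimnames(out) <- list(genes, colnames(mat))
    out
}

#' Read / write an annotation table
#'
#' Columns: \code{gene_id}, \code{top_hit_locus}, \code{description},
#' \code{go_terms}, \code{categories}; the multi-valued fields are
#' ";"-separated in the file and list-columns in memory.
#'
#' @param path TSV path.
#' @return data.frame with list-columns \code{go_terms}, \code{categories}.
#' @export
readAnnotationTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("gene_id", "top_hit_locus", "description", "go_terms",
              "categories")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("annotation table lacks column(s): ",
             paste(miss, collapse = ", "))
    splitField <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                     function(v) v[nzchar(v)])
    df$go_terms <- splitField(df$go_terms)
    df$categories <- splitField(df$categories)
    badGO <- unlist(df$go_terms)
    badGO <- badGO[!grepl("^GO:[0-9]{7}$", badGO)]
    if (length(badGO))
        stop("malformed GO term id(s): ", paste(unique(badGO),
                                                collapse = ", "))
    df
}

#' @rdname readAnnotationTable
#' @param annotations data.frame as returned by \code{readAnnotationTable}.
#' @export
writeAnnotationTable <- function(annotations, path) {
    out <- annotations
    out$go_terms <- vapply(annotations$go_terms, paste, character(1),
                           collapse = ";")
    out$categories <- vapply(annotations$categories, paste, character(1),
                             collapse = ";")
    .writeTSV(out, path)
}

#' Assign functional categories by keyword matching
#'
#' A category is added to a gene when any of its keywords occurs
#' (case-insensitive substring) in the gene's description or in the name of
#' any GO term it is annotated to. This emulates keyword querying of a GO
#' repository (e.g. "egg cell", "response to auxin") against a supplied
#' annotation table.
#'
#' @param annotations annotation data.frame (see
#'   \code{\link{readAnnotationTable}}).
#' @param keywordSets named list: category -> character vector of keywords.
#' @param termNames optional named character vector, GO id -> term name,
#'   used to match keywords against GO term names.
#' @return the annotation table with updated \code{categories}.
#' @export
keywordAnnotate <- function(annotations, keywordSets, termNames = NULL) {
    for (i in seq_len(nrow(annotations))) {
        hay <- tolower(annotations$description[i])
        ids <- annotations$go_terms[[i]]
        if (!is.null(termNames) && length(ids))
            hay <- c(hay, tolower(unname(termNames[intersect(
                ids, names(termNames))])))
        for (cat in names(keywordSets)) {
            kws <- tolower(keywordSets[[cat]])
            hit <- any(vapply(kws, function(k)
                any(grepl(k, hay, fixed = TRUE)), logical(1)))
            if (hit && !(cat %in% annotations$categories[[i]]))
                annotations$categories[[i]] <-
                    c(annotations$categories[[i]], cat)
        }
    }
    annotations
}
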