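#' Read a BLAT PSL alignment file
#'
#' Standard 21-column PSL (no header, or with the 5-line psLayout header),
#' 0-based half-open coordinates. Query (unigene) start/end are forward
#' coordinates for both strands, as PSL mandates; target (contig)
#' coordinates are always forward. The fraction identity is derived as
#' (matches + repMatches) / (qEnd - qStart) since PSL carries no identity
#' column.
#'
#' @param path PSL file.
#' @return data.frame with columns unigene_id, unigene_length, u_start,
#'   u_end, contig_id, contig_length, g_start, g_end, strand, matches,
#'   fident.
#' @export
readPSL <- function(path) {
    lines <- readLines(path)
    # drop the optional psLayout header (ends with a dashed line)
    dash <- grep("^-{10,}", lines)
    if (length(dash)) lines <- lines[-seq_len(dash[1])]
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(unigene_id = character(), unigene_length =
                          integer(), u_start = integer(), u_end = integer(),
                          contig_id = character(), contig_length = integer(),
                          g_start = integer(), g_end = integer(),
                          strand = character(), matches = integer(),
                          fident = numeric(), stringsAsFactors = FALSE))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 21)
    if (length(bad))
        stop("malformed PSL row ", bad[1], ": fewer than 21 columns")
    f <- function(i) vapply(fields, `[`, character(1), i)
    n <- function(i) as.integer(f(i))
    matches <- n(1); repMatches <- n(3)
    qStart <- n(12); qEnd <- n(13)
    rec <- data.frame(
        unigene_id = f(10), unigene_length = n(11),
        u_start = qStart, u_end = qEnd,
        contig_id = f(14), contig_length = n(15),
        g_start = n(16), g_end = n(17),
        strand = substr(f(9), 1, 1),
        matches = matches,
        fident = (matches + repMatches) / (qEnd - qStart),
        stringsAsFactors = FALSE)
    .validateAlignments(rec)
    rec
}

.validateAlignments <- function(rec) {
    with(rec, {
        if (any(u_start < 0 | u_start >= u_end | u_end > unigene_length))
            stop("invalid unigene interval in alignment record(s): ",
                 paste(unigene_id[u_start < 0 | u_start >= u_end |
                                  u_end > unigene_length], collapse = ", "))
        if (any(g_start < 0 | g_start >= g_end | g_end > contig_length))
            stop("invalid contig interval in alignment record(s): ",
                 paste(unigene_id[g_start < 0 | g_start >= g_end |
                                  g_end > contig_length], collapse = ", "))
        if (any(matches > u_end - u_start))
            stop("matches exceed aligned length for: ",
                 paste(unigene_id[matches > u_end - u_start],
                       collapse = ", "))
        if (!all(strand %in% c("+", "-")))
            stop("strand must be '+' or '-'")
    })
    invisible(rec)
}

#' Write alignment records as 21-column PSL
#'
#' Inverse of \code{\link{readPSL}} for the columns this pipeline uses;
#' unused PSL columns (inserts, block structure) are emitted as a single
#' full-length block with zero inserts. Mismatches are back-computed from
#' the stored fraction identity.
#'
#' @param rec alignment data.frame (layout of \code{\link{readPSL}}).
#' @param path output path.
#' @export
writePSL <- function(rec, path) {
    alnLen <- rec$u_end - rec$u_start
    mism <- pmax(0L, alnLen - rec$matches)
    qStarts <- ifelse(rec$strand == "+", rec$u_start,
                      rec$unigene_length - rec$u_end)
    lines <- sprintf(
        "%d\t%d\t0\t0\t0\t0\t0\t0\t%s\t%s\t%d\t%d\t%d\t%s\t%d\t%d\t%d\t1\t%d,\t%d,\t%d,",
        rec$matches, mism, rec$strand, rec$unigene_id, rec$unigene_length,
        rec$u_start, rec$u_end, rec$contig_id, rec$contig_length,
        rec$g_start, rec$g_end, alnLen, qStarts, rec$g_start)
    writeLines(lines, path)
    invisible(path)
}

#' Strand-aware unaligned end segments of an alignment
#'
#' Returns, per record, the unaligned bases at the unigene's 5' and 3'
#' ends (u5, u3) and the unaligned contig bases on the side corresponding
#' to each unigene end (g5, g3). On the minus strand the unigene's 5' end
#' faces the high-coordinate side of the contig, so the contig overhangs
#' swap.
#'
#' @param rec alignment data.frame.
#' @return data.frame u5, u3, g5, g3 (one row per record).
#' @export
endOverhangs <- function(rec) {
    u5 <- rec$u_start
    u3 <- rec$unigene_length - rec$u_end
    left <- rec$g_start
    right <- rec$contig_length - rec$g_end
    minus <- rec$strand == "-"
    data.frame(u5 = u5, u3 = u3,
               g5 = ifelse(minus, right, left),
               g3 = ifelse(minus, left, right))
}

#' Match-count and identity gates for a BLAT hit
#'
#' @param rec alignment data.frame.
#' @param minMatch minimum matched bases (inclusive, default 50).
#' @param minFident minimum fraction identity (inclusive, default 0.97).
#' @return logical vector.
#' @export
passesBlatThresholds <- function(rec, minMatch = 50, minFident = 0.97) {
    rec$matches >= minMatch & rec$fident >= minFident
}

#' High-quality top-hit predicate on end overhangs
#'
#' A hit is retained only when neither end carries a long unaligned
#' segment shared by unigene and contig. Per end E in {5', 3'} the end
#' passes iff the unigene overhang uE is at most \code{adapterAllowance}
#' bases (room for an untrimmed adapter), or the contig overhang gE is
#' smaller than uE, or gE is under \code{contigEndEscape} bases (the
#' alignment reaches the contig's edge). With
#' \code{threeBpEscape = "3prime-only"} the contig-end escape applies only
#' at the 3' end, the stricter literal reading.
#'
#' @param rec alignment data.frame; must already satisfy
#'   \code{\link{passesBlatThresholds}} to be meaningful.
#' @param adapterAllowance unigene-overhang allowance in bases (default 10,
#'   inclusive).
#' @param contigEndEscape contig-overhang escape in bases (default 3,
#'   strict: gE < 3 passes).
#' @param threeBpEscape apply the contig-end escape at "both" ends
#'   (default) or at the "3prime-only" end.
#' @param contigShorterLenient whether a contig overhang smaller than the
#'   unigene overhang passes on its own (default TRUE). The written rule
#'   only constrains the case gE >= uE, leaving gE < uE with uE > 10
#'   ambiguous; both behaviours are selectable. Note that with the default
#'   lenient reading the contig-end escape is logically subsumed
#'   (gE < 3 <= uE implies gE < uE whenever uE > 10), so the escape flag
#'   only bites under the strict reading.
#' @return logical vector: retained flag per record.
#' @export
isHighQualityHit <- function(rec, adapterAllowance = 10,
                             contigEndEscape = 3,
                             threeBpEscape = c("both", "3prime-only"),
                             contigShorterLenient = TRUE) {
    threeBpEscape <- match.arg(threeBpEscape)
    ov <- endOverhangs(rec)
    endPass <- function(u, g, escape)
        u <= adapterAllowance | (contigShorterLenient & g < u) |
            (escape & g < contigEndEscape)
    endPass(ov$u5, ov$g5, threeBpEscape == "both") &
        endPass(ov$u3, ov$g3, TRUE)
}

#' Select the top genomic hit per unigene
#'
#' Among the hits of one unigene that pass both the BLAT thresholds and
#' the end-overhang quality filter, the hit with the most matched bases
#' wins; ties break by higher fraction identity, then by lexicographically
#' smallest contig id. Returns NULL when no hit survives.
#'
#' @param hits alignment data.frame, all rows sharing one unigene_id.
#' @param ... passed to \code{\link{isHighQualityHit}}.
#' @return single-row data.frame or NULL.
#' @export
selectTopHit <- function(hits, ...) {
    if (length(unique(hits$unigene_id)) > 1)
        stop("hits must all belong to one unigene")
    keep <- hits[passesBlatThresholds(hits) & isHighQualityHit(hits, ...), ,
                 drop = FALSE]
    if (!nrow(keep)) return(NULL)
    ord <- order(-keep$matches, -keep$fident, keep$contig_id)
    keep[ord[1], , drop = FALSE]
}

#' Extract genomic flanks around an aligned segment
#'
#' For each side of the aligned interval the available contig bases beyond
#' the interval are taken up to \code{maxFlank}; a flank is emitted only
#' when at least \code{minFlank} bases are available. Sequences are
#' returned in the unigene's 5'->3' orientation (reverse-complemented for
#' minus-strand hits) and tagged with their forward contig coordinates
#' (0-based half-open).
#'
#' @param rec single-row alignment data.frame.
#' @param contigSeq the contig sequence (character or DNAString); its
#'   length must equal the record's contig_length.
#' @param minFlank,maxFlank flank length policy in bases (defaults 100 and
#'   1001).
#' @return list with elements \code{upstream} and \code{downstream}, each
#'   either NULL or a list(seq, contig_id, start, end).
#' @export
extractFlanks <- function(rec, contigSeq, minFlank = 100, maxFlank = 1001) {
    if (minFlank <= 0 || minFlank > maxFlank)
        stop("need 0 < minFlank <= maxFlank")
    seq <- Biostrings::DNAString(as.character(contigSeq))
    if (length(seq) != rec$contig_length)
        stop("contig sequence length (", length(seq),
             ") does not match contig_length (", rec$contig_length, ")")
    takeLeft <- function() {            # low-coordinate side of the contig
        avail <- rec$g_start
        if (avail < minFlank) return(NULL)
        len <- min(avail, maxFlank)
        list(start = rec$g_start - len, end = rec$g_start)
    }
    takeRight <- function() {           # high-coordinate side
        avail <- rec$contig_length - rec$g_end
        if (avail < minFlank) return(NULL)
        len <- min(avail, maxFlank)
        list(start = rec$g_end, end = rec$g_end + len)
    }
    # unigene-upstream is the contig's left side on +, right side on -
    up <- if (rec$strand == "+") takeLeft() else takeRight()
    dn <- if (rec$strand == "+") takeRight() else takeLeft()
    grab <- function(iv) {
        if (is.null(iv)) return(NULL)
        s <- Biostrings::subseq(seq, iv$start + 1, iv$end)
        if (rec$strand == "-") s <- Biostrings::reverseComplement(s)
        list(seq = as.character(s), contig_id = rec$contig_id,
             start = iv$start, end = iv$end)
    }
    list(upstream = grab(up), downstream = grab(dn))
}

#' Write extracted flanks as FASTA
#'
#' Records are named \code{<unigene>|<contig>:<start>-<end>|<side>}.
#'
#' @param flanks named list: unigene id -> result of
#'   \code{\link{extractFlanks}}.
#' @param path output FASTA path.
#' @export
writeFlanksFasta <- function(flanks, path) {
    seqs <- character(); nms <- character()
    for (ug in names(flanks))
        for (side in c("upstream", "downstream")) {
            fl <- flanks[[ug]][[side]]
            if (is.null(fl)) next
            seqs <- c(seqs, fl$seq)
            nms <- c(nms, sprintf("%s|%s:%d-%d|%s", ug, fl$contig_id,
                                  fl$start, fl$end, side))
        }
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(seqs, nms)), path)
    invisible(path)
}

#' Read a tabular protein-search hit table
#'
#' TSV with columns query, subject, similarity (percent), evalue; used for
#' the precomputed direct and flank-based protein hits consumed by
#' \code{\link{transferAnnotation}}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readBlastHits <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("query", "subject", "similarity", "evalue")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
    df$evalue <- suppressWarnings(as.numeric(df$evalue))
    df$similarity <- suppressWarnings(as.numeric(df$similarity))
    bad <- which(is.na(df$evalue) | is.na(df$similarity))
    if (length(bad))
        stop("malformed hit row ", bad[1] + 1L,
             ": non-numeric evalue or similarity")
    df
}

#' Transfer a functional annotation from direct or flank-based hits
#'
#' The direct protein hit is used when its E-value is at most
#' \code{directEvalue} and its similarity at least \code{minSimilarity};
#' otherwise the best flank-based hit with E-value at most
#' \code{flankEvalue} is used; otherwise the unigene stays unannotated.
#' "Best" is smallest E-value, ties broken by higher similarity.
#'
#' @param unigeneId the unigene to annotate.
#' @param directHits,flankHits hit data.frames (see
#'   \code{\link{readBlastHits}}); flank queries may be flank ids prefixed
#'   with the unigene id (\code{"<unigene>|..."}).
#' @param directEvalue,flankEvalue E-value cutoffs (defaults 1e-9, 1e-10).
#' @param minSimilarity similarity cutoff in percent for direct hits
#'   (default 70).
#' @return one-row data.frame: gene_id, top_hit_locus, source
#'   ("direct", "flank" or "none").
#' @export
transferAnnotation <- function(unigeneId, directHits, flankHits,
                               directEvalue = 1e-9, flankEvalue = 1e-10,
                               minSimilarity = 70) {
    pick <- function(h) h[order(h$evalue, -h$similarity)[1], , drop = FALSE]
    d <- directHits[directHits$query == unigeneId &
                    directHits$evalue <= directEvalue &
                    directHits$similarity >= minSimilarity, , drop = FALSE]
    if (nrow(d)) {
        best <- pick(d)
        return(data.frame(gene_id = unigeneId,
                          top_hit_locus = best$subject, source = "direct",
                          stringsAsFactors = FALSE))
    }
    fq <- flankHits$query == unigeneId |
        startsWith(flankHits$query, paste0(unigeneId, "|"))
    f <- flankHits[fq & flankHits$evalue <= flankEvalue, , drop = FALSE]
    if (nrow(f)) {
        best <- pick(f)
        return(data.frame(gene_id = unigeneId,
                          top_hit_locus = best$subject, source = "flank",
                          stringsAsFactors = FALSE))
    }
    data.frame(gene_id = unigeneId, top_hit_locus = "", source = "none",
               stringsAsFactors = FALSE)
}
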