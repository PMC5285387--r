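.configDefaults <- list(
    dialect = "plain_tsv", log2_input = FALSE,
    p_threshold = 0.01, fc_threshold = 2,
    cor_low = -0.98, cor_high = 0.98,
    predicates = "(C1|C2)&(C5|C6)",
    ordination_genes = "degs", seed = 17L)

#' Validate a pipeline configuration
#'
#' Reads a YAML key-value file (or takes an equivalent named list), fills
#' the documented defaults (p = 0.01, fc = 2, correlation thresholds
#' +/-0.98) and checks every constraint, reporting all violations at once
#' rather than the first.
#'
#' @param config path to a YAML file, or a named list.
#' @return list of class "PipelineConfig".
#' @export
validateConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) stop("config must be a file path or a list")
    cfg <- utils::modifyList(.configDefaults, config)
    v <- character()
    for (key in c("matrix", "metadata")) {
        if (is.null(cfg[[key]]))
            v <- c(v, paste0("missing required key: ", key))
        else if (!file.exists(cfg[[key]]))
            v <- c(v, paste0(key, ": file not found: ", cfg[[key]]))
    }
    if (!cfg$dialect %in% c("plain_tsv", "series_matrix"))
        v <- c(v, "dialect must be plain_tsv or series_matrix")
    if (!is.numeric(cfg$p_threshold) || cfg$p_threshold <= 0 ||
        cfg$p_threshold >= 1)
        v <- c(v, "p_threshold must lie in (0, 1)")
    if (!is.numeric(cfg$fc_threshold) || cfg$fc_threshold < 1)
        v <- c(v, "fc_threshold must be >= 1")
    if (!is.numeric(cfg$cor_high) || cfg$cor_high < -1 || cfg$cor_high > 1 ||
        !is.numeric(cfg$cor_low) || cfg$cor_low < -1 || cfg$cor_low > 1 ||
        cfg$cor_low > cfg$cor_high)
        v <- c(v, "correlation thresholds must satisfy -1 <= low <= high <= 1")
    for (p in cfg$predicates)
        if (inherits(try(.parsePredicate(p), silent = TRUE), "try-error"))
            v <- c(v, paste0("unparsable predicate: ", p))
    for (key in c("obo", "annotations"))
        if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
            v <- c(v, paste0(key, ": file not found: ", cfg[[key]]))
    if (length(v))
        stop("invalid configuration:\n  ", paste(v, collapse = "\n  "))
    structure(cfg, class = "PipelineConfig")
}

.configHash <- function(cfg) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(deparse(cfg[order(names(unclass(cfg)))]), tmp)
    unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: import and validation, 75th-percentile
#' normalisation, DEG calling with C1..C8 cluster assignment, Venn
#' overlaps of the four comparisons' DEG sets, thresholded Pearson
#' co-expression network over all DEGs with one sub-network per
#' configured predicate, optional GO enrichment of the DEG set, and
#' sample ordination. Every output is written under \code{outDir} and
#' stamped with a hash of the configuration; a rerun with identical
#' configuration and inputs is byte-identical.
#'
#' @param config a "PipelineConfig" (see \code{\link{validateConfig}}), or
#'   a path / list accepted by it.
#' @param outDir output directory (created if needed).
#' @return list of class "RunReport": cluster_counts, union_counts,
#'   network (stats), subnetworks (per predicate), enrichment (data.frame
#'   or NULL), config_hash, files.
#' @export
runPipeline <- function(config, outDir) {
    cfg <- if (inherits(config, "PipelineConfig")) config
           else validateConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, code)
        tryCatch(code, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))

    se <- stage("import", {
        mat <- readExpressionMatrix(cfg$matrix, cfg$dialect,
                                    log2Input = cfg$log2_input)
        md <- readSampleMetadata(cfg$metadata)
        PistilSE(mat, md)
    })
    norm <- stage("normalize", percentileNormalize(intensities(se)))
    seN <- PistilSE(norm, data.frame(
        sample_id = colnames(se),
        mode = SummarizedExperiment::colData(se)$mode,
        stage = SummarizedExperiment::colData(se)$stage,
        replicate = SummarizedExperiment::colData(se)$replicate))

    degs <- stage("deg", callDEGs(seN, pThreshold = cfg$p_threshold,
                                  fcThreshold = cfg$fc_threshold))
    files <- c(degs = file.path(outDir, "degs.tsv"))
    .writeTSV(degs, files["degs"])
    sets <- clusterSets(degs)
    clusterCounts <- vapply(sets, length, integer(1))
    unionCounts <- degUnionCounts(degs)

    venn <- stage("venn", vennOverlaps(list(
        Sex11_vs_Sex14 = clusterUnion(sets, c("C1", "C2")),
        Apo11_vs_Apo14 = clusterUnion(sets, c("C3", "C4")),
        Sex11_vs_Apo11 = clusterUnion(sets, c("C5", "C6")),
        Sex14_vs_Apo14 = clusterUnion(sets, c("C7", "C8")))))
    files["venn"] <- file.path(outDir, "venn.tsv")
    .writeTSV(venn, files["venn"])

    degGenes <- unique(unlist(sets, use.names = FALSE))
    net <- stage("network", {
        if (length(degGenes) >= 2)
            suppressWarnings(buildCorrelationNetwork(
                norm, degGenes, low = cfg$cor_low, high = cfg$cor_high))
        else methods::new("CorrelationNetwork",
                          thresholds = c(cfg$cor_low, cfg$cor_high))
    })
    files["network"] <- file.path(outDir, "network.sif")
    exportNetwork(net, files["network"], "sif")
    subStats <- list()
    for (i in seq_along(cfg$predicates)) {
        pred <- cfg$predicates[[i]]
        sub <- stage("subnetwork", extractSubnetwork(net, degs, pred))
        f <- file.path(outDir, sprintf("subnetwork_%d.sif", i))
        files[paste0("subnetwork_", i)] <- f
        exportNetwork(sub, f, "sif")
        subStats[[pred]] <- networkStats(sub)[c("n_nodes", "n_edges",
                                                "n_components")]
    }

    enrich <- NULL
    if (!is.null(cfg$obo) && !is.null(cfg$annotations)) {
        enrich <- stage("enrichment", {
            ont <- readOBO(cfg$obo)
            ann <- utils::read.delim(cfg$annotations,
                                     stringsAsFactors = FALSE)
            hypergeometricEnrichment(
                intersect(degGenes, rownames(norm)), rownames(norm),
                ann, ont)
        })
        files["enrichment"] <- file.path(outDir, "enrichment.tsv")
        .writeTSV(enrich, files["enrichment"])
    }

    ordGenes <- if (identical(cfg$ordination_genes, "degs") &&
                    length(degGenes) >= 1) degGenes else rownames(norm)
    ord <- stage("ordination", ordinateSamples(seN, ordGenes))
    files["ordination"] <- file.path(outDir, "ordination.tsv")
    .writeTSV(data.frame(sample_id = rownames(ord$points),
                         axis1 = ord$points[, 1], axis2 = ord$points[, 2]),
              files["ordination"])
    files["scree"] <- file.path(outDir, "scree.tsv")
    .writeTSV(data.frame(axis = seq_along(ord$eig), eigenvalue = ord$eig,
                         explained = pmax(ord$eig, 0) /
                             sum(pmax(ord$eig, 0))),
              files["scree"])

    hash <- .configHash(cfg)
    netStats <- networkStats(net)
    report <- c(
        paste0("apoPistil pipeline report (package version ",
               as.character(utils::packageVersion("apoPistil")), ")"),
        paste0("config_hash: ", hash), "",
        "DEG counts per cluster:",
        sprintf("  %s: %d", names(clusterCounts), clusterCounts),
        sprintf("union up (C1|C3|C5|C7): %d", unionCounts["up"]),
        sprintf("union down (C2|C4|C6|C8): %d", unionCounts["down"]), "",
        sprintf("network: %d nodes, %d edges, %d components",
                netStats$n_nodes, netStats$n_edges,
                netStats$n_components),
        unlist(lapply(names(subStats), function(p)
            sprintf("subnetwork %s: %d nodes, %d edges", p,
                    subStats[[p]]$n_nodes, subStats[[p]]$n_edges))),
        if (!is.null(enrich))
            sprintf("enrichment: %d terms tested, %d with q < 0.05",
                    nrow(enrich), sum(enrich$q_value < 0.05)))
    files["report"] <- file.path(outDir, "report.txt")
    writeLines(report, files["report"])

    structure(list(cluster_counts = clusterCounts,
                   union_counts = unionCounts,
                   network = netStats, subnetworks = subStats,
                   enrichment = enrich, config_hash = hash,
                   files = files),
              class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
    cat("RunReport (config", substr(x$config_hash, 1, 8), ")\n")
    cat("  clusters:", paste(names(x$cluster_counts), x$cluster_counts,
                             sep = "=", collapse = " "), "\n")
    cat("  union up/down:", x$union_counts["up"], "/",
        x$union_counts["down"], "\n")
    cat("  network:", x$network$n_nodes, "nodes,",
        x$network$n_edges, "edges\n")
    invisible(x)
}
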