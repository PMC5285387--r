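#' Simulation configuration for the synthetic pistil study
#'
#' Bundles every knob of the fixture generators. The defaults emulate the
#' study design the pipeline targets: 2 reproductive modes (sexual,
#' apomictic) x 2 floral stages (11, 14) x 3 biological replicates = 12
#' arrays, log-normal baseline intensities, multiplicative noise, planted
#' differential genes at a 4-fold effect and planted co-expression modules
#' whose members share one latent profile.
#'
#' @param nGenes total number of genes on the simulated array.
#' @param nDegPerCluster named integer vector over clusters C1..C8 giving
#'   how many differential genes to plant per cluster.
#' @param plantedFC linear-scale fold-change magnitude planted in the test
#'   group of each differential gene (>= 2 for recovery against the
#'   pipeline's default threshold).
#' @param baselineLogMean,baselineLogSd mean and sd of per-gene baseline
#'   intensity on the log2 scale.
#' @param noiseCV coefficient of variation of the multiplicative
#'   (log-normal) measurement noise; 0 gives exact group means.
#' @param nCorrModules,moduleSize number and size of planted co-expression
#'   modules (drawn from non-differential genes).
#' @param moduleProfileSd sd (log2) of the shared latent profile across
#'   samples within a module.
#' @param moduleJitterSd sd (log2) of the per-gene jitter around the module
#'   profile; small values give within-module Pearson r >= 0.98.
#' @param nReplicates biological replicates per (mode, stage) group.
#' @param qpcrNBio,qpcrNTech biological / technical replicates per group in
#'   the qPCR fixture.
#' @param qpcrEfficiency amplification efficiency used to construct Ct
#'   values (2 = perfect doubling per cycle).
#' @param qpcrNoiseSd sd (cycles) of Gaussian noise added to Ct values.
#' @param qpcrTrueRatios named numeric vector of true target quantities per
#'   group, relative to the calibrator group.
#' @param seed integer seed; every generator is deterministic given the
#'   configuration.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nGenes = 2000L,
                             nDegPerCluster = stats::setNames(rep(5L, 8),
                                                              .CLUSTERS),
                             plantedFC = 4,
                             baselineLogMean = 7,
                             baselineLogSd = 1,
                             noiseCV = 0.1,
                             nCorrModules = 2L,
                             moduleSize = 5L,
                             moduleProfileSd = 1,
                             moduleJitterSd = 0.05,
                             nReplicates = 3L,
                             qpcrNBio = 5L,
                             qpcrNTech = 3L,
                             qpcrEfficiency = 2,
                             qpcrNoiseSd = 0,
                             qpcrTrueRatios = c("sexual:11" = 1,
                                                "apomictic:11" = 0.25,
                                                "sexual:14" = 2,
                                                "apomictic:14" = 0.5),
                             seed = 17L) {
    .checkCluster(names(nDegPerCluster))
    full <- stats::setNames(rep(0L, 8), .CLUSTERS)
    full[names(nDegPerCluster)] <- as.integer(nDegPerCluster)
    if (any(full < 0)) stop("nDegPerCluster entries must be >= 0")
    if (nGenes < 0 || nCorrModules < 0 || moduleSize < 0)
        stop("counts must be >= 0")
    if (sum(full) + nCorrModules * moduleSize > nGenes)
        stop("planted genes (DEGs + modules) exceed nGenes")
    if (plantedFC <= 0) stop("plantedFC must be positive")
    if (noiseCV < 0) stop("noiseCV must be >= 0")
    if (nReplicates < 2) stop("need >= 2 replicates per group")
    structure(list(nGenes = as.integer(nGenes), nDegPerCluster = full,
                   plantedFC = plantedFC, baselineLogMean = baselineLogMean,
                   baselineLogSd = baselineLogSd, noiseCV = noiseCV,
                   nCorrModules = as.integer(nCorrModules),
                   moduleSize = as.integer(moduleSize),
                   moduleProfileSd = moduleProfileSd,
                   moduleJitterSd = moduleJitterSd,
                   nReplicates = as.integer(nReplicates),
                   qpcrNBio = as.integer(qpcrNBio),
                   qpcrNTech = as.integer(qpcrNTech),
                   qpcrEfficiency = qpcrEfficiency,
                   qpcrNoiseSd = qpcrNoiseSd,
                   qpcrTrueRatios = qpcrTrueRatios,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

.sampleSheet <- function(nReplicates) {
    grid <- expand.grid(replicate = seq_len(nReplicates),
                        stage = .STAGES, mode = .MODES,
                        stringsAsFactors = FALSE)
    short <- c(sexual = "Sex", apomictic = "Apo")
    data.frame(sample_id = paste0(short[grid$mode], grid$stage, "_r",
                                  grid$replicate),
               mode = grid$mode, stage = grid$stage,
               replicate = paste0("r", grid$replicate),
               stringsAsFactors = FALSE)
}

#' Generate a synthetic two-mode, two-stage pistil expression study
#'
#' Baseline intensities are drawn log-normally per gene and shared across
#' samples; each planted differential gene has its comparison's test group
#' multiplied (up clusters) or divided (down clusters) by
#' \code{plantedFC}; measurement noise is multiplicative log-normal with
#' coefficient of variation \code{noiseCV}. Module genes follow one latent
#' log2 profile per module plus per-gene jitter.
#'
#' Because the four canonical comparisons form a cycle over the four
#' (mode, stage) groups, perturbing a single group makes the gene
#' differential in exactly two comparisons; the returned \code{truth_deg}
#' table records the complete induced truth (one row per affected
#' gene x comparison), with \code{planted} flagging the cluster the gene
#' was planted for.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list of class \code{"SyntheticStudy"}: \code{se} (a
#'   \linkS4class{PistilSE}), \code{truth_deg} (gene, comparison, cluster,
#'   true_fc, planted), \code{truth_modules} (list of gene-id sets) and
#'   \code{config}.
#' @export
generateExpressionStudy <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    comps <- canonicalComparisons()
    sheet <- .sampleSheet(config$nReplicates)
    groups <- paste0(sheet$mode, ":", sheet$stage)
    grpLevels <- paste0(rep(.MODES, each = 2), ":", .STAGES)
    nS <- nrow(sheet)
    geneIds <- sprintf("g%05d", seq_len(config$nGenes))

    nDeg <- config$nDegPerCluster
    degGenes <- geneIds[seq_len(sum(nDeg))]
    degCluster <- rep(names(nDeg), times = nDeg)
    modGenes <- geneIds[sum(nDeg) + seq_len(config$nCorrModules *
                                            config$moduleSize)]
    truthModules <- if (length(modGenes))
        split(modGenes, rep(seq_len(config$nCorrModules),
                            each = config$moduleSize)) else list()

    # group multiplier matrix: genes x 4 groups, all 1 except planted cells
    mult <- matrix(1, config$nGenes, length(grpLevels),
                   dimnames = list(geneIds, grpLevels))
    for (i in seq_along(degGenes)) {
        cl <- degCluster[i]
        row <- comps[comps$up == cl | comps$down == cl, ]
        tg <- paste0(row$test_mode, ":", row$test_stage)
        mult[degGenes[i], tg] <- if (row$up == cl) config$plantedFC
                                 else 1 / config$plantedFC
    }

    # full induced truth from the multiplier matrix (pure arithmetic)
    truth <- do.call(rbind, lapply(seq_len(nrow(comps)), function(j) {
        tg <- paste0(comps$test_mode[j], ":", comps$test_stage[j])
        rg <- paste0(comps$ref_mode[j], ":", comps$ref_stage[j])
        ratio <- mult[, tg] / mult[, rg]
        hit <- which(ratio != 1)
        if (!length(hit)) return(NULL)
        data.frame(gene = geneIds[hit], comparison = comps$name[j],
                   cluster = ifelse(ratio[hit] > 1, comps$up[j],
                                    comps$down[j]),
                   true_fc = ifelse(ratio[hit] >= 1, ratio[hit],
                                    -1 / ratio[hit]),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(truth))
        truth <- data.frame(gene = character(), comparison = character(),
                            cluster = character(), true_fc = numeric(),
                            stringsAsFactors = FALSE)
    planted <- stats::setNames(degCluster, degGenes)
    truth$planted <- !is.na(planted[truth$gene]) &
        planted[truth$gene] == truth$cluster
    rownames(truth) <- NULL

    mat <- .withSeed(config$seed, {
        base <- 2^stats::rnorm(config$nGenes, config$baselineLogMean,
                               config$baselineLogSd)
        expected <- base * mult[, match(groups, grpLevels)]
        sigma <- sqrt(log(1 + config$noiseCV^2))
        noise <- if (sigma > 0)
            matrix(exp(stats::rnorm(config$nGenes * nS, -sigma^2 / 2,
                                    sigma)), config$nGenes, nS)
        else 1
        m <- expected * noise
        dimnames(m) <- list(geneIds, sheet$sample_id)
        # module genes: shared latent log2 profile + per-gene jitter
        for (mod in truthModules) {
            latent <- stats::rnorm(nS, 0, config$moduleProfileSd)
            for (g in mod)
                m[g, ] <- base[match(g, geneIds)] *
                    2^(latent + stats::rnorm(nS, 0, config$moduleJitterSd))
        }
        m
    })

    se <- PistilSE(mat, sheet)
    structure(list(se = se, truth_deg = truth,
                   truth_modules = truthModules, config = config),
              class = "SyntheticStudy")
}

#' @export
print.SyntheticStudy <- function(x, ...) {
    cat("SyntheticStudy:", nrow(x$se), "genes x", ncol(x$se), "samples;",
        sum(x$truth_deg$planted), "planted DEGs (",
        nrow(x$truth_deg), "induced truth rows ),",
        length(x$truth_modules), "modules\n")
    invisible(x)
}

#' Write a synthetic study's matrix and metadata as tab-delimited files
#'
#' @param study a \code{"SyntheticStudy"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mPath <- file.path(dir, "matrix.tsv")
    dPath <- file.path(dir, "metadata.tsv")
    writeExpressionMatrix(intensities(study$se), mPath)
    cd <- SummarizedExperiment::colData(study$se)
    .writeTSV(data.frame(sample_id = rownames(cd), mode = cd$mode,
                         stage = cd$stage, replicate = cd$replicate),
              dPath)
    invisible(c(matrix = mPath, metadata = dPath))
}

# ---- alignment fixtures ----------------------------------------------------

# independent oracle for the retention rule, kept deliberately separate from
# isHighQualityHit(): truth flags come from this direct evaluation.
.overhangTruth <- function(u5, u3, g5, g3, matches, fident) {
    endOK <- function(u, g) (u <= 10) || (g < u) || (g < 3)
    (matches >= 50) && (fident >= 0.97) && endOK(u5, g5) && endOK(u3, g3)
}

#' Generate alignment records exercising every branch of the end-overhang
#' retention rule
#'
#' Builds unigene-to-contig alignments (PSL-style coordinates) whose
#' unaligned end segments cover all branches of the quality predicate:
#' overhang 0, <= 10 bp (adapter allowance), > 10 bp; contig-side overhang
#' < 3 bp, >= 3 bp, smaller / not smaller than the unigene overhang; plus
#' hits failing the match-count and fraction-identity gates, on both
#' strands. Truth flags are computed by direct evaluation of the written
#' predicate, independently of the filtering code under test.
#'
#' @param config a \code{\link{simulationConfig}} (seed drives the contig
#'   sequences).
#' @return list with \code{alignments} (data.frame in the layout of
#'   \code{\link{readPSL}}), \code{contigs} (\code{DNAStringSet}) and
#'   \code{truth} (named logical: retained flag per record id).
#' @export
generateAlignmentFixtures <- function(config = simulationConfig()) {
    cases <- data.frame(
        id = sprintf("u%02d", 1:12),
        u5 = c(0, 50,  0, 10, 11, 30,  0,  0, 0,  0,  2,  0),
        u3 = c(0,  0, 20, 10,  0,  0, 15, 20, 0,  0, 11,  0),
        g5 = c(200, 300, 40, 500, 600, 12, 80, 40, 150, 90,  1, 35),
        g3 = c(150,  10,  2, 500,   0,  0, 15,  2, 120, 60, 50, 25),
        strand = c("+", "+", "+", "+", "+", "+", "+", "-", "+", "+",
                   "+", "-"),
        alnLen = c(400, 380, 350, 500, 420, 360, 300, 340, 60, 200,
                   310, 280),
        mismatch = c(0, 0, 0, 0, 0, 0, 0, 0, 11, 8, 0, 0),
        stringsAsFactors = FALSE)
    # case 9: matches 49 < 50; case 10: fident 192/200 = 0.96 < 0.97
    cases$matches <- cases$alnLen - cases$mismatch

    recs <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
        c_ <- cases[i, ]
        qSize <- c_$u5 + c_$alnLen + c_$u3
        tSize <- c_$g5 + c_$alnLen + c_$g3
        if (c_$strand == "+") { tStart <- c_$g5; tEnd <- tSize - c_$g3 }
        else                  { tStart <- c_$g3; tEnd <- tSize - c_$g5 }
        data.frame(unigene_id = c_$id,
                   unigene_length = as.integer(qSize),
                   u_start = as.integer(c_$u5),
                   u_end = as.integer(c_$u5 + c_$alnLen),
                   contig_id = paste0("ctg_", c_$id),
                   contig_length = as.integer(tSize),
                   g_start = as.integer(tStart),
                   g_end = as.integer(tEnd), strand = c_$strand,
                   matches = as.integer(c_$matches),
                   fident = c_$matches / c_$alnLen,
                   stringsAsFactors = FALSE)
    }))

    truth <- vapply(seq_len(nrow(cases)), function(i)
        .overhangTruth(cases$u5[i], cases$u3[i], cases$g5[i], cases$g3[i],
                       cases$matches[i], cases$matches[i] / cases$alnLen[i]),
        logical(1))
    names(truth) <- cases$id

    contigs <- .withSeed(config$seed + 1L, {
        seqs <- vapply(recs$contig_length, function(n)
            paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = ""), character(1))
        Biostrings::DNAStringSet(stats::setNames(seqs, recs$contig_id))
    })
    list(alignments = recs, contigs = contigs, truth = truth)
}

# ---- GO fixture ------------------------------------------------------------

#' Generate a toy GO DAG with one planted over-represented term
#'
#' The ontology has four levels (root, two branches, a diamond join and a
#' leaf). Population genes are annotated so that the planted term's genes
#' are heavily over-sampled in the designated study set, making its
#' hypergeometric upper-tail p-value, after Benjamini-Hochberg correction,
#' fall below 0.05.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{ontology} (\linkS4class{GOOntology}),
#'   \code{annotations} (data.frame gene, term; direct annotations only),
#'   \code{study}, \code{population} (character vectors) and
#'   \code{truth_enriched_term}.
#' @export
generateGOFixture <- function(config = simulationConfig()) {
    terms <- data.frame(
        id = c("GO:0008150", "GO:0000100", "GO:0000200", "GO:0000110",
               "GO:0000120", "GO:0000111"),
        name = c("biological_process", "reproductive process",
                 "metabolic process", "embryo sac development",
                 "cell fate specification", "egg cell differentiation"),
        namespace = "biological_process", stringsAsFactors = FALSE)
    edges <- data.frame(
        child = c("GO:0000100", "GO:0000200", "GO:0000110", "GO:0000120",
                  "GO:0000120", "GO:0000111"),
        parent = c("GO:0008150", "GO:0008150", "GO:0000100", "GO:0000100",
                   "GO:0000200", "GO:0000110"),
        relation = c("is_a", "is_a", "is_a", "is_a", "part_of", "is_a"),
        stringsAsFactors = FALSE)
    ontology <- methods::new("GOOntology", terms = terms, edges = edges)

    population <- sprintf("g%03d", 1:100)
    ann <- rbind(
        data.frame(gene = population[1:5],  term = "GO:0000111"),
        data.frame(gene = population[6:10], term = "GO:0000110"),
        data.frame(gene = population[11:30], term = "GO:0000200"),
        data.frame(gene = population[31:60], term = "GO:0000120"),
        data.frame(gene = population[61:100], term = "GO:0008150"))
    ann$gene <- as.character(ann$gene); ann$term <- as.character(ann$term)
    study <- c(population[1:8], population[31:32])
    list(ontology = ontology, annotations = ann, study = study,
         population = population, truth_enriched_term = "GO:0000110")
}

# ---- qPCR fixture ----------------------------------------------------------

#' Generate a Ct table with known relative quantities
#'
#' Ct values are constructed as \code{Ct = Ct0 - log(quantity) / log(E)} for
#' amplification efficiency \code{E}, so the configured group ratios are the
#' exact truth at zero Ct noise. The reference gene (HpTIP4) has constant
#' quantity in every sample; each group carries at least five biological
#' replicates as in the validation assays the fixture emulates.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{ct} (data.frame sample_id, mode, stage, gene,
#'   tech_rep, ct), \code{truth} (data.frame gene, group, ratio),
#'   \code{efficiency}, \code{reference_gene}, \code{calibrator}.
#' @export
generateQpcrFixture <- function(config = simulationConfig()) {
    E <- config$qpcrEfficiency
    ratios <- config$qpcrTrueRatios
    groups <- names(ratios)
    target <- "HpACR4"; ref <- "HpTIP4"
    ct0 <- c(HpACR4 = 24, HpTIP4 = 20)
    rows <- expand.grid(bio = seq_len(config$qpcrNBio),
                        tech = seq_len(config$qpcrNTech),
                        gene = c(target, ref), group = groups,
                        stringsAsFactors = FALSE)
    qty <- ifelse(rows$gene == ref, 1, ratios[rows$group])
    ct <- ct0[rows$gene] - log(qty) / log(E)
    ct <- .withSeed(config$seed + 2L,
                    ct + stats::rnorm(length(ct), 0, config$qpcrNoiseSd))
    ms <- do.call(rbind, strsplit(rows$group, ":", fixed = TRUE))
    tab <- data.frame(
        sample_id = paste0(gsub(":", "", rows$group), "_b", rows$bio),
        mode = ms[, 1], stage = ms[, 2], gene = rows$gene,
        tech_rep = rows$tech, ct = as.numeric(ct),
        stringsAsFactors = FALSE)
    truth <- data.frame(gene = target, group = groups,
                        ratio = as.numeric(ratios),
                        stringsAsFactors = FALSE)
    list(ct = tab, truth = truth, efficiency = E, reference_gene = ref,
         calibrator = groups[1])
}
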