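test_that("exact linear relations produce r = +/-1 edges and random noise
          produces none", {
    set.seed(21)
    base <- rlnorm(12, 5)
    m <- rbind(A = base, B = 2 * base, C = -base + 2 * max(base),
               t(matrix(rlnorm(12 * 30, 5), 12,
                        dimnames = list(NULL, paste0("n", 1:30)))))
    colnames(m) <- paste0("s", 1:12)
    net <- buildCorrelationNetwork(m)
    e <- networkEdges(net)
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    expect_true("A B" %in% key)
    expect_equal(e$r[key == "A B"], 1)
    expect_true("A C" %in% key)
    expect_equal(e$r[key == "A C"], -1)
    # brute-force check: every reported edge matches direct cor()
    for (i in seq_len(nrow(e)))
        expect_equal(e$r[i], cor(m[e$from[i], ], m[e$to[i], ]))
    # no noise-only pair reaches |r| >= 0.98
    noisePairs <- key[grepl("^n", e$from) & grepl("^n", e$to)]
    expect_length(noisePairs, 0)
})

test_that("fewer than 3 samples and zero-variance genes are handled", {
    m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_error(buildCorrelationNetwork(m), "3 samples")
    m2 <- rbind(flat = rep(1, 5), x = rnorm(5), y = rnorm(5))
    colnames(m2) <- paste0("s", 1:5)
    expect_warning(net <- buildCorrelationNetwork(m2), "zero-variance")
    expect_false("flat" %in% networkNodes(net))
})

test_that("planted modules are recovered as complete subgraphs with no
          background edges", {
    st <- generateExpressionStudy(simulationConfig(
        nGenes = 500, nCorrModules = 2, moduleSize = 5, seed = 17))
    m <- intensities(st$se)
    modGenes <- unlist(st$truth_modules)
    background <- setdiff(rownames(m), c(modGenes,
                                         st$truth_deg$gene))[1:200]
    net <- buildCorrelationNetwork(m, c(modGenes, background))
    e <- networkEdges(net)
    sameModule <- function(a, b) any(vapply(st$truth_modules,
        function(mod) a %in% mod && b %in% mod, TRUE))
    # every within-module pair present, nothing else
    for (mod in st$truth_modules) {
        pairs <- combn(mod, 2)
        for (j in seq_len(ncol(pairs))) {
            hit <- (e$from == pairs[1, j] & e$to == pairs[2, j]) |
                   (e$from == pairs[2, j] & e$to == pairs[1, j])
            expect_true(any(hit))
        }
    }
    expect_true(all(mapply(sameModule, e$from, e$to)))
})

test_that("subnetwork extraction keeps exactly the seeds' incident edges", {
    net <- methods::new("CorrelationNetwork",
        nodes = c("a", "b", "c", "d"),
        edges = data.frame(from = c("a", "b", "c"),
                           to = c("b", "c", "a"), r = c(0.99, 0.99, 0.99),
                           stringsAsFactors = FALSE),
        thresholds = c(-0.98, 0.98))
    degs <- data.frame(gene = c("a", "a", "d"),
                       comparison = c("Sex11_vs_Sex14", "Sex11_vs_Apo11",
                                      "Sex11_vs_Sex14"),
                       cluster = c("C1", "C5", "C1"),
                       stringsAsFactors = FALSE)
    # triangle with single seed "a": its two incident edges, three nodes
    sub <- extractSubnetwork(net, degs, "(C1|C2)&(C5|C6)")
    expect_setequal(networkNodes(sub), c("a", "b", "c"))
    expect_equal(nrow(networkEdges(sub)), 2)
    expect_true(all(networkEdges(sub)$from == "a" |
                    networkEdges(sub)$to == "a"))
    # seed "d" satisfies C1 but has no incident edge -> dropped
    subC1 <- extractSubnetwork(net, degs, "C1")
    expect_false("d" %in% networkNodes(subC1))
    # predicate matching nothing -> empty network
    empty <- extractSubnetwork(net, degs, "C7&C8")
    expect_length(networkNodes(empty), 0)
    expect_error(extractSubnetwork(net, degs, "C1|CX"), "unresolvable")
})

test_that("subnetwork extraction is idempotent and returns a subgraph", {
    st <- generateExpressionStudy(simulationConfig(nGenes = 300, seed = 2))
    m <- intensities(st$se)
    degs <- callDEGs(st$se)
    genes <- unique(degs$gene[!is.na(degs$cluster)])
    net <- suppressWarnings(buildCorrelationNetwork(m, genes))
    sub <- extractSubnetwork(net, degs, "(C1|C2)&(C5|C6)")
    expect_true(all(networkNodes(sub) %in% networkNodes(net)))
    edgeKey <- function(n) with(networkEdges(n),
        paste(pmin(from, to), pmax(from, to)))
    expect_true(all(edgeKey(sub) %in% edgeKey(net)))
    again <- extractSubnetwork(sub, degs, "(C1|C2)&(C5|C6)")
    expect_setequal(edgeKey(again), edgeKey(sub))
    expect_setequal(networkNodes(again), networkNodes(sub))
})

test_that("network statistics count nodes, edges, degrees and
          components", {
    empty <- methods::new("CorrelationNetwork")
    se <- networkStats(empty)
    expect_equal(se$n_nodes, 0L); expect_equal(se$n_components, 0L)
    one <- methods::new("CorrelationNetwork", nodes = c("a", "b"),
        edges = data.frame(from = "a", to = "b", r = 1,
                           stringsAsFactors = FALSE),
        thresholds = c(-0.98, 0.98))
    s1 <- networkStats(one)
    expect_equal(s1$n_edges, 1L)
    expect_equal(unname(s1$degree), c(1, 1))
    expect_equal(s1$n_components, 1L)
    two <- methods::new("CorrelationNetwork",
        nodes = c("a", "b", "c", "d"),
        edges = data.frame(from = c("a", "c"), to = c("b", "d"),
                           r = c(1, -1), stringsAsFactors = FALSE),
        thresholds = c(-0.98, 0.98))
    expect_equal(networkStats(two)$n_components, 2L)
})

test_that("network export round-trips through edge_tsv, graphml and sif", {
    net <- methods::new("CorrelationNetwork",
        nodes = c("a", "b", "c"),
        edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                           r = c(0.987654321098765, -0.99),
                           stringsAsFactors = FALSE),
        thresholds = c(-0.98, 0.98))
    tsv <- tempfile(fileext = ".tsv")
    exportNetwork(net, tsv, "edge_tsv")
    back <- importNetwork(tsv, "edge_tsv")
    expect_equal(networkEdges(back), networkEdges(net))
    gml <- tempfile(fileext = ".graphml")
    exportNetwork(net, gml, "graphml")
    back2 <- importNetwork(gml, "graphml")
    expect_setequal(networkNodes(back2), networkNodes(net))
    expect_equal(networkEdges(back2)$r, networkEdges(net)$r,
                 tolerance = 1e-12)
    sif <- tempfile(fileext = ".sif")
    exportNetwork(net, sif, "sif")
    expect_identical(readLines(sif), c("a\tpc\tb", "b\tpc\tc"))
    expect_error(exportNetwork(net, tsv, "dot"), "arg")
})
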