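test_that("75th-percentile normalisation follows the interpolated quantile
          rule and removes scale", {
    # hand computation: 75th percentile of (1,2,3,4) by linear
    # interpolation between order statistics is 3.25
    m1 <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("g", 1:4),
                                                      "s1"))
    out1 <- percentileNormalize(m1)
    expect_equal(unname(out1[, 1]), c(1, 2, 3, 4) / 3.25 * 3.25)
    expect_equal(unname(quantile(out1[, 1], 0.75, names = FALSE)),
                 unname(quantile(m1[, 1], 0.75, names = FALSE)))

    # a sample that is an exact 2x copy collapses onto the first
    m2 <- cbind(s1 = c(1, 5, 2, 8), s2 = 2 * c(1, 5, 2, 8))
    rownames(m2) <- paste0("g", 1:4)
    out2 <- percentileNormalize(m2)
    expect_equal(unname(out2[, 1]), unname(out2[, 2]))
    # after normalisation all samples share one 75th percentile
    q <- apply(out2, 2, quantile, 0.75, names = FALSE)
    expect_equal(unname(q[1]), unname(q[2]))

    expect_error(percentileNormalize(cbind(s1 = c(0, 0, 0, 0, 1))),
                 "zero")
})

test_that("fold changes are invariant to the normalisation constant", {
    set.seed(1)
    m <- matrix(rlnorm(60, 5), 5, 12,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
    n1 <- percentileNormalize(m)
    n2 <- n1 * 7.3   # any global constant
    fc1 <- signedFoldChange(rowMeans(n1[, 1:3]), rowMeans(n1[, 4:6]))
    fc2 <- signedFoldChange(rowMeans(n2[, 1:3]), rowMeans(n2[, 4:6]))
    expect_equal(fc1, fc2)
})

test_that("pooled t-test matches the closed form and a reference
          implementation", {
    res <- unpairedTTest(c(1, 2, 3), c(2, 3, 4))
    expect_equal(unname(res["t"]), -1.224745, tolerance = 1e-6)
    expect_equal(unname(res["df"]), 4)
    expect_equal(unname(res["p"]), 0.2878641, tolerance = 1e-6)

    set.seed(42)
    for (i in 1:100) {
        a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
        mine <- unpairedTTest(a, b)
        ref <- t.test(a, b, var.equal = TRUE)
        expect_equal(unname(mine["t"]), unname(ref$statistic),
                     tolerance = 1e-10)
        expect_equal(unname(mine["p"]), ref$p.value, tolerance = 1e-10)
        swapped <- unpairedTTest(b, a)
        expect_equal(unname(swapped["t"]), -unname(mine["t"]))
        expect_equal(unname(swapped["p"]), unname(mine["p"]))
    }
})

test_that("degenerate zero-variance groups follow the documented
          convention", {
    expect_equal(unname(unpairedTTest(c(1, 1), c(1, 1))["p"]), 1)
    expect_equal(unname(unpairedTTest(c(1, 1), c(2, 2))["p"]), 0)
    expect_equal(unname(unpairedTTest(c(2, 2), c(2, 2))["t"]), 0)
})

test_that("signed fold change is antisymmetric with magnitude >= 1", {
    expect_equal(signedFoldChange(2, 1), 2)
    expect_equal(signedFoldChange(1, 2), -2)
    expect_equal(signedFoldChange(3, 3), 1)
    expect_error(signedFoldChange(0, 1), "positive")
    set.seed(7)
    a <- rlnorm(1000); b <- rlnorm(1000)
    fab <- signedFoldChange(a, b); fba <- signedFoldChange(b, a)
    neq <- a != b
    expect_equal(fab[neq], -fba[neq])
    expect_true(all(abs(fab) >= 1))
    expect_true(all(fab[a == b] == 1))
})

test_that("callDEGs assigns planted clusters exactly at zero noise", {
    cfg <- simulationConfig(nGenes = 400,
                            nDegPerCluster = setNames(rep(2L, 8),
                                                      paste0("C", 1:8)),
                            plantedFC = 4, noiseCV = 0,
                            nCorrModules = 0)
    st <- generateExpressionStudy(cfg)
    degs <- callDEGs(st$se)
    called <- degs[!is.na(degs$cluster), ]
    truthKey <- with(st$truth_deg, paste(gene, comparison, cluster))
    callKey <- with(called, paste(gene, comparison, cluster))
    expect_setequal(callKey, truthKey)
})

test_that("a worked down-regulated call lands in C6 and threshold edges
          hold", {
    # one gene at signed FC -2.23 in the sexual-vs-apomictic stage-11
    # comparison (ref sexual, test apomictic), small p -> cluster C6;
    # a second gene at FC 1.9 misses the fold-change gate at any p
    md <- tinyMetadata()
    base <- 100
    m <- rbind(
        ipt2 = c(rep(base, 3) * c(0.995, 1, 1.005),          # Sex11
                 rep(base, 3) * c(0.99, 1, 1.01),            # Sex14
                 rep(base / 2.23, 3) * c(0.995, 1, 1.005),   # Apo11
                 rep(base, 3) * c(0.99, 1, 1.01)),           # Apo14
        weak = c(rep(base, 3) * c(0.999, 1, 1.001),
                 rep(base * 1.9, 3) * c(0.999, 1, 1.001),
                 rep(base, 3), rep(base, 3)))
    colnames(m) <- md$sample_id
    degs <- callDEGs(PistilSE(m, md))
    ipt2 <- degs[degs$gene == "ipt2" &
                 degs$comparison == "Sex11_vs_Apo11", ]
    expect_identical(ipt2$cluster, "C6")
    expect_equal(ipt2$signed_fc, -2.23, tolerance = 1e-6)
    weak <- degs[degs$gene == "weak" &
                 degs$comparison == "Sex11_vs_Sex14", ]
    expect_lt(weak$p, 0.01)
    expect_true(is.na(weak$cluster))     # FC 1.9 < 2
})

test_that("raising the fold-change threshold never grows any cluster", {
    st <- generateExpressionStudy(simulationConfig(nGenes = 300, seed = 3))
    d2 <- callDEGs(st$se, fcThreshold = 2)
    d3 <- callDEGs(st$se, fcThreshold = 3)
    s2 <- vapply(clusterSets(d2), length, 1L)
    s3 <- vapply(clusterSets(d3), length, 1L)
    expect_true(all(s3 <= s2))
})

test_that("groups with fewer than 2 replicates are rejected by name", {
    md <- tinyMetadata()
    keep <- !(md$mode == "sexual" & md$stage == "11" &
              md$replicate != "r1")
    m <- matrix(rlnorm(24), 2, 12,
                dimnames = list(c("g1", "g2"), md$sample_id))
    expect_error(callDEGs(PistilSE(m[, md$sample_id[keep]], md[keep, ])),
                 "sexual:11")
})

test_that("venn region counts equal brute-force membership enumeration", {
    expect_equal(sum(vennOverlaps(list(A = "a", B = "b"))$count[3]), 0)
    same <- vennOverlaps(list(A = letters[1:13], B = letters[1:13]))
    expect_equal(same$count[same$region == "A&B"], 13)
    set.seed(11)
    sets <- list(X = sample(letters, 10), Y = sample(letters, 12),
                 Z = sample(letters, 8))
    venn <- vennOverlaps(sets)
    for (el in unique(unlist(sets))) {
        membership <- names(sets)[vapply(sets, function(s) el %in% s,
                                         TRUE)]
        region <- paste(membership, collapse = "&")
        expect_true(region %in% venn$region)
    }
    # total over regions = number of distinct elements
    expect_equal(sum(venn$count), length(unique(unlist(sets))))
    expect_error(clusterUnion(list(C1 = "a"), c("C1", "C9")), "C9")
})
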