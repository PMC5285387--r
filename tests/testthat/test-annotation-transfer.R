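test_that("end overhangs are strand-aware", {
    plus <- recFromOverhangs(50, 7, 30, 200, "+")
    ov <- endOverhangs(plus)
    expect_equal(unlist(ov), c(u5 = 50, u3 = 7, g5 = 30, g3 = 200))
    # same geometry on the minus strand swaps the contig sides
    minus <- recFromOverhangs(50, 7, 30, 200, "-")
    ovm <- endOverhangs(minus)
    expect_equal(unlist(ovm), c(u5 = 50, u3 = 7, g5 = 30, g3 = 200))
    expect_equal(minus$g_start, 200)     # forward-coordinate bookkeeping
    # full-length alignment has zero unigene overhangs
    full <- recFromOverhangs(0, 0, 12, 34, "+")
    expect_equal(unlist(endOverhangs(full)),
                 c(u5 = 0, u3 = 0, g5 = 12, g3 = 34))
})

test_that("BLAT gates are inclusive at their boundaries", {
    r <- recFromOverhangs(0, 0, 0, 0, alnLen = 100, matches = 50)
    r$fident <- 0.97
    expect_true(passesBlatThresholds(r))
    r$matches <- 49
    expect_false(passesBlatThresholds(r))
    r$matches <- 60; r$fident <- 0.969
    expect_false(passesBlatThresholds(r))
})

test_that("retention predicate matches brute force on the exhaustive
          overhang grid", {
    vals <- c(0, 1, 3, 10, 11, 50)
    grid <- expand.grid(u5 = vals, g5 = vals, u3 = vals, g3 = vals)
    recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
        recFromOverhangs(grid$u5[i], grid$u3[i], grid$g5[i], grid$g3[i])))
    got <- isHighQualityHit(recs)
    want <- vapply(seq_len(nrow(grid)), function(i)
        bruteForceRetained(grid$u5[i], grid$u3[i], grid$g5[i],
                           grid$g3[i]), logical(1))
    expect_equal(nrow(grid), 1296)
    expect_identical(got, want)
})

test_that("the 3-bp contig-end escape and the short-contig leniency are
          selectable", {
    rec5 <- recFromOverhangs(20, 0, 2, 100)
    # lenient default: g5 = 2 < u5 = 20 passes regardless of the escape
    expect_true(isHighQualityHit(rec5))
    expect_true(isHighQualityHit(rec5, threeBpEscape = "3prime-only"))
    # strict reading: only the contig-end escape can save the 5' end
    expect_true(isHighQualityHit(rec5, contigShorterLenient = FALSE))
    expect_false(isHighQualityHit(rec5, threeBpEscape = "3prime-only",
                                  contigShorterLenient = FALSE))
    rec3 <- recFromOverhangs(0, 20, 100, 2)   # 3' escape unaffected
    expect_true(isHighQualityHit(rec3, threeBpEscape = "3prime-only",
                                 contigShorterLenient = FALSE))
    strictFail <- recFromOverhangs(20, 0, 5, 100)  # g5 = 5: no escape
    expect_true(isHighQualityHit(strictFail))
    expect_false(isHighQualityHit(strictFail,
                                  contigShorterLenient = FALSE))
})

test_that("top-hit selection ranks by matches, fident, then contig id", {
    h <- rbind(recFromOverhangs(0, 0, 10, 10, alnLen = 400, matches = 400,
                                contig = "c2"),
               recFromOverhangs(0, 0, 10, 10, alnLen = 400, matches = 380,
                                contig = "c1"))
    expect_equal(selectTopHit(h)$contig_id, "c2")
    tie <- rbind(recFromOverhangs(0, 0, 10, 10, alnLen = 400,
                                  matches = 400, contig = "c2"),
                 recFromOverhangs(0, 0, 10, 10, alnLen = 400,
                                  matches = 400, contig = "c1"))
    expect_equal(selectTopHit(tie)$contig_id, "c1")
    none <- recFromOverhangs(50, 0, 300, 0)
    expect_null(selectTopHit(none))
    single <- recFromOverhangs(0, 0, 10, 10)
    expect_equal(selectTopHit(single)$contig_id, "ctg1")
})

test_that("flank extraction respects the 100-1001 policy and orientation", {
    set.seed(99)
    rec <- recFromOverhangs(0, 0, 600, 1500, "+")
    seq <- randomDNA(rec$contig_length)
    fl <- extractFlanks(rec, seq)
    expect_equal(nchar(fl$upstream$seq), 600)
    expect_equal(nchar(fl$downstream$seq), 1001)       # capped
    expect_equal(fl$upstream$start, 0)
    expect_equal(fl$downstream$start, rec$g_end)
    short <- recFromOverhangs(0, 0, 50, 600, "+")
    fs <- extractFlanks(short, randomDNA(short$contig_length))
    expect_null(fs$upstream)                            # below minimum
    expect_equal(nchar(fs$downstream$seq), 600)
    expect_error(extractFlanks(rec, randomDNA(10)), "length")
    # flanks never overlap the aligned interval
    expect_lte(fl$upstream$end, rec$g_start)
    expect_gte(fl$downstream$start, rec$g_end)
})

test_that("reverse-complementing the contig leaves status and flank
          sequences invariant", {
    set.seed(3)
    rec <- recFromOverhangs(5, 20, 400, 900, "+")
    seq <- randomDNA(rec$contig_length)
    flip <- rec
    flip$strand <- "-"
    flip$g_start <- rec$contig_length - rec$g_end
    flip$g_end <- rec$contig_length - rec$g_start
    rcSeq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    expect_identical(isHighQualityHit(rec), isHighQualityHit(flip))
    f1 <- extractFlanks(rec, seq)
    f2 <- extractFlanks(flip, rcSeq)
    expect_identical(f1$upstream$seq, f2$upstream$seq)
    expect_identical(f1$downstream$seq, f2$downstream$seq)
})

test_that("PSL files round-trip through write and read", {
    fx <- generateAlignmentFixtures(simulationConfig())
    f <- tempfile(fileext = ".psl")
    writePSL(fx$alignments, f)
    back <- readPSL(f)
    expect_equal(back, fx$alignments)
    writeLines("1\t2\t3", f)
    expect_error(readPSL(f), "malformed PSL row 1")
})

test_that("annotation transfer prefers direct hits and falls through by
          E-value", {
    direct <- data.frame(query = c("u1", "u2"),
                         subject = c("AT1G01010", "AT1G02020"),
                         similarity = c(80, 90),
                         evalue = c(1e-10, 1e-8))
    flank <- data.frame(query = c("u2|ctg:0-100|upstream", "u2"),
                        subject = c("AT9G09090", "AT8G08080"),
                        similarity = c(75, 99),
                        evalue = c(1e-12, 1e-11))
    r1 <- transferAnnotation("u1", direct, flank)
    expect_equal(r1$source, "direct")
    expect_equal(r1$top_hit_locus, "AT1G01010")
    # direct E = 1e-8 fails the 1e-9 gate -> best flank hit by E-value
    r2 <- transferAnnotation("u2", direct, flank)
    expect_equal(r2$source, "flank")
    expect_equal(r2$top_hit_locus, "AT9G09090")
    r3 <- transferAnnotation("u3", direct, flank)
    expect_equal(r3$source, "none")
    expect_equal(r3$top_hit_locus, "")
})

test_that("flank FASTA export uses the declared id scheme", {
    rec <- recFromOverhangs(0, 0, 200, 200, "+")
    seq <- randomDNA(rec$contig_length)
    fl <- extractFlanks(rec, seq)
    f <- tempfile(fileext = ".fa")
    writeFlanksFasta(list(u1 = fl), f)
    ss <- Biostrings::readDNAStringSet(f)
    expect_length(ss, 2)
    expect_match(names(ss)[1], "^u1\\|ctg1:0-200\\|upstream$")
})

test_that("malformed hit tables error with the row number", {
    f <- tempfile()
    writeLines(c("query\tsubject\tsimilarity\tevalue",
                 "u1\tAT1\t80\t1e-10", "u2\tAT2\tbad\t1e-3"), f)
    expect_error(suppressWarnings(readBlastHits(f)), "row 3")
})
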