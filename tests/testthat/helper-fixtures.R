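# Shared helpers for building tiny in-code fixtures.

# minimal 12-sample metadata matching the generator's layout
tinyMetadata <- function(nrep = 3) {
    grid <- expand.grid(replicate = seq_len(nrep), stage = c("11", "14"),
                        mode = c("sexual", "apomictic"),
                        stringsAsFactors = FALSE)
    short <- c(sexual = "Sex", apomictic = "Apo")
    data.frame(sample_id = paste0(short[grid$mode], grid$stage, "_r",
                                  grid$replicate),
               mode = grid$mode, stage = grid$stage,
               replicate = paste0("r", grid$replicate),
               stringsAsFactors = FALSE)
}

# a valid alignment record from end overhangs; alnLen bases, full identity
recFromOverhangs <- function(u5, u3, g5, g3, strand = "+", alnLen = 100,
                             matches = alnLen, id = "u1",
                             contig = "ctg1") {
    qSize <- u5 + alnLen + u3
    tSize <- g5 + alnLen + g3
    if (strand == "+") { tStart <- g5; tEnd <- tSize - g3 }
    else               { tStart <- g3; tEnd <- tSize - g5 }
    data.frame(unigene_id = id, unigene_length = qSize, u_start = u5,
               u_end = u5 + alnLen, contig_id = contig,
               contig_length = tSize, g_start = tStart, g_end = tEnd,
               strand = strand, matches = matches,
               fident = matches / alnLen, stringsAsFactors = FALSE)
}

# independent brute-force restatement of the retention rule
bruteForceRetained <- function(u5, u3, g5, g3) {
    pass <- function(u, g) u <= 10 || g < u || g < 3
    pass(u5, g5) && pass(u3, g3)
}

# exact hypergeometric upper tail by combinatorial enumeration
enumUpperTail <- function(k, N, K, n) {
    i <- seq(k, min(n, K))
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
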