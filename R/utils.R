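# Run code with a fixed RNG state, restoring the caller's stream afterwards.
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

.checkCluster <- function(cluster) {
    bad <- setdiff(cluster, .CLUSTERS)
    if (length(bad))
        stop("unknown cluster label(s): ", paste(bad, collapse = ", "),
             " (expected C1..C8)")
    invisible(cluster)
}

# Write a data.frame as plain TSV without quoting or row names.
.writeTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
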