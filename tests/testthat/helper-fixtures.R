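# shared fixtures and independent oracles (deliberately naive code paths)

toyPanel <- function() {
    LociPanel(position = c(5L, 10L, 15L), wt = c("A", "K", "G"),
              mutants = list("V", "R", "E"), referenceId = "toy")
}

# all 8 toy allele-IDs by explicit Cartesian product (oracle for the
# enumerator)
toyAlleleIDs <- function() {
    g <- expand.grid(c("A", "V"), c("K", "R"), c("E", "G"),
                     stringsAsFactors = FALSE)
    sort(paste0(g[, 1], g[, 2], g[, 3]))
}

# random toy count table over the full 8-allele space
randomToyCounts <- function(seed, lambda0 = 200, lambda1 = 150) {
    set.seed(seed)
    ids <- toyAlleleIDs()
    m <- cbind(t0 = rpois(length(ids), lambda0) + 1L,
               c1 = rpois(length(ids), lambda1) + 1L)
    rownames(m) <- ids
    AlleleCounts(m, toyPanel())
}

# a toy table whose per-locus effects factorise exactly: t0 uniform,
# t1 = t0 * prod(w over carried mutations); integer by construction
multiplicativeToyCounts <- function(base = 16L, w = c(2L, 3L, 5L)) {
    ids <- toyAlleleIDs()
    pan <- toyPanel()
    mut <- c("V", "R", "E")
    t1 <- vapply(ids, function(id) {
        carried <- strsplit(id, "")[[1]] == mut
        base * prod(w[carried])
    }, numeric(1))
    m <- cbind(t0 = rep(base, length(ids)), c1 = as.integer(t1))
    rownames(m) <- ids
    AlleleCounts(m, pan)
}

# brute-force marginal/pair fitness by explicit per-allele summation;
# independent of the package's membership-matrix machinery
bfFitness <- function(x, positions, residues, tFrom, tTo, pseudocount) {
    pan <- panel(x)
    lo <- pan@loci
    cn <- SummarizedExperiment::assay(x, "counts")
    mut0 <- wt0 <- mut1 <- wt1 <- 0
    for (id in rownames(cn)) {
        isMut <- TRUE; isWt <- TRUE; excluded <- FALSE
        for (k in seq_along(positions)) {
            j <- which(lo$position == positions[k])
            r <- substr(id, j, j)
            allowed <- c(lo$wt[j], lo$mutants[[j]])
            if (!r %in% allowed) excluded <- TRUE
            if (r != residues[k]) isMut <- FALSE
            if (r != lo$wt[j]) isWt <- FALSE
        }
        if (excluded) next
        if (isMut) {
            mut0 <- mut0 + cn[id, tFrom]; mut1 <- mut1 + cn[id, tTo]
        }
        if (isWt) {
            wt0 <- wt0 + cn[id, tFrom]; wt1 <- wt1 + cn[id, tTo]
        }
    }
    if (pseudocount == 0 && any(c(mut0, wt0, mut1, wt1) == 0))
        return(NA_real_)
    log(((mut1 + pseudocount) / (wt1 + pseudocount)) /
        ((mut0 + pseudocount) / (wt0 + pseudocount)))
}

# hamming distance oracle: position-by-position comparison
bfHamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# a small truth model for fast read-level tests
smallReadTruth <- function(perBaseError = 0, indelRate = 0,
                           offtargetRate = 0,
                           readTotals = c(t0 = 150, c1 = 100)) {
    truthModel("null", perBaseError = perBaseError, indelRate = indelRate,
               offtargetRate = offtargetRate, readTotals = readTotals)
}
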