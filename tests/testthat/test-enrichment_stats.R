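test_that("the epistasis filter keeps WT-at-degenerate-loci alleles and
           leaves 11 focal mutations / 55 pairs", {
    pan <- defaultPanel()
    wt <- wildtypeAlleleID(pan)
    ids <- c(wt,
             paste0("K", substr(wt, 2, 13)),              # E103K: kept
             paste0(substr(wt, 1, 9), "D", substr(wt, 11, 13)),  # D at 319
             paste0(substr(wt, 1, 10), "S", substr(wt, 12, 13))) # S at 320
    m <- matrix(5L, length(ids), 2,
                dimnames = list(ids, c("t0", "c1")))
    x <- AlleleCounts(m, pan)
    fx <- filterForEpistasis(x)
    expect_setequal(alleleIDs(fx), ids[1:2])

    fm <- focalMutations(pan)
    expect_identical(nrow(fm), 11L)
    expect_identical(nrow(t(combn(nrow(fm), 2))), 55L)
    expect_false(any(fm$position %in% c(319L, 320L)))
})

test_that("marginal fitness follows the log ratio-of-ratios formula", {
    # construct a toy table with known aggregates: at locus 5 (A->V),
    # mutant carriers 100 -> 200 while WT stays 100 -> 100
    ids <- c("VKG", "AKG")
    m <- matrix(c(100L, 100L, 200L, 100L), 2, 2,
                dimnames = list(ids, c("t0", "c1")))
    x <- AlleleCounts(m, toyPanel())
    w <- marginalFitness(x, 5, "V", pseudocount = 0)
    expect_equal(w$W, log(2))
    expect_equal(c(w$mut_t0, w$wt_t0, w$mut_t1, w$wt_t1),
                 c(100, 100, 200, 100))

    # both groups doubling cancels out
    m2 <- matrix(c(100L, 100L, 200L, 200L), 2, 2,
                 dimnames = list(ids, c("t0", "c1")))
    w2 <- marginalFitness(AlleleCounts(m2, toyPanel()), 5, "V",
                          pseudocount = 0)
    expect_equal(w2$W, 0)
})

test_that("zero aggregates are flagged undefined at pseudocount 0 and
           finite with the default pseudocount", {
    ids <- c("VKG", "AKG")
    m <- matrix(c(0L, 100L, 50L, 100L), 2, 2,
                dimnames = list(ids, c("t0", "c1")))
    x <- AlleleCounts(m, toyPanel())
    w0 <- marginalFitness(x, 5, "V", pseudocount = 0)
    expect_true(w0$undefined)
    expect_true(is.na(w0$W))
    w5 <- marginalFitness(x, 5, "V", pseudocount = 0.5)
    expect_false(w5$undefined)
    expect_true(is.finite(w5$W))
})

test_that("marginal and pair fitness equal the brute-force per-allele
           aggregation oracle exactly", {
    for (seed in c(101, 102, 103)) {
        x <- randomToyCounts(seed)
        for (pc in c(0, 0.5)) {
            for (spec in list(list(5, "V"), list(10, "R"), list(15, "E"))) {
                got <- marginalFitness(x, spec[[1]], spec[[2]],
                                       pseudocount = pc)$W
                want <- bfFitness(x, spec[[1]], spec[[2]], "t0", "c1", pc)
                expect_identical(got, want)
            }
            got <- pairFitness(x, 5, "V", 10, "R", pseudocount = pc)$W
            want <- bfFitness(x, c(5, 10), c("V", "R"), "t0", "c1", pc)
            expect_identical(got, want)
        }
    }
})

test_that("alleles with unexpected residues are excluded from both
           fitness groups", {
    ids <- c("VKG", "AKG", "ZKG")  # Z is outside the designed alphabet
    m <- matrix(c(100L, 100L, 50L, 200L, 100L, 50L), 3, 2,
                dimnames = list(ids, c("t0", "c1")))
    x <- AlleleCounts(m, toyPanel())
    w <- marginalFitness(x, 5, "V", pseudocount = 0)
    expect_equal(c(w$mut_t0, w$wt_t0), c(100, 100))  # Z row ignored
})

test_that("on an exactly multiplicative table W_ij = W_i + W_j and all
           epsilon are zero", {
    x <- multiplicativeToyCounts()
    wi <- marginalFitness(x, 5, "V", pseudocount = 0)$W
    wj <- marginalFitness(x, 10, "R", pseudocount = 0)$W
    wij <- pairFitness(x, 5, "V", 10, "R", pseudocount = 0)$W
    expect_equal(wij, wi + wj)
    eps <- pairwiseEpistasis(x, pseudocount = 0)
    expect_identical(nrow(eps), 3L)
    expect_equal(eps$epsilon, rep(0, 3))
})

test_that("epsilon is W_ij minus the sum of singles, by construction", {
    x <- randomToyCounts(7)
    eps <- pairwiseEpistasis(x, pseudocount = 0.5)
    expect_equal(eps$epsilon, eps$W_ij - (eps$W_i + eps$W_j))
})

test_that("fitness is invariant to sequencing depth (scaling one time
           point)", {
    x <- randomToyCounts(11)
    cn <- SummarizedExperiment::assay(x, "counts")
    cn[, "c1"] <- cn[, "c1"] * 7L
    x7 <- AlleleCounts(cn, toyPanel())
    for (spec in list(list(5, "V"), list(10, "R"))) {
        expect_equal(
            marginalFitness(x7, spec[[1]], spec[[2]], pseudocount = 0)$W,
            marginalFitness(x, spec[[1]], spec[[2]], pseudocount = 0)$W)
    }
})

test_that("estimating epistasis on a later interval warns", {
    ids <- toyAlleleIDs()
    set.seed(3)
    m <- matrix(rpois(24, 100) + 1L, 8, 3,
                dimnames = list(ids, c("t0", "c1", "c3")))
    x <- AlleleCounts(m, toyPanel())
    expect_warning(pairwiseEpistasis(x, tFrom = "c1", tTo = "c3"),
                   "first selection interval")
})

test_that("background profiles are indicator-like for a single allele and
           flat for a balanced library", {
    pan <- toyPanel()
    m <- matrix(c(10L, 10L), 1, 2, dimnames = list("VKG", c("t0", "c1")))
    x <- AlleleCounts(m, pan)
    bp <- backgroundProfile(x, 5, "V")
    expect_equal(unname(bp$mutant["10", "K"]), 1)
    expect_equal(unname(bp$mutant["15", "G"]), 1)
    expect_true(isTRUE(attr(bp$reference, "empty")))

    # balanced synthetic library: binary loci near 0.5/0.5 and focal
    # backgrounds near-identical (total variation below 3 binomial SE)
    truth <- truthModel("null", offtargetRate = 0)
    set.seed(41)
    lib <- generateLibrary(truth, nClones = 60000)
    agg <- tapply(lib$n, lib$allele_id, sum)
    m <- matrix(as.integer(agg), ncol = 1, dimnames = list(names(agg), "t0"))
    m <- cbind(m, t0b = m[, 1])
    colnames(m) <- c("t0", "c1")
    x <- AlleleCounts(m, defaultPanel())
    pan13 <- defaultPanel()
    bp1 <- backgroundProfile(x, 103, "K")
    bp2 <- backgroundProfile(x, 118, "S")
    se3 <- 3 * sqrt(0.25 / 30000)  # ~carriers of one binary mutation
    binary <- as.character(
        panelPositions(pan13)[lengths(mutantResidues(pan13)) == 1L])
    wtOf <- setNames(wtResidues(pan13),
                     as.character(panelPositions(pan13)))
    for (p in setdiff(binary, c("103", "118")))
        expect_lt(abs(bp1$mutant[p, wtOf[p]] - 0.5), 3 * se3)
    # total-variation distance between two focal backgrounds is small
    for (p in setdiff(rownames(bp1$mutant), "118")) {
        cols <- union(colnames(bp1$mutant), colnames(bp2$mutant))
        f1 <- setNames(rep(0, length(cols)), cols)
        f2 <- f1
        f1[colnames(bp1$mutant)] <- bp1$mutant[p, ]
        f2[colnames(bp2$mutant)] <- bp2$mutant[p, ]
        tv <- 0.5 * sum(abs(f1 - f2))
        expect_lt(tv, 0.05)
    }
})

test_that("position composition reproduces the design frequencies of a
           fresh library", {
    truth <- truthModel("null", offtargetRate = 0)
    set.seed(51)
    lib <- generateLibrary(truth, nClones = 80000)
    agg <- tapply(lib$n, lib$allele_id, sum)
    m <- cbind(t0 = as.integer(agg), c1 = as.integer(agg))
    rownames(m) <- names(agg)
    x <- AlleleCounts(m, defaultPanel())
    comp <- positionComposition(x, "t0")
    expect_equal(unname(rowSums(comp)), rep(1, nrow(comp)))
    # degenerate-codon locus 319: G 1/2, E 1/4, D 1/4
    expect_lt(abs(comp["319", "G"] - 0.5), 0.01)
    expect_lt(abs(comp["319", "E"] - 0.25), 0.01)
    expect_lt(abs(comp["319", "D"] - 0.25), 0.01)
    for (p in c("103", "118", "161"))
        expect_lt(abs(comp[p, ][wtResidues(defaultPanel())[
            match(as.integer(p), panelPositions(defaultPanel()))]] - 0.5),
            0.01)

    # single-allele table gives an indicator composition
    m1 <- matrix(c(4L, 4L), 1, 2, dimnames = list("VKG", c("t0", "c1")))
    comp1 <- positionComposition(AlleleCounts(m1, toyPanel()), "t0")
    expect_equal(unname(comp1["5", "V"]), 1)
})

test_that("diversity trajectory: equal compositions give equal entropy,
           fixation gives zero, selection shrinks it", {
    ids <- toyAlleleIDs()
    m <- cbind(t0 = rep(10L, 8), c1 = rep(20L, 8))
    rownames(m) <- ids
    d <- diversityTrajectory(AlleleCounts(m, toyPanel()))
    expect_equal(d$shannon[1], d$shannon[2])
    expect_equal(d$shannon[1], log(8))

    m2 <- cbind(t0 = rep(10L, 8), c1 = c(80L, rep(0L, 7)))
    rownames(m2) <- ids
    d2 <- diversityTrajectory(AlleleCounts(m2, toyPanel()))
    expect_equal(d2$shannon[2], 0)
    expect_identical(d2$richness[2], 1L)

    se <- makeBenchmark("full-course", seed = 61, nClones = 24576)
    d3 <- diversityTrajectory(se@counts)
    expect_true(all(diff(d3$shannon) < 0.05))
    expect_lt(d3$shannon[nrow(d3)], d3$shannon[1])
})
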