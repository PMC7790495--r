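test_that("the synthetic reference ORF is deterministic and consistent
           with the panel", {
    ref1 <- syntheticReference()
    ref2 <- syntheticReference()
    expect_identical(as.character(ref1), as.character(ref2))
    expect_identical(length(ref1), 1014L)
    pan <- defaultPanel()
    refchr <- as.character(ref1)
    for (j in seq_len(length(pan))) {
        p <- panelPositions(pan)[j]
        cod <- substr(refchr, 3 * p - 2, 3 * p)
        expect_identical(unname(Biostrings::GENETIC_CODE[cod]),
                         wtResidues(pan)[j])
    }
    # codon 234 is Ala so the documented off-target hotspot is encodable
    expect_identical(unname(Biostrings::GENETIC_CODE[
        substr(refchr, 3 * 234 - 2, 3 * 234)]), "A")
    # no internal stop codons
    aa <- as.character(Biostrings::translate(ref1))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
})

test_that("alignment handles identity, reverse complement and a single
           insertion", {
    ref <- syntheticReference()
    refchr <- as.character(ref)

    aln <- alignToReference(refchr, ref)
    expect_identical(aln$identity, 1)
    expect_identical(aln$orientation, "forward")
    expect_identical(aln$nInsertions + aln$nDeletions, 0L)

    rc <- as.character(Biostrings::reverseComplement(ref))
    alnR <- alignToReference(rc, ref)
    expect_identical(alnR$orientation, "reverse")
    expect_identical(alnR$identity, 1)

    # one inserted base in a toy sequence: exactly one insertion column
    toyRef <- substr(refchr, 1, 30)
    toyRead <- paste0(substr(toyRef, 1, 12), "A", substr(toyRef, 13, 30))
    alnI <- alignToReference(toyRead, toyRef)
    expect_identical(alnI$nInsertions, 1L)
    expect_identical(alnI$nDeletions, 0L)
    rep <- correctIndels(alnI)
    expect_identical(rep$sequence, toyRef)
})

test_that("garbage reads are unalignable", {
    ref <- syntheticReference()
    set.seed(1)
    junk <- paste(sample(c("A", "C", "G", "T"), 1014, replace = TRUE),
                  collapse = "")
    expect_identical(alignToReference(junk, ref)$status, "unalignable")
})

test_that("indel correction restores reference coordinates", {
    ref <- syntheticReference()
    refchr <- as.character(ref)

    # deletion inside a non-focal codon is filled back with reference bases
    del <- paste0(substr(refchr, 1, 599), substr(refchr, 601, 1014))
    rep <- correctIndels(alignToReference(del, ref))
    expect_identical(nchar(rep$sequence), rep$end - rep$start + 1L)
    expect_identical(substr(rep$sequence, 598 - rep$start + 1,
                            600 - rep$start + 1),
                     substr(refchr, 598, 600))
    expect_length(rep$deletedRefPositions, 1L)
    expect_identical(rep$sequence,
                     substr(refchr, rep$start, rep$end))

    # random indel patterns: repaired length always equals the aligned span
    set.seed(99)
    for (r in 1:25) {
        x <- strsplit(refchr, "")[[1]]
        nDel <- sample(0:3, 1); nIns <- sample(0:3, 1)
        if (nDel) x <- x[-sample(seq_along(x), nDel)]
        if (nIns) for (k in seq_len(nIns))
            x <- append(x, sample(c("A", "C", "G", "T"), 1),
                        after = sample(length(x), 1))
        rd <- paste(x, collapse = "")
        rep <- correctIndels(alignToReference(rd, ref))
        expect_identical(nchar(rep$sequence), rep$end - rep$start + 1L)
    }
})

test_that("allele-ID extraction reads focal codons and counts off-target
           codon mismatches", {
    pan <- defaultPanel()
    ref <- syntheticReference()
    refchr <- as.character(ref)

    call <- extractAlleleID(refchr, ref, pan)
    expect_identical(call$allele_id, "ETDHSKYDVGGAA")
    expect_identical(call$offtarget_mismatches, 0L)
    expect_true(all(call$flags == "expected_wt"))

    # E103K at the first focal codon
    mut <- refchr
    substr(mut, 307, 309) <- "AAA"
    call <- extractAlleleID(mut, ref, pan)
    expect_identical(substr(call$allele_id, 1, 1), "K")
    expect_identical(unname(call$flags[1]), "expected_mut")
    expect_identical(call$offtarget_mismatches, 0L)

    # A234V is off-target under the default panel: ID unchanged, 1 mismatch
    mut <- refchr
    substr(mut, 3 * 234 - 2, 3 * 234) <- "GTT"
    call <- extractAlleleID(mut, ref, pan)
    expect_identical(call$allele_id, "ETDHSKYDVGGAA")
    expect_identical(call$offtarget_mismatches, 1L)
    expect_identical(call$substitutions$codon, 234L)
    expect_false(call$substitutions$synonymous)

    # N in a focal codon gives X and an unexpected flag
    mut <- refchr
    substr(mut, 307, 307) <- "N"
    call <- extractAlleleID(mut, ref, pan)
    expect_identical(substr(call$allele_id, 1, 1), "X")
    expect_identical(unname(call$flags[1]), "unexpected")
})

test_that("curation counts identical reads with multiplicity and discards
           short reads", {
    pan <- defaultPanel()
    ref <- syntheticReference()
    refchr <- as.character(ref)
    reads <- list(t0 = rep(refchr, 10))
    out <- curateAndCount(reads, ref, pan)
    expect_identical(unname(SummarizedExperiment::assay(out$counts)[
        "ETDHSKYDVGGAA", "t0"]), 10L)
    expect_identical(out$report$summary$n_too_short, 0L)

    # reads truncated before the last focal codon are all too_short
    short <- substr(refchr, 1, 900)
    expect_error(curateAndCount(list(t0 = rep(short, 5)), ref, pan),
                 "no reads passed")

    mixed <- curateAndCount(list(t0 = c(rep(refchr, 4), rep(short, 3))),
                            ref, pan)
    expect_identical(mixed$report$summary$n_too_short, 3L)
    expect_identical(mixed$report$summary$n_pass, 4L)

    expect_error(curateAndCount(list(t0 = character(0)), ref, pan),
                 "t0")
})

test_that("zero-error synthetic reads re-curate to the exact ground-truth
           counts", {
    truth <- smallReadTruth()
    se <- makeBenchmark(truth = truth, seed = 5, nClones = 2000,
                        emitReads = TRUE)
    cur <- curateAndCount(se@reads$reads, syntheticReference(),
                          defaultPanel())
    want <- SummarizedExperiment::assay(se@counts, "counts")
    got <- SummarizedExperiment::assay(cur$counts, "counts")
    expect_identical(sort(rownames(got)), sort(rownames(want)))
    expect_identical(got[rownames(want), colnames(want)], want)
    expect_identical(sum(cur$report$summary$n_too_short), 0L)
    expect_identical(sum(cur$report$summary$n_unalignable), 0L)
})

test_that("reads with indels are repaired back to their source allele", {
    truth <- smallReadTruth(perBaseError = 0, indelRate = 3e-4,
                            readTotals = c(t0 = 60, c1 = 40))
    se <- makeBenchmark(truth = truth, seed = 11, nClones = 1000,
                        emitReads = TRUE)
    cur <- curateAndCount(se@reads$reads, syntheticReference(),
                          defaultPanel())
    want <- SummarizedExperiment::assay(se@counts, "counts")
    got <- SummarizedExperiment::assay(cur$counts, "counts")
    expect_identical(got[rownames(want), colnames(want)], want)
})

test_that("focal-codon error rate matches the binomial expectation at a
           0.3% per-base error", {
    truth <- smallReadTruth(perBaseError = 0.003, indelRate = 0,
                            readTotals = c(t0 = 2000, c1 = 10))
    se <- makeBenchmark(truth = truth, seed = 21, nClones = 1500,
                        emitReads = TRUE)
    pan <- defaultPanel()
    ref <- syntheticReference()
    reads <- as.character(se@reads$reads$t0)
    tmap <- se@reads$truth
    tmap <- tmap[tmap$timepoint == "t0", ]
    pos <- panelPositions(pan)
    focalIdx <- as.vector(vapply(pos, function(p) (3 * p - 2):(3 * p),
                                 integer(3)))
    nErr <- 0L
    for (i in seq_along(reads)) {
        tmpl <- encodeAllele(tmap$allele_id[i], pan, ref)
        r <- reads[i]
        rc <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(r)))
        mmF <- sum(charToRaw(r) != charToRaw(tmpl))
        mmR <- sum(charToRaw(rc) != charToRaw(tmpl))
        oriented <- if (mmR < mmF) rc else r
        tv <- strsplit(tmpl, "")[[1]][focalIdx]
        rv <- strsplit(oriented, "")[[1]][focalIdx]
        if (any(tv != rv)) nErr <- nErr + 1L
    }
    p <- 1 - (1 - 0.003)^(3 * 13)
    phat <- nErr / length(reads)
    tol <- 3.5 * sqrt(p * (1 - p) / length(reads))
    expect_lt(abs(phat - p), tol)
})

test_that("an injected A234V hotspot is detected above a flat off-target
           background", {
    truth <- smallReadTruth(offtargetRate = 0.4,
                            readTotals = c(t0 = 800, c1 = 10))
    se <- makeBenchmark(truth = truth, seed = 31, nClones = 2000,
                        emitReads = TRUE,
                        hotspot = list(codon = 234, residue = "V",
                                       fraction = 0.05))
    cur <- curateAndCount(se@reads$reads, syntheticReference(),
                          defaultPanel())
    hits <- detectOfftargetHotspots(cur$report, minFold = 10)
    expect_gt(nrow(hits), 0)
    expect_identical(hits$substitution[1], "A234V")

    # without the hotspot the spectrum is flat and nothing is reported
    se0 <- makeBenchmark(truth = truth, seed = 32, nClones = 2000,
                         emitReads = TRUE)
    cur0 <- curateAndCount(se0@reads$reads, syntheticReference(),
                           defaultPanel())
    expect_identical(nrow(detectOfftargetHotspots(cur0$report,
                                                  minFold = 10)), 0L)
})
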