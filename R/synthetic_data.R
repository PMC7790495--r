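#' Library design frequencies per locus
#'
#' The residue frequencies the combinatorial library aims for at each
#' locus: an even wild-type/mutant split at binary loci, and, where a
#' degenerate codon is declared, the residue frequencies implied by a
#' uniform draw over its codon expansion (GRM at 319: G 1/2, E 1/4, D 1/4;
#' RRT at 320: G, D, N, S each 1/4).
#'
#' @param panel a [LociPanel-class].
#' @return list, one named numeric vector (summing to 1) per locus.
#' @export
designFrequencies <- function(panel) {
    lo <- panel@loci
    lapply(seq_len(nrow(lo)), function(j) {
        if (!is.na(lo$codon[j])) {
            exp <- expandDegenerateCodon(lo$codon[j])
            f <- table(exp$residue) / nrow(exp)
            setNames(as.numeric(f), names(f))
        } else {
            mut <- lo$mutants[[j]]
            setNames(c(0.5, rep(0.5 / length(mut), length(mut))),
                     c(lo$wt[j], mut))
        }
    })
}

# per-cycle selection coefficients (natural log) of the focal mutations:
# mostly beneficial (they were selected for the ancestral attI x attI
# activity), a few mildly deleterious, spanning roughly e^-0.35..e^1.1
.defaultSelection <- c(
    E103K = 0.80, T118S = 0.55, D161G = 0.45, H162Q = 0.30, S173R = 1.10,
    K219R = 0.20, Y220N = -0.15, D299E = 0.35, V315A = 0.10, A321G = -0.35,
    A329T = 0.50, G319D = -0.20, G319E = 0.60, G320D = 0.50, G320N = 0.45,
    G320S = -0.10)

#' Build a TruthModel for a synthetic experiment
#'
#' Presets bundle the study conditions the generator emulates:
#' \describe{
#'   \item{`"null"`}{multiplicative truth (no epistasis), time points t0
#'     and cycle 1 at the usable-read totals 67179 and 21622.}
#'   \item{`"full-course"`}{as `"null"` but six selection cycles with
#'     sequencing at t0/c1/c3/c6 (totals 67179, 21622, 31694, 18907).}
#'   \item{`"sign-epistasis"`}{as `"null"` plus one injected negative
#'     interaction, V315A x A321G with epsilon = -0.9, making V315A
#'     beneficial alone but the double mutant worse than the A321G
#'     single.}
#' }
#' All components can be overridden.
#'
#' @param preset one of `"null"`, `"full-course"`, `"sign-epistasis"`.
#' @param panel the [LociPanel-class] (default [defaultPanel()]).
#' @param selection named per-mutation ln selection coefficients.
#' @param epistasis data.frame `mutation_i`/`mutation_j`/`epsilon`.
#' @param offtargetRate fraction of clones carrying an unintended coding
#'   mutation (default 0.4).
#' @param perBaseError per-base substitution rate of the consensus reads
#'   (default 0.003).
#' @param indelRate per-base indel rate (default 5e-4).
#' @param readTotals named read totals per time point.
#' @param nCycles number of selection cycles.
#' @return a [TruthModel-class].
#' @export
truthModel <- function(preset = c("null", "full-course", "sign-epistasis"),
                       panel = defaultPanel(), selection = NULL,
                       epistasis = NULL, offtargetRate = 0.4,
                       perBaseError = 0.003, indelRate = 5e-4,
                       readTotals = NULL, nCycles = NULL) {
    preset <- match.arg(preset)
    if (is.null(selection)) selection <- .defaultSelection
    noEpi <- data.frame(mutation_i = character(0),
                        mutation_j = character(0), epsilon = numeric(0))
    if (is.null(epistasis))
        epistasis <- switch(preset,
            "sign-epistasis" = data.frame(mutation_i = "V315A",
                                          mutation_j = "A321G",
                                          epsilon = -0.9),
            noEpi)
    if (is.null(readTotals))
        readTotals <- switch(preset,
            "full-course" = c(t0 = 67179, c1 = 21622, c3 = 31694,
                             c6 = 18907),
            c(t0 = 67179, c1 = 21622))
    if (is.null(nCycles))
        nCycles <- switch(preset, "full-course" = 6L, 1L)
    new("TruthModel", panel = panel, design = designFrequencies(panel),
        selection = selection, epistasis = epistasis,
        offtargetRate = offtargetRate, perBaseError = perBaseError,
        indelRate = indelRate, readTotals = readTotals,
        nCycles = as.integer(nCycles), preset = preset)
}

#' Generate a combinatorial clone library
#'
#' Draws `nClones` clones locus-independently from the design frequencies
#' (equivalently, a multinomial over the enumerated allele space with
#' product frequencies) and marks a fraction `offtargetRate` of clones
#' with one unintended coding mutation placed uniformly over the non-focal
#' sense codons (random non-wild-type target residue).  An optional
#' hotspot (e.g. A234V in 5% of clones) can be injected on top.
#'
#' @param truth a [TruthModel-class].
#' @param nClones library size (default 5 x the theoretical allele space,
#'   the oversampling used when the real library was built).
#' @param hotspot optional list `(codon =, residue =, fraction =)`.
#' @param reference reference ORF used to pick substitution targets
#'   (default [syntheticReference()] of the truth's panel).
#' @return data.frame of clone groups: `allele_id`, `offtarget_codon`
#'   (`NA` = clean), `offtarget_res`, `n`.
#' @export
generateLibrary <- function(truth, nClones = NULL, hotspot = NULL,
                            reference = NULL) {
    pan <- truth@panel
    space <- enumerateAlleleSpace(pan)
    if (is.null(nClones)) nClones <- 5L * space$count
    if (nClones <= 0) stop("'nClones' must be positive")
    res <- .residueMatrix(space$ids, pan)
    f <- rep(1, space$count)
    for (j in seq_len(length(pan)))
        f <- f * truth@design[[j]][res[, j]]
    n <- rmultinom(1L, nClones, f)[, 1L]
    ids <- space$ids
    keep <- n > 0L
    ids <- ids[keep]; n <- n[keep]

    if (is.null(reference)) reference <- syntheticReference(pan)
    refchr <- as.character(reference)
    nAA <- nchar(refchr) %/% 3L
    nonfocal <- setdiff(2:(nAA - 1L), panelPositions(pan))
    aa <- sort(setdiff(unique(GENETIC_CODE), "*"))

    nClean <- n
    rows <- list()
    if (!is.null(hotspot)) {
        nh <- rbinom(length(n), n, hotspot$fraction)
        nClean <- nClean - nh
        hit <- nh > 0L
        if (any(hit))
            rows$hotspot <- data.frame(
                allele_id = ids[hit],
                offtarget_codon = as.integer(hotspot$codon),
                offtarget_res = hotspot$residue, n = nh[hit])
    }
    if (truth@offtargetRate > 0) {
        no <- rbinom(length(nClean), nClean, truth@offtargetRate)
        nClean <- nClean - no
        tot <- sum(no)
        if (tot > 0L) {
            alleleOf <- rep(ids, no)
            codon <- sample(nonfocal, tot, replace = TRUE)
            wtres <- GENETIC_CODE[substring(refchr, 3L * codon - 2L,
                                            3L * codon)]
            target <- vapply(wtres, function(w)
                sample(setdiff(aa, w), 1L), "")
            key <- paste(alleleOf, codon, target, sep = "|")
            agg <- table(key)
            parts <- strsplit(names(agg), "|", fixed = TRUE)
            rows$offtarget <- data.frame(
                allele_id = vapply(parts, `[`, "", 1L),
                offtarget_codon = as.integer(vapply(parts, `[`, "", 2L)),
                offtarget_res = vapply(parts, `[`, "", 3L),
                n = as.integer(agg))
        }
    }
    rows$clean <- data.frame(allele_id = ids[nClean > 0L],
                             offtarget_codon = NA_integer_,
                             offtarget_res = NA_character_,
                             n = nClean[nClean > 0L])
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' True genotype fitness of allele-IDs
#'
#' Linear-scale fitness under the truth model: `ln w = sum` of the carried
#' mutations' selection coefficients `+ sum` of the injected epistasis
#' terms whose two members are both carried.  The wild type gets `w = 1`.
#'
#' @param truth a [TruthModel-class].
#' @param ids character vector of allele-IDs over the truth's panel.
#' @return named numeric vector of linear-scale fitness.
#' @export
assignTrueFitness <- function(truth, ids) {
    pan <- truth@panel
    lo <- pan@loci
    res <- .residueMatrix(ids, pan)
    lnw <- numeric(length(ids))
    carriers <- list()
    for (j in seq_len(nrow(lo))) {
        for (m in lo$mutants[[j]]) {
            name <- paste0(lo$wt[j], lo$position[j], m)
            s <- truth@selection[name]
            if (is.na(s))
                stop("no selection coefficient for mutation ", name)
            mask <- res[, j] == m
            lnw <- lnw + s * mask
            carriers[[name]] <- mask
        }
    }
    ep <- truth@epistasis
    for (r in seq_len(nrow(ep))) {
        ci <- carriers[[ep$mutation_i[r]]]
        cj <- carriers[[ep$mutation_j[r]]]
        if (is.null(ci) || is.null(cj))
            stop("epistasis term refers to a mutation outside the panel")
        lnw <- lnw + ep$epsilon[r] * (ci & cj)
    }
    setNames(exp(lnw), ids)
}

#' Deterministic selection trajectory
#'
#' Propagates genotype frequencies through `nCycles` replicator updates
#' ([updateFrequencies()]) under fixed linear-scale fitness; noise from
#' the selection step itself is neglected (population sizes during
#' enrichment dwarf the read counts).
#'
#' @param f0 initial frequency vector (normalised internally).
#' @param w linear-scale fitness aligned with `f0`.
#' @param nCycles number of cycles.
#' @return matrix `length(f0) x (nCycles + 1)`, columns `cycle0` ...
#'   `cycle<n>`.
#' @export
runSelection <- function(f0, w, nCycles) {
    f0 <- f0 / sum(f0)
    out <- matrix(NA_real_, length(f0), nCycles + 1L,
                  dimnames = list(names(f0),
                                  paste0("cycle", 0:nCycles)))
    out[, 1L] <- f0
    f <- f0
    for (k in seq_len(nCycles)) {
        f <- updateFrequencies(f, w)
        out[, k + 1L] <- f
    }
    out
}

# map a time-point label to its selection cycle: t0 -> 0, c<k> -> k
.cycleOf <- function(tp) {
    if (tp == "t0") return(0L)
    k <- suppressWarnings(as.integer(sub("^c", "", tp)))
    if (is.na(k)) stop("cannot map time point '", tp, "' to a cycle; ",
                       "use labels 't0', 'c1', 'c2', ...")
    k
}

#' Simulate sequencing reads from a clone library
#'
#' Samples reads from the clone-group frequencies at each requested time
#' point, builds each clone's DNA (reference ORF with the allele's focal
#' codons and its off-target substitution, if any), then applies uniform
#' per-base substitution errors, uniform single-base indels, and a random
#' orientation.  The read-to-allele truth map is retained.
#'
#' @param library clone-group table from [generateLibrary()].
#' @param frequencies matrix from [runSelection()] (rows = clone groups).
#' @param truth the [TruthModel-class].
#' @param totals named read totals (default `truth@readTotals`); names map
#'   to cycles as `t0`/`c1`/...
#' @param reference the reference ORF (default [syntheticReference()]).
#' @param outdir if non-`NULL`, write one FASTQ (constant quality) per
#'   time point plus a `read_truth.tsv`.
#' @return list: `reads` (per-time-point [Biostrings::DNAStringSet]),
#'   `truth` (data.frame timepoint/read_id/allele_id), `files`.
#' @export
sequenceReads <- function(library, frequencies, truth,
                          totals = truth@readTotals, reference = NULL,
                          outdir = NULL) {
    if (is.null(reference)) reference <- syntheticReference(truth@panel)
    refchr <- as.character(reference)
    reads <- list(); files <- character(0); truthMaps <- list()
    tmplCache <- new.env(parent = emptyenv())
    for (tp in names(totals)) {
        cyc <- .cycleOf(tp)
        if (cyc + 1L > ncol(frequencies))
            stop("no simulated cycle for time point '", tp, "'")
        idx <- sample.int(nrow(library), totals[[tp]], replace = TRUE,
                          prob = frequencies[, cyc + 1L])
        seqs <- .buildReads(library, idx, truth, refchr, tmplCache)
        names(seqs) <- sprintf("%s_read%06d", tp, seq_along(seqs))
        dss <- DNAStringSet(seqs)
        reads[[tp]] <- dss
        truthMaps[[tp]] <- data.frame(timepoint = tp, read_id = names(seqs),
                                      allele_id = library$allele_id[idx])
        if (!is.null(outdir)) {
            if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
            fp <- file.path(outdir, paste0("reads_", tp, ".fastq"))
            writeXStringSet(dss, fp, format = "fastq",
                            qualities = PhredQuality(strrep("I", width(dss))))
            files <- c(files, fp)
        }
    }
    truthMap <- do.call(rbind, truthMaps)
    rownames(truthMap) <- NULL
    if (!is.null(outdir)) {
        fp <- file.path(outdir, "read_truth.tsv")
        write.table(truthMap, fp, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, fp)
    }
    list(reads = reads, truth = truthMap, files = files)
}

# clone template sequence: reference + focal codons + off-target codon
.cloneTemplate <- function(library, row, truth, refchr, cache) {
    key <- paste0(library$allele_id[row], "|",
                  library$offtarget_codon[row], "|",
                  library$offtarget_res[row])
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    seqchr <- encodeAllele(library$allele_id[row], truth@panel, refchr)
    oc <- library$offtarget_codon[row]
    if (!is.na(oc))
        substr(seqchr, 3L * oc - 2L, 3L * oc) <-
            .codonFor(library$offtarget_res[row])
    tmpl <- strsplit(seqchr, "", fixed = TRUE)[[1]]
    cache[[key]] <- tmpl
    tmpl
}

.buildReads <- function(library, idx, truth, refchr, cache) {
    bases <- c("A", "C", "G", "T")
    e <- truth@perBaseError
    ir <- truth@indelRate
    vapply(idx, function(row) {
        x <- .cloneTemplate(library, row, truth, refchr, cache)
        L <- length(x)
        nSub <- rbinom(1L, L, e)
        if (nSub > 0L) {
            at <- sample.int(L, nSub)
            for (p in at)
                x[p] <- sample(setdiff(bases, x[p]), 1L)
        }
        nInd <- rbinom(1L, L, ir)
        if (nInd > 0L) {
            for (k in seq_len(nInd)) {
                p <- sample.int(length(x), 1L)
                if (runif(1L) < 0.5) {
                    x <- append(x, sample(bases, 1L), after = p)
                } else {
                    x <- x[-p]
                }
            }
        }
        s <- paste(x, collapse = "")
        if (runif(1L) < 0.5)
            s <- as.character(reverseComplement(DNAString(s)))
        s
    }, "")
}

#' Generate a full ground-truthed benchmark experiment
#'
#' One call produces a reproducible synthetic experiment for a preset:
#' clone library, deterministic selection trajectory, per-time-point
#' sampled allele counts (and, optionally, error-bearing reads), plus the
#' truth tables downstream estimates are judged against.  All randomness
#' flows from `seed`; the same seed gives byte-identical outputs.
#'
#' @param preset passed to [truthModel()] (`"null"`, `"full-course"`,
#'   `"sign-epistasis"`).
#' @param seed integer seed.
#' @param nClones library size (default 5 x allele space).
#' @param emitReads also simulate reads with sequencing errors (slower;
#'   scale `readTotals` down via `truth`).
#' @param outdir directory for FASTQ/TSV output (implies `emitReads`).
#' @param hotspot optional hotspot spec for [generateLibrary()].
#' @param truth optionally a pre-built/overridden [TruthModel-class]
#'   (ignores `preset`).
#' @return a [SyntheticExperiment-class].
#' @examples
#' se <- makeBenchmark("null", seed = 1,
#'                     truth = truthModel("null",
#'                                        readTotals = c(t0 = 2000, c1 = 1000)))
#' se
#' @export
makeBenchmark <- function(preset = c("null", "full-course",
                                     "sign-epistasis"),
                          seed = 1L, nClones = NULL, emitReads = FALSE,
                          outdir = NULL, hotspot = NULL, truth = NULL) {
    if (is.null(truth)) truth <- truthModel(match.arg(preset))
    set.seed(seed)
    lib <- generateLibrary(truth, nClones = nClones, hotspot = hotspot)
    wAllele <- assignTrueFitness(truth, unique(lib$allele_id))
    wRow <- wAllele[lib$allele_id]
    freqs <- runSelection(lib$n, wRow, truth@nCycles)

    totals <- truth@readTotals
    cnt <- matrix(0L, length(wAllele), length(totals),
                  dimnames = list(names(wAllele), names(totals)))
    readIdx <- list()
    for (tp in names(totals)) {
        cyc <- .cycleOf(tp)
        if (cyc > truth@nCycles)
            stop("time point '", tp, "' lies beyond the simulated cycles")
        idx <- sample.int(nrow(lib), totals[[tp]], replace = TRUE,
                          prob = freqs[, cyc + 1L])
        readIdx[[tp]] <- idx
        tab <- tapply(rep(1L, length(idx)), lib$allele_id[idx], sum)
        cnt[names(tab), tp] <- as.integer(tab)
    }
    observed <- rowSums(cnt) > 0L
    counts <- AlleleCounts(cnt[observed, , drop = FALSE], truth@panel)

    reads <- list()
    if (emitReads || !is.null(outdir)) {
        refchr <- as.character(syntheticReference(truth@panel))
        cache <- new.env(parent = emptyenv())
        rl <- list(); tm <- list(); files <- character(0)
        for (tp in names(totals)) {
            seqs <- .buildReads(lib, readIdx[[tp]], truth, refchr, cache)
            names(seqs) <- sprintf("%s_read%06d", tp, seq_along(seqs))
            dss <- DNAStringSet(seqs)
            rl[[tp]] <- dss
            tm[[tp]] <- data.frame(timepoint = tp, read_id = names(seqs),
                                   allele_id = lib$allele_id[readIdx[[tp]]])
            if (!is.null(outdir)) {
                if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
                fp <- file.path(outdir, paste0("reads_", tp, ".fastq"))
                writeXStringSet(dss, fp, format = "fastq",
                                qualities = PhredQuality(strrep("I",
                                                                width(dss))))
                files <- c(files, fp)
            }
        }
        truthMap <- do.call(rbind, tm); rownames(truthMap) <- NULL
        reads <- list(reads = rl, truth = truthMap, files = files)
        if (!is.null(outdir)) {
            writePanel(truth@panel, file.path(outdir, "panel.tsv"))
            write.table(truthMap, file.path(outdir, "read_truth.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }

    fm <- focalMutations(truth@panel)
    singlesTruth <- data.frame(mutation = fm$mutation,
                               W_true = unname(truth@selection[fm$mutation]))
    cmb <- t(combn(nrow(fm), 2L))
    pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    pairsTruth <- data.frame(mutation_i = fm$mutation[cmb[, 1L]],
                             mutation_j = fm$mutation[cmb[, 2L]],
                             epsilon_true = 0)
    if (nrow(truth@epistasis)) {
        hitKey <- pairKey(truth@epistasis$mutation_i,
                          truth@epistasis$mutation_j)
        m <- match(pairKey(pairsTruth$mutation_i, pairsTruth$mutation_j),
                   hitKey)
        pairsTruth$epsilon_true[!is.na(m)] <-
            truth@epistasis$epsilon[m[!is.na(m)]]
    }
    new("SyntheticExperiment", truth = truth, library = lib,
        frequencies = freqs, counts = counts,
        truthTables = list(singles = singlesTruth, pairs = pairsTruth,
                           alleleFitness = wAllele),
        reads = reads)
}
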