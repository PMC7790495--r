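#' Filter a count table for the epistasis analysis
#'
#' Applies the data-processing rule used before fitness/epistasis
#' estimation: alleles must be wild type at every multi-mutant locus (the
#' degenerate-codon positions, 319 and 320 on the default panel) and wild
#' type or the expected single mutant at every other locus.  On the default
#' panel this retains alleles over the 11 binary loci, i.e. 11 focal
#' mutations and 55 unordered pairs.
#'
#' @param x an [AlleleCounts-class].
#' @param wtOnlyPositions positions forced to wild type; defaults to the
#'   loci with more than one allowed mutant residue.
#' @return the filtered [AlleleCounts-class] (metadata notes the filter).
#' @export
filterForEpistasis <- function(x, wtOnlyPositions = NULL) {
    pan <- panel(x)
    lo <- pan@loci
    if (is.null(wtOnlyPositions))
        wtOnlyPositions <- lo$position[lengths(lo$mutants) > 1L]
    res <- .residueMatrix(alleleIDs(x), pan)
    keep <- rep(TRUE, nrow(res))
    for (j in seq_len(ncol(res))) {
        ok <- if (lo$position[j] %in% wtOnlyPositions)
            res[, j] == lo$wt[j]
        else res[, j] %in% c(lo$wt[j], lo$mutants[[j]])
        keep <- keep & ok
    }
    if (!any(keep))
        stop("no alleles left after the epistasis filter")
    out <- x[keep, ]
    metadata(out)$epistasisFilter <- list(wtOnlyPositions = wtOnlyPositions)
    out
}

#' Focal mutations retained by the epistasis filter
#'
#' The single expected mutation per binary locus (loci forced to wild type
#' by [filterForEpistasis()] are excluded).  For the default panel this is
#' the 11-mutation set behind the 55 analysed pairs.
#'
#' @param panel a [LociPanel-class].
#' @param wtOnlyPositions as in [filterForEpistasis()].
#' @return data.frame with columns `locus` (index), `position`, `wt`,
#'   `residue`, `mutation`.
#' @export
focalMutations <- function(panel, wtOnlyPositions = NULL) {
    lo <- panel@loci
    if (is.null(wtOnlyPositions))
        wtOnlyPositions <- lo$position[lengths(lo$mutants) > 1L]
    keep <- !(lo$position %in% wtOnlyPositions)
    idx <- which(keep)
    do.call(rbind, lapply(idx, function(j)
        data.frame(locus = j, position = lo$position[j], wt = lo$wt[j],
                   residue = lo$mutants[[j]],
                   mutation = paste0(lo$wt[j], lo$position[j],
                                     lo$mutants[[j]]))))
}

# log ratio-of-ratios fitness with the shared pseudocount policy
.fitnessW <- function(mut0, wt0, mut1, wt1, pseudocount) {
    if (pseudocount == 0 && (mut0 == 0 || wt0 == 0 || mut1 == 0 || wt1 == 0))
        return(NA_real_)
    log(((mut1 + pseudocount) / (wt1 + pseudocount)) /
        ((mut0 + pseudocount) / (wt0 + pseudocount)))
}

#' Marginal fitness of a focal mutation
#'
#' The relative fitness effect W of a mutation across one selection
#' interval, aggregated over genetic backgrounds:
#' `W = ln[(mut_t1/wt_t1) / (mut_t0/wt_t0)]`, where `mut_t` sums the counts
#' of all alleles carrying `residue` at `position` and `wt_t` the counts of
#' alleles wild type there.  Alleles with an unexpected residue at the
#' locus belong to neither group.  The pseudocount (default 0.5) is added
#' to each of the four aggregates; with `pseudocount = 0`, a zero aggregate
#' makes W `NA` (flagged, not dropped).
#'
#' @param x an [AlleleCounts-class] (normally already filtered with
#'   [filterForEpistasis()]).
#' @param position focal protein position.
#' @param residue the mutant residue whose fitness is estimated.
#' @param tFrom,tTo time-point labels (default: first two columns).
#' @param pseudocount added to each count aggregate (default 0.5).
#' @return one-row data.frame: `position`, `residue`, `W`, `mut_t0`,
#'   `wt_t0`, `mut_t1`, `wt_t1`, `coverage_t0`, `coverage_t1`,
#'   `undefined`.
#' @export
marginalFitness <- function(x, position, residue,
                            tFrom = timepoints(x)[1L],
                            tTo = timepoints(x)[2L], pseudocount = 0.5) {
    grp <- .locusGroups(x, position, residue)
    .fitnessRow(x, grp$mut, grp$wt, tFrom, tTo, pseudocount,
                position = position, residue = residue)
}

#' Joint fitness of a mutation pair
#'
#' As [marginalFitness()], with the mutant group restricted to alleles
#' carrying both mutations and the reference group to alleles wild type at
#' both loci; alleles carrying exactly one of the two mutations belong to
#' neither group.
#'
#' @inheritParams marginalFitness
#' @param position_i,residue_i,position_j,residue_j the two mutations.
#' @return one-row data.frame as for [marginalFitness()], with the pair in
#'   `position`/`residue` (comma-joined).
#' @export
pairFitness <- function(x, position_i, residue_i, position_j, residue_j,
                        tFrom = timepoints(x)[1L],
                        tTo = timepoints(x)[2L], pseudocount = 0.5) {
    gi <- .locusGroups(x, position_i, residue_i)
    gj <- .locusGroups(x, position_j, residue_j)
    .fitnessRow(x, gi$mut & gj$mut, gi$wt & gj$wt, tFrom, tTo, pseudocount,
                position = paste(position_i, position_j, sep = ","),
                residue = paste(residue_i, residue_j, sep = ","))
}

.locusGroups <- function(x, position, residue) {
    pan <- panel(x)
    lo <- pan@loci
    j <- match(position, lo$position)
    if (is.na(j)) stop("position ", position, " is not a panel locus")
    allowed <- c(lo$wt[j], lo$mutants[[j]])
    if (!residue %in% allowed)
        stop("residue '", residue, "' is not in the designed alphabet at ",
             position)
    res <- .residueMatrix(alleleIDs(x), pan)[, j]
    excluded <- !(res %in% allowed)
    list(mut = res == residue & !excluded, wt = res == lo$wt[j] & !excluded)
}

.fitnessRow <- function(x, mutSel, wtSel, tFrom, tTo, pseudocount,
                        position, residue) {
    cn <- assay(x, "counts")
    if (!all(c(tFrom, tTo) %in% colnames(cn)))
        stop("time points not found in the count table")
    if (match(tFrom, colnames(cn)) >= match(tTo, colnames(cn)))
        stop("'tFrom' must precede 'tTo'")
    mut0 <- sum(cn[mutSel, tFrom]); mut1 <- sum(cn[mutSel, tTo])
    wt0 <- sum(cn[wtSel, tFrom]);   wt1 <- sum(cn[wtSel, tTo])
    W <- .fitnessW(mut0, wt0, mut1, wt1, pseudocount)
    data.frame(position = position, residue = residue, W = W,
               mut_t0 = mut0, wt_t0 = wt0, mut_t1 = mut1, wt_t1 = wt1,
               coverage_t0 = mut0 + wt0, coverage_t1 = mut1 + wt1,
               undefined = is.na(W))
}

#' Fitness of every retained focal mutation
#'
#' Convenience wrapper computing [marginalFitness()] for each mutation in
#' [focalMutations()]; the result feeds
#' [genotypeFitnessFromSingles()] and [simulateNull()].
#'
#' @inheritParams marginalFitness
#' @return data.frame, one row per focal mutation, columns as
#'   [marginalFitness()] plus `mutation`.
#' @export
singleFitnessTable <- function(x, tFrom = timepoints(x)[1L],
                               tTo = timepoints(x)[2L], pseudocount = 0.5) {
    fm <- focalMutations(panel(x))
    out <- do.call(rbind, lapply(seq_len(nrow(fm)), function(i)
        marginalFitness(x, fm$position[i], fm$residue[i], tFrom, tTo,
                        pseudocount)))
    out$mutation <- fm$mutation
    out
}

#' Pairwise epistasis between focal mutations
#'
#' For each unordered pair (i, j) of retained focal mutations, computes
#' `epsilon = W_ij - (W_i + W_j)` over one selection interval.  Only the
#' first interval (t0 to cycle 1) gives estimates whose genetic-background
#' profiles are comparable across mutations; requesting a later interval
#' works but warns.  Confidence columns are `NA` until [assignConfidence()]
#' is run with a [simulateNull()] distribution.
#'
#' @inheritParams marginalFitness
#' @param pairs optional two-column matrix/data.frame of mutation names to
#'   restrict to (default: all pairs).
#' @return data.frame, one row per pair: `mutation_i`, `mutation_j`,
#'   positions/residues, `W_i`, `W_j`, `W_ij`, `epsilon`, `undefined`,
#'   `confidence`, `sig95`, `sig99`, `n_sims`.
#' @export
pairwiseEpistasis <- function(x, tFrom = timepoints(x)[1L],
                              tTo = timepoints(x)[2L], pseudocount = 0.5,
                              pairs = NULL) {
    if (match(tFrom, timepoints(x)) != 1L || match(tTo, timepoints(x)) != 2L)
        warning("epistasis estimates are only strictly comparable over the ",
                "first selection interval; the genetic-background profile ",
                "of each focal mutation drifts at later time points")
    fm <- focalMutations(panel(x))
    singles <- singleFitnessTable(x, tFrom, tTo, pseudocount)
    cmb <- t(combn(nrow(fm), 2L))
    if (!is.null(pairs)) {
        pairs <- as.matrix(pairs)
        keyWant <- paste(pmin(pairs[, 1L], pairs[, 2L]),
                         pmax(pairs[, 1L], pairs[, 2L]))
        keyAll <- paste(pmin(fm$mutation[cmb[, 1L]], fm$mutation[cmb[, 2L]]),
                        pmax(fm$mutation[cmb[, 1L]], fm$mutation[cmb[, 2L]]))
        cmb <- cmb[keyAll %in% keyWant, , drop = FALSE]
    }
    rows <- lapply(seq_len(nrow(cmb)), function(r) {
        i <- cmb[r, 1L]; j <- cmb[r, 2L]
        pf <- pairFitness(x, fm$position[i], fm$residue[i],
                          fm$position[j], fm$residue[j], tFrom, tTo,
                          pseudocount)
        Wi <- singles$W[i]; Wj <- singles$W[j]
        eps <- pf$W - (Wi + Wj)
        data.frame(mutation_i = fm$mutation[i], mutation_j = fm$mutation[j],
                   position_i = fm$position[i], residue_i = fm$residue[i],
                   position_j = fm$position[j], residue_j = fm$residue[j],
                   W_i = Wi, W_j = Wj, W_ij = pf$W, epsilon = eps,
                   mut_t0 = pf$mut_t0, wt_t0 = pf$wt_t0,
                   mut_t1 = pf$mut_t1, wt_t1 = pf$wt_t1,
                   undefined = is.na(eps), confidence = NA_real_,
                   sig95 = NA, sig99 = NA, n_sims = NA_integer_)
    })
    do.call(rbind, rows)
}

#' Genetic-background profile of a focal mutation
#'
#' For the alleles carrying a focal mutation (and, separately, for the
#' wild-type-at-locus reference set), the count-weighted residue
#' composition at every other panel locus at one time point.  Similar
#' profiles across focal mutations are what make background-averaged
#' fitness estimates comparable.
#'
#' @inheritParams marginalFitness
#' @param timepoint which column to weight by (default first).
#' @return list with `mutant` and `reference`: matrices (other loci x
#'   residues) of frequencies summing to 1 per row, or an empty list
#'   (flagged via attribute `empty`) when the group has no carriers.
#' @export
backgroundProfile <- function(x, position, residue,
                              timepoint = timepoints(x)[1L]) {
    grp <- .locusGroups(x, position, residue)
    pan <- panel(x)
    j <- match(position, pan@loci$position)
    prof <- function(sel) {
        w <- assay(x, "counts")[sel, timepoint]
        if (sum(w) == 0) return(structure(list(), empty = TRUE))
        res <- .residueMatrix(alleleIDs(x)[sel], pan)[, -j, drop = FALSE]
        letters <- sort(unique(as.vector(res)))
        m <- sapply(letters, function(a)
            colSums(matrix(w * (res == a), nrow = length(w))))
        m <- matrix(m, ncol = length(letters),
                    dimnames = list(pan@loci$position[-j], letters))
        m / sum(w)
    }
    list(mutant = prof(grp$mut), reference = prof(grp$wt))
}

#' Residue composition per panel locus
#'
#' The count-weighted residue frequencies at each focal position at one
#' time point: the numeric table behind a per-position sequence logo of
#' the library.
#'
#' @inheritParams backgroundProfile
#' @return matrix (loci x residues) of frequencies; rows sum to 1.
#' @export
positionComposition <- function(x, timepoint = timepoints(x)[1L]) {
    pan <- panel(x)
    w <- assay(x, "counts")[, timepoint]
    if (sum(w) == 0) stop("no counts at time point '", timepoint, "'")
    res <- .residueMatrix(alleleIDs(x), pan)
    letters <- sort(unique(as.vector(res)))
    m <- sapply(letters, function(a)
        colSums(matrix(w * (res == a), nrow = length(w))))
    m <- matrix(m, ncol = length(letters),
                dimnames = list(pan@loci$position, letters))
    m / sum(w)
}

#' Allele diversity across time points
#'
#' Number of distinct allele-IDs observed and Shannon entropy (nats) of the
#' allele frequency distribution at each time point; selection drives both
#' down as the fittest combinations take over.
#'
#' @param x an [AlleleCounts-class] with at least two time points.
#' @return data.frame: `timepoint`, `richness`, `shannon`.
#' @export
diversityTrajectory <- function(x) {
    cn <- assay(x, "counts")
    if (ncol(cn) < 2L) stop("need at least two time points")
    out <- lapply(colnames(cn), function(tp) {
        w <- cn[, tp]
        p <- w[w > 0] / sum(w)
        data.frame(timepoint = tp, richness = sum(w > 0),
                   shannon = -sum(p * log(p)))
    })
    do.call(rbind, out)
}
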