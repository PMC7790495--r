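#' Genotype fitness under the no-epistasis assumption
#'
#' Assigns every allele a linear-scale relative fitness from single-focal-
#' mutation estimates only: `w_a = prod exp(W_i)` over the mutations the
#' allele carries; the wild-type allele gets `w = 1`.  Alleles carrying a
#' mutation whose W is undefined (or absent from `singles`) get `NA` and
#' are reported with a warning — the caller decides whether to drop them.
#'
#' @param singles data.frame with columns `mutation` and `W`, as from
#'   [singleFitnessTable()].
#' @param ids character vector of allele-IDs.
#' @param panel the [LociPanel-class].
#' @return named numeric vector of linear-scale fitness, one per allele.
#' @export
genotypeFitnessFromSingles <- function(singles, ids, panel) {
    Wlut <- setNames(singles$W, singles$mutation)
    muts <- alleleMutations(ids, panel)
    w <- vapply(muts, function(m) {
        if (!length(m)) return(1)
        Wi <- Wlut[m]
        if (anyNA(Wi)) return(NA_real_)
        exp(sum(Wi))
    }, numeric(1))
    names(w) <- ids
    if (anyNA(w))
        warning(sum(is.na(w)), " allele(s) carry mutations with undefined W",
                " and were assigned NA fitness")
    w
}

#' One deterministic selection update of allele frequencies
#'
#' The replicator update `f'_a = f_a w_a / sum_b f_b w_b`: frequencies
#' after one enrichment cycle under relative fitness `w`, normalised by the
#' mean population fitness.  Iterating `n` cycles equals a single update
#' with `w^n`.
#'
#' @param f non-negative frequency vector (need not be normalised; must not
#'   be all zero).
#' @param w positive linear-scale fitness vector aligned with `f`.
#' @return frequency vector summing to 1.
#' @examples
#' updateFrequencies(c(0.5, 0.5), c(2, 1))  # 2/3, 1/3
#' @export
updateFrequencies <- function(f, w) {
    if (length(f) != length(w))
        stop("'f' and 'w' must be aligned")
    if (!is.null(names(f)) && !is.null(names(w)) &&
        !identical(names(f), names(w)))
        stop("names of 'f' and 'w' disagree")
    if (any(f < 0) || sum(f) == 0)
        stop("'f' must be non-negative and not all zero")
    x <- f * w
    x / sum(x)
}

#' Poisson resampling of read counts
#'
#' Draws each allele's count from a Poisson with mean equal to its
#' frequency times `targetTotal`.  With the default `targetTotal =
#' sum(counts)` the mean is simply the observed count, the scheme used to
#' regenerate time-0 counts in the null simulation.
#'
#' @param counts non-negative numeric vector of observed counts.
#' @param targetTotal expected total of the resample (default: observed
#'   total).
#' @return integer vector of resampled counts (zero counts stay zero).
#' @export
poissonResample <- function(counts, targetTotal = sum(counts)) {
    if (targetTotal <= 0) stop("'targetTotal' must be positive")
    mu <- counts / sum(counts) * targetTotal
    out <- rpois(length(counts), mu)
    names(out) <- names(counts)
    out
}

# membership matrices shared by the vectorised estimators: columns are
# focal mutations (singles) and unordered pairs (carriers / double-WT)
.membership <- function(x) {
    pan <- panel(x)
    fm <- focalMutations(pan)
    res <- .residueMatrix(alleleIDs(x), pan)
    K <- nrow(fm)
    Ms <- matrix(0, nrow(res), K)   # carries mutation k
    Ws <- matrix(0, nrow(res), K)   # wild type at locus of k
    for (k in seq_len(K)) {
        col <- res[, fm$locus[k]]
        Ms[, k] <- col == fm$residue[k]
        Ws[, k] <- col == fm$wt[k]
    }
    cmb <- t(combn(K, 2L))
    P <- nrow(cmb)
    Mp <- matrix(0, nrow(res), P)
    Wp <- matrix(0, nrow(res), P)
    for (p in seq_len(P)) {
        Mp[, p] <- Ms[, cmb[p, 1L]] * Ms[, cmb[p, 2L]]
        Wp[, p] <- Ws[, cmb[p, 1L]] * Ws[, cmb[p, 2L]]
    }
    list(fm = fm, Ms = Ms, Ws = Ws, Mp = Mp, Wp = Wp, cmb = cmb,
         pairNames = paste(fm$mutation[cmb[, 1L]], fm$mutation[cmb[, 2L]],
                           sep = ":"))
}

.vecW <- function(m0, w0, m1, w1, pc) {
    W <- log(((m1 + pc) / (w1 + pc)) / ((m0 + pc) / (w0 + pc)))
    if (pc == 0)
        W[m0 == 0 | w0 == 0 | m1 == 0 | w1 == 0] <- NA_real_
    W
}

#' Simulate the selection-sequencing experiment under no epistasis
#'
#' The Poisson-resampling null model.  Each replicate (1) resamples the
#' observed t0 counts by Poisson draws (mean = observed count) to simulate
#' true genotype frequencies, (2) propagates them through one selection
#' cycle with the no-epistasis genotype fitness built from the real
#' single-mutation estimates (`f1 = f0 w / wbar`), (3) draws simulated t1
#' counts Poisson at the real t1 total, and (4) re-estimates every single
#' and pair W and every pairwise epsilon from the real t0 counts plus the
#' simulated t1 counts, with the same pseudocount policy as the real-data
#' estimator.  The resulting per-pair epsilon distributions calibrate the
#' real estimates via [assignConfidence()].
#'
#' @param x a filtered [AlleleCounts-class] (apply [filterForEpistasis()]
#'   first; filtering precedes simulation).
#' @param tFrom,tTo the selection interval (default: first two time
#'   points).
#' @param nSims number of replicates (default 1000).
#' @param seed integer seed governing the whole run; replicate r uses a
#'   sub-stream derived from it, so results do not depend on execution
#'   order.
#' @param pseudocount as in [marginalFitness()]; must match the policy used
#'   for the real estimates so confidences are comparable.
#' @return a `NullDistribution`: list with `eps` (nSims x pairs matrix of
#'   simulated epsilon), `pairNames`, `nUndefined` per pair (replicates
#'   with zero carriers at pseudocount 0, excluded from `eps`), `nSims`,
#'   `quantiles`, and the run parameters.
#' @export
simulateNull <- function(x, tFrom = timepoints(x)[1L],
                         tTo = timepoints(x)[2L], nSims = 1000L,
                         seed = NULL, pseudocount = 0.5) {
    cn <- assay(x, "counts")
    stopifnot(all(c(tFrom, tTo) %in% colnames(cn)))
    c0 <- cn[, tFrom]
    T1 <- sum(cn[, tTo])
    mem <- .membership(x)
    singles <- singleFitnessTable(x, tFrom, tTo, pseudocount)
    w <- genotypeFitnessFromSingles(singles, alleleIDs(x), panel(x))
    usable <- !is.na(w)
    if (!all(usable)) {
        x0 <- c0; x0[!usable] <- 0
        c0sim <- x0
    } else c0sim <- c0
    w[!usable] <- 0

    # real-t0 aggregates are constant across replicates (estimation reuses
    # the real t0 counts; resampling only feeds the frequency propagation)
    m0s <- drop(crossprod(mem$Ms, c0)); w0s <- drop(crossprod(mem$Ws, c0))
    m0p <- drop(crossprod(mem$Mp, c0)); w0p <- drop(crossprod(mem$Wp, c0))

    if (!is.null(seed)) set.seed(seed)
    subseeds <- sample.int(.Machine$integer.max - 1L, nSims)
    P <- ncol(mem$Mp)
    eps <- matrix(NA_real_, nSims, P, dimnames = list(NULL, mem$pairNames))
    i1 <- mem$cmb[, 1L]; i2 <- mem$cmb[, 2L]
    for (r in seq_len(nSims)) {
        set.seed(subseeds[r])
        c0s <- rpois(length(c0sim), c0sim)
        fw <- c0s * w
        s <- sum(fw)
        if (s == 0) next
        c1s <- rpois(length(fw), fw / s * T1)
        m1s <- drop(crossprod(mem$Ms, c1s))
        w1s <- drop(crossprod(mem$Ws, c1s))
        m1p <- drop(crossprod(mem$Mp, c1s))
        w1p <- drop(crossprod(mem$Wp, c1s))
        Wsng <- .vecW(m0s, w0s, m1s, w1s, pseudocount)
        Wpar <- .vecW(m0p, w0p, m1p, w1p, pseudocount)
        eps[r, ] <- Wpar - (Wsng[i1] + Wsng[i2])
    }
    nUndefined <- colSums(is.na(eps))
    if (any(nUndefined > 0.05 * nSims))
        warning("more than 5% of replicates gave undefined epistasis for ",
                sum(nUndefined > 0.05 * nSims), " pair(s)")
    out <- list(eps = eps, pairNames = mem$pairNames,
                pairs = data.frame(mutation_i = mem$fm$mutation[i1],
                                   mutation_j = mem$fm$mutation[i2]),
                nUndefined = nUndefined, nSims = nSims,
                quantiles = apply(eps, 2L, quantile,
                                  probs = c(0.01, 0.05, 0.5, 0.95, 0.99),
                                  na.rm = TRUE),
                tFrom = tFrom, tTo = tTo, pseudocount = pseudocount,
                seed = seed)
    class(out) <- "NullDistribution"
    out
}

#' @export
print.NullDistribution <- function(x, ...) {
    cat(sprintf("Poisson-resampling null distribution: %d pairs x %d sims (%s -> %s)\n",
                length(x$pairNames), x$nSims, x$tFrom, x$tTo))
    if (any(x$nUndefined > 0))
        cat(sprintf("  undefined replicates excluded for %d pair(s)\n",
                    sum(x$nUndefined > 0)))
    invisible(x)
}

#' Assign null-model confidence to epistasis estimates
#'
#' One-sided empirical confidence of each real epistasis estimate against
#' its no-epistasis null distribution: for positive epsilon, the fraction
#' of simulated estimates below the real one; for negative epsilon, the
#' fraction above (ties count one half).  A confidence of exactly 1 only
#' bounds the level at `1 - 1/n_sims`; the `confidence_label` column spells
#' this out.  Significance flags are set at the 95% and 99% levels.  The
#' column `null_exceedance` stores the plain null-CDF position
#' `F_null(epsilon_real)`, the quantity that is uniform on (0,1) under the
#' null and therefore the right input for calibration checks.
#'
#' @param epsTable data.frame from [pairwiseEpistasis()].
#' @param nullDist a `NullDistribution` from [simulateNull()].
#' @return `epsTable` with `confidence`, `confidence_label`, `sig95`,
#'   `sig99`, `n_sims` and `null_exceedance` filled in.
#' @export
assignConfidence <- function(epsTable, nullDist) {
    key <- paste(epsTable$mutation_i, epsTable$mutation_j, sep = ":")
    idx <- match(key, nullDist$pairNames)
    if (anyNA(idx))
        stop("pairs in 'epsTable' missing from the null distribution: ",
             paste(key[is.na(idx)], collapse = ", "))
    epsTable$confidence <- NA_real_
    epsTable$confidence_label <- NA_character_
    epsTable$null_exceedance <- NA_real_
    epsTable$sig95 <- NA
    epsTable$sig99 <- NA
    epsTable$n_sims <- NA_integer_
    for (r in seq_len(nrow(epsTable))) {
        sims <- nullDist$eps[, idx[r]]
        sims <- sims[!is.na(sims)]
        n <- length(sims)
        e <- epsTable$epsilon[r]
        if (is.na(e) || n == 0L) next
        below <- sum(sims < e) + 0.5 * sum(sims == e)
        conf <- if (e > 0) below / n
                else if (e < 0) (n - below) / n
                else 0.5
        epsTable$confidence[r] <- conf
        epsTable$null_exceedance[r] <- below / n
        epsTable$confidence_label[r] <- if (conf == 1)
            sprintf("> %.4f", 1 - 1 / n) else sprintf("%.4f", conf)
        epsTable$sig95[r] <- conf >= 0.95
        epsTable$sig99[r] <- conf >= 0.99
        epsTable$n_sims[r] <- n
    }
    epsTable
}
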