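#' Recombination frequency from colony counts
#'
#' The plate-assay readout: the ratio of recombinant colonies (growing
#' without DAP, or transconjugants carrying the incoming marker) to the
#' total count.  Vectorised over replicates.
#'
#' @param recombinants non-negative counts of recombinant colonies.
#' @param total positive total colony counts; `recombinants <= total`.
#' @return frequencies in \[0, 1\].
#' @examples
#' recombinationFrequency(10, 1000)  # 0.01
#' @export
recombinationFrequency <- function(recombinants, total) {
    if (any(total <= 0)) stop("'total' must be positive")
    if (any(recombinants < 0) || any(recombinants > total))
        stop("'recombinants' must lie in [0, total]")
    recombinants / total
}

#' Summarise replicate assay measurements
#'
#' Mean and standard error of the recombination frequency over independent
#' replicates (at least three are expected), per allele and reaction.
#'
#' @param data data.frame with columns `allele`, `reaction`, and either
#'   `frequency` or the raw counts `recombinants` + `total`.
#' @return data.frame: `allele`, `reaction`, `n`, `mean`, `se`.
#' @export
assaySummary <- function(data) {
    if (!"frequency" %in% colnames(data))
        data$frequency <- recombinationFrequency(data$recombinants,
                                                 data$total)
    if (any(data$frequency < 0 | data$frequency > 1))
        stop("frequencies must lie in [0, 1]")
    sp <- split(data, list(data$allele, data$reaction), drop = TRUE)
    out <- lapply(sp, function(d)
        data.frame(allele = d$allele[1L], reaction = d$reaction[1L],
                   n = nrow(d), mean = mean(d$frequency),
                   se = if (nrow(d) > 1L) sd(d$frequency) / sqrt(nrow(d))
                        else NA_real_))
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Fold change in recombination frequency
#'
#' Ratio of a mutant's mean recombination frequency to a reference
#' allele's, with the standard error propagated by the first-order
#' (delta-method) quotient rule:
#' `se = fold * sqrt((se_mut/mean_mut)^2 + (se_ref/mean_ref)^2)`.
#'
#' @param mutant,reference mean frequencies (reference must be positive).
#' @param mutantSE,referenceSE replicate standard errors (optional; `NA`
#'   propagates to an `NA` fold SE).
#' @return one-row data.frame: `fold`, `se`.
#' @examples
#' foldChange(1.85e-2, 1.82e-4)  # ~101.6, prints as a 100-fold increase
#' @export
foldChange <- function(mutant, reference, mutantSE = NA_real_,
                       referenceSE = NA_real_) {
    if (reference <= 0) stop("'reference' frequency must be positive")
    fold <- mutant / reference
    se <- fold * sqrt((mutantSE / mutant)^2 + (referenceSE / reference)^2)
    data.frame(fold = fold, se = se)
}

#' Multiplicative (no-epistasis) expectation of combined fold increases
#'
#' Under independent loci the expected fold increase of a combination
#' mutant is the product of its members' individual fold increases;
#' equivalently `exp(sum(log(x)))`.
#'
#' @param x positive fold increases of the member single mutations.
#' @return the expected combined fold increase.
#' @examples
#' multiplicativeExpectation(c(7.6, 5.4, 7.2))  # 295.5, i.e. ~300-fold
#' @export
multiplicativeExpectation <- function(x) {
    if (any(x <= 0)) stop("fold increases must be positive")
    prod(x)
}

#' Assay-scale epistasis with propagated error
#'
#' Compares the multiplicative expectation `E = prod(x_i)` of the member
#' single-mutant fold increases with the observed fold increase `O` of the
#' combination mutant.  Errors are propagated to first order:
#' `sigma_E = E * sqrt(sum((s_i/x_i)^2))` for the product and
#' `sigma_eps = sqrt(sigma_E^2 + s_O^2)` for the difference
#' `epsilon = E - O`.  Epistasis (negative: the combination underperforms
#' its expectation) is called significant when `epsilon > k * sigma_eps`.
#'
#' @param x positive fold increases of the member single mutants.
#' @param s their standard errors (same length; `NA` allowed, making the
#'   significance call unavailable).
#' @param observed observed fold increase of the combination mutant.
#' @param observedSE its standard error.
#' @param k significance multiple (default 2, roughly a 95% one-sided
#'   criterion).
#' @return one-row data.frame: `expected`, `sigma_expected`, `observed`,
#'   `observed_se`, `epsilon`, `sigma_epsilon`, `significant`.
#' @examples
#' epistasisWithError(c(2, 3), c(0.2, 0.3), observed = 6, observedSE = 0)
#' @export
epistasisWithError <- function(x, s, observed, observedSE, k = 2) {
    if (any(x <= 0)) stop("fold increases must be positive")
    if (length(s) != length(x)) stop("'x' and 's' must be aligned")
    E <- prod(x)
    sigmaE <- E * sqrt(sum((s / x)^2))
    eps <- E - observed
    sigmaEps <- sqrt(sigmaE^2 + observedSE^2)
    significant <- if (is.na(sigmaEps)) NA else eps > k * sigmaEps
    data.frame(expected = E, sigma_expected = sigmaE, observed = observed,
               observed_se = observedSE, epsilon = eps,
               sigma_epsilon = sigmaEps, significant = significant)
}
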