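#' LociPanel: the focal-mutation panel
#'
#' An ordered panel of focal protein positions on a reference ORF.  Each
#' locus records the wild-type residue, the allowed mutant residues, and
#' optionally the degenerate (IUPAC) codon used to build the library at that
#' position.  The panel fixes the allele-ID alphabet: an allele-ID is a
#' string with one residue per panel locus, in ascending position order.
#'
#' Validity requires strictly increasing, duplicate-free positions; the
#' wild-type residue must not be listed among the mutants; and when a
#' degenerate codon is given, its expansion must translate exactly to the
#' set \{wild type\} U \{mutants\} with no stop codon.
#'
#' @slot loci a [S4Vectors::DataFrame] with columns `position` (1-based
#'   residue index), `wt` (one-letter residue), `mutants` (list of one-letter
#'   residues), `codon` (IUPAC triplet or `NA`).
#' @slot referenceId name of the reference ORF the positions refer to.
#'
#' @seealso [LociPanel()], [defaultPanel()], [enumerateAlleleSpace()]
#' @exportClass LociPanel
setClass("LociPanel",
         slots = c(loci = "DFrame", referenceId = "character"))

setValidity("LociPanel", function(object) {
    lo <- object@loci
    need <- c("position", "wt", "mutants", "codon")
    if (!all(need %in% colnames(lo)))
        return(paste("loci must have columns", paste(need, collapse = ", ")))
    if (nrow(lo) == 0L)
        return("panel must contain at least one locus")
    pos <- lo$position
    if (any(diff(pos) <= 0))
        return("protein positions must be strictly increasing (no duplicates)")
    for (i in seq_len(nrow(lo))) {
        wt <- lo$wt[i]
        mut <- lo$mutants[[i]]
        if (nchar(wt) != 1L)
            return("wt residues must be single letters")
        if (length(mut) < 1L)
            return(sprintf("locus %d needs at least one mutant residue", pos[i]))
        if (wt %in% mut)
            return(sprintf("locus %d: wt residue '%s' listed among mutants",
                           pos[i], wt))
        cod <- lo$codon[i]
        if (!is.na(cod)) {
            exp <- tryCatch(expandDegenerateCodon(cod),
                            error = function(e) conditionMessage(e))
            if (is.character(exp))
                return(sprintf("locus %d: %s", pos[i], exp))
            if (any(exp$stop))
                return(sprintf("locus %d: degenerate codon %s expands to a stop codon",
                               pos[i], cod))
            if (!setequal(exp$residue, c(wt, mut)))
                return(sprintf(
                    "locus %d: codon %s translates to {%s}, panel declares {%s}",
                    pos[i], cod, paste(sort(unique(exp$residue)), collapse = ","),
                    paste(sort(c(wt, mut)), collapse = ",")))
        }
    }
    TRUE
})

#' AlleleCounts: allele-ID read counts per enrichment time point
#'
#' The central observable of the analysis: a matrix of curated read counts
#' with one row per allele-ID (13-letter residue string for the default
#' panel) and one column per sequencing time point (e.g. `t0`, `c1`, `c3`,
#' `c6`).  Extends [SummarizedExperiment::SummarizedExperiment]; the panel
#' that defines the allele-ID alphabet is carried in `metadata(x)$panel`.
#' Row metadata records, per allele, the number of loci at which the residue
#' falls outside the designed alphabet (`nUnexpected`).
#'
#' @seealso [AlleleCounts()], [curateAndCount()], [filterForEpistasis()]
#' @exportClass AlleleCounts
setClass("AlleleCounts", contains = "SummarizedExperiment")

setValidity("AlleleCounts", function(object) {
    if (!"counts" %in% names(assays(object)))
        return("an AlleleCounts object needs a 'counts' assay")
    cn <- assay(object, "counts")
    if (any(cn < 0) || any(cn != round(cn)))
        return("counts must be non-negative integers")
    pan <- metadata(object)$panel
    if (is.null(pan) || !is(pan, "LociPanel"))
        return("metadata(object)$panel must be a LociPanel")
    ids <- rownames(object)
    if (is.null(ids) || any(nchar(ids) != nrow(pan@loci)))
        return("rownames must be allele-IDs with one residue per panel locus")
    if (anyDuplicated(ids))
        return("duplicated allele-IDs")
    TRUE
})

#' TruthModel: ground truth for a synthetic selection-sequencing experiment
#'
#' Defines the study conditions a synthetic experiment is generated under:
#' the panel, per-locus library design frequencies, per-mutation selection
#' coefficients (natural-log scale, per enrichment cycle), injected pairwise
#' epistasis terms, the off-target mutation rate of the assembled library,
#' sequencing error rates, read totals per time point and the number of
#' selection cycles.
#'
#' @slot panel the [LociPanel].
#' @slot design list, one element per locus: named residue frequencies that
#'   sum to 1 (codon-level degeneracy already aggregated to residues).
#' @slot selection named numeric, natural-log selection coefficient per
#'   mutation (names like `"E103K"`).
#' @slot epistasis data.frame with columns `mutation_i`, `mutation_j`,
#'   `epsilon` (ln scale) of injected pairwise interactions.
#' @slot offtargetRate probability that a library clone carries an
#'   unintended coding mutation outside the focal loci.
#' @slot perBaseError per-base substitution error rate of the (consensus)
#'   long reads.
#' @slot indelRate per-base indel rate of the reads.
#' @slot readTotals named integer vector of usable reads per time point
#'   (names `t0`, `c1`, ...).
#' @slot nCycles number of selection cycles simulated.
#' @slot preset name of the preset the model was built from.
#'
#' @seealso [truthModel()], [makeBenchmark()]
#' @exportClass TruthModel
setClass("TruthModel",
         slots = c(panel = "LociPanel", design = "list",
                   selection = "numeric", epistasis = "data.frame",
                   offtargetRate = "numeric", perBaseError = "numeric",
                   indelRate = "numeric", readTotals = "numeric",
                   nCycles = "integer", preset = "character"))

setValidity("TruthModel", function(object) {
    if (length(object@design) != nrow(object@panel@loci))
        return("design must have one element per panel locus")
    for (d in object@design) {
        if (abs(sum(d) - 1) > 1e-9 || any(d < 0))
            return("design frequencies per locus must be non-negative and sum to 1")
    }
    rates <- c(object@offtargetRate, object@perBaseError, object@indelRate)
    if (any(rates < 0 | rates > 1))
        return("rates must lie in [0, 1]")
    if (any(object@readTotals <= 0))
        return("read totals must be positive")
    if (nrow(object@epistasis) &&
        !all(c("mutation_i", "mutation_j", "epsilon") %in%
             colnames(object@epistasis)))
        return("epistasis needs columns mutation_i, mutation_j, epsilon")
    TRUE
})

#' SyntheticExperiment: a generated experiment with known ground truth
#'
#' Bundles everything [makeBenchmark()] produces for one seed: the
#' [TruthModel], the clone-level library table, the deterministic allele
#' frequency trajectory across selection cycles, the sampled
#' [AlleleCounts] per time point, truth tables (per-mutation W, per-pair
#' epistasis, per-allele fitness) and, optionally, simulated reads.
#'
#' @slot truth the [TruthModel] used.
#' @slot library data.frame of clone groups: `allele_id`, `offtarget_codon`
#'   (NA if none), `offtarget_res`, `n` clones.
#' @slot frequencies matrix (clone groups x cycles 0..nCycles) of true
#'   frequencies.
#' @slot counts sampled [AlleleCounts].
#' @slot truthTables list with elements `singles` (mutation, W_true),
#'   `pairs` (mutation_i, mutation_j, epsilon_true) and `alleleFitness`
#'   (named linear-scale fitness per allele present in the library).
#' @slot reads list: per-time-point `DNAStringSet` plus a read-to-allele
#'   truth map (empty unless reads were emitted).
#'
#' @seealso [makeBenchmark()]
#' @exportClass SyntheticExperiment
setClass("SyntheticExperiment",
         slots = c(truth = "TruthModel", library = "data.frame",
                   frequencies = "matrix", counts = "AlleleCounts",
                   truthTables = "list", reads = "list"))

setMethod("show", "LociPanel", function(object) {
    lo <- object@loci
    cat(sprintf("LociPanel with %d loci on '%s'\n", nrow(lo),
                object@referenceId))
    cat(sprintf("  wild-type allele-ID: %s\n", wildtypeAlleleID(object)))
    for (i in seq_len(nrow(lo)))
        cat(sprintf("  %4d  %s -> {%s}%s\n", lo$position[i], lo$wt[i],
                    paste(lo$mutants[[i]], collapse = ","),
                    ifelse(is.na(lo$codon[i]), "",
                           paste0("  [", lo$codon[i], "]"))))
    invisible(object)
})

setMethod("show", "TruthModel", function(object) {
    cat(sprintf("TruthModel (preset '%s'): %d loci, %d cycles\n",
                object@preset, nrow(object@panel@loci), object@nCycles))
    cat(sprintf("  read totals: %s\n",
                paste(names(object@readTotals), object@readTotals,
                      sep = "=", collapse = ", ")))
    cat(sprintf("  off-target rate %.2f, per-base error %.4f, indel rate %.4f\n",
                object@offtargetRate, object@perBaseError, object@indelRate))
    if (nrow(object@epistasis)) {
        cat("  injected epistasis:\n")
        for (i in seq_len(nrow(object@epistasis)))
            cat(sprintf("    %s x %s: %.3f\n", object@epistasis$mutation_i[i],
                        object@epistasis$mutation_j[i],
                        object@epistasis$epsilon[i]))
    } else cat("  no injected epistasis (multiplicative truth)\n")
    invisible(object)
})

setMethod("show", "SyntheticExperiment", function(object) {
    cat(sprintf("SyntheticExperiment ('%s'): %d clone groups, %d alleles observed\n",
                object@truth@preset, nrow(object@library),
                nrow(object@counts)))
    cat(sprintf("  time points: %s\n",
                paste(colnames(object@counts), collapse = ", ")))
    if (length(object@reads))
        cat(sprintf("  reads emitted for: %s\n",
                    paste(names(object@reads$reads), collapse = ", ")))
    invisible(object)
})
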