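#' Construct an AlleleCounts object
#'
#' @param counts integer matrix, alleles x time points; rownames are
#'   allele-IDs, colnames time-point labels in chronological order.
#' @param panel the [LociPanel-class] defining the allele-ID alphabet.
#' @return an [AlleleCounts-class] object with assay `counts`, per-allele
#'   `nUnexpected` row metadata and the panel in `metadata()`.
#' @examples
#' pan <- defaultPanel()
#' m <- matrix(c(10L, 5L), 1, 2,
#'             dimnames = list(wildtypeAlleleID(pan), c("t0", "c1")))
#' AlleleCounts(m, pan)
#' @export
AlleleCounts <- function(counts, panel) {
    stopifnot(is(panel, "LociPanel"), is.matrix(counts))
    mode(counts) <- "integer"
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("t", seq_len(ncol(counts)) - 1L)
    flags <- alleleFlags(rownames(counts), panel)
    rd <- DataFrame(alleleID = rownames(counts),
                    nMutations = as.integer(rowSums(flags == "expected_mut")),
                    nUnexpected = as.integer(rowSums(flags == "unexpected")))
    se <- SummarizedExperiment(assays = list(counts = counts), rowData = rd)
    metadata(se)$panel <- panel
    new("AlleleCounts", se)
}

#' Accessors for AlleleCounts
#'
#' `panel()` returns the [LociPanel-class] carried by the object,
#' `alleleIDs()` the allele-ID strings, `timepoints()` the ordered
#' time-point labels and `countTotals()` the per-time-point read totals.
#'
#' @param x an [AlleleCounts-class] object.
#' @return see above.
#' @aliases panel
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))

#' @rdname panel
#' @export
setMethod("panel", "AlleleCounts", function(x) metadata(x)$panel)

#' @rdname panel
#' @aliases alleleIDs
#' @export
setGeneric("alleleIDs", function(x) standardGeneric("alleleIDs"))

#' @rdname panel
#' @export
setMethod("alleleIDs", "AlleleCounts", function(x) rownames(x))

#' @rdname panel
#' @aliases timepoints
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname panel
#' @export
setMethod("timepoints", "AlleleCounts", function(x) colnames(x))

#' @rdname panel
#' @aliases countTotals
#' @export
setGeneric("countTotals", function(x) standardGeneric("countTotals"))

#' @rdname panel
#' @export
setMethod("countTotals", "AlleleCounts",
          function(x) colSums(assay(x, "counts")))

setMethod("show", "AlleleCounts", function(object) {
    cn <- assay(object, "counts")
    cat(sprintf("AlleleCounts: %d allele-IDs x %d time points (%s)\n",
                nrow(cn), ncol(cn), paste(colnames(cn), collapse = ", ")))
    cat(sprintf("  totals: %s\n",
                paste(colnames(cn), colSums(cn), sep = "=", collapse = ", ")))
    cat(sprintf("  panel: %d loci, wild type %s\n",
                length(panel(object)), wildtypeAlleleID(panel(object))))
    nu <- sum(rowData(object)$nUnexpected > 0)
    if (nu) cat(sprintf("  %d allele-IDs carry unexpected residues\n", nu))
    invisible(object)
})

#' Read or write an allele count table as TSV
#'
#' Long-format interchange: columns `timepoint`, `allele_id`, `count`.
#' Time-point order follows first appearance in the file (write order is
#' the object's column order).
#'
#' @param path file path.
#' @param panel the [LociPanel-class] for `readCountTable`.
#' @param x an [AlleleCounts-class] for `writeCountTable`.
#' @return `readCountTable()` an [AlleleCounts-class]; `writeCountTable()`
#'   the path, invisibly.
#' @export
readCountTable <- function(path, panel) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("timepoint", "allele_id", "count")
    if (!all(need %in% colnames(df)))
        stop("count table needs columns ", paste(need, collapse = ", "))
    tps <- unique(df$timepoint)
    ids <- unique(df$allele_id)
    m <- matrix(0L, length(ids), length(tps), dimnames = list(ids, tps))
    m[cbind(match(df$allele_id, ids), match(df$timepoint, tps))] <-
        as.integer(df$count)
    AlleleCounts(m, panel)
}

#' @rdname readCountTable
#' @export
writeCountTable <- function(x, path) {
    cn <- assay(x, "counts")
    df <- data.frame(timepoint = rep(colnames(cn), each = nrow(cn)),
                     allele_id = rep(rownames(cn), ncol(cn)),
                     count = as.vector(cn))
    df <- df[df$count > 0, ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
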