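#' Expand a degenerate IUPAC codon
#'
#' Enumerates the full Cartesian expansion of a 3-letter IUPAC codon and
#' translates each expanded codon with the standard genetic code.  This is
#' how degenerate library primers such as `GRM` (positions coding Gly/Glu,
#' plus the unintended Asp) or `RRT` (Gly/Asp/Asn plus the unintended Ser)
#' define the residue alphabet at a panel locus.
#'
#' Stop codons in the expansion are flagged, not dropped: whether a design
#' tolerates them is the caller's decision (a [LociPanel] refuses them).
#'
#' @param codon a single 3-character IUPAC nucleotide string.
#' @return a data.frame with one row per expanded DNA codon: `codon`,
#'   `residue` (one-letter amino acid, `*` for stop) and `stop` (logical).
#' @examples
#' expandDegenerateCodon("GRM")   # E, D, G
#' expandDegenerateCodon("RRT")   # N, S, D, G
#' @export
expandDegenerateCodon <- function(codon) {
    if (!is.character(codon) || length(codon) != 1L || is.na(codon) ||
        nchar(codon) != 3L)
        stop("'codon' must be a single 3-letter IUPAC string")
    nts <- strsplit(toupper(codon), "", fixed = TRUE)[[1]]
    bad <- setdiff(nts, names(IUPAC_CODE_MAP))
    if (length(bad))
        stop("non-IUPAC symbol(s) in codon: ", paste(bad, collapse = ", "))
    opts <- lapply(nts, function(x) strsplit(IUPAC_CODE_MAP[[x]], "")[[1]])
    grid <- expand.grid(p3 = opts[[3]], p2 = opts[[2]], p1 = opts[[1]],
                        stringsAsFactors = FALSE)
    codons <- sort(paste0(grid$p1, grid$p2, grid$p3))
    residues <- unname(GENETIC_CODE[codons])
    data.frame(codon = codons, residue = residues, stop = residues == "*",
               stringsAsFactors = FALSE)
}

#' Construct a LociPanel
#'
#' @param position integer vector of 1-based protein positions (strictly
#'   increasing).
#' @param wt character vector of wild-type one-letter residues.
#' @param mutants list of character vectors (or a character vector of
#'   comma-joined residues) of allowed mutant residues per locus.
#' @param codon optional character vector of degenerate IUPAC codons
#'   (`NA` where the locus was built with a plain two-way mixture).
#' @param referenceId name of the reference ORF.
#' @return a [LociPanel-class] object.
#' @examples
#' LociPanel(c(5, 9), c("A", "G"), list("V", c("D", "N")))
#' @export
LociPanel <- function(position, wt, mutants, codon = NA_character_,
                      referenceId = "reference") {
    if (is.character(mutants))
        mutants <- strsplit(mutants, ",", fixed = TRUE)
    mutants <- lapply(mutants, function(m) sort(unique(trimws(m))))
    codon <- rep_len(as.character(codon), length(position))
    ord <- order(position)
    loci <- DataFrame(position = as.integer(position)[ord],
                      wt = as.character(wt)[ord],
                      codon = codon[ord])
    loci$mutants <- IRanges::CharacterList(mutants[ord])
    new("LociPanel", loci = loci[, c("position", "wt", "mutants", "codon")],
        referenceId = referenceId)
}

#' The default 13-locus integrase panel
#'
#' The panel of 13 focal mutations combined in the purification library:
#' E103K, T118S, D161G, H162Q, S173R, K219R, Y220N, D299E, V315A, G319E,
#' G320D/N, A321G and A329T.  Positions 319 and 320 were built with the
#' degenerate codons `GRM` and `RRT`, which add the unintended residues
#' Asp (319) and Ser (320) to the designed alphabet; these count as
#' expected mutants.  The wild-type allele-ID is `"ETDHSKYDVGGAA"` and the
#' theoretical allele space has 2^11 x 3 x 4 = 24,576 members.
#'
#' @param hotspot if `TRUE`, append the optional 14th tracked locus A234V
#'   (an off-target substitution hotspot) so analyses excluding or tracking
#'   it can use the same machinery.  Default `FALSE`.
#' @return a [LociPanel-class].
#' @examples
#' defaultPanel()
#' enumerateAlleleSpace(defaultPanel())$count  # 24576
#' @export
defaultPanel <- function(hotspot = FALSE) {
    position <- c(103L, 118L, 161L, 162L, 173L, 219L, 220L, 299L, 315L,
                  319L, 320L, 321L, 329L)
    wt <- c("E", "T", "D", "H", "S", "K", "Y", "D", "V", "G", "G", "A", "A")
    mutants <- list("K", "S", "G", "Q", "R", "R", "N", "E", "A",
                    c("D", "E"), c("D", "N", "S"), "G", "T")
    codon <- c(rep(NA_character_, 9), "GRM", "RRT", NA, NA)
    if (hotspot) {
        position <- c(position, 234L)
        wt <- c(wt, "A")
        mutants <- c(mutants, list("V"))
        codon <- c(codon, NA)
    }
    LociPanel(position, wt, mutants, codon,
              referenceId = "synthetic_intI1_like")
}

#' @describeIn LociPanel-class number of loci in the panel.
#' @param x a `LociPanel`.
#' @export
setMethod("length", "LociPanel", function(x) nrow(x@loci))

#' Panel accessors
#'
#' `panelPositions()`, `wtResidues()`, `mutantResidues()` and
#' `allowedResidues()` read the locus specification off a [LociPanel-class];
#' `wildtypeAlleleID()` assembles the all-wild-type allele-ID string;
#' `mutationNames()` lists the canonical mutation names (e.g. `"E103K"`),
#' one per allowed mutant residue.
#'
#' @param panel a [LociPanel-class].
#' @return vectors or lists parallel to the panel loci.
#' @export
panelPositions <- function(panel) panel@loci$position

#' @rdname panelPositions
#' @export
wtResidues <- function(panel) panel@loci$wt

#' @rdname panelPositions
#' @export
mutantResidues <- function(panel) panel@loci$mutants

#' @rdname panelPositions
#' @export
allowedResidues <- function(panel)
    mapply(function(w, m) sort(c(w, m)), panel@loci$wt, panel@loci$mutants,
           SIMPLIFY = FALSE)

#' @rdname panelPositions
#' @export
wildtypeAlleleID <- function(panel) paste(panel@loci$wt, collapse = "")

#' @rdname panelPositions
#' @export
mutationNames <- function(panel) {
    lo <- panel@loci
    unlist(lapply(seq_len(nrow(lo)), function(i)
        paste0(lo$wt[i], lo$position[i], lo$mutants[[i]])))
}

#' Enumerate the theoretical allele space of a panel
#'
#' Counts and lists every allele-ID over the panel alphabet: the Cartesian
#' product of \{wild type\} U \{mutants\} across loci.  For the default
#' 13-locus panel (11 binary loci, 3 residues at 319, 4 at 320) this is
#' 2^11 x 3 x 4 = 24,576 alleles, the theoretical size of the purification
#' library.
#'
#' @param panel a [LociPanel-class].
#' @param enumerate if `FALSE`, return only the count (for very large
#'   panels).
#' @return list with `count` (numeric) and `ids` (character vector of all
#'   allele-IDs in lexicographic order, or `NULL`).
#' @examples
#' enumerateAlleleSpace(defaultPanel())$count
#' @export
enumerateAlleleSpace <- function(panel, enumerate = TRUE) {
    stopifnot(is(panel, "LociPanel"))
    sets <- allowedResidues(panel)
    count <- prod(lengths(sets))
    ids <- NULL
    if (enumerate) {
        if (count > 5e6)
            stop("allele space too large to enumerate (", count,
                 "); use enumerate = FALSE for the count")
        ids <- ""
        for (s in sets)
            ids <- paste0(rep(ids, each = length(s)), s)
    }
    list(count = count, ids = ids)
}

#' Hamming distance between allele-IDs
#'
#' Number of panel loci at which two allele-IDs differ.  Vectorised over
#' pairs (arguments are recycled to a common length).
#'
#' @param a,b character vectors of allele-IDs of equal string length.
#' @return integer vector of distances.
#' @examples
#' alleleDistance("ETDHSKYDVGGAA", "KTDHSKYDVGGAA")  # 1
#' @export
alleleDistance <- function(a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
    if (any(nchar(a) != nchar(b)))
        stop("allele-IDs must have equal length (same panel)")
    as.integer(mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b))
}

#' Per-locus status flags and carried mutations of allele-IDs
#'
#' `alleleFlags()` classifies each position of each allele-ID as
#' `expected_wt`, `expected_mut` or `unexpected` (residue outside the
#' designed alphabet, e.g. a sequencing error, a stop codon `*` or an
#' ambiguous `X`).  `alleleMutations()` returns, per allele, the canonical
#' names of the expected mutations it carries.
#'
#' @param ids character vector of allele-IDs.
#' @param panel the [LociPanel-class] the IDs are written over.
#' @return `alleleFlags()`: a character matrix (alleles x loci);
#'   `alleleMutations()`: a list of character vectors.
#' @export
alleleFlags <- function(ids, panel) {
    lo <- panel@loci
    mut <- as.list(lo$mutants)
    res <- .residueMatrix(ids, panel)
    flags <- matrix("unexpected", nrow = nrow(res), ncol = ncol(res),
                    dimnames = list(ids, lo$position))
    for (j in seq_len(ncol(res))) {
        flags[res[, j] == lo$wt[j], j] <- "expected_wt"
        flags[res[, j] %in% mut[[j]], j] <- "expected_mut"
    }
    flags
}

#' @rdname alleleFlags
#' @export
alleleMutations <- function(ids, panel) {
    lo <- panel@loci
    mut <- as.list(lo$mutants)
    res <- .residueMatrix(ids, panel)
    hits <- matrix(FALSE, nrow(res), ncol(res))
    for (j in seq_len(ncol(res)))
        hits[, j] <- res[, j] %in% mut[[j]]
    lapply(seq_len(nrow(res)), function(i) {
        j <- which(hits[i, ])
        paste0(lo$wt[j], lo$position[j], res[i, j])
    })
}

# alleles x loci residue matrix; shared by most estimators
.residueMatrix <- function(ids, panel) {
    L <- length(panel)
    if (any(nchar(ids) != L))
        stop("allele-ID length does not match the panel")
    matrix(unlist(strsplit(ids, "", fixed = TRUE), use.names = FALSE),
           ncol = L, byrow = TRUE, dimnames = list(ids, NULL))
}

#' Read or write a loci panel as TSV
#'
#' The structured panel config: tab-separated columns `position`, `wt`,
#' `mutants` (comma-joined) and `codon` (empty or `NA` when absent).  A copy
#' of the default panel ships as
#' `system.file("extdata", "default_panel.tsv", package = "combEpi")`.
#'
#' @param path file path.
#' @param panel a [LociPanel-class] (for `writePanel`).
#' @param referenceId reference ORF name recorded in the panel.
#' @return `readPanel()` returns a [LociPanel-class]; `writePanel()` its
#'   path, invisibly.
#' @export
readPanel <- function(path, referenceId = "reference") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("position", "wt", "mutants")
    if (!all(need %in% colnames(df)))
        stop("panel file needs columns ", paste(need, collapse = ", "))
    codon <- if ("codon" %in% colnames(df)) as.character(df$codon)
             else NA_character_
    codon[!is.na(codon) & codon == ""] <- NA_character_
    LociPanel(df$position, df$wt, df$mutants, codon, referenceId)
}

#' @rdname readPanel
#' @export
writePanel <- function(panel, path) {
    lo <- panel@loci
    df <- data.frame(position = lo$position, wt = lo$wt,
                     mutants = vapply(lo$mutants, paste, "", collapse = ","),
                     codon = ifelse(is.na(lo$codon), "", lo$codon))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
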