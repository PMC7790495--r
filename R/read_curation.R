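#' Deterministic synthetic reference ORF
#'
#' A 1014-bp coding sequence (337 sense codons + stop) standing in for the
#' integrase ORF the panel positions refer to.  It is synthetic: non-focal
#' codons are arbitrary (deterministically generated, stop-free) sense
#' codons; focal codons carry the panel's wild-type residues, drawn from
#' the degenerate-codon expansion where one is declared; codon 234 is fixed
#' to Ala (`GCT`) so the documented off-target hotspot (A234V) is
#' representable.  Every call returns the same sequence for a given panel.
#'
#' @param panel a [LociPanel-class]; positions must fit within 337 codons.
#' @param nCodons total codons including the stop (default 338, i.e. a
#'   1014-bp ORF).
#' @return a named [Biostrings::DNAString].
#' @examples
#' ref <- syntheticReference()
#' length(ref)  # 1014
#' @export
syntheticReference <- function(panel = defaultPanel(), nCodons = 338L) {
    lo <- panel@loci
    if (max(lo$position) >= nCodons)
        stop("panel positions exceed the ORF length")
    sense <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
    codons <- .withSeed(20161014L,
                        sample(sense, nCodons - 1L, replace = TRUE))
    if (!234L %in% lo$position && nCodons > 234L)
        codons[234L] <- "GCT"
    for (i in seq_len(nrow(lo)))
        codons[lo$position[i]] <- .codonFor(lo$wt[i], lo$codon[i])
    codons <- c(codons, "TAA")
    ref <- DNAString(paste(codons, collapse = ""))
    ref
}

#' Encode an allele-ID as a DNA sequence
#'
#' The reference ORF with each focal codon replaced by a codon encoding the
#' allele-ID's residue at that locus (drawn from the locus' degenerate
#' codon expansion where one is declared, otherwise the alphabetically
#' first codon of the residue).  This is the template the read simulator
#' mutates, and the inverse of [extractAlleleID()] on error-free data.
#'
#' @param allele_id allele-ID string over the panel.
#' @param panel the [LociPanel-class].
#' @param reference the reference ORF (default [syntheticReference()]).
#' @return a character DNA sequence of the reference's length.
#' @export
encodeAllele <- function(allele_id, panel = defaultPanel(),
                         reference = syntheticReference(panel)) {
    refchr <- as.character(reference)
    lo <- panel@loci
    codons <- substring(refchr, seq(1L, nchar(refchr) - 2L, 3L),
                        seq(3L, nchar(refchr), 3L))
    resv <- strsplit(allele_id, "", fixed = TRUE)[[1]]
    if (length(resv) != nrow(lo))
        stop("allele-ID length does not match the panel")
    for (j in seq_len(nrow(lo)))
        codons[lo$position[j]] <- .codonFor(resv[j], lo$codon[j])
    paste(codons, collapse = "")
}

# first codon encoding `residue`; prefer the degenerate-codon expansion
.codonFor <- function(residue, degenerate = NA_character_) {
    if (!is.na(degenerate)) {
        exp <- expandDegenerateCodon(degenerate)
        hit <- exp$codon[exp$residue == residue]
        if (length(hit)) return(hit[1L])
    }
    sort(names(GENETIC_CODE)[GENETIC_CODE == residue])[1L]
}

# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    expr
}

# nucleotide range (1-based, inclusive) spanned by the focal codons
.focalSpan <- function(panel) {
    pos <- panelPositions(panel)
    c(3L * min(pos) - 2L, 3L * max(pos))
}

#' Read long amplicon reads from FASTA/FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] choosing the format
#' from the file extension (`.fastq`/`.fq`, optionally `.gz`, are FASTQ).
#'
#' @param path file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
readReads <- function(path) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
        "fastq" else "fasta"
    readDNAStringSet(path, format = fmt)
}

#' Align a read to the reference ORF
#'
#' Global alignment with free end gaps (Needleman-Wunsch "overlap" mode) of
#' a read, or its reverse complement, whichever scores higher, against the
#' reference.  Scoring: match +1, mismatch -1, gap opening -2, gap
#' extension -1.  Reads whose best alignment identity (matches over
#' alignment columns) falls below `minIdentity` are labelled unalignable.
#'
#' @param read a character string, [Biostrings::DNAString] or single-element
#'   `DNAStringSet`.
#' @param reference the reference ORF (`DNAString` or character).
#' @param minIdentity identity threshold below which `status` is
#'   `"unalignable"` (default 0.8).
#' @param gapOpening,gapExtension positive penalties passed to
#'   [Biostrings::pairwiseAlignment()].
#' @return a list: `pattern` and `subject` (aligned strings with `-` gaps),
#'   `start`/`end` (reference span), `orientation` (`"forward"` or
#'   `"reverse"`), `identity`, `score`, `nInsertions`, `nDeletions`,
#'   `status` (`"pass"` or `"unalignable"`).
#' @examples
#' ref <- syntheticReference()
#' aln <- alignToReference(as.character(ref), ref)
#' aln$identity
#' @export
alignToReference <- function(read, reference, minIdentity = 0.8,
                             gapOpening = 2, gapExtension = 1) {
    read <- as.character(read)[1L]
    refchr <- as.character(reference)
    mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                        baseOnly = FALSE)
    alnF <- pairwiseAlignment(read, refchr, type = "overlap",
                              substitutionMatrix = mat,
                              gapOpening = gapOpening,
                              gapExtension = gapExtension)
    rc <- as.character(reverseComplement(DNAString(read)))
    alnR <- pairwiseAlignment(rc, refchr, type = "overlap",
                              substitutionMatrix = mat,
                              gapOpening = gapOpening,
                              gapExtension = gapExtension)
    if (score(alnR) > score(alnF)) {
        aln <- alnR; orientation <- "reverse"
    } else {
        aln <- alnF; orientation <- "forward"
    }
    p <- as.character(pattern(aln))
    s <- as.character(subject(aln))
    pc <- strsplit(p, "", fixed = TRUE)[[1]]
    sc <- strsplit(s, "", fixed = TRUE)[[1]]
    ident <- sum(pc == sc) / length(pc)
    list(pattern = p, subject = s,
         start = start(subject(aln)), end = end(subject(aln)),
         orientation = orientation, identity = ident,
         score = score(aln),
         nInsertions = sum(sc == "-"), nDeletions = sum(pc == "-"),
         status = if (ident < minIdentity) "unalignable" else "pass")
}

#' Correct indels in an aligned read
#'
#' Applies the blanket indel-repair rule used on consensus long reads whose
#' residual indels are technical artifacts: bases the read inserts relative
#' to the reference are removed, and reference positions the read deletes
#' are filled back in with the reference base.  The repaired sequence is in
#' reference coordinates and has exactly the length of the aligned
#' reference span.
#'
#' @param aln an alignment as returned by [alignToReference()].
#' @return a list: `sequence` (repaired read), `start`, `end`,
#'   `nInsertions`, `nDeletions`, `orientation`, `identity`, `status`.
#' @export
correctIndels <- function(aln) {
    pc <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
    sc <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
    keep <- sc != "-"
    out <- ifelse(pc[keep] == "-", sc[keep], pc[keep])
    refIdx <- aln$start - 1L + seq_len(sum(keep))
    list(sequence = paste(out, collapse = ""),
         deletedRefPositions = refIdx[pc[keep] == "-"],
         start = aln$start, end = aln$end,
         nInsertions = aln$nInsertions, nDeletions = aln$nDeletions,
         orientation = aln$orientation, identity = aln$identity,
         status = aln$status)
}

#' Extract the allele-ID from a repaired read
#'
#' Translates each focal codon of an indel-corrected read and assembles the
#' allele-ID string; codons containing `N` give residue `X` and stop codons
#' `*`, both flagged unexpected.  Codons outside the focal loci (and before
#' the stop) that are fully covered by the read are compared with the
#' reference at the DNA level: each differing codon counts as one
#' off-target mismatch, and its residue-level substitution (synonymous or
#' not) is recorded for the mutation spectrum.
#'
#' @param repaired output of [correctIndels()], or a character sequence
#'   assumed to start at reference position 1.
#' @param reference the reference ORF.
#' @param panel the [LociPanel-class].
#' @return a list: `allele_id`, `flags` (per-locus
#'   expected_wt/expected_mut/unexpected), `offtarget_mismatches`,
#'   `substitutions` (data.frame codon/wt_res/obs_res/synonymous).
#' @export
extractAlleleID <- function(repaired, reference, panel) {
    if (is.character(repaired))
        repaired <- list(sequence = repaired, start = 1L,
                         end = nchar(repaired))
    seqchr <- repaired$sequence
    st <- repaired$start; en <- repaired$end
    refchr <- as.character(reference)
    lo <- panel@loci
    span <- .focalSpan(panel)
    if (st > span[1L] || en < span[2L])
        stop("repaired read does not cover all focal codons")

    codonAt <- function(p) substr(seqchr, 3L * p - 2L - st + 1L,
                                  3L * p - st + 1L)
    res <- vapply(lo$position, function(p) {
        cod <- codonAt(p)
        aa <- unname(GENETIC_CODE[cod])
        if (is.na(aa)) "X" else aa
    }, "")
    id <- paste(res, collapse = "")
    flags <- alleleFlags(id, panel)[1L, ]

    nAA <- nchar(refchr) %/% 3L
    iMin <- ceiling((st + 2L) / 3L)
    iMax <- min(en %/% 3L, nAA)
    cand <- setdiff(seq(iMin, iMax), lo$position)
    refCodons <- substring(refchr, 3L * cand - 2L, 3L * cand)
    cand <- cand[GENETIC_CODE[refCodons] != "*"]
    refCodons <- substring(refchr, 3L * cand - 2L, 3L * cand)
    obsCodons <- substring(seqchr, 3L * cand - 2L - st + 1L,
                           3L * cand - st + 1L)
    mism <- which(obsCodons != refCodons)
    subs <- data.frame(codon = integer(0), wt_res = character(0),
                       obs_res = character(0), synonymous = logical(0))
    if (length(mism)) {
        wt_res <- unname(GENETIC_CODE[refCodons[mism]])
        obs_res <- unname(GENETIC_CODE[obsCodons[mism]])
        obs_res[is.na(obs_res)] <- "X"
        subs <- data.frame(codon = cand[mism], wt_res = wt_res,
                           obs_res = obs_res,
                           synonymous = wt_res == obs_res)
    }
    list(allele_id = id, flags = flags,
         offtarget_mismatches = length(mism), substitutions = subs)
}

#' Curate reads into an allele count table
#'
#' The full read-curation pipeline, per time point: a length filter (a read
#' must be able to span the first through last focal codon), alignment to
#' the reference in the better-scoring orientation, indel correction,
#' allele-ID extraction and counting.  Reads identical in length to the
#' reference whose direct mismatch fraction is at most
#' `fastPathMaxMismatch` skip the alignment step (no indels possible at
#' that identity under the scoring scheme).  Duplicate read sequences are
#' processed once and counted with multiplicity.
#'
#' @param reads named list (names = time-point labels, chronological), each
#'   element a [Biostrings::DNAStringSet], character vector of sequences,
#'   or a FASTA/FASTQ file path.
#' @param reference the reference ORF ([Biostrings::DNAString], character,
#'   or FASTA path).
#' @param panel the [LociPanel-class].
#' @param minIdentity alignment identity threshold (default 0.8).
#' @param fastPathMaxMismatch maximum mismatch fraction for the
#'   alignment-free fast path (default 0.05).
#' @return a list with `counts` (an [AlleleCounts-class]) and `report`: a
#'   list holding `summary` (per-time-point data.frame with columns
#'   n_reads, n_pass, n_too_short, n_unalignable, n_with_indels,
#'   n_repaired_focal, mean_offtarget) and `spectrum` (aggregated
#'   off-target substitution counts: codon, wt_res, obs_res, synonymous,
#'   count).
#' @export
curateAndCount <- function(reads, reference, panel,
                           minIdentity = 0.8, fastPathMaxMismatch = 0.05) {
    if (is.character(reference) && length(reference) == 1L &&
        file.exists(reference))
        reference <- readDNAStringSet(reference)[[1L]]
    refchr <- as.character(reference)
    refrc <- as.character(reverseComplement(DNAString(refchr)))
    if (is.null(names(reads)) || any(names(reads) == ""))
        stop("'reads' must be a named list, one element per time point")
    span <- .focalSpan(panel)
    spanLen <- span[2L] - span[1L] + 1L

    tallies <- list()
    summaries <- list()
    spectra <- list()
    for (tp in names(reads)) {
        rr <- reads[[tp]]
        if (is.character(rr) && length(rr) == 1L && file.exists(rr))
            rr <- readReads(rr)
        rr <- as.character(rr)
        if (length(rr) == 0L)
            stop("no reads for time point '", tp, "'")
        tab <- table(rr)
        useqs <- names(tab)
        mult <- as.integer(tab)

        ids <- character(length(useqs))
        stat <- character(length(useqs))
        offt <- integer(length(useqs))
        hasIndel <- logical(length(useqs))
        repairedFocal <- integer(length(useqs))
        subsList <- vector("list", length(useqs))
        for (k in seq_along(useqs)) {
            s <- useqs[k]
            L <- nchar(s)
            if (L < spanLen) { stat[k] <- "too_short"; next }
            rep <- NULL
            if (L == nchar(refchr)) {
                mmF <- sum(charToRaw(s) != charToRaw(refchr))
                mmR <- sum(charToRaw(s) != charToRaw(refrc))
                if (min(mmF, mmR) <= fastPathMaxMismatch * L) {
                    oriented <- if (mmR < mmF)
                        as.character(reverseComplement(DNAString(s))) else s
                    rep <- list(sequence = oriented,
                                deletedRefPositions = integer(0),
                                start = 1L, end = L,
                                nInsertions = 0L, nDeletions = 0L,
                                orientation = if (mmR < mmF) "reverse"
                                              else "forward",
                                identity = 1 - min(mmF, mmR) / L,
                                status = "pass")
                }
            }
            if (is.null(rep)) {
                aln <- alignToReference(s, refchr, minIdentity = minIdentity)
                if (aln$status == "unalignable") {
                    stat[k] <- "unalignable"; next
                }
                if (aln$start > span[1L] || aln$end < span[2L]) {
                    stat[k] <- "too_short"; next
                }
                rep <- correctIndels(aln)
            }
            call <- extractAlleleID(rep, refchr, panel)
            stat[k] <- "pass"
            ids[k] <- call$allele_id
            offt[k] <- call$offtarget_mismatches
            hasIndel[k] <- rep$nInsertions > 0L || rep$nDeletions > 0L
            if (rep$nDeletions > 0L)
                repairedFocal[k] <- .deletionsInFocal(rep, panel)
            else repairedFocal[k] <- 0L
            subsList[[k]] <- call$substitutions
        }

        pass <- stat == "pass"
        cnt <- if (any(pass))
            tapply(mult[pass], ids[pass], sum) else integer(0)
        tallies[[tp]] <- cnt
        summaries[[tp]] <- data.frame(
            timepoint = tp,
            n_reads = sum(mult),
            n_pass = sum(mult[pass]),
            n_too_short = sum(mult[stat == "too_short"]),
            n_unalignable = sum(mult[stat == "unalignable"]),
            n_with_indels = sum(mult[pass & hasIndel]),
            n_repaired_focal = sum(mult[pass][repairedFocal[pass] > 0L]),
            mean_offtarget = if (any(pass))
                sum(mult[pass] * offt[pass]) / sum(mult[pass]) else NA_real_)
        keep <- which(pass & vapply(subsList, NROW, 0L) > 0L)
        if (length(keep)) {
            sp <- do.call(rbind, lapply(keep, function(k)
                cbind(subsList[[k]], count = mult[k])))
            spectra[[tp]] <- sp
        }
    }

    ids <- sort(unique(unlist(lapply(tallies, names))))
    if (length(ids) == 0L)
        stop("no reads passed curation at any time point")
    m <- matrix(0L, length(ids), length(reads),
                dimnames = list(ids, names(reads)))
    for (tp in names(tallies))
        m[names(tallies[[tp]]), tp] <- as.integer(tallies[[tp]])

    spectrum <- data.frame(codon = integer(0), wt_res = character(0),
                           obs_res = character(0), synonymous = logical(0),
                           count = integer(0))
    if (length(spectra)) {
        sp <- do.call(rbind, spectra)
        agg <- stats::aggregate(count ~ codon + wt_res + obs_res + synonymous,
                                data = sp, FUN = sum)
        spectrum <- agg[order(-agg$count), ]
        rownames(spectrum) <- NULL
    }
    summary <- do.call(rbind, summaries)
    rownames(summary) <- NULL
    list(counts = AlleleCounts(m, panel),
         report = list(summary = summary, spectrum = spectrum,
                       panel = panel))
}

# focal codons of a repaired read that contain repaired (deleted) bases;
# such codons are accepted as reference-residue calls but tracked
.deletionsInFocal <- function(rep, panel) {
    del <- rep$deletedRefPositions
    if (!length(del)) return(0L)
    pos <- panelPositions(panel)
    sum(vapply(pos, function(p)
        any(del >= 3L * p - 2L & del <= 3L * p), logical(1)))
}

#' Detect off-target substitution hotspots
#'
#' Scans the off-target mutation spectrum of a curation report for codon
#' positions whose non-synonymous substitution frequency stands far above
#' the background (a configurable multiple of the median per-position
#' frequency), as happened for the A234V substitution that accumulated
#' during the selection cycles.
#'
#' @param report the `report` element returned by [curateAndCount()].
#' @param minFold positions are reported when their frequency is at least
#'   `minFold` times the median per-position frequency (default 10).
#' @param minCount minimum substitution count to consider (default 3).
#' @return a data.frame (`codon`, `substitution`, `count`, `frequency`,
#'   `fold_over_median`) sorted by decreasing frequency; zero rows when the
#'   spectrum is flat.
#' @export
detectOfftargetHotspots <- function(report, minFold = 10, minCount = 3L) {
    sp <- report$spectrum
    empty <- data.frame(codon = integer(0), substitution = character(0),
                        count = integer(0), frequency = numeric(0),
                        fold_over_median = numeric(0))
    if (NROW(sp) == 0L) return(empty)
    sp <- sp[!sp$synonymous & sp$obs_res != "X", , drop = FALSE]
    if (NROW(sp) == 0L) return(empty)
    nPass <- sum(report$summary$n_pass)
    perPos <- tapply(sp$count, sp$codon, sum)
    med <- median(perPos / nPass)
    agg <- stats::aggregate(count ~ codon + wt_res + obs_res, data = sp,
                            FUN = sum)
    agg$frequency <- agg$count / nPass
    agg$fold_over_median <- agg$frequency / med
    hit <- agg[agg$fold_over_median >= minFold & agg$count >= minCount, ]
    if (NROW(hit) == 0L) return(empty)
    out <- data.frame(codon = hit$codon,
                      substitution = paste0(hit$wt_res, hit$codon,
                                            hit$obs_res),
                      count = hit$count, frequency = hit$frequency,
                      fold_over_median = hit$fold_over_median)
    out <- out[order(-out$frequency), ]
    rownames(out) <- NULL
    out
}
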