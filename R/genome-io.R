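## Genome and interval I/O, lesion inference, sequence-context annotation.

#' Load a genome from FASTA
#'
#' Reads a (possibly multi-line, possibly lowercase) FASTA file into an
#' uppercase \code{DNAStringSet}. Ambiguity codes other than \code{N} are
#' either rejected (\code{strict = TRUE}) or mapped to \code{N}.
#'
#' @param fastaPath path to a FASTA file.
#' @param strict logical; reject IUPAC ambiguity codes other than N.
#' @return A \code{DNAStringSet}, one element per chromosome in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' loadGenome(fa)
#' @export
loadGenome <- function(fastaPath, strict = TRUE) {
    if (!file.exists(fastaPath))
        stop("FASTA file not found: ", fastaPath)
    gen <- readDNAStringSet(fastaPath)
    if (length(gen) == 0L)
        stop("empty FASTA file: ", fastaPath)
    if (anyDuplicated(names(gen)))
        stop("duplicate chromosome names in ", fastaPath)
    names(gen) <- sub("\\s.*$", "", names(gen))
    if (anyDuplicated(names(gen)))
        stop("duplicate chromosome names (after header truncation) in ",
             fastaPath)
    gen <- DNAStringSet(toupper(as.character(gen)))
    other <- BiocGenerics::width(gen) - rowSums(
        Biostrings::letterFrequency(gen, letters = c("A", "C", "G", "T", "N")))
    if (any(other > 0)) {
        if (strict)
            stop("non-ACGTN characters in sequence(s): ",
                 paste(names(gen)[other > 0], collapse = ", "))
        chr <- as.character(gen)
        chr <- gsub("[^ACGTN]", "N", chr)
        gen <- DNAStringSet(chr)
    }
    gen
}

## shift a logical vector: lagL gives x[i-1] (FALSE at the left edge),
## leadL gives x[i+1] (FALSE at the right edge)
.lagL <- function(x) c(FALSE, x[-length(x)])
.leadL <- function(x) c(x[-1L], FALSE)

#' Per-position dipyrimidine-cytosine masks
#'
#' For every chromosome, flags positions carrying a cytosine with at least
#' one same-strand pyrimidine neighbour -- the denominator unit for
#' normalised dCPD frequency -- separately for the plus and minus strand.
#' A minus-strand cytosine appears as G on the plus strand; its same-strand
#' neighbours are pyrimidines exactly when the flanking plus-strand bases
#' are purines. Positions at chromosome ends and next to N never qualify
#' on the N side.
#'
#' @param genome DNAStringSet.
#' @return Named list (per chromosome) of lists with logical vectors
#'   \code{plus} and \code{minus}.
#' @export
dipyrimidineCytosines <- function(genome) {
    res <- lapply(seq_along(genome), function(i) {
        b <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1L]]
        pyr <- b == "C" | b == "T"
        pur <- b == "G" | b == "A"
        plus <- (b == "C") & (.lagL(pyr) | .leadL(pyr))
        minus <- (b == "G") & (.lagL(pur) | .leadL(pur))
        list(plus = plus, minus = minus)
    })
    names(res) <- names(genome)
    res
}

#' Infer lesion positions from aligned reads
#'
#' The damaged (deaminated) cytosine is inferred as the base on the strand
#' opposite the read, immediately upstream of the read's 5' end: a
#' plus-strand read starting at position \eqn{s} implies a minus-strand
#' lesion at \eqn{s - 1}; a minus-strand read ending at \eqn{e} implies a
#' plus-strand lesion at \eqn{e + 1} (1-based coordinates). Reads whose
#' inferred lesion falls outside the chromosome are dropped; reads on
#' chromosomes absent from the genome are skipped. Both tallies are stored
#' in \code{metadata()} of the result.
#'
#' @param reads GRanges of aligned reads; strand must be + or -.
#' @param genome DNAStringSet the reads were aligned to.
#' @return Width-1 GRanges of lesion positions (strand = lesion strand)
#'   with \code{metadata()} fields \code{nDroppedBoundary},
#'   \code{nSkippedChrom}.
#' @export
callLesions <- function(reads, genome) {
    stopifnot(is(reads, "GRanges"))
    str <- as.character(strand(reads))
    if (any(str == "*"))
        stop("reads without strand information cannot be used for ",
             "lesion calling")
    known <- as.character(seqnames(reads)) %in% names(genome)
    nSkipped <- sum(!known)
    if (nSkipped > 0L) {
        warning(nSkipped, " read(s) on chromosomes absent from the genome ",
                "were skipped")
        reads <- reads[known]
        str <- str[known]
    }
    chrom <- as.character(seqnames(reads))
    pos <- ifelse(str == "+", start(reads) - 1L, end(reads) + 1L)
    lesStrand <- ifelse(str == "+", "-", "+")
    len <- setNames(BiocGenerics::width(genome), names(genome))
    inside <- pos >= 1L & pos <= len[chrom]
    nDropped <- sum(!inside)
    gr <- GRanges(chrom[inside], IRanges(pos[inside], width = 1L),
                  strand = lesStrand[inside])
    seqlengths(gr) <- len[seqlevels(gr)]
    metadata(gr) <- list(nDroppedBoundary = nDropped,
                         nSkippedChrom = nSkipped)
    gr
}

#' Annotate lesions with trinucleotide context
#'
#' Fills in, for each lesion, the base read on the lesion strand, the
#' 3-mer on the lesion strand centred on the lesion (the reverse complement
#' of the plus-strand window for minus-strand lesions), and whether the
#' lesion has at least one same-strand pyrimidine neighbour
#' (\code{dipyrimidineOk}). Lesions at chromosome ends or whose window
#' touches an N get an \code{NA} trinucleotide and are excluded from
#' context tallies downstream.
#'
#' @param lesions width-1 GRanges from [callLesions()].
#' @param genome DNAStringSet.
#' @return The input GRanges with metadata columns \code{centralBase},
#'   \code{trinucleotide}, \code{dipyrimidineOk}.
#' @export
annotateContext <- function(lesions, genome) {
    stopifnot(is(lesions, "GRanges"))
    n <- length(lesions)
    central <- character(n)
    tri <- rep(NA_character_, n)
    chrom <- as.character(seqnames(lesions))
    pos <- start(lesions)
    str <- as.character(strand(lesions))
    len <- setNames(BiocGenerics::width(genome), names(genome))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        s <- genome[[ch]]
        L <- len[[ch]]
        p <- pos[idx]
        cb <- as.character(Biostrings::extractAt(
            s, IRanges(pmin(pmax(p, 1L), L), width = 1L)))
        interior <- p >= 2L & p <= L - 1L
        tw <- rep(NA_character_, length(idx))
        if (any(interior)) {
            tw[interior] <- as.character(Biostrings::extractAt(
                s, IRanges(p[interior] - 1L, p[interior] + 1L)))
        }
        central[idx] <- cb
        tri[idx] <- tw
    }
    minus <- str == "-"
    if (any(minus)) {
        central[minus] <- .revcompChar(central[minus])
        ok <- minus & !is.na(tri)
        tri[ok] <- .revcompChar(tri[ok])
    }
    tri[!is.na(tri) & grepl("N", tri)] <- NA_character_
    central[grepl("N", central)] <- NA_character_
    dipy <- !is.na(tri) &
        (substr(tri, 1L, 1L) %in% c("C", "T") |
         substr(tri, 3L, 3L) %in% c("C", "T"))
    mcols(lesions)$centralBase <- central
    mcols(lesions)$trinucleotide <- tri
    mcols(lesions)$dipyrimidineOk <- dipy
    lesions
}

.revcompChar <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

#' Count k-mer occurrences on both strands of a genome
#'
#' Counts every k-mer window on the plus and the minus strand. Windows
#' containing N contribute to no k-mer, so the total equals
#' \eqn{2 \sum_c (L_c - k + 1)} minus the N-window exclusions. Optionally
#' restricts the returned table to k-mers with a given central base.
#'
#' @param genome DNAStringSet.
#' @param k odd window size (default 3).
#' @param centerBase optional single base; keep only k-mers with this
#'   central base.
#' @return Named numeric vector of counts over k-mers.
#' @export
countContextOccurrences <- function(genome, k = 3L, centerBase = NULL) {
    stopifnot(k %% 2L == 1L, k >= 1L)
    counts <- NULL
    for (i in seq_along(genome)) {
        s <- genome[[i]]
        if (length(s) < k) next
        fwd <- oligonucleotideFrequency(s, width = k)
        rev <- oligonucleotideFrequency(reverseComplement(s), width = k)
        cc <- fwd + rev
        counts <- if (is.null(counts)) cc else counts + cc
    }
    if (is.null(counts)) {
        km <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
        counts <- setNames(numeric(length(km)), km)
    }
    if (!is.null(centerBase)) {
        mid <- (k + 1L) %/% 2L
        counts <- counts[substr(names(counts), mid, mid) == centerBase]
    }
    counts
}

#' Remove lesions inside excluded regions
#'
#' Removes lesions falling inside any of the supplied intervals and/or
#' within a fixed distance of a chromosome end (the subtelomere filter:
#' the study excludes regions within 5 kb of telomere ends as single-strand
#' resection there elevates deamination). The number of removed lesions is
#' recorded in \code{metadata()}.
#'
#' @param lesions GRanges.
#' @param regions optional GRanges of regions to exclude, or a path to a
#'   BED file.
#' @param chromEndDistance optional distance in bp; exclude lesions within
#'   this distance of either end of their chromosome.
#' @param genome DNAStringSet; required when \code{chromEndDistance} is
#'   given (for chromosome lengths).
#' @return Filtered GRanges with \code{metadata()$nExcluded}.
#' @export
excludeRegions <- function(lesions, regions = NULL, chromEndDistance = NULL,
                           genome = NULL) {
    stopifnot(is(lesions, "GRanges"))
    excl <- GRanges()
    if (!is.null(regions)) {
        if (is.character(regions)) regions <- readBedFeatures(regions)
        excl <- c(excl, granges(regions))
    }
    if (!is.null(chromEndDistance)) {
        if (is.null(genome))
            stop("genome is required for chromosome-end exclusion")
        d <- as.integer(chromEndDistance)
        len <- BiocGenerics::width(genome)
        for (i in seq_along(genome)) {
            L <- len[i]
            nm <- names(genome)[i]
            if (2L * d >= L) {
                excl <- c(excl, GRanges(nm, IRanges(1L, L)))
            } else {
                excl <- c(excl, GRanges(nm, IRanges(c(1L, L - d + 1L),
                                                    c(d, L))))
            }
        }
    }
    if (length(excl) == 0L) {
        metadata(lesions)$nExcluded <- 0L
        return(lesions)
    }
    hit <- overlapsAny(lesions, excl, ignore.strand = TRUE)
    out <- lesions[!hit]
    metadata(out)$nExcluded <- sum(hit)
    out
}

#' Read and write BED6 feature and lesion files
#'
#' Thin wrappers around rtracklayer's BED support. BED files are 0-based
#' half-open on disk; the returned GRanges is 1-based closed. Lesions are
#' written with the trinucleotide context in the BED name field.
#'
#' @param path BED file path.
#' @param requireStrand logical; fail if any record lacks a strand (lesion
#'   calling is strand-dependent).
#' @return \code{readBedFeatures} a GRanges.
#' @export
readBedFeatures <- function(path, requireStrand = FALSE) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
        error = function(e) {
            .bedDiagnose(path)
            stop("malformed BED file ", path, ": ", conditionMessage(e))
        })
    if (requireStrand && any(as.character(strand(gr)) == "*"))
        stop("BED file ", path, " has records without a strand; ",
             "a strand column is required")
    gr
}

## report the first syntactically bad line, with its number
.bedDiagnose <- function(path) {
    ln <- readLines(path, warn = FALSE)
    for (i in seq_along(ln)) {
        if (grepl("^(#|track|browser)", ln[i]) || !nzchar(ln[i])) next
        f <- strsplit(ln[i], "\t")[[1L]]
        if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2L]))) ||
            is.na(suppressWarnings(as.integer(f[3L]))))
            stop("malformed BED line ", i, " in ", path, ": ", ln[i])
    }
    invisible(NULL)
}

#' @rdname readBedFeatures
#' @param lesions annotated lesion GRanges.
#' @export
writeLesionsBed <- function(lesions, path) {
    nm <- mcols(lesions)$trinucleotide
    if (is.null(nm)) nm <- rep(".", length(lesions))
    nm[is.na(nm)] <- "."
    out <- granges(lesions)
    mcols(out)$name <- nm
    mcols(out)$score <- rep(0L, length(out))
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' @rdname readBedFeatures
#' @param genome DNAStringSet; re-annotates contexts after reading.
#' @export
readLesionsBed <- function(path, genome = NULL) {
    gr <- readBedFeatures(path, requireStrand = TRUE)
    gr <- granges(gr)
    if (!is.null(genome)) gr <- annotateContext(gr, genome)
    gr
}
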