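## Binned metagene, site-aligned and ratio profiles of normalized dCPD
## frequency.

## per-chromosome integer count vectors of lesions by strand
.lesionCounts <- function(lesions, genome) {
    len <- setNames(BiocGenerics::width(genome), names(genome))
    out <- list()
    chrom <- as.character(seqnames(lesions))
    str <- as.character(strand(lesions))
    pos <- start(lesions)
    for (ch in names(genome)) {
        i <- chrom == ch
        out[[ch]] <- list(
            plus = tabulate(pos[i & str == "+"], nbins = len[[ch]]),
            minus = tabulate(pos[i & str == "-"], nbins = len[[ch]]))
    }
    out
}

## range-sum helper on a cumulative-sum vector (1-based closed [a, b])
.rangeSum <- function(cs, a, b) {
    a <- pmax(a, 1L)
    n <- length(cs)
    b <- pmin(b, n)
    bad <- a > b
    res <- cs[pmin(b, n)] - ifelse(a > 1L, cs[a - 1L], 0)
    res[bad] <- 0
    res
}

#' Binned metagene profile of normalized dCPD frequency
#'
#' Divides every gene body into \code{nBody} equal bins (bin \eqn{i} covers
#' \eqn{[\lfloor (i-1)L/n \rfloor, \lfloor iL/n \rfloor)} of the gene, a
#' deterministic rule for all lengths) plus fixed-width flanking bins,
#' \code{nFlank} upstream of the TSS and \code{nFlank} downstream of the
#' TES. Minus-strand genes are flipped so bin 1 abuts the TSS. Lesions on
#' both strands are pooled; per-bin counts and dipyrimidine-cytosine
#' denominators are summed across genes before division. Bins with an
#' empty denominator get \code{NA} (never 0). Genes shorter than
#' \code{nBody} bp are skipped and tallied; flank bins running off a
#' chromosome end are truncated (denominators adjust).
#'
#' @param lesions GRanges of lesions.
#' @param genes GRanges with strand; TSS/TES are start/end in
#'   transcription orientation.
#' @param genome DNAStringSet.
#' @param nBody number of gene-body bins (default 6).
#' @param flankBin flank bin width in bp (default 167).
#' @param nFlank flank bins on each side (default 3).
#' @return A [BinnedProfile-class] (kind \code{"gene"}).
#' @export
geneMetaprofile <- function(lesions, genes, genome, nBody = 6L,
                            flankBin = 167L, nFlank = 3L) {
    stopifnot(is(genes, "GRanges"), length(genes) > 0L)
    if (any(as.character(strand(genes)) == "*"))
        stop("genes must be stranded")
    masks <- dipyrimidineCytosines(genome)
    lc <- .lesionCounts(lesions, genome)
    csL <- lapply(names(genome), function(ch)
        cumsum(lc[[ch]]$plus + lc[[ch]]$minus))
    csD <- lapply(names(genome), function(ch)
        cumsum(as.integer(masks[[ch]]$plus) +
               as.integer(masks[[ch]]$minus)))
    names(csL) <- names(csD) <- names(genome)

    keep <- BiocGenerics::width(genes) >= nBody
    nSkipped <- sum(!keep)
    genes <- genes[keep]
    chrom <- as.character(seqnames(genes))
    s <- start(genes)
    e <- end(genes)
    L <- e - s + 1L
    minus <- as.character(strand(genes)) == "-"

    labels <- c(paste0("up", rev(seq_len(nFlank))),
                paste0("body", seq_len(nBody)),
                paste0("down", seq_len(nFlank)))
    nb <- length(labels)
    lesBin <- numeric(nb)
    dipyBin <- numeric(nb)
    binBounds <- function(j) {
        ## genomic [a, b] of bin j (1..nb) for every gene, in orientation
        if (j <= nFlank) {                       # upstream flank
            jj <- nFlank - j + 1L                # distance rank from TSS
            a <- ifelse(minus, e + (jj - 1L) * flankBin + 1L,
                        s - jj * flankBin)
            b <- ifelse(minus, e + jj * flankBin,
                        s - (jj - 1L) * flankBin - 1L)
        } else if (j <= nFlank + nBody) {        # body
            i <- j - nFlank
            lo <- floor((i - 1L) * L / nBody)
            hi <- floor(i * L / nBody)
            a <- ifelse(minus, e - hi + 1L, s + lo)
            b <- ifelse(minus, e - lo, s + hi - 1L)
        } else {                                  # downstream flank
            jj <- j - nFlank - nBody
            a <- ifelse(minus, s - jj * flankBin,
                        e + (jj - 1L) * flankBin + 1L)
            b <- ifelse(minus, s - (jj - 1L) * flankBin - 1L,
                        e + jj * flankBin)
        }
        cbind(a, b)
    }
    for (j in seq_len(nb)) {
        ab <- binBounds(j)
        for (ch in unique(chrom)) {
            i <- chrom == ch
            lesBin[j] <- lesBin[j] +
                sum(.rangeSum(csL[[ch]], ab[i, 1L], ab[i, 2L]))
            dipyBin[j] <- dipyBin[j] +
                sum(.rangeSum(csD[[ch]], ab[i, 1L], ab[i, 2L]))
        }
    }
    bins <- data.frame(bin = labels, lesions = lesBin, dipyC = dipyBin,
        normFreq = ifelse(dipyBin > 0, lesBin / dipyBin, NA_real_),
        stringsAsFactors = FALSE)
    new("BinnedProfile", bins = bins, kind = "gene", mode = "",
        nSites = length(genes), nSkipped = as.integer(nSkipped))
}

#' Per-offset profile around aligned sites
#'
#' Tallies lesions (both strands pooled) and dipyrimidine cytosines at
#' every offset in \code{-halfwidth..halfwidth} relative to site
#' midpoints, orienting by site strand when present. Offsets beyond
#' chromosome bounds are skipped (denominators adjust).
#'
#' @param lesions GRanges of lesions.
#' @param sites GRanges of site midpoints (width 1 or midpoint of wider
#'   ranges; optional strand orients the profile).
#' @param genome DNAStringSet.
#' @param halfwidth profile half-width in bp (default 100).
#' @return A [BinnedProfile-class] (kind \code{"site"}), bins keyed by
#'   offset.
#' @export
siteProfile <- function(lesions, sites, genome, halfwidth = 100L) {
    stopifnot(is(sites, "GRanges"))
    if (length(sites) == 0L) stop("empty site list")
    masks <- dipyrimidineCytosines(genome)
    lc <- .lesionCounts(lesions, genome)
    len <- setNames(BiocGenerics::width(genome), names(genome))
    mid <- as.integer((start(sites) + end(sites)) / 2)
    chrom <- as.character(seqnames(sites))
    flip <- as.character(strand(sites)) == "-"
    offs <- seq.int(-halfwidth, halfwidth)
    lesOff <- numeric(length(offs))
    dipyOff <- numeric(length(offs))
    lesVec <- lapply(names(genome), function(ch)
        lc[[ch]]$plus + lc[[ch]]$minus)
    dipyVec <- lapply(names(genome), function(ch)
        as.integer(masks[[ch]]$plus) + as.integer(masks[[ch]]$minus))
    names(lesVec) <- names(dipyVec) <- names(genome)
    for (oi in seq_along(offs)) {
        o <- offs[oi]
        p <- ifelse(flip, mid - o, mid + o)
        for (ch in unique(chrom)) {
            i <- chrom == ch
            pp <- p[i]
            ok <- pp >= 1L & pp <= len[[ch]]
            lesOff[oi] <- lesOff[oi] + sum(lesVec[[ch]][pp[ok]])
            dipyOff[oi] <- dipyOff[oi] + sum(dipyVec[[ch]][pp[ok]])
        }
    }
    bins <- data.frame(bin = offs, lesions = lesOff, dipyC = dipyOff,
        normFreq = ifelse(dipyOff > 0, lesOff / dipyOff, NA_real_))
    new("BinnedProfile", bins = bins, kind = "site", mode = "",
        nSites = length(sites), nSkipped = 0L)
}

#' Total dipyrimidine-cytosine-associated lesion count
#'
#' The genome-wide normalisation total used for cellular-vs-naked
#' enrichment: the number of lesions mapping to cytosines in a
#' dipyrimidine context.
#'
#' @param lesions annotated GRanges.
#' @return Integer count.
#' @export
totalDipyLesions <- function(lesions) {
    ok <- mcols(lesions)$dipyrimidineOk
    if (is.null(ok))
        stop("lesions must be annotated; run annotateContext() first")
    sum(ok, na.rm = TRUE)
}

#' Cellular-vs-naked dCPD enrichment per bin
#'
#' For matching cellular and naked-DNA profiles, the per-bin enrichment is
#' \eqn{(c_b / n_b) (N / C)} where \eqn{c_b, n_b} are the bin's lesion
#' counts and \eqn{C, N} the genome-wide dipyrimidine-cytosine-associated
#' lesion totals of each sample. Bins where the naked count is 0 are
#' \code{NA} and reported via the \code{nUndefined} attribute. The
#' normalisation makes the enrichment invariant to global down-sampling of
#' either library.
#'
#' @param profileCellular,profileNaked [BinnedProfile-class] objects with
#'   identical bin structure.
#' @param totalCellular,totalNaked genome-wide dipyrimidine-associated
#'   lesion totals, see [totalDipyLesions()].
#' @return A [BinnedProfile-class] whose bins carry an additional
#'   \code{enrichment} column (and per-strand enrichment columns when the
#'   inputs are strand-resolved).
#' @export
enrichmentRatio <- function(profileCellular, profileNaked,
                            totalCellular, totalNaked) {
    stopifnot(is(profileCellular, "BinnedProfile"),
              is(profileNaked, "BinnedProfile"))
    bc <- profileCellular@bins
    bn <- profileNaked@bins
    if (nrow(bc) != nrow(bn) || !identical(bc$bin, bn$bin) ||
        profileCellular@kind != profileNaked@kind)
        stop("mismatched bin structures between cellular and naked profiles")
    if (totalCellular <= 0 || totalNaked <= 0)
        stop("lesion totals must be positive")
    scale <- totalNaked / totalCellular
    bc$enrichment <- ifelse(bn$lesions > 0,
                            (bc$lesions / bn$lesions) * scale, NA_real_)
    for (strCol in c("Plus", "Minus")) {
        lp <- paste0("les", strCol)
        if (lp %in% names(bc) && lp %in% names(bn)) {
            bc[[paste0("enrichment", strCol)]] <-
                ifelse(bn[[lp]] > 0, (bc[[lp]] / bn[[lp]]) * scale,
                       NA_real_)
        }
    }
    out <- profileCellular
    out@bins <- bc
    attr(out@bins, "nUndefined") <- sum(is.na(bc$enrichment))
    out
}

#' Write a profile as TSV
#'
#' @param profile a [BinnedProfile-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeProfileTsv <- function(profile, path) {
    stopifnot(is(profile, "BinnedProfile"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# kind=%s mode=%s nSites=%d nSkipped=%d",
        profile@kind, profile@mode, profile@nSites, profile@nSkipped), con)
    writeLines("# lesions: read counts; dipyC: dipyrimidine-cytosine positions; normFreq: lesions/dipyC", con)
    write.table(profile@bins, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
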