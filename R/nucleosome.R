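## Dyad-aligned profiling, rotational/backbone phase classification,
## nonparametric group comparison.

#' Dyad-aligned lesion profile
#'
#' Tallies lesions and dipyrimidine cytosines per strand at every offset
#' relative to nucleosome dyads. Three modes: \code{"aggregate"} pools the
#' strands at each offset; \code{"strand"} additionally keeps per-strand
#' columns; \code{"aligned53"} flips minus-strand offsets (offset o of the
#' minus strand maps to -o) so both strands read 5'->3' before pooling.
#'
#' @param lesions GRanges of lesions.
#' @param dyads GRanges of single-bp dyad positions.
#' @param genome DNAStringSet.
#' @param halfwidth window half-width in bp (default 73, the nucleosome).
#' @param mode \code{"aggregate"}, \code{"strand"} or \code{"aligned53"}.
#' @return A [BinnedProfile-class] (kind \code{"dyad"}), bins keyed by
#'   offset, with per-strand columns \code{lesPlus}, \code{lesMinus},
#'   \code{dipyPlus}, \code{dipyMinus} and the mode's pooled
#'   \code{lesions}/\code{dipyC}/\code{normFreq}.
#' @export
dyadProfile <- function(lesions, dyads, genome, halfwidth = 73L,
                        mode = c("aggregate", "strand", "aligned53")) {
    mode <- match.arg(mode)
    stopifnot(is(dyads, "GRanges"))
    if (length(dyads) == 0L) stop("empty dyad list")
    masks <- dipyrimidineCytosines(genome)
    lc <- .lesionCounts(lesions, genome)
    len <- setNames(BiocGenerics::width(genome), names(genome))
    chrom <- as.character(seqnames(dyads))
    dpos <- start(dyads)
    offs <- seq.int(-halfwidth, halfwidth)
    lesP <- lesM <- dipP <- dipM <- numeric(length(offs))
    for (oi in seq_along(offs)) {
        o <- offs[oi]
        for (ch in unique(chrom)) {
            p <- dpos[chrom == ch] + o
            ok <- p >= 1L & p <= len[[ch]]
            p <- p[ok]
            lesP[oi] <- lesP[oi] + sum(lc[[ch]]$plus[p])
            lesM[oi] <- lesM[oi] + sum(lc[[ch]]$minus[p])
            dipP[oi] <- dipP[oi] + sum(masks[[ch]]$plus[p])
            dipM[oi] <- dipM[oi] + sum(masks[[ch]]$minus[p])
        }
    }
    if (mode == "aligned53") {
        rev_ <- rev(seq_along(offs))       # offset o -> -o
        lesions_ <- lesP + lesM[rev_]
        dipy_ <- dipP + dipM[rev_]
    } else {
        lesions_ <- lesP + lesM
        dipy_ <- dipP + dipM
    }
    bins <- data.frame(bin = offs, lesions = lesions_, dipyC = dipy_,
        normFreq = ifelse(dipy_ > 0, lesions_ / dipy_, NA_real_),
        lesPlus = lesP, lesMinus = lesM, dipyPlus = dipP, dipyMinus = dipM,
        normFreqPlus = ifelse(dipP > 0, lesP / dipP, NA_real_),
        normFreqMinus = ifelse(dipM > 0, lesM / dipM, NA_real_))
    new("BinnedProfile", bins = bins, kind = "dyad", mode = mode,
        nSites = length(dyads), nSkipped = 0L)
}

#' Build a rotational/backbone phase table
#'
#' Constructs the default classification of dyad offsets into rotational
#' settings and strand-specific backbone settings. Minor-out band centres
#' follow a ~10.17 bp helical period anchored so the two positions
#' immediately flanking the dyad axis (-2 and +2) are minor-out; minor-in
#' centres sit midway between consecutive same-side minor-out centres.
#' Bands are centre +/- \code{bandHalfwidth}; all remaining offsets are
#' intermediate. At intermediate offsets the plus strand is backbone-out
#' 5' (smaller coordinate) of the nearest minor-in centre and backbone-in
#' 3' of it; the minus strand is mirrored. Offsets equidistant from two
#' minor-in centres (only offset 0 under the default) get no backbone
#' class.
#'
#' @param period helical period in bp (default 10.17).
#' @param minorOutCenters explicit centre offsets; default: the periodic
#'   construction anchored at \code{phase}.
#' @param phase anchor offset of the first minor-out centre (default 2).
#' @param bandHalfwidth rotational band half-width (default 1, giving 3 bp
#'   bands).
#' @param halfwidth table half-width (default 73).
#' @return A [PhaseTable-class].
#' @export
buildPhaseTable <- function(period = 10.17, minorOutCenters = NULL,
                            phase = 2, bandHalfwidth = 1L,
                            halfwidth = 73L) {
    if (is.null(minorOutCenters)) {
        k <- 0:floor((halfwidth + period / 2 - phase) / period)
        pos <- round(phase + period * k)
        pos <- pos[pos <= halfwidth]
        minorOutCenters <- sort(unique(c(-pos, pos)))
    }
    minorOutCenters <- sort(as.integer(minorOutCenters))
    if (any(abs(minorOutCenters) > halfwidth))
        stop("centers must lie within [-halfwidth, halfwidth]")
    ## minor-in centres: midpoints of consecutive minor-out centres whose
    ## band would not collide with the flanking minor-out bands
    minGap <- 2L * (2L * bandHalfwidth + 1L)
    mids <- (head(minorOutCenters, -1L) + tail(minorOutCenters, -1L)) / 2
    gaps <- diff(minorOutCenters)
    ## round midpoints away from zero so the table is mirror-symmetric
    m <- mids[gaps >= minGap]
    minorInCenters <- as.integer(sign(m) * floor(abs(m) + 0.5))
    allCenters <- c(minorOutCenters, minorInCenters)
    if (any(diff(sort(allCenters)) <= 2L * bandHalfwidth))
        stop("overlapping rotational bands")
    offs <- seq.int(-halfwidth, halfwidth)
    nearestDist <- function(x, centers)
        vapply(x, function(o) min(abs(o - centers)), numeric(1))
    rot <- rep("intermediate", length(offs))
    rot[nearestDist(offs, minorOutCenters) <= bandHalfwidth] <- "minor_out"
    rot[nearestDist(offs, minorInCenters) <= bandHalfwidth] <- "minor_in"
    bbPlus <- bbMinus <- rep("none", length(offs))
    inter <- which(rot == "intermediate")
    for (i in inter) {
        o <- offs[i]
        d <- abs(o - minorInCenters)
        nearest <- minorInCenters[d == min(d)]
        if (length(nearest) > 1L) next    # equidistant: no backbone class
        if (o < nearest) {
            bbPlus[i] <- "backbone_out"; bbMinus[i] <- "backbone_in"
        } else {
            bbPlus[i] <- "backbone_in"; bbMinus[i] <- "backbone_out"
        }
    }
    tb <- data.frame(offset = offs, rotational = rot,
                     backbone_plus = bbPlus, backbone_minus = bbMinus,
                     stringsAsFactors = FALSE)
    new("PhaseTable", table = tb, provenance = "default")
}

#' Read/write a phase table as TSV
#'
#' The on-disk format is a TSV with columns \code{offset},
#' \code{rotational}, \code{backbone_plus}, \code{backbone_minus};
#' round-trips exactly.
#'
#' @param path file path.
#' @return \code{readPhaseTable} a [PhaseTable-class].
#' @export
readPhaseTable <- function(path) {
    tb <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    new("PhaseTable", table = tb, provenance = normalizePath(path))
}

#' @rdname readPhaseTable
#' @param x a [PhaseTable-class].
#' @export
writePhaseTable <- function(x, path) {
    stopifnot(is(x, "PhaseTable"))
    write.table(x@table, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. For small samples
#' (\eqn{n_a + n_b \le} \code{exactLimit}) the p-value is exact by
#' enumeration of all group assignments (ties handled by the midrank U);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. Always \eqn{U_a + U_b = n_a n_b}.
#'
#' @param groupA,groupB numeric vectors (non-empty).
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"} (of group A relative to group B).
#' @param exactLimit switch to enumeration when the pooled size is at most
#'   this (default 12).
#' @return List with \code{U} (the U statistic of group A), \code{p} and
#'   \code{method}.
#' @export
mannWhitneyU <- function(groupA, groupB,
                         alternative = c("two.sided", "less", "greater"),
                         exactLimit = 12L) {
    alternative <- match.arg(alternative)
    na <- length(groupA); nb <- length(groupB)
    if (na == 0L || nb == 0L) stop("both groups must be non-empty")
    pooled <- c(groupA, groupB)
    uStat <- function(idxA) {
        r <- rank(pooled)
        sum(r[idxA]) - length(idxA) * (length(idxA) + 1) / 2
    }
    U <- uStat(seq_len(na))
    if (length(unique(pooled)) == 1L) {
        warning("constant pooled data; p = 1")
        return(list(U = U, p = 1, method = "degenerate"))
    }
    N <- na + nb
    if (N <= exactLimit) {
        combos <- utils::combn(N, na)
        r <- rank(pooled)
        allU <- apply(combos, 2L, function(ix)
            sum(r[ix]) - na * (na + 1) / 2)
        pLess <- mean(allU <= U)
        pGreater <- mean(allU >= U)
        p <- switch(alternative,
            two.sided = min(1, 2 * min(pLess, pGreater)),
            less = pLess, greater = pGreater)
        return(list(U = U, p = p, method = "exact"))
    }
    mu <- na * nb / 2
    ties <- table(pooled)
    tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tieAdj))
    cc <- 0.5
    p <- switch(alternative,
        two.sided = 2 * pnorm(-(max(abs(U - mu) - cc, 0)) / sigma),
        less = pnorm((U - mu + cc) / sigma),
        greater = pnorm(-(U - mu - cc) / sigma))
    list(U = U, p = min(1, p), method = "normal")
}

#' Compare profile values between phase classes
#'
#' Pools per-offset values of a dyad-aligned profile by rotational class
#' (minor-in vs minor-out, on the aggregate values) or by strand-specific
#' backbone class (backbone-out vs backbone-in, on the per-strand values),
#' and tests the two focal classes with a Mann-Whitney U test. The median
#' difference and its direction are reported alongside the p-value.
#'
#' @param profile a dyad [BinnedProfile-class]; if produced by
#'   [enrichmentRatio()] its enrichment columns are compared, otherwise
#'   the normalized frequency columns.
#' @param phaseTbl a [PhaseTable-class].
#' @param grouping \code{"rotational"} or \code{"backbone"}.
#' @param excludeCore drop offsets with \code{|offset| <= 3} (the
#'   single-gyre dyad core) from the comparison.
#' @return List with \code{valuesA}, \code{valuesB}, \code{classA},
#'   \code{classB}, \code{medianA}, \code{medianB}, \code{direction},
#'   \code{U}, \code{p}.
#' @export
phaseGroupCompare <- function(profile, phaseTbl,
                              grouping = c("rotational", "backbone"),
                              excludeCore = FALSE) {
    grouping <- match.arg(grouping)
    stopifnot(is(profile, "BinnedProfile"), is(phaseTbl, "PhaseTable"))
    bins <- profile@bins
    pt <- phaseTable(phaseTbl)
    m <- match(bins$bin, pt$offset)
    if (anyNA(m)) stop("profile offsets missing from the phase table")
    keep <- if (excludeCore) abs(bins$bin) > 3 else rep(TRUE, nrow(bins))
    if (grouping == "rotational") {
        valCol <- if ("enrichment" %in% names(bins)) "enrichment"
                  else "normFreq"
        v <- bins[[valCol]]
        rot <- pt$rotational[m]
        a <- v[keep & rot == "minor_in"]
        b <- v[keep & rot == "minor_out"]
        classA <- "minor_in"; classB <- "minor_out"
    } else {
        vp <- if ("enrichmentPlus" %in% names(bins)) bins$enrichmentPlus
              else bins$normFreqPlus
        vm <- if ("enrichmentMinus" %in% names(bins)) bins$enrichmentMinus
              else bins$normFreqMinus
        if (is.null(vp) || is.null(vm))
            stop("backbone grouping needs a strand-resolved profile ",
                 "(mode = 'strand')")
        bbP <- pt$backbone_plus[m]
        bbM <- pt$backbone_minus[m]
        a <- c(vp[keep & bbP == "backbone_out"],
               vm[keep & bbM == "backbone_out"])
        b <- c(vp[keep & bbP == "backbone_in"],
               vm[keep & bbM == "backbone_in"])
        classA <- "backbone_out"; classB <- "backbone_in"
    }
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L)
        stop("a phase class has no offsets with defined values")
    tst <- mannWhitneyU(a, b)
    medA <- median(a); medB <- median(b)
    list(valuesA = a, valuesB = b, classA = classA, classB = classB,
         medianA = medA, medianB = medB,
         direction = if (medA > medB) paste(classA, ">", classB)
                     else paste(classA, "<", classB),
         U = tst$U, p = tst$p)
}

#' Nucleosome vs linker normalized dCPD frequency
#'
#' Compares the dipyrimidine-normalized lesion frequency inside
#' nucleosomes (|offset| <= \code{halfwidth}) against adjacent linker DNA
#' (|offset| within \code{linkerRange}), with a rank-sum test over
#' per-nucleosome values. Overlapping windows double-count positions
#' unless \code{dedupe} is set (which drops dyads whose linker window
#' overlaps a neighbouring nucleosome window).
#'
#' @param lesions GRanges of lesions.
#' @param dyads GRanges of dyad positions.
#' @param genome DNAStringSet.
#' @param halfwidth nucleosome half-width (default 73).
#' @param linkerRange absolute-offset range of the linker (default
#'   \code{c(74, 93)}).
#' @param dedupe drop dyads with overlapping windows.
#' @return List with \code{nucFreq}, \code{linkerFreq} (pooled normalized
#'   frequencies), \code{ratio}, per-nucleosome value vectors, \code{U},
#'   \code{p}, and \code{nOverlapping}.
#' @export
nucleosomeVsLinker <- function(lesions, dyads, genome, halfwidth = 73L,
                               linkerRange = c(74L, 93L),
                               dedupe = FALSE) {
    stopifnot(is(dyads, "GRanges"), length(dyads) > 0L)
    if (linkerRange[2L] < linkerRange[1L] ||
        linkerRange[1L] <= halfwidth)
        stop("linker range must lie beyond the nucleosome half-width")
    masks <- dipyrimidineCytosines(genome)
    lc <- .lesionCounts(lesions, genome)
    len <- setNames(BiocGenerics::width(genome), names(genome))
    csL <- lapply(names(genome), function(ch)
        cumsum(lc[[ch]]$plus + lc[[ch]]$minus))
    csD <- lapply(names(genome), function(ch)
        cumsum(as.integer(masks[[ch]]$plus) +
               as.integer(masks[[ch]]$minus)))
    names(csL) <- names(csD) <- names(genome)
    chrom <- as.character(seqnames(dyads))
    dpos <- start(dyads)
    span <- linkerRange[2L]
    full <- GRanges(chrom, IRanges(dpos - span, dpos + span))
    nOver <- sum(countOverlaps(full, full) > 1L)
    if (dedupe && nOver > 0L) {
        keep <- countOverlaps(full, full) == 1L
        chrom <- chrom[keep]; dpos <- dpos[keep]
    }
    nd <- length(dpos)
    if (nd == 0L) stop("no dyads left after de-duplication")
    nucLes <- nucDip <- linkLes <- linkDip <- numeric(nd)
    for (i in seq_len(nd)) {
        ch <- chrom[i]; d <- dpos[i]
        nucLes[i] <- .rangeSum(csL[[ch]], d - halfwidth, d + halfwidth)
        nucDip[i] <- .rangeSum(csD[[ch]], d - halfwidth, d + halfwidth)
        linkLes[i] <-
            .rangeSum(csL[[ch]], d - linkerRange[2L], d - linkerRange[1L]) +
            .rangeSum(csL[[ch]], d + linkerRange[1L], d + linkerRange[2L])
        linkDip[i] <-
            .rangeSum(csD[[ch]], d - linkerRange[2L], d - linkerRange[1L]) +
            .rangeSum(csD[[ch]], d + linkerRange[1L], d + linkerRange[2L])
    }
    nucVals <- ifelse(nucDip > 0, nucLes / nucDip, NA_real_)
    linkVals <- ifelse(linkDip > 0, linkLes / linkDip, NA_real_)
    a <- nucVals[!is.na(nucVals)]
    b <- linkVals[!is.na(linkVals)]
    if (length(a) == 0L || length(b) == 0L)
        stop("no informative nucleosome or linker windows")
    tst <- mannWhitneyU(a, b)
    nucFreq <- sum(nucLes) / sum(nucDip)
    linkerFreq <- sum(linkLes) / sum(linkDip)
    list(nucFreq = nucFreq, linkerFreq = linkerFreq,
         ratio = nucFreq / linkerFreq, perNucleosome = a, perLinker = b,
         U = tst$U, p = tst$p, nOverlapping = nOver)
}
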