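## Forward simulation of the deamination study design: context-weighted CPD
## formation, exponential deamination (cellular vs naked), read emission.

## C-centered trinucleotides compatible with CPD formation: at least one
## same-strand pyrimidine neighbour
.dipyContexts <- c("ACC", "ACT", "CCA", "CCC", "CCG", "CCT",
                   "GCC", "GCT", "TCA", "TCC", "TCG", "TCT")

#' Deamination rate presets per trinucleotide context
#'
#' Half-life-derived rate constants (\code{k = ln2 / t1/2}, per hour) for
#' the cellular and the naked-DNA (in vitro) deamination regimes. The four
#' TCN cellular half-lives are the measured values (TCG 3.7 h, TCA 9.7 h,
#' TCT 10 h, TCC 13 h); the remaining contexts use mid-range values from
#' the reported NCT (6-10 h) and NCC (13-26 h) windows, and the naked-DNA
#' preset uses TCG 8.2 h with the other TCN contexts in the reported
#' 32-77 h window. Values outside the printed ranges are plausible
#' placeholders for simulation only.
#'
#' @param mode \code{"cellular"} or \code{"naked"}.
#' @return Named numeric vector of rate constants (per hour) over the 12
#'   CPD-compatible C-centred trinucleotides.
#' @export
kCtxPreset <- function(mode = c("cellular", "naked")) {
    mode <- match.arg(mode)
    tHalf <- switch(mode,
        cellular = c(TCG = 3.7, TCA = 9.7, TCT = 10, TCC = 13,
                     ACT = 8, GCT = 9, CCT = 6,
                     ACC = 18, GCC = 22, CCC = 26, CCA = 15, CCG = 12),
        naked = c(TCG = 8.2, TCA = 32, TCT = 50, TCC = 77,
                  ACT = 25, GCT = 30, CCT = 18,
                  ACC = 120, GCC = 150, CCC = 180, CCA = 100, CCG = 90))
    log(2) / tHalf[.dipyContexts]
}

#' Build a simulation configuration
#'
#' Collects all simulator parameters with defaults emulating the study
#' design: a yeast-like base composition, a time course of 0/6/24/48 h,
#' cellular deamination modifiers (transcription-factor-site suppression,
#' minor-in rotational elevation, strand-specific backbone-out elevation),
#' and trinucleotide rate presets derived from the measured half-lives.
#' \code{formationProb} is calibrated so the density of cytosine-containing
#' CPDs is of the order of the measured plateau (~0.6 dCPDs per kb at full
#' deamination).
#'
#' @param genomeLength genome size in bp (>= 2000).
#' @param baseComposition named probabilities for A, C, G, T.
#' @param nGenes,geneLengthRange gene track parameters.
#' @param nTfbs number of transcription-factor binding-site midpoints.
#' @param tfbsMargin bp around a TFBS midpoint subject to cellular
#'   suppression.
#' @param nDyads number of nucleosome dyads (default: one per 2 kb).
#' @param dyadSpacing minimum dyad separation in bp (>= 167).
#' @param formationProb baseline CPD probability per candidate cytosine.
#' @param formationWeight named per-context formation weights (unitless).
#' @param formationRotAmplitude amplitude of rotational modulation of
#'   formation at nucleosomes (minor-out elevated); 0 disables.
#' @param kCtx named per-context deamination rate constants (per hour).
#' @param cellularModifiers list with \code{tfbsFactor},
#'   \code{minorInMult}, \code{backboneOutMult}, \code{nucleosomeMult};
#'   applied only in cellular mode.
#' @param timepoints hours, ascending, first may be 0.
#' @param readsPerTimepoint sequencing depth per time point.
#' @param readLengthRange read lengths drawn uniformly from this range.
#' @param phaseTable a [PhaseTable-class]; default [buildPhaseTable()].
#' @param seed integer root seed; all stage seeds derive from it.
#' @return A list of class \code{dcpdSimConfig}.
#' @export
simulationConfig <- function(genomeLength = 2e5,
        baseComposition = c(A = 0.31, C = 0.19, G = 0.19, T = 0.31),
        nGenes = 40, geneLengthRange = c(500, 2000),
        nTfbs = 60, tfbsMargin = 10,
        nDyads = NULL, dyadSpacing = 167,
        formationProb = 0.0022,
        formationWeight = NULL,
        formationRotAmplitude = 0,
        kCtx = kCtxPreset("cellular"),
        cellularModifiers = list(tfbsFactor = 0.5, minorInMult = 1.5,
                                 backboneOutMult = 1.4, nucleosomeMult = 1),
        timepoints = c(0, 6, 24, 48),
        readsPerTimepoint = 2e5,
        readLengthRange = c(20, 50),
        phaseTable = NULL,
        seed = 1L) {
    if (genomeLength < 2000) stop("genomeLength must be >= 2000")
    if (is.null(nDyads)) nDyads <- max(1L, floor(genomeLength / 2000))
    if (is.null(formationWeight))
        formationWeight <- setNames(rep(1, length(.dipyContexts)),
                                    .dipyContexts)
    if (any(kCtx < 0)) stop("all rate constants must be >= 0")
    if (is.unsorted(timepoints)) stop("timepoints must be ascending")
    mods <- cellularModifiers
    if (any(unlist(mods) <= 0)) stop("cellular modifiers must be > 0")
    if (is.null(phaseTable)) phaseTable <- buildPhaseTable()
    structure(list(genomeLength = as.integer(genomeLength),
        baseComposition = baseComposition, nGenes = nGenes,
        geneLengthRange = geneLengthRange, nTfbs = nTfbs,
        tfbsMargin = tfbsMargin, nDyads = as.integer(nDyads),
        dyadSpacing = as.integer(dyadSpacing),
        formationProb = formationProb, formationWeight = formationWeight,
        formationRotAmplitude = formationRotAmplitude, kCtx = kCtx,
        cellularModifiers = mods, timepoints = timepoints,
        readsPerTimepoint = readsPerTimepoint,
        readLengthRange = readLengthRange, phaseTable = phaseTable,
        seed = as.integer(seed)), class = "dcpdSimConfig")
}

#' Simulate a genome with gene, TFBS and dyad tracks
#'
#' Draws a random genome under the configured base composition and places
#' three non-overlapping-per-track feature sets: stranded genes (TSS/TES
#' from start/end plus strand), TFBS midpoints, and nucleosome dyads with
#' a guaranteed minimum spacing. Deterministic under the config seed.
#'
#' @param config a [simulationConfig()].
#' @return List with elements \code{genome} (DNAStringSet, one chromosome
#'   \code{"chrS"}), \code{genes}, \code{tfbs}, \code{dyads} (GRanges).
#' @export
simulateGenomeAndFeatures <- function(config) {
    stopifnot(inherits(config, "dcpdSimConfig"))
    set.seed(config$seed)
    L <- config$genomeLength
    comp <- config$baseComposition[c("A", "C", "G", "T")]
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = comp / sum(comp))
    genome <- DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- "chrS"

    ## dyads: slot-based placement guarantees pairwise spacing
    nD <- config$nDyads
    gap <- floor((L - 200) / nD)
    if (gap < config$dyadSpacing)
        stop("infeasible packing: ", nD, " dyads with spacing ",
             config$dyadSpacing, " do not fit in ", L, " bp")
    jitter <- floor(runif(nD) * (gap - config$dyadSpacing + 1))
    dyadPos <- 100L + (seq_len(nD) - 1L) * gap + as.integer(jitter)
    dyads <- GRanges("chrS", IRanges(dyadPos, width = 1L))

    ## genes: one per slot, length within range, random strand
    nG <- config$nGenes
    slot <- floor(L / nG)
    glmax <- min(config$geneLengthRange[2L], slot - 20L)
    if (glmax < config$geneLengthRange[1L])
        stop("infeasible packing: gene slots of ", slot,
             " bp cannot hold genes of length >= ",
             config$geneLengthRange[1L])
    glen <- config$geneLengthRange[1L] +
        floor(runif(nG) * (glmax - config$geneLengthRange[1L] + 1))
    gstart <- (seq_len(nG) - 1L) * slot + 1L +
        floor(runif(nG) * (slot - glen - 5L))
    gstrand <- ifelse(runif(nG) < 0.5, "+", "-")
    genes <- GRanges("chrS", IRanges(as.integer(gstart),
                                     width = as.integer(glen)),
                     strand = gstrand)
    mcols(genes)$name <- sprintf("gene%03d", seq_len(nG))

    ## TFBS midpoints, one per slot
    nT <- config$nTfbs
    tslot <- floor(L / nT)
    tmid <- (seq_len(nT) - 1L) * tslot + 20L +
        floor(runif(nT) * (tslot - 40L))
    tfbs <- GRanges("chrS", IRanges(as.integer(tmid), width = 1L))

    for (gr in list(genes, tfbs, dyads)) seqlengths(gr) <- c(chrS = L)
    list(genome = genome, genes = genes, tfbs = tfbs, dyads = dyads)
}

## candidate CPD sites: interior dipyrimidine cytosines on both strands,
## with trinucleotide context, ordered (strand +,- ; then position)
.candidateSites <- function(genome) {
    masks <- dipyrimidineCytosines(genome)
    out <- list()
    for (ch in names(genome)) {
        b <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1L]]
        L <- length(b)
        for (str in c("+", "-")) {
            m <- if (str == "+") masks[[ch]]$plus else masks[[ch]]$minus
            p <- which(m)
            p <- p[p >= 2L & p <= L - 1L]
            tri <- paste0(b[p - 1L], b[p], b[p + 1L])
            if (str == "-") tri <- .revcompChar(tri)
            out[[length(out) + 1L]] <- data.frame(chrom = ch, pos = p,
                strand = str, context = tri, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

## dyad offset of each position (NA when > halfwidth from every dyad);
## assumes dyads on one chromosome, sorted, spacing > 2*halfwidth
.dyadOffset <- function(pos, dyadPos, halfwidth = 73L) {
    if (length(dyadPos) == 0L) return(rep(NA_integer_, length(pos)))
    dyadPos <- sort(dyadPos)
    i <- findInterval(pos, dyadPos)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(dyadPos))
    dLo <- pos - dyadPos[lo]
    dHi <- pos - dyadPos[hi]
    off <- ifelse(abs(dLo) <= abs(dHi), dLo, dHi)
    off[abs(off) > halfwidth] <- NA_integer_
    as.integer(off)
}

#' Simulate CPD formation and deamination
#'
#' CPD formation: every interior dipyrimidine cytosine is a CPD with
#' probability proportional to its context formation weight and (optionally)
#' a rotational factor elevated at minor-out settings; the formation draw is
#' shared between modes (same seed), since the cellular and naked samples
#' were irradiated identically. Deamination: each CPD carries one latent
#' exponential deamination time with rate \code{kEff}; in cellular mode
#' \code{kEff} is the context rate times the cellular modifiers (TFBS
#' suppression within midpoint +/- margin, minor-in multiplier,
#' strand-specific backbone-out multiplier, nucleosome-wide multiplier);
#' in naked mode \code{kEff} is the context rate unmodified. The latent
#' uniform draw behind the deamination time is also shared between modes,
#' so deaminated-site sets nest over time and the two modes coincide
#' exactly when all modifiers are 1.
#'
#' @param sim output of [simulateGenomeAndFeatures()].
#' @param config the same [simulationConfig()].
#' @param mode \code{"cellular"} or \code{"naked"}.
#' @return A [SimulationTruth-class].
#' @export
simulateDamageAndDeamination <- function(sim, config,
                                         mode = c("cellular", "naked")) {
    mode <- match.arg(mode)
    stopifnot(inherits(config, "dcpdSimConfig"))
    cand <- .candidateSites(sim$genome)
    missing <- setdiff(unique(cand$context), names(config$kCtx))
    if (length(missing) > 0L)
        stop("contexts missing from kCtx: ", paste(missing, collapse = ", "))

    ## formation (shared draw between modes)
    w <- config$formationWeight[cand$context]
    w[is.na(w)] <- 0
    off <- .dyadOffset(cand$pos, start(sim$dyads))
    rotF <- rep(1, nrow(cand))
    if (config$formationRotAmplitude != 0) {
        has <- !is.na(off)
        rotF[has] <- 1 + config$formationRotAmplitude *
            cos(2 * pi * (abs(off[has]) - 2) / 10.17)
    }
    p <- pmin(1, config$formationProb * w * rotF)
    set.seed(config$seed + 1L)
    formed <- runif(nrow(cand)) < p
    cand <- cand[formed, , drop = FALSE]
    off <- off[formed]

    ## effective rate
    k <- unname(config$kCtx[cand$context])
    kEff <- k
    if (mode == "cellular") {
        mods <- config$cellularModifiers
        if (length(sim$tfbs) > 0L && mods$tfbsFactor != 1) {
            tf <- GRanges(cand$chrom,
                IRanges(cand$pos, width = 1L))
            win <- resize(sim$tfbs, 2L * config$tfbsMargin + 1L,
                          fix = "center")
            inTf <- overlapsAny(tf, win, ignore.strand = TRUE)
            kEff[inTf] <- kEff[inTf] * mods$tfbsFactor
        }
        has <- !is.na(off)
        if (any(has)) {
            pt <- phaseTable(config$phaseTable)
            rot <- pt$rotational[match(off[has], pt$offset)]
            bb <- ifelse(cand$strand[has] == "+",
                         pt$backbone_plus[match(off[has], pt$offset)],
                         pt$backbone_minus[match(off[has], pt$offset)])
            f <- rep(mods$nucleosomeMult, sum(has))
            f[rot == "minor_in"] <- f[rot == "minor_in"] * mods$minorInMult
            f[bb == "backbone_out"] <- f[bb == "backbone_out"] *
                mods$backboneOutMult
            kEff[has] <- kEff[has] * f
        }
    }

    ## latent deamination time (shared uniform draw between modes)
    set.seed(config$seed + 2L)
    u <- runif(nrow(cand))
    deamTime <- ifelse(kEff > 0, -log1p(-u) / kEff, Inf)

    sites <- GRanges(cand$chrom, IRanges(cand$pos, width = 1L),
                     strand = cand$strand)
    seqlengths(sites) <- setNames(BiocGenerics::width(sim$genome),
                                  names(sim$genome))[seqlevels(sites)]
    mcols(sites)$context <- cand$context
    mcols(sites)$k <- k
    mcols(sites)$kEff <- kEff
    mcols(sites)$deamTime <- deamTime
    new("SimulationTruth", genome = sim$genome,
        features = list(genes = sim$genes, tfbs = sim$tfbs,
                        dyads = sim$dyads),
        sites = sites, mode = mode, config = unclass(config))
}

#' Sites deaminated by a given time
#'
#' @param truth a [SimulationTruth-class].
#' @param timepoint hours.
#' @return GRanges subset of the truth sites with deamination time
#'   \code{<= timepoint}.
#' @export
deaminatedSites <- function(truth, timepoint) {
    stopifnot(is(truth, "SimulationTruth"))
    truth@sites[mcols(truth@sites)$deamTime <= timepoint]
}

#' Emit sequencing reads from deaminated sites
#'
#' Samples reads uniformly with replacement from the sites deaminated by
#' \code{timepoint} and places each read so that [callLesions()] recovers
#' the site exactly: a minus-strand lesion at position p yields a
#' plus-strand read starting at p+1; a plus-strand lesion at p yields a
#' minus-strand read ending at p-1. Read lengths are uniform over the
#' configured range, clipped at chromosome ends (irrelevant to decoding).
#'
#' @param truth a [SimulationTruth-class].
#' @param timepoint hours.
#' @param depth number of reads to emit.
#' @param seed integer seed for the sampling.
#' @return GRanges of reads (strand = read strand).
#' @export
emitReads <- function(truth, timepoint, depth, seed = 1L) {
    stopifnot(is(truth, "SimulationTruth"))
    depth <- as.integer(depth)
    sites <- deaminatedSites(truth, timepoint)
    if (depth == 0L)
        return(GRanges(seqlengths = seqlengths(truth@sites)))
    if (length(sites) == 0L)
        stop("no deaminated sites at t = ", timepoint,
             " but depth > 0 requested")
    set.seed(seed)
    idx <- sample.int(length(sites), depth, replace = TRUE)
    lr <- truth@config$readLengthRange
    rl <- lr[1L] + floor(runif(depth) * (lr[2L] - lr[1L] + 1))
    pos <- start(sites)[idx]
    str <- as.character(strand(sites))[idx]
    chrom <- as.character(seqnames(sites))[idx]
    len <- seqlengths(truth@sites)[chrom]
    ## minus-strand lesion -> plus-strand read downstream of it
    rStart <- ifelse(str == "-", pos + 1L, pmax(pos - rl, 1L))
    rEnd <- ifelse(str == "-", pmin(pos + rl, len), pos - 1L)
    rStrand <- ifelse(str == "-", "+", "-")
    reads <- GRanges(chrom, IRanges(as.integer(rStart), as.integer(rEnd)),
                     strand = rStrand)
    seqlengths(reads) <- seqlengths(truth@sites)[seqlevels(reads)]
    reads
}

#' Write simulation outputs to disk
#'
#' Writes the genome as FASTA, the feature tracks and the per-timepoint
#' read sets as BED6, and the ground truth (site table and configuration
#' summary) as JSON.
#'
#' @param truth a [SimulationTruth-class].
#' @param outdir output directory (created if needed).
#' @param readSeedBase per-timepoint emission seeds are
#'   \code{readSeedBase + index}.
#' @return Invisibly, a named list of the written paths.
#' @export
writeSimulation <- function(truth, outdir, readSeedBase = 1000L) {
    stopifnot(is(truth, "SimulationTruth"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(outdir, "genome.fa"))
    writeXStringSet(truth@genome, paths$genome)
    for (fe in names(truth@features)) {
        paths[[fe]] <- file.path(outdir, paste0(fe, ".bed"))
        rtracklayer::export(truth@features[[fe]], paths[[fe]],
                            format = "BED")
    }
    cfg <- truth@config
    tps <- cfg$timepoints
    depth <- cfg$readsPerTimepoint
    for (i in seq_along(tps)) {
        d <- if (length(deaminatedSites(truth, tps[i])) == 0L) 0L
             else depth
        reads <- emitReads(truth, tps[i], d, seed = readSeedBase + i)
        nm <- sprintf("reads_%s_t%g.bed", truth@mode, tps[i])
        paths[[nm]] <- file.path(outdir, nm)
        rtracklayer::export(reads, paths[[nm]], format = "BED")
    }
    st <- truth@sites
    truthJson <- list(mode = truth@mode,
        nSites = length(st),
        sites = data.frame(chrom = as.character(seqnames(st)),
            pos0 = start(st) - 1L, strand = as.character(strand(st)),
            context = mcols(st)$context, kEff = mcols(st)$kEff,
            deamTime = mcols(st)$deamTime),
        seed = cfg$seed, timepoints = tps)
    paths$truth <- file.path(outdir, sprintf("truth_%s.json", truth@mode))
    jsonlite::write_json(truthJson, paths$truth, digits = NA,
                         auto_unbox = TRUE)
    invisible(paths)
}
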