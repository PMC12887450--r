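## Trinucleotide enrichment, absolute scaling by bulk gel measurements,
## one-phase association kinetics.

#' Trinucleotide enrichment of lesions
#'
#' For each C-centred trinucleotide context, the enrichment score is the
#' fraction of lesion reads in that context divided by the fraction of
#' genomic trinucleotides (both strands) in that context. Within the chosen
#' context universe, read fractions and genome fractions each sum to 1, so
#' the genome-fraction-weighted mean enrichment is exactly 1 whenever all
#' reads are context-assignable.
#'
#' @param lesions GRanges annotated by [annotateContext()] (or the
#'   \code{trinucleotide} metadata column filled some other way).
#' @param genome DNAStringSet.
#' @param contexts \code{"NCN16"} (all 16 C-centred trinucleotides, the
#'   default) or \code{"dipy12"} (the 12 compatible with CPD formation).
#' @return data.frame with columns \code{context}, \code{readCount},
#'   \code{readFraction}, \code{genomeCount}, \code{genomeFraction},
#'   \code{enrichment}; attribute \code{"nUnassigned"} counts lesions
#'   outside the universe (undefined or non-C contexts).
#' @export
trinucleotideEnrichment <- function(lesions, genome,
                                    contexts = c("NCN16", "dipy12")) {
    contexts <- match.arg(contexts)
    tri <- mcols(lesions)$trinucleotide
    if (is.null(tri))
        stop("lesions must be annotated with trinucleotide context; ",
             "run annotateContext() first")
    universe <- if (contexts == "dipy12") .dipyContexts else {
        km <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L)
        sort(km[substr(km, 2L, 2L) == "C"])
    }
    inU <- !is.na(tri) & tri %in% universe
    nReads <- sum(inU)
    if (length(lesions) == 0L || nReads == 0L)
        stop("no lesions with an assignable context")
    readCount <- as.numeric(table(factor(tri[inU], levels = universe)))
    gAll <- countContextOccurrences(genome, 3L)
    genomeCount <- as.numeric(gAll[universe])
    gTotal <- sum(genomeCount)
    if (gTotal == 0) stop("no genomic occurrences of any context")
    readFraction <- readCount / nReads
    genomeFraction <- genomeCount / gTotal
    enrichment <- ifelse(genomeCount > 0,
                         readFraction / genomeFraction, NA_real_)
    out <- data.frame(context = universe, readCount = readCount,
        readFraction = readFraction, genomeCount = genomeCount,
        genomeFraction = genomeFraction, enrichment = enrichment,
        stringsAsFactors = FALSE)
    attr(out, "nUnassigned") <- length(lesions) - nReads
    out
}

#' Scale enrichment scores to absolute dCPD frequencies
#'
#' Multiplies each context's enrichment score by the bulk uracil frequency
#' measured on genomic DNA (alkaline gel assay, uracils per kb), yielding
#' an absolute dCPD frequency per kb of total DNA per context. By
#' construction the genome-fraction-weighted mean of the absolute values
#' equals the bulk input (up to any unassigned-context mass).
#'
#' @param table output of [trinucleotideEnrichment()].
#' @param bulkUracilsPerKb non-negative bulk measurement.
#' @param perSite also add a per-context-site variant
#'   (\code{absolutePerSiteKb}): lesions per kb of context sites rather
#'   than per kb of total DNA.
#' @return The table with an \code{absolutePerKb} column added.
#' @export
absoluteDcpdFrequency <- function(table, bulkUracilsPerKb,
                                  perSite = FALSE) {
    if (!is.numeric(bulkUracilsPerKb) || length(bulkUracilsPerKb) != 1L ||
        is.na(bulkUracilsPerKb) || bulkUracilsPerKb < 0)
        stop("bulkUracilsPerKb must be a single non-negative number")
    table$absolutePerKb <- table$enrichment * bulkUracilsPerKb
    if (perSite) {
        ## lesions per kb of sites of this context: divide the per-kb-of-
        ## total-DNA value by the context's share of positions
        table$absolutePerSiteKb <- table$absolutePerKb /
            ifelse(table$genomeFraction > 0, table$genomeFraction, NA_real_)
    }
    table
}

#' Fit one-phase association kinetics
#'
#' Nonlinear least squares fit of \eqn{y(t) = P (1 - e^{-kt})}, the
#' one-phase association model for deamination time courses. The fit is
#' deterministic: initialisation is \eqn{P_0 = \max(y)},
#' \eqn{k_0 = \ln 2 / \mathrm{median}(t > 0)}, with bounds
#' \eqn{k \in (10^{-6}, 10]} per hour. Non-convergence or degenerate input
#' (all-zero y) yields a flagged, never silent, result.
#'
#' @param t timepoints in hours (>= 3 values).
#' @param y absolute dCPD frequency at each timepoint (>= 0).
#' @param context optional context label carried into the result.
#' @return A [KineticFit-class].
#' @export
fitOnePhase <- function(t, y, context = NA_character_) {
    stopifnot(length(t) == length(y))
    if (length(t) < 3L) stop("at least 3 timepoints are required")
    if (any(y < 0)) stop("y must be non-negative")
    fail <- function(msg) new("KineticFit", context = context,
        timepoints = as.numeric(t), y = as.numeric(y), k = NA_real_,
        plateau = NA_real_, tHalf = NA_real_,
        residuals = rep(NA_real_, length(y)), converged = FALSE,
        message = msg)
    if (all(y == 0)) return(fail("all-zero y; no deamination signal"))
    p0 <- max(y)
    tpos <- t[t > 0]
    k0 <- if (length(tpos) > 0) log(2) / median(tpos) else 0.1
    k0 <- min(max(k0, 2e-6), 10)
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ P * (1 - exp(-k * tt)),
            data = data.frame(tt = t, y = y),
            start = list(P = p0, k = k0),
            lower = c(P = 1e-12, k = 1e-6), upper = c(P = Inf, k = 10),
            control = minpack.lm::nls.lm.control(
                ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
        error = function(e) e)
    if (inherits(fit, "error"))
        return(fail(paste("fit failed:", conditionMessage(fit))))
    cf <- coef(fit)
    new("KineticFit", context = context, timepoints = as.numeric(t),
        y = as.numeric(y), k = unname(cf["k"]), plateau = unname(cf["P"]),
        tHalf = log(2) / unname(cf["k"]),
        residuals = as.numeric(y - predict(fit)), converged = TRUE,
        message = "")
}

#' Strand breaks per kb from number-average fragment lengths
#'
#' Under Poisson random breakage, the break frequency per kb follows from
#' the number-average fragment lengths of the damaged and the control
#' sample: \eqn{1000 (1/L_d - 1/L_c)}. This is the fragment-length to
#' breaks-per-kb conversion behind alkaline gel quantification.
#'
#' @param numberAvgLenDamaged number-average fragment length (bp) of the
#'   digested, damaged sample.
#' @param numberAvgLenControl number-average length of the control;
#'   \code{Inf} for unbroken DNA.
#' @return Breaks per kb.
#' @export
breaksPerKbFromLengths <- function(numberAvgLenDamaged,
                                   numberAvgLenControl) {
    if (any(numberAvgLenDamaged <= 0) ||
        any(numberAvgLenControl <= 0))
        stop("fragment lengths must be > 0")
    if (any(numberAvgLenDamaged > numberAvgLenControl))
        stop("damaged-sample fragments longer than control implies a ",
             "negative break frequency")
    1000 * (1 / numberAvgLenDamaged - 1 / numberAvgLenControl)
}

#' Per-context kinetic analysis of a lesion time course
#'
#' Convenience wrapper: computes the trinucleotide enrichment table at
#' each timepoint, scales to absolute dCPD frequencies with the matching
#' bulk gel measurement, and fits one-phase association kinetics per
#' context.
#'
#' @param lesionsList list of annotated lesion GRanges, one per timepoint.
#' @param timepoints hours, same length as \code{lesionsList}.
#' @param bulkPerKb bulk uracils per kb at each timepoint.
#' @param genome DNAStringSet.
#' @param contexts context universe, see [trinucleotideEnrichment()].
#' @param fitContexts contexts to fit (default: those with positive
#'   absolute frequency at the last timepoint).
#' @return List with \code{table} (long data.frame: timepoint x context
#'   absolute frequencies) and \code{fits} (named list of
#'   [KineticFit-class]).
#' @export
contextKinetics <- function(lesionsList, timepoints, bulkPerKb, genome,
                            contexts = "NCN16", fitContexts = NULL) {
    stopifnot(length(lesionsList) == length(timepoints),
              length(bulkPerKb) == length(timepoints))
    rows <- list()
    for (i in seq_along(timepoints)) {
        if (bulkPerKb[i] > 0 || length(lesionsList[[i]]) > 0) {
            tab <- trinucleotideEnrichment(lesionsList[[i]], genome,
                                           contexts = contexts)
            tab <- absoluteDcpdFrequency(tab, bulkPerKb[i])
        } else {
            tab <- data.frame(context = character(0))
        }
        if (nrow(tab) > 0) {
            tab$timepoint <- timepoints[i]
            rows[[length(rows) + 1L]] <- tab
        }
    }
    long <- do.call(rbind, rows)
    ctxAll <- unique(long$context)
    if (is.null(fitContexts)) fitContexts <- ctxAll
    fits <- list()
    for (ctx in fitContexts) {
        sub <- long[long$context == ctx, ]
        tt <- sub$timepoint
        yy <- sub$absolutePerKb
        ## timepoints absent from the table (zero-signal) contribute y = 0
        missingT <- setdiff(timepoints, tt)
        if (length(missingT) > 0) {
            tt <- c(tt, missingT)
            yy <- c(yy, rep(0, length(missingT)))
        }
        o <- order(tt)
        fits[[ctx]] <- fitOnePhase(tt[o], yy[o], context = ctx)
    }
    list(table = long, fits = fits)
}
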