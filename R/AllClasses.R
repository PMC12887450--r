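#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' Rotational and backbone phase classification of nucleosomal offsets
#'
#' A \code{PhaseTable} assigns every dyad offset in \code{-halfwidth..halfwidth}
#' (default \code{-73..+73}, the 147 bp of nucleosomal DNA) to exactly one
#' rotational class (\code{minor_in}, \code{minor_out} or \code{intermediate})
#' and, at intermediate offsets only, a strand-specific backbone class
#' (\code{backbone_in}, \code{backbone_out} or \code{none}).
#'
#' @slot table data.frame with columns \code{offset}, \code{rotational},
#'   \code{backbone_plus}, \code{backbone_minus}.
#' @slot provenance character scalar; \code{"default"} for the built-in
#'   periodic construction or the path of a user-supplied table.
#'
#' @seealso [buildPhaseTable()], [readPhaseTable()], [writePhaseTable()]
#' @export
setClass("PhaseTable",
    representation(table = "data.frame", provenance = "character"))

setValidity("PhaseTable", function(object) {
    tb <- object@table
    need <- c("offset", "rotational", "backbone_plus", "backbone_minus")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(tb$offset))
        return("duplicate offsets")
    if (any(diff(sort(tb$offset)) != 1L))
        return("offsets must be contiguous")
    rot <- c("minor_in", "minor_out", "intermediate")
    if (!all(tb$rotational %in% rot))
        return("invalid rotational class")
    bb <- c("backbone_in", "backbone_out", "none")
    if (!all(tb$backbone_plus %in% bb) || !all(tb$backbone_minus %in% bb))
        return("invalid backbone class")
    inter <- tb$rotational == "intermediate"
    if (any(tb$backbone_plus[!inter] != "none") ||
        any(tb$backbone_minus[!inter] != "none"))
        return("backbone classes are only assigned at intermediate offsets")
    shared <- tb$backbone_plus != "none" & tb$backbone_plus == tb$backbone_minus
    if (any(shared))
        return("the two strands may not share a backbone class at an offset")
    TRUE
})

#' One-phase association kinetic fit
#'
#' Result of fitting \eqn{y(t) = P (1 - e^{-kt})} to a deamination time
#' course, the model used for CPD deamination kinetics. On success \code{k}
#' (h^-1) and \code{plateau} are positive and \code{tHalf = ln 2 / k}.
#'
#' @slot context character; sequence context label (may be \code{NA}).
#' @slot timepoints numeric; hours.
#' @slot y numeric; absolute dCPD frequency at each timepoint.
#' @slot k,plateau,tHalf numeric scalars (NA when the fit failed).
#' @slot residuals numeric; observed minus fitted.
#' @slot converged logical scalar.
#' @slot message character; diagnostics when not converged.
#'
#' @seealso [fitOnePhase()]
#' @export
setClass("KineticFit",
    representation(context = "character", timepoints = "numeric",
        y = "numeric", k = "numeric", plateau = "numeric", tHalf = "numeric",
        residuals = "numeric", converged = "logical", message = "character"))

setValidity("KineticFit", function(object) {
    if (length(object@timepoints) != length(object@y))
        return("timepoints and y differ in length")
    if (object@converged) {
        if (!is.finite(object@k) || object@k <= 0)
            return("converged fit requires k > 0")
        if (!is.finite(object@plateau) || object@plateau <= 0)
            return("converged fit requires plateau > 0")
        if (abs(object@tHalf * object@k - log(2)) > 1e-8)
            return("tHalf * k must equal ln 2")
    }
    TRUE
})

#' Binned lesion profile over aligned genomic features
#'
#' Per-bin (or per-offset) lesion counts with matching counts of
#' dipyrimidine-context cytosines (the normalisation denominator), as used
#' for gene metaprofiles, TFBS profiles and dyad-aligned profiles. The
#' normalised frequency is \code{lesions / dipyC} and is \code{NA} (never 0)
#' where the denominator is empty.
#'
#' @slot bins data.frame; always has columns \code{bin}, \code{lesions},
#'   \code{dipyC}, \code{normFreq}; strand-resolved profiles add per-strand
#'   columns.
#' @slot kind character; \code{"gene"}, \code{"site"} or \code{"dyad"}.
#' @slot mode character; for dyad profiles one of \code{"aggregate"},
#'   \code{"strand"}, \code{"aligned53"}; otherwise \code{""}.
#' @slot nSites integer; number of features aggregated.
#' @slot nSkipped integer; features skipped (e.g. genes shorter than the
#'   number of body bins).
#'
#' @seealso [geneMetaprofile()], [siteProfile()], [dyadProfile()]
#' @export
setClass("BinnedProfile",
    representation(bins = "data.frame", kind = "character",
        mode = "character", nSites = "integer", nSkipped = "integer"))

setValidity("BinnedProfile", function(object) {
    need <- c("bin", "lesions", "dipyC", "normFreq")
    if (!all(need %in% names(object@bins)))
        return(paste("bins must have columns:", paste(need, collapse = ", ")))
    TRUE
})

#' Ground truth of a forward deamination simulation
#'
#' Holds everything the simulator knows: the genome, the feature tracks, the
#' CPD sites with their per-site effective deamination rate and latent
#' deamination time, and the configuration. Deaminated-site sets at
#' increasing times are nested by construction because each site carries a
#' single exponential deamination time.
#'
#' @slot genome DNAStringSet.
#' @slot features list with elements \code{genes}, \code{tfbs}, \code{dyads}
#'   (GRanges).
#' @slot sites GRanges of CPD sites (width 1, stranded) with metadata
#'   columns \code{context}, \code{k}, \code{kEff}, \code{deamTime}.
#' @slot mode character; \code{"cellular"} or \code{"naked"}.
#' @slot config list; the [simulationConfig()] used.
#'
#' @seealso [simulateDamageAndDeamination()], [deaminatedSites()],
#'   [emitReads()]
#' @export
setClass("SimulationTruth",
    representation(genome = "DNAStringSet", features = "list",
        sites = "GRanges", mode = "character", config = "list"))

setValidity("SimulationTruth", function(object) {
    if (!object@mode %in% c("cellular", "naked"))
        return("mode must be 'cellular' or 'naked'")
    mc <- names(S4Vectors::mcols(object@sites))
    need <- c("context", "k", "kEff", "deamTime")
    if (!all(need %in% mc))
        return(paste("sites must carry metadata:", paste(need, collapse = ", ")))
    TRUE
})

setMethod("show", "PhaseTable", function(object) {
    tb <- object@table
    cat("PhaseTable over offsets", min(tb$offset), "..", max(tb$offset),
        sprintf("(%d positions)\n", nrow(tb)))
    cat("  rotational:", sum(tb$rotational == "minor_in"), "minor_in,",
        sum(tb$rotational == "minor_out"), "minor_out,",
        sum(tb$rotational == "intermediate"), "intermediate\n")
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "KineticFit", function(object) {
    cat("KineticFit", if (!is.na(object@context)) object@context else "",
        if (object@converged) "(converged)" else "(NOT converged)", "\n")
    if (object@converged)
        cat(sprintf("  k = %.4g /h, plateau = %.4g, t1/2 = %.4g h\n",
            object@k, object@plateau, object@tHalf))
    else cat(" ", object@message, "\n")
})

setMethod("show", "BinnedProfile", function(object) {
    cat("BinnedProfile [", object@kind,
        if (nzchar(object@mode)) paste0("/", object@mode) else "", "] ",
        nrow(object@bins), " bins over ", object@nSites, " features",
        if (object@nSkipped > 0L) sprintf(" (%d skipped)", object@nSkipped),
        "\n", sep = "")
})

setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth (", object@mode, " mode)\n", sep = "")
    cat("  genome:", length(object@genome), "sequence(s),",
        sum(Biostrings::width(object@genome)), "bp\n")
    cat("  CPD sites:", length(object@sites), "\n")
})

#' Accessors for phase tables, fits, profiles and simulation truth
#'
#' @param x the object.
#' @return \code{phaseTable} the classification data.frame;
#'   \code{profileBins} the per-bin data.frame; \code{fitCoefficients} a
#'   named numeric vector \code{c(k, plateau, tHalf)}; \code{truthSites} the
#'   site-level GRanges.
#' @name accessors
NULL

#' @rdname accessors
#' @export
phaseTable <- function(x) {
    stopifnot(is(x, "PhaseTable"))
    x@table
}

#' @rdname accessors
#' @export
profileBins <- function(x) {
    stopifnot(is(x, "BinnedProfile"))
    x@bins
}

#' @rdname accessors
#' @export
fitCoefficients <- function(x) {
    stopifnot(is(x, "KineticFit"))
    c(k = x@k, plateau = x@plateau, tHalf = x@tHalf)
}

#' @rdname accessors
#' @export
truthSites <- function(x) {
    stopifnot(is(x, "SimulationTruth"))
    x@sites
}
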