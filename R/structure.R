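## Solvent accessible surface area (Shrake-Rupley with a deterministic
## spiral lattice) and backbone B-factor profiling of nucleosome structures.

#' Default van der Waals radii
#'
#' Bondi-style heavy-atom radii in Angstrom, united-atom treatment (no
#' hydrogen inflation; crystal structures typically lack hydrogens).
#'
#' @return Named numeric vector (element -> radius).
#' @export
defaultVdwRadii <- function() {
    c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)
}

#' Parse a PDB structure into atom records
#'
#' Reads ATOM (and optionally HETATM) records, resolves alternate
#' locations (keeps blank or 'A'), optionally drops waters and common
#' ions, and assigns per-atom van der Waals radii by element (falling back
#' to the first letter of the atom name when the element column is
#' absent).
#'
#' @param pdbPath path to a PDB file.
#' @param keepHet include HETATM records.
#' @param dropWater drop HOH/WAT residues and monatomic ions.
#' @param radii named element -> radius map, see [defaultVdwRadii()].
#' @return data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{atom}, \code{x}, \code{y}, \code{z}, \code{b},
#'   \code{element}, \code{radius}.
#' @export
parseStructure <- function(pdbPath, keepHet = FALSE, dropWater = TRUE,
                           radii = defaultVdwRadii()) {
    if (!file.exists(pdbPath)) stop("PDB file not found: ", pdbPath)
    pdb <- tryCatch(bio3d::read.pdb(pdbPath),
        error = function(e) stop("unparseable PDB file ", pdbPath, ": ",
                                 conditionMessage(e)))
    at <- pdb$atom
    if (!keepHet) at <- at[at$type == "ATOM", , drop = FALSE]
    if (nrow(at) == 0L) stop("no atoms retained from ", pdbPath)
    alt <- at$alt
    alt[is.na(alt)] <- ""
    at <- at[alt %in% c("", "A"), , drop = FALSE]
    if (dropWater)
        at <- at[!(at$resid %in% c("HOH", "WAT", "NA", "CL", "MG", "MN",
                                   "K", "ZN", "CA")), , drop = FALSE]
    el <- at$elesy
    if (is.null(el)) el <- rep(NA_character_, nrow(at))
    el <- toupper(trimws(el))
    noEl <- is.na(el) | el == ""
    el[noEl] <- substr(gsub("[0-9']", "", toupper(at$elety[noEl])), 1L, 1L)
    r <- radii[el]
    unknown <- is.na(r)
    if (any(unknown)) {
        warning(sum(unknown), " atom(s) with unknown element assigned ",
                "the carbon radius")
        r[unknown] <- radii[["C"]]
    }
    out <- data.frame(chain = at$chain, resno = at$resno,
        resid = trimws(at$resid), atom = trimws(at$elety),
        x = at$x, y = at$y, z = at$z, b = at$b,
        element = el, radius = unname(r), stringsAsFactors = FALSE)
    if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z)))
        stop("non-finite coordinates in ", pdbPath)
    out
}

## deterministic generalized-spiral (golden-angle) unit sphere lattice
.spiralLattice <- function(n) {
    k <- seq_len(n)
    z <- 1 - (2 * k - 1) / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- (k - 1) * pi * (3 - sqrt(5))
    cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom SASA by test-point counting on a deterministic golden-angle
#' spiral lattice (no randomness anywhere): each atom's expanded sphere
#' (van der Waals radius + probe radius) carries \code{nPoints} points; a
#' point is exposed if it lies outside every neighbouring expanded
#' sphere; SASA is \eqn{4\pi (r_i + w)^2} times the exposed fraction. The
#' probe radius \eqn{w} is 1.4 A for water and 1.1 A for hydroxide, the
#' two species implicated in hydrolytic attack on cytosine C4.
#'
#' @param atoms data.frame from [parseStructure()] (needs \code{x},
#'   \code{y}, \code{z}, \code{radius}).
#' @param probeRadius probe radius in Angstrom (> 0), or \code{"water"} /
#'   \code{"hydroxide"}.
#' @param nPoints lattice points per atom (>= 92; default 960).
#' @param orientation optional 3x3 rotation applied to the lattice (lets
#'   the lattice co-rotate with a rigidly transformed molecule, making
#'   SASA exactly rotation-invariant).
#' @return Numeric vector of per-atom SASA values (Angstrom^2).
#' @export
shrakeRupleySasa <- function(atoms, probeRadius = 1.4, nPoints = 960L,
                             orientation = NULL) {
    if (is.character(probeRadius))
        probeRadius <- switch(match.arg(probeRadius,
                                        c("water", "hydroxide")),
                              water = 1.4, hydroxide = 1.1)
    stopifnot(probeRadius > 0, nPoints >= 92L)
    n <- nrow(atoms)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    R <- atoms$radius + probeRadius
    lattice <- .spiralLattice(nPoints)
    if (!is.null(orientation)) {
        stopifnot(is.matrix(orientation), all(dim(orientation) == c(3, 3)))
        lattice <- lattice %*% t(orientation)
    }
    sasa <- numeric(n)
    maxR <- max(R)
    for (i in seq_len(n)) {
        d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
              (xyz[, 3L] - xyz[i, 3L])^2
        nb <- which(d2 < (R[i] + R)^2 & d2 > 0)
        if (length(nb) == 0L) {
            sasa[i] <- 4 * pi * R[i]^2
            next
        }
        pts <- sweep(lattice * R[i], 2L, xyz[i, ], "+")
        buried <- logical(nPoints)
        for (j in nb) {
            if (all(buried)) break
            free <- which(!buried)
            dj2 <- (pts[free, 1L] - xyz[j, 1L])^2 +
                   (pts[free, 2L] - xyz[j, 2L])^2 +
                   (pts[free, 3L] - xyz[j, 3L])^2
            buried[free[dj2 < R[j]^2]] <- TRUE
        }
        sasa[i] <- 4 * pi * R[i]^2 * (1 - sum(buried) / nPoints)
    }
    sasa
}

#' Canonical offset map for a two-chain 147-bp duplex
#'
#' Maps (chain, residue number) to dyad offset and strand for an idealized
#' 147-bp nucleosomal duplex: the plus chain runs 5'->3' with residue 74 at
#' the dyad (offset = resno - 74); the antiparallel minus chain pairs
#' residue k with offset 74 - k.
#'
#' @param chainPlus,chainMinus chain identifiers.
#' @param halfwidth dyad half-width (default 73; 2*halfwidth+1 residues
#'   per chain).
#' @return data.frame with columns \code{chain}, \code{resno},
#'   \code{offset}, \code{strand}.
#' @export
duplexOffsetMap <- function(chainPlus = "I", chainMinus = "J",
                            halfwidth = 73L) {
    n <- 2L * halfwidth + 1L
    rbind(
        data.frame(chain = chainPlus, resno = seq_len(n),
                   offset = seq_len(n) - (halfwidth + 1L), strand = "+",
                   stringsAsFactors = FALSE),
        data.frame(chain = chainMinus, resno = seq_len(n),
                   offset = (halfwidth + 1L) - seq_len(n), strand = "-",
                   stringsAsFactors = FALSE))
}

#' Read/write an offset map as TSV
#'
#' @param path file path.
#' @return \code{readOffsetMap} the data.frame.
#' @export
readOffsetMap <- function(path) {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c(chain = "character", strand = "character"))
}

#' @rdname readOffsetMap
#' @param map offset map data.frame.
#' @export
writeOffsetMap <- function(map, path) {
    write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.cytosineResnames <- c("DC", "C", "CYT")

#' Cytosine C4 solvent accessibility by rotational class
#'
#' Computes per-atom SASA for the whole structure (occlusion needs every
#' atom), extracts the C4 atom of each cytosine residue, maps residues to
#' dyad offsets, attaches the rotational class from a phase table, and
#' compares minor-in against minor-out with a Mann-Whitney U test. The C4
#' atom is the site of hydrolytic attack during cytosine deamination, so
#' its accessibility is the structural correlate of deamination propensity.
#'
#' @param atoms data.frame from [parseStructure()].
#' @param probeRadius probe radius (1.4 water, 1.1 hydroxide).
#' @param offsetMap data.frame (chain, resno, offset, strand), see
#'   [duplexOffsetMap()].
#' @param phaseTbl a [PhaseTable-class].
#' @param nPoints lattice points per atom.
#' @return List with \code{table} (chain, resno, offset, strand,
#'   rotational, sasa), \code{nZero}, \code{U}, \code{p},
#'   \code{medianMinorIn}, \code{medianMinorOut}.
#' @export
c4SasaByClass <- function(atoms, probeRadius = 1.4, offsetMap,
                          phaseTbl = buildPhaseTable(), nPoints = 960L) {
    isC4 <- atoms$atom == "C4" & atoms$resid %in% .cytosineResnames
    if (!any(isC4)) stop("structure contains no cytosine C4 atoms")
    sasa <- shrakeRupleySasa(atoms, probeRadius, nPoints)
    c4 <- atoms[isC4, c("chain", "resno"), drop = FALSE]
    c4$sasa <- sasa[isC4]
    key <- paste(c4$chain, c4$resno)
    mkey <- paste(offsetMap$chain, offsetMap$resno)
    m <- match(key, mkey)
    c4$offset <- offsetMap$offset[m]
    c4$strand <- offsetMap$strand[m]
    pt <- phaseTable(phaseTbl)
    c4$rotational <- pt$rotational[match(c4$offset, pt$offset)]
    a <- c4$sasa[!is.na(c4$rotational) & c4$rotational == "minor_in"]
    b <- c4$sasa[!is.na(c4$rotational) & c4$rotational == "minor_out"]
    tst <- if (length(a) > 0L && length(b) > 0L) mannWhitneyU(a, b)
           else list(U = NA_real_, p = NA_real_)
    list(table = c4, nZero = sum(c4$sasa == 0),
         U = tst$U, p = tst$p,
         medianMinorIn = if (length(a)) median(a) else NA_real_,
         medianMinorOut = if (length(b)) median(b) else NA_real_)
}

#' Backbone B-factor profile aligned 5'->3'
#'
#' Averages the crystallographic B-factor (a proxy for DNA backbone
#' mobility) over the backbone atoms of each nucleotide, maps residues to
#' dyad offsets, aligns both strands in the same 5'->3' orientation
#' (minus-strand offset o maps to -o) and averages across the aligned
#' strands; then compares backbone-out against backbone-in offsets with a
#' Mann-Whitney U test. Residues lacking all backbone atoms are excluded
#' and tallied.
#'
#' @param atoms data.frame from [parseStructure()].
#' @param offsetMap data.frame (chain, resno, offset, strand).
#' @param phaseTbl a [PhaseTable-class].
#' @param backboneAtoms atom names treated as backbone (default the
#'   phosphate and sugar backbone set).
#' @return List with \code{profile} (alignedOffset, meanB, nStrands),
#'   \code{perResidue}, \code{nExcluded}, \code{U}, \code{p},
#'   \code{medianOut}, \code{medianIn}.
#' @export
backboneBfactorProfile <- function(atoms, offsetMap,
        phaseTbl = buildPhaseTable(),
        backboneAtoms = c("P", "OP1", "OP2", "O1P", "O2P",
                          "O5'", "C5'", "C4'", "C3'", "O3'")) {
    mkey <- paste(offsetMap$chain, offsetMap$resno)
    akey <- paste(atoms$chain, atoms$resno)
    mapped <- akey %in% mkey
    at <- atoms[mapped & atoms$atom %in% backboneAtoms, , drop = FALSE]
    resKey <- paste(at$chain, at$resno)
    perRes <- tapply(at$b, resKey, mean)
    allRes <- unique(mkey)
    nExcluded <- sum(!(allRes %in% names(perRes)))
    m <- match(names(perRes), mkey)
    pr <- data.frame(chain = offsetMap$chain[m],
        resno = offsetMap$resno[m], offset = offsetMap$offset[m],
        strand = offsetMap$strand[m], meanB = as.numeric(perRes),
        stringsAsFactors = FALSE)
    ## 5'->3' alignment: minus-strand offsets flip sign
    pr$alignedOffset <- ifelse(pr$strand == "-", -pr$offset, pr$offset)
    prof <- stats::aggregate(meanB ~ alignedOffset, data = pr, FUN = mean)
    cnt <- stats::aggregate(meanB ~ alignedOffset, data = pr, FUN = length)
    prof$nStrands <- cnt$meanB
    pt <- phaseTable(phaseTbl)
    ## after 5'->3' alignment the two strands share the plus-strand
    ## backbone class (table antisymmetry)
    prof$backbone <- pt$backbone_plus[match(prof$alignedOffset, pt$offset)]
    a <- prof$meanB[!is.na(prof$backbone) & prof$backbone == "backbone_out"]
    b <- prof$meanB[!is.na(prof$backbone) & prof$backbone == "backbone_in"]
    tst <- if (length(a) > 0L && length(b) > 0L) mannWhitneyU(a, b)
           else list(U = NA_real_, p = NA_real_)
    list(profile = prof, perResidue = pr,
         nExcluded = as.integer(nExcluded), U = tst$U, p = tst$p,
         medianOut = if (length(a)) median(a) else NA_real_,
         medianIn = if (length(b)) median(b) else NA_real_)
}

#' Synthetic idealized nucleosomal duplex structure
#'
#' Builds a synthetic (not experimentally derived) atom table for a
#' two-chain B-DNA-like duplex wrapped as a flat helix: per nucleotide a
#' phosphate/sugar backbone atom set plus the base C4 atom (cytosines
#' only). Geometry is parameterized (10.17 bp/turn twist, 3.38 A rise
#' unrolled along a line) and is intended for testing parsers, SASA
#' grouping and B-factor aggregation -- not for biophysical inference.
#'
#' @param sequence plus-strand sequence (default a random-free repeating
#'   pattern of length 147).
#' @param chainPlus,chainMinus chain identifiers.
#' @param bValues per-residue B-factors of the plus chain (recycled;
#'   default 20).
#' @param bValuesMinus per-residue B-factors of the minus chain in its own
#'   5'->3' residue order; the default mirrors \code{bValues} so that B is
#'   a per-base-pair property. Pass an explicit vector for strand-specific
#'   B patterns.
#' @return data.frame in the [parseStructure()] layout.
#' @export
syntheticDuplexStructure <- function(sequence = NULL, chainPlus = "I",
                                     chainMinus = "J", bValues = 20,
                                     bValuesMinus = NULL) {
    if (is.null(sequence))
        sequence <- paste(rep(c("A", "C", "G", "T"), length.out = 147),
                          collapse = "")
    bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    n <- length(bases)
    comp <- c(A = "T", C = "G", G = "C", T = "A")[bases]
    bVal <- rep_len(bValues, n)
    radii <- defaultVdwRadii()
    bbAtoms <- c(P = "P", OP1 = "O", OP2 = "O", `O5'` = "O", `C5'` = "C",
                 `C4'` = "C", `C3'` = "C", `O3'` = "O")
    ## backbone atoms on a cylinder of radius 9.4 A around the helix axis
    ## (x axis); base C4 closer to the axis
    mkChain <- function(chain, bvec, seqv, phase0, zsign) {
        rows <- list()
        twist <- 2 * pi / 10.17
        for (i in seq_len(n)) {
            ang <- phase0 + zsign * twist * (i - 1L)
            axisX <- 3.38 * (i - 1L)
            resname <- paste0("D", seqv[i])
            for (ai in seq_along(bbAtoms)) {
                ## small fixed offsets separate atoms within a residue
                da <- 0.12 * ai
                rows[[length(rows) + 1L]] <- data.frame(chain = chain,
                    resno = i, resid = resname, atom = names(bbAtoms)[ai],
                    x = axisX + 0.3 * ai,
                    y = 9.4 * cos(ang + da), z = 9.4 * sin(ang + da),
                    b = bvec[i], element = unname(bbAtoms[ai]),
                    radius = unname(radii[bbAtoms[ai]]),
                    stringsAsFactors = FALSE)
            }
            if (seqv[i] == "C") {
                rows[[length(rows) + 1L]] <- data.frame(chain = chain,
                    resno = i, resid = resname, atom = "C4",
                    x = axisX + 1.2,
                    y = 3.0 * cos(ang), z = 3.0 * sin(ang),
                    b = bvec[i], element = "C",
                    radius = unname(radii["C"]),
                    stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, rows)
    }
    bValM <- if (is.null(bValuesMinus)) rev(bVal)
             else rep_len(bValuesMinus, n)
    plus <- mkChain(chainPlus, bVal, bases, 0, +1)
    minus <- mkChain(chainMinus, bValM, rev(comp), pi, -1)
    rbind(plus, minus)
}

#' Write an atom table as a PDB file
#'
#' @param atoms data.frame in the [parseStructure()] layout.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeStructurePdb <- function(atoms, path) {
    bio3d::write.pdb(file = path,
        xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
        resno = atoms$resno, resid = atoms$resid, chain = atoms$chain,
        elety = atoms$atom, b = atoms$b, elesy = atoms$element)
    invisible(path)
}
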