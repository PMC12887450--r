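test_that("PDB parsing handles minimal files, altLoc and the duplex fixture", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c(
        "ATOM      1  C4   DC I   1      1.000   2.000   3.000  1.00 20.00           C",
        "END"), f)
    at <- parseStructure(f)
    expect_equal(nrow(at), 1L)
    expect_equal(at$x, 1)
    expect_equal(at$z, 3)
    expect_equal(at$atom, "C4")
    expect_equal(at$radius, 1.70)
    expect_equal(at$b, 20)

    ## altLoc pair: only the A conformer is retained
    writeLines(c(
        "ATOM      1  CA ALEU A   1      0.000   0.000   0.000  0.50 10.00           C",
        "ATOM      2  CA BLEU A   1      1.000   0.000   0.000  0.50 10.00           C",
        "END"), f)
    at2 <- parseStructure(f)
    expect_equal(nrow(at2), 1L)
    expect_equal(at2$x, 0)

    ## synthetic 147-bp duplex: 294 residues, writes and re-parses
    atoms <- syntheticDuplexStructure()
    expect_equal(length(unique(paste(atoms$chain, atoms$resno))), 294L)
    pf <- withr::local_tempfile(fileext = ".pdb")
    writeStructurePdb(atoms, pf)
    back <- parseStructure(pf)
    expect_equal(nrow(back), nrow(atoms))
    expect_equal(back$x, atoms$x, tolerance = 1e-3)
    expect_equal(sort(unique(back$chain)), c("I", "J"))

    expect_error(parseStructure(withr::local_tempfile()), "not found")
})

test_that("SASA matches analytic spheres for both probe radii", {
    atom <- data.frame(chain = "A", resno = 1, resid = "DC", atom = "C4",
        x = 0, y = 0, z = 0, b = 0, element = "C", radius = 1.7)
    for (w in c(1.4, 1.1)) {
        s <- shrakeRupleySasa(atom, w, 960L)
        expect_lt(abs(s - 4 * pi * (1.7 + w)^2) / (4 * pi * (1.7 + w)^2),
                  0.01)
    }
    ## named probe presets
    expect_equal(shrakeRupleySasa(atom, "water", 960L),
                 shrakeRupleySasa(atom, 1.4, 960L))
    ## convergence: 5000 points within 0.3%
    s5 <- shrakeRupleySasa(atom, 1.4, 5000L)
    expect_lt(abs(s5 - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.003)
})

test_that("SASA matches the two-sphere spherical-cap closed form", {
    R <- 1.7 + 1.4
    for (d in c(1.5, 2.5, 4.0, 5.5)) {
        atoms <- data.frame(chain = "A", resno = 1:2, resid = "DC",
            atom = c("C1", "C2"), x = c(0, d), y = 0, z = 0, b = 0,
            element = "C", radius = 1.7)
        s <- shrakeRupleySasa(atoms, 1.4, 960L)
        ## equal spheres: buried cap height h = R - d/2 on each
        analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
        expect_lt(abs(s[1L] - analytic) / analytic, 0.015)
        expect_lt(abs(s[2L] - analytic) / analytic, 0.015)
    }
})

test_that("SASA is rigid-motion invariant and additive over molecules", {
    set.seed(71)
    n <- 40
    atoms <- data.frame(chain = "A", resno = seq_len(n), resid = "DC",
        atom = "CX", x = rnorm(n, sd = 3), y = rnorm(n, sd = 3),
        z = rnorm(n, sd = 3), b = 0, element = "C", radius = 1.7)
    s0 <- shrakeRupleySasa(atoms, 1.4, 480L)

    ## translation leaves SASA exactly unchanged
    at2 <- transform(atoms, x = x + 11.3, y = y - 4.2, z = z + 0.7)
    expect_equal(shrakeRupleySasa(at2, 1.4, 480L), s0, tolerance = 1e-9)

    ## rotation with a co-rotated lattice is exactly invariant
    th <- 0.83
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(Rz)
    at3 <- atoms
    at3$x <- xyz[, 1L]; at3$y <- xyz[, 2L]; at3$z <- xyz[, 3L]
    expect_equal(shrakeRupleySasa(at3, 1.4, 480L, orientation = Rz), s0,
                 tolerance = 1e-9)

    ## disjoint molecules: total SASA is additive
    far <- transform(atoms, x = x + 100)
    both <- rbind(atoms, far)
    expect_equal(sum(shrakeRupleySasa(both, 1.4, 480L)), 2 * sum(s0),
                 tolerance = 1e-9)
})

test_that("C4 accessibility separates exposed from buried rotational classes", {
    pt <- buildPhaseTable()
    tb <- phaseTable(pt)
    omap <- duplexOffsetMap()
    ## constructed geometry: minor-in cytosine C4 atoms isolated
    ## (exposed), minor-out C4 atoms caged by a shell of atoms (buried)
    mkC4 <- function(resno, cx) data.frame(chain = "I", resno = resno,
        resid = "DC", atom = "C4", x = cx, y = 0, z = 0, b = 0,
        element = "C", radius = 1.7)
    shell <- function(resno, cx) {
        pts <- dCPDseq:::.spiralLattice(60L) * 2.2
        data.frame(chain = "I", resno = resno, resid = "DC",
            atom = paste0("S", seq_len(60L)), x = cx + pts[, 1L],
            y = pts[, 2L], z = pts[, 3L], b = 0, element = "C",
            radius = 1.7)
    }
    inRes <- omap$resno[match(tb$offset[tb$rotational == "minor_in"],
                              omap$offset[omap$chain == "I"])][1:6]
    outRes <- omap$resno[match(tb$offset[tb$rotational == "minor_out"],
                               omap$offset[omap$chain == "I"])][1:6]
    atoms <- do.call(rbind, c(
        lapply(seq_along(inRes), function(i) mkC4(inRes[i], i * 40)),
        lapply(seq_along(outRes), function(i) {
            cx <- 1000 + i * 40
            rbind(mkC4(outRes[i], cx), shell(outRes[i], cx))
        })))
    res <- c4SasaByClass(atoms, 1.4, omap, pt, nPoints = 480L)
    sIn <- res$table$sasa[res$table$rotational == "minor_in"]
    sOut <- res$table$sasa[res$table$rotational == "minor_out"]
    expect_true(all(sOut == 0))            # fully buried
    expect_true(all(sIn > 100))            # fully exposed spheres
    expect_lt(res$p, 0.01)
    expect_gt(res$medianMinorIn, res$medianMinorOut)
    expect_equal(res$nZero, 6L)

    ## isolated cytosine: self-consistent with the plain SASA call
    one <- mkC4(74, 0)
    resOne <- c4SasaByClass(one, 1.4, omap, pt, nPoints = 480L)
    expect_equal(resOne$table$sasa,
                 shrakeRupleySasa(one, 1.4, 480L))

    ## no cytosines at all is fatal
    noC <- data.frame(chain = "I", resno = 1, resid = "DA", atom = "C4",
        x = 0, y = 0, z = 0, b = 0, element = "C", radius = 1.7)
    expect_error(c4SasaByClass(noC, 1.4, omap, pt), "no cytosine")
})

test_that("backbone B-factor aggregation averages atoms, residues, strands", {
    omap <- duplexOffsetMap()
    pt <- buildPhaseTable()
    ## one residue with backbone atoms B = {10, 20, 30} averages to 20
    at <- data.frame(chain = "I", resno = 74,
        resid = "DC", atom = c("P", "C5'", "O3'"),
        x = 1:3, y = 0, z = 0, b = c(10, 20, 30), element = c("P", "C", "O"),
        radius = 1.8)
    res <- backboneBfactorProfile(at, omap, pt)
    expect_equal(res$perResidue$meanB, 20)
    expect_equal(res$profile$meanB[res$profile$alignedOffset == 0], 20)

    ## constant B over the full duplex: flat profile, degenerate test
    atoms <- syntheticDuplexStructure(bValues = 20)
    expect_warning(resC <- backboneBfactorProfile(atoms, omap, pt),
                   "constant")
    expect_true(all(resC$profile$meanB == 20))
    expect_equal(resC$p, 1)
    ## both strands contribute at every aligned offset
    expect_true(all(resC$profile$nStrands == 2))

    ## B elevated exactly at plus-strand backbone-out offsets (the
    ## aligned class): comparison significant, correct direction
    tb <- phaseTable(pt)
    bOut <- tb$offset[tb$backbone_plus == "backbone_out"]
    bPlus <- ifelse((seq_len(147) - 74) %in% bOut, 40, 20)
    ## strand-specific mobility: each strand is hot where ITS backbone
    ## faces the solvent; in the minus chain's own 5'->3' residue order
    ## that is the same index pattern as the plus chain
    atomsHot <- syntheticDuplexStructure(bValues = bPlus,
                                         bValuesMinus = bPlus)
    resH <- backboneBfactorProfile(atomsHot, omap, pt)
    expect_lt(resH$p, 1e-4)
    expect_gt(resH$medianOut, resH$medianIn)

    ## residues lacking all backbone atoms are excluded with a tally
    atC4only <- data.frame(chain = "I", resno = 10, resid = "DC",
        atom = "C4", x = 0, y = 0, z = 0, b = 5, element = "C",
        radius = 1.7)
    resX <- backboneBfactorProfile(rbind(at, atC4only), omap, pt)
    expect_equal(resX$nExcluded, 293L)
})

test_that("offset maps cover both chains antiparallel and round-trip", {
    omap <- duplexOffsetMap()
    expect_equal(nrow(omap), 294L)
    expect_equal(range(omap$offset), c(-73, 73))
    ## chain I residue 74 and chain J residue 74 both sit at the dyad
    expect_equal(omap$offset[omap$chain == "I" & omap$resno == 74], 0)
    expect_equal(omap$offset[omap$chain == "J" & omap$resno == 74], 0)
    ## antiparallel: J residue 1 pairs with offset +73
    expect_equal(omap$offset[omap$chain == "J" & omap$resno == 1], 73)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeOffsetMap(omap, f)
    expect_identical(readOffsetMap(f), omap)
})
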