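test_that("default phase table partitions offsets with mirror symmetry", {
    pt <- buildPhaseTable()
    tb <- phaseTable(pt)
    expect_equal(nrow(tb), 147L)
    expect_true(all(table(tb$rotational) > 0))
    ## every offset has exactly one rotational class (rows are unique
    ## offsets by validity); the dyad-flanking +/-2 are minor-out
    expect_equal(tb$rotational[tb$offset %in% c(-2, 2)],
                 c("minor_out", "minor_out"))
    ## backbone classes only at intermediate offsets, never shared
    inter <- tb$rotational == "intermediate"
    expect_true(all(tb$backbone_plus[!inter] == "none"))
    expect_true(all(tb$backbone_plus[inter & tb$backbone_plus != "none"] !=
        tb$backbone_minus[inter & tb$backbone_plus != "none"]))
    ## strand antisymmetry: class(+, o) == class(-, -o)
    m <- match(-tb$offset, tb$offset)
    expect_identical(tb$backbone_plus, tb$backbone_minus[m])
    expect_identical(tb$rotational, tb$rotational[m])
})

test_that("backbone rule traces the 5'-of-minor-in convention", {
    ## minor-out at +5/+15 puts a minor-in centre at +10; the plus strand
    ## is backbone-out at {7,8} (5' of the centre) and backbone-in at
    ## {12,13}; the minus strand is reversed
    pt <- buildPhaseTable(minorOutCenters = c(5, 15), halfwidth = 20)
    tb <- phaseTable(pt)
    expect_equal(tb$rotational[tb$offset %in% 9:11], rep("minor_in", 3))
    expect_equal(tb$backbone_plus[tb$offset %in% c(7, 8)],
                 rep("backbone_out", 2))
    expect_equal(tb$backbone_plus[tb$offset %in% c(12, 13)],
                 rep("backbone_in", 2))
    expect_equal(tb$backbone_minus[tb$offset %in% c(7, 8)],
                 rep("backbone_in", 2))
    expect_equal(tb$backbone_minus[tb$offset %in% c(12, 13)],
                 rep("backbone_out", 2))
    ## overlapping bands are fatal
    expect_error(buildPhaseTable(minorOutCenters = c(5, 7)), "overlapping")
})

test_that("phase tables round-trip through TSV", {
    pt <- buildPhaseTable()
    f <- withr::local_tempfile(fileext = ".tsv")
    writePhaseTable(pt, f)
    back <- readPhaseTable(f)
    expect_identical(phaseTable(back), phaseTable(pt))
})

test_that("Mann-Whitney U: exact enumeration, ties, conservation", {
    ## enumeration of all 20 assignments of {1..6} into groups of 3
    r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$U, 0)
    expect_equal(r$p, 0.1)
    expect_equal(r$method, "exact")

    ## identical constant groups: degenerate, p = 1
    expect_warning(rc <- mannWhitneyU(c(2, 2), c(2, 2)), "constant")
    expect_equal(rc$p, 1)

    ## U conservation on random data, both exact and approximate paths
    set.seed(14)
    for (rep_ in 1:20) {
        na <- sample(2:20, 1)
        nb <- sample(2:20, 1)
        a <- sample(1:12, na, replace = TRUE)   # ties likely
        b <- sample(1:12, nb, replace = TRUE)
        ua <- mannWhitneyU(a, b)$U
        ub <- mannWhitneyU(b, a)$U
        expect_equal(ua + ub, na * nb)
    }

    ## exact p agrees with wilcox.test when there are no ties
    set.seed(15)
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(mannWhitneyU(a, b)$p,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)

    ## approximate p agrees with wilcox.test's corrected normal approx
    a2 <- rnorm(30); b2 <- rnorm(25)
    expect_equal(mannWhitneyU(a2, b2)$p,
                 stats::wilcox.test(a2, b2, exact = FALSE,
                                    correct = TRUE)$p.value,
                 tolerance = 1e-6)
})

test_that("normal approximation tracks exact enumeration for n <= 12", {
    set.seed(16)
    vals <- rnorm(12)
    worst <- 0
    for (na in 2:10) {
        a <- vals[seq_len(na)]
        b <- vals[(na + 1):12]
        pe <- mannWhitneyU(a, b, exactLimit = 12L)$p
        pa <- mannWhitneyU(a, b, exactLimit = 0L)$p
        worst <- max(worst, abs(pe - pa))
    }
    expect_lt(worst, 0.05)
})

test_that("dyad profiles resolve strand and 5'->3' alignment", {
    gen <- randomGenome(2000, seed = 51)
    dyad <- GenomicRanges::GRanges("chrR", IRanges::IRanges(1000, 1000))
    ## single plus-strand lesion 10 bp left of the dyad
    les <- lesionsAt("chrR", 990, "+")
    pb <- profileBins(dyadProfile(les, dyad, gen, mode = "strand"))
    expect_equal(pb$lesPlus[pb$bin == -10], 1)
    expect_equal(sum(pb$lesPlus), 1)
    expect_equal(sum(pb$lesMinus), 0)

    ## aggregate pools the strands at the genomic offset
    lesB <- c(les, lesionsAt("chrR", 1010, "-"))
    pa <- profileBins(dyadProfile(lesB, dyad, gen, mode = "aggregate"))
    expect_equal(pa$lesions[pa$bin == -10], 1)
    expect_equal(pa$lesions[pa$bin == 10], 1)

    ## aligned53 maps the minus-strand offset +10 to -10
    p53 <- profileBins(dyadProfile(lesB, dyad, gen, mode = "aligned53"))
    expect_equal(p53$lesions[p53$bin == -10], 2)
    expect_equal(p53$lesions[p53$bin == 10], 0)

    expect_error(dyadProfile(les, dyad[0], gen), "empty dyad")
})

test_that("phase group comparison reports direction and significance", {
    pt <- buildPhaseTable()
    tb <- phaseTable(pt)
    ## constructed profile: minor-in offsets elevated 1.5x with small
    ## deterministic jitter
    jit <- rep_len(c(-0.02, 0.01, 0, 0.02, -0.01), nrow(tb))
    val <- ifelse(tb$rotational == "minor_in", 1.5, 1.0) + jit
    prof <- new("BinnedProfile", bins = data.frame(bin = tb$offset,
        lesions = 1, dipyC = 1, normFreq = 1, enrichment = val,
        enrichmentPlus = ifelse(tb$backbone_plus == "backbone_out",
                                1.4, 1.0) + jit,
        enrichmentMinus = ifelse(tb$backbone_minus == "backbone_out",
                                 1.4, 1.0) - jit),
        kind = "dyad", mode = "strand", nSites = 1L, nSkipped = 0L)
    rot <- phaseGroupCompare(prof, pt, "rotational")
    expect_equal(rot$direction, "minor_in > minor_out")
    expect_lt(rot$p, 0.01)
    bb <- phaseGroupCompare(prof, pt, "backbone")
    expect_equal(bb$direction, "backbone_out > backbone_in")
    expect_lt(bb$p, 0.01)
    ## core exclusion drops |offset| <= 3 from the pooled values
    rotX <- phaseGroupCompare(prof, pt, "rotational", excludeCore = TRUE)
    expect_lt(length(rotX$valuesB), length(rot$valuesB))
})

test_that("nucleosome vs linker comparison detects enrichment", {
    gen <- randomGenome(20000, seed = 61)
    dyads <- GenomicRanges::GRanges("chrR",
        IRanges::IRanges(seq(1000, 19000, by = 400), width = 1))
    masks <- dipyrimidineCytosines(gen)[[1L]]
    dipy <- which(masks$plus)
    off <- dCPDseq:::.dyadOffset(dipy, start(dyads), halfwidth = 93L)
    ## lesions twice at nucleosomal dipyC positions, once elsewhere
    nuc <- dipy[!is.na(off) & abs(off) <= 73]
    rest <- setdiff(dipy, nuc)
    les <- c(lesionsAt("chrR", rep(nuc, 2L), "+"),
             lesionsAt("chrR", rest, "+"))
    res <- nucleosomeVsLinker(les, dyads, gen)
    expect_gt(res$ratio, 1.3)
    expect_lt(res$p, 0.01)

    ## uniform lesions: ratio is exactly 1
    lesU <- c(lesionsAt("chrR", dipy, "+"),
              lesionsAt("chrR", which(masks$minus), "-"))
    ## uniform coverage makes every per-window value identical, so the
    ## rank test degenerates (warns) while the ratio stays exactly 1
    resU <- suppressWarnings(nucleosomeVsLinker(lesU, dyads, gen))
    expect_equal(resU$ratio, 1, tolerance = 1e-12)

    ## invalid linker definition is fatal
    expect_error(nucleosomeVsLinker(les, dyads, gen,
                                    linkerRange = c(10, 20)), "linker")
    ## widely spaced dyads have no overlapping windows
    expect_equal(resU$nOverlapping, 0L)
    ## tightly spaced dyads are reported and can be de-duplicated
    dy2 <- GenomicRanges::GRanges("chrR",
        IRanges::IRanges(c(1000, 1100, 3000), width = 1))
    resO <- suppressWarnings(nucleosomeVsLinker(lesU, dy2, gen))
    expect_gt(resO$nOverlapping, 0L)
    resD <- suppressWarnings(
        nucleosomeVsLinker(lesU, dy2, gen, dedupe = TRUE))
    expect_lt(length(resD$perNucleosome), length(resO$perNucleosome))
})
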