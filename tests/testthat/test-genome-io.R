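test_that("loadGenome folds case, keeps record order, enforces alphabet", {
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">c1", "acgt"), fa)
    gen <- loadGenome(fa)
    expect_equal(as.character(gen[["c1"]]), "ACGT")
    expect_equal(BiocGenerics::width(gen), 4L)

    writeLines(c(">a desc", "ACG", "TTA", ">b", "ggg"), fa)
    gen2 <- loadGenome(fa)
    expect_equal(names(gen2), c("a", "b"))
    expect_equal(as.character(gen2[["a"]]), "ACGTTA")

    writeLines(c(">r", "ACRGT"), fa)
    expect_error(loadGenome(fa), "non-ACGTN")
    lax <- loadGenome(fa, strict = FALSE)
    expect_equal(as.character(lax[[1L]]), "ACNGT")

    writeLines(c(">d", "ACGT", ">d", "ACGT"), fa)
    expect_error(loadGenome(fa), "duplicate")

    writeLines(character(0), fa)
    expect_error(loadGenome(fa))
})

test_that("lesion calling follows the upstream-of-5'-end convention", {
    gen <- dnaSet(c(c1 = "ATCGA"))
    ## plus read over the last base (0-based [4,5)) -> minus lesion at
    ## 0-based 3, whose minus-strand base is complement(G) = C
    r <- GenomicRanges::GRanges("c1", IRanges::IRanges(5, 5), strand = "+")
    les <- annotateContext(callLesions(r, gen), gen)
    expect_equal(start(les), 4L)
    expect_equal(as.character(strand(les)), "-")
    expect_equal(S4Vectors::mcols(les)$centralBase, "C")

    ## minus read [0,3) -> plus lesion at 0-based 3 (1-based 4)
    r2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 3), strand = "-")
    les2 <- callLesions(r2, gen)
    expect_equal(start(les2), 4L)
    expect_equal(as.character(strand(les2)), "+")

    ## plus read at chromosome start has no upstream base: dropped
    r3 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 3), strand = "+")
    les3 <- callLesions(r3, gen)
    expect_length(les3, 0L)
    expect_equal(S4Vectors::metadata(les3)$nDroppedBoundary, 1L)

    ## unknown chromosome skipped with warning
    r4 <- suppressWarnings(
        c(r, GenomicRanges::GRanges("cX", IRanges::IRanges(2, 4),
                                    strand = "+")))
    expect_warning(les4 <- callLesions(r4, gen), "skipped")
    expect_length(les4, 1L)
    expect_equal(S4Vectors::metadata(les4)$nSkippedChrom, 1L)

    ## strandless reads are fatal
    r5 <- GenomicRanges::GRanges("c1", IRanges::IRanges(2, 4), strand = "*")
    expect_error(callLesions(r5, gen), "strand")
})

test_that("context annotation is strand-aware and excludes edges and N", {
    gen <- dnaSet(c(c1 = "TTCGA"))
    les <- annotateContext(lesionsAt("c1", 3, "+"), gen)
    expect_equal(S4Vectors::mcols(les)$centralBase, "C")
    expect_equal(S4Vectors::mcols(les)$trinucleotide, "TCG")
    expect_true(S4Vectors::mcols(les)$dipyrimidineOk)

    ## minus-strand 3-mer is the reverse complement of the plus window
    gen2 <- dnaSet(c(c1 = "ATCGA"))
    les2 <- annotateContext(lesionsAt("c1", 4, "-"), gen2)
    expect_equal(S4Vectors::mcols(les2)$trinucleotide, "TCG")

    ## chromosome end: undefined context
    les3 <- annotateContext(lesionsAt("c1", 1, "+"), gen)
    expect_true(is.na(S4Vectors::mcols(les3)$trinucleotide))
    expect_false(S4Vectors::mcols(les3)$dipyrimidineOk)

    ## N in window: undefined
    gen4 <- dnaSet(c(c1 = "TNCGA"))
    les4 <- annotateContext(lesionsAt("c1", 3, "+"), gen4)
    expect_true(is.na(S4Vectors::mcols(les4)$trinucleotide))

    ## trinucleotide[2] == centralBase wherever defined
    gen5 <- randomGenome(400, seed = 5)
    pos <- seq(2, 399)
    for (str in c("+", "-")) {
        l5 <- annotateContext(lesionsAt("chrR", pos, str), gen5)
        tri <- S4Vectors::mcols(l5)$trinucleotide
        expect_identical(substr(tri, 2, 2), S4Vectors::mcols(l5)$centralBase)
        pyr <- substr(tri, 1, 1) %in% c("C", "T") |
               substr(tri, 3, 3) %in% c("C", "T")
        expect_identical(S4Vectors::mcols(l5)$dipyrimidineOk, pyr)
    }
})

test_that("context counting matches brute force and strand symmetry", {
    ## enumeration by hand: ACGT has plus {ACG, CGT}, minus {ACG, CGT}
    gen <- dnaSet(c(c1 = "ACGT"))
    cc <- countContextOccurrences(gen, 3)
    expect_equal(unname(cc[["ACG"]]), 2)
    expect_equal(unname(cc[["CGT"]]), 2)
    expect_equal(sum(cc), 4)

    ## brute-force oracle on a random genome, including one with N
    gen2 <- randomGenome(2000, seed = 11)
    expect_equal(countContextOccurrences(gen2, 3)[names(bruteContextCounts(gen2))],
                 bruteContextCounts(gen2))
    s <- as.character(gen2[[1L]])
    substr(s, 100, 101) <- "NN"
    gen3 <- dnaSet(c(chrN = s))
    expect_equal(countContextOccurrences(gen3, 3)[names(bruteContextCounts(gen3))],
                 bruteContextCounts(gen3))
    ## N windows excluded from the total (4 windows per strand touch NN)
    expect_equal(sum(countContextOccurrences(gen3, 3)),
                 2 * (2000 - 3 + 1) - 8)

    ## reverse-complement symmetry of the double-strand count
    cc2 <- countContextOccurrences(gen2, 3)
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
    expect_equal(unname(cc2[rc(names(cc2))]), unname(cc2))

    ## all-A genome: no C-centred contexts
    genA <- dnaSet(c(cA = strrep("A", 50)))
    expect_true(all(countContextOccurrences(genA, 3, centerBase = "C") == 0))

    ## chromosome shorter than k contributes nothing
    genS <- dnaSet(c(s1 = "AC"))
    expect_equal(sum(countContextOccurrences(genS, 3)), 0)
})

test_that("region exclusion removes lesions near chromosome ends", {
    gen <- dnaSet(c(c1 = strrep("ACGT", 3000)))   # 12 kb
    pos <- c(1L, 5000L, 5001L, 6000L, 7000L, 7001L, 12000L)
    les <- lesionsAt("c1", pos, "+")
    out <- excludeRegions(les, chromEndDistance = 5000, genome = gen)
    ## excluded: [1,5000] and [7001,12000]
    expect_equal(start(out), c(5001L, 6000L, 7000L))
    expect_equal(S4Vectors::metadata(out)$nExcluded, 4L)

    ## empty exclusion set is the identity
    out2 <- excludeRegions(les)
    expect_equal(start(out2), pos)
    expect_equal(S4Vectors::metadata(out2)$nExcluded, 0L)

    ## all-covering interval empties the output
    all_ <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 12000))
    expect_length(excludeRegions(les, regions = all_), 0L)

    ## malformed BED is fatal with the line number
    bad <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("c1\t0\t100\tx\t0\t+", "c1\tnot_a_number\t5"), bad)
    expect_error(excludeRegions(les, regions = bad), "line 2")
})

test_that("dipyrimidine-cytosine masks agree with a naive scan", {
    gen <- randomGenome(500, seed = 99)
    m <- dipyrimidineCytosines(gen)[[1L]]
    b <- strsplit(as.character(gen[[1L]]), "")[[1L]]
    for (p in seq_along(b)) {
        nb <- c(if (p > 1) b[p - 1], if (p < length(b)) b[p + 1])
        expect_identical(m$plus[p],
                         b[p] == "C" && any(nb %in% c("C", "T")))
        ## minus-strand cytosine = plus G; minus neighbours are
        ## complements of the plus flanks
        expect_identical(m$minus[p],
                         b[p] == "G" && any(chartr("ACGT", "TGCA", nb)
                                            %in% c("C", "T")))
    }
})

test_that("lesion BED round-trips through 0-based half-open files", {
    gen <- randomGenome(300, seed = 3)
    les <- annotateContext(lesionsAt("chrR", c(10L, 50L, 200L),
                                     c("+", "-", "+")), gen)
    f <- withr::local_tempfile(fileext = ".bed")
    writeLesionsBed(les, f)
    raw <- read.table(f, sep = "\t")
    expect_equal(raw$V2, start(les) - 1L)   # 0-based starts on disk
    expect_equal(raw$V3, start(les))
    back <- readLesionsBed(f, gen)
    expect_equal(start(back), start(les))
    expect_equal(as.character(strand(back)), as.character(strand(les)))
    expect_equal(S4Vectors::mcols(back)$trinucleotide,
                 S4Vectors::mcols(les)$trinucleotide)
})
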