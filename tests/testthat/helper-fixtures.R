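## fixtures shared across test files; everything is generated in code

## DNAStringSet from named character vector
dnaSet <- function(...) {
    x <- c(...)
    gen <- Biostrings::DNAStringSet(unname(x))
    names(gen) <- names(x)
    gen
}

## width-1 lesion GRanges (1-based positions)
lesionsAt <- function(chrom, pos, strand) {
    if (length(pos) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                           strand = strand)
}

## random ACGT genome of length n under a fixed seed
randomGenome <- function(n, seed = 42L, name = "chrR") {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    dnaSet(setNames(s, name))
}

## independent brute-force double-strand k-mer counter (oracle)
bruteContextCounts <- function(genome, k = 3L) {
    km <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
        stringsAsFactors = FALSE)[, k:1, drop = FALSE], 1L, paste,
        collapse = ""))
    counts <- setNames(numeric(length(km)), km)
    rc <- function(s) chartr("ACGT", "TGCA",
        paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
    for (i in seq_along(genome)) {
        s <- as.character(genome[[i]])
        L <- nchar(s)
        if (L < k) next
        for (p in seq_len(L - k + 1L)) {
            w <- substr(s, p, p + k - 1L)
            if (grepl("N", w)) next
            counts[w] <- counts[w] + 1
            counts[rc(w)] <- counts[rc(w)] + 1
        }
    }
    counts
}

## small shared simulation for module tests (lazy, cached per session)
.simCache <- new.env()
smallSim <- function() {
    if (!is.null(.simCache$sim)) return(.simCache$sim)
    cfg <- simulationConfig(genomeLength = 30000, nGenes = 6, nTfbs = 10,
        nDyads = 15, formationProb = 0.05, readsPerTimepoint = 5000,
        seed = 7L)
    sim <- simulateGenomeAndFeatures(cfg)
    .simCache$sim <- list(cfg = cfg, sim = sim,
        cellular = simulateDamageAndDeamination(sim, cfg, "cellular"),
        naked = simulateDamageAndDeamination(sim, cfg, "naked"))
    .simCache$sim
}
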