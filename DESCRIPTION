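Package: dCPDseq
Title: Genome-Wide Analysis of Cytosine Deamination in UV-Induced
    Cyclobutane Pyrimidine Dimers
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing deaminated cyclobutane pyrimidine dimers
    (dCPDs) mapped at single-nucleotide resolution. Infers lesion positions
    from aligned sequencing reads, scores trinucleotide-context enrichment,
    scales lesion counts to absolute frequencies with bulk uracil
    measurements, fits one-phase association deamination kinetics, profiles
    normalized dCPD frequency and cellular-versus-naked enrichment over gene
    bodies, transcription factor binding sites and nucleosome dyads,
    classifies nucleosomal positions into rotational and strand-specific
    backbone settings, computes solvent accessible surface area of cytosine
    C4 atoms and backbone B-factor profiles from nucleosome structures, and
    relates per-context mutation frequency to damage frequency with
    prediction-interval outlier detection. A forward simulator of
    context-dependent CPD formation and exponential deamination with full
    ground truth drives validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Software, Epigenetics, Sequencing, DNADamage
RoxygenNote: 7.3.3
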