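# dCPDseq

Genome-wide analysis of cytosine deamination in UV-induced cyclobutane
pyrimidine dimers (CPDs).

UV light crosslinks adjacent pyrimidines into CPDs. Cytosine-containing
CPDs are chemically unstable: the damaged cytosine deaminates to uracil
with a half-life of hours, and replicative bypass of the deaminated
lesion (dCPD) fixes a C>T substitution — the signature mutation of skin
cancer. This package analyses single-nucleotide-resolution dCPD maps from
repair-deficient yeast: it infers lesion positions from aligned
sequencing reads, quantifies how flanking sequence context sets the
deamination rate, and measures how chromatin — DNA-bound transcription
factors and nucleosome rotational geometry — modulates the reaction. It
is aimed at researchers analysing damage-sequencing libraries of this
design, and at anyone needing its component methods: one-phase
association kinetics, trinucleotide enrichment normalisation,
dyad-aligned profiling with rotational/backbone classification,
deterministic Shrake–Rupley solvent accessibility, and
prediction-interval outlier regression.

## The core quantities

* **Lesion inference.** The deaminated cytosine is the base on the
  opposite strand immediately upstream of a read's 5' end: a plus-strand
  read starting at *s* implies a minus-strand lesion at *s − 1*; a
  minus-strand read ending at *e* implies a plus-strand lesion at
  *e + 1*.
* **Trinucleotide enrichment.** For context *c*:
  `E_c = (reads_c / reads_total) / (genome_c / genome_total)`, genomic
  counts taken over both strands. Multiplying `E_c` by the bulk uracil
  frequency from an alkaline gel gives the absolute dCPD frequency per
  kb per context.
* **Deamination kinetics.** One-phase association
  `y(t) = P (1 − e^(−kt))`, `t1/2 = ln2 / k`, fitted by deterministic
  bounded nonlinear least squares.
* **dCPD enrichment.** Per bin/offset,
  `(cell_b / naked_b) × (naked_total / cell_total)`, which cancels
  sequence composition and damage-formation effects and isolates the
  cellular modulation of deamination.
* **Nucleosome phase.** Offsets −73..+73 from the dyad are classified
  minor-in / minor-out / intermediate on a 10.17-bp period;
  intermediate offsets carry strand-specific backbone-out / backbone-in
  classes (backbone-out 5' of the nearest minor-in centre). Group
  differences are tested with an exact-or-corrected Mann–Whitney U.
* **Structure.** Solvent accessibility of the cytosine C4 atom (the
  site of hydrolytic attack) with water (1.4 Å) or hydroxide (1.1 Å)
  probes on a deterministic spiral lattice; backbone B-factor profiles
  aligned 5'→3'.

## Worked example

Simulate a cellular deamination time course with the measured TCN
half-life presets, call lesions from the emitted reads, and re-fit the
per-context kinetics:

```r
library(dCPDseq)

cfg <- simulationConfig(genomeLength = 200000, formationProb = 0.05,
                        readsPerTimepoint = 1e5, seed = 42)
sim   <- simulateGenomeAndFeatures(cfg)
truth <- simulateDamageAndDeamination(sim, cfg, "cellular")

tps  <- cfg$timepoints                      # 0, 6, 24, 48 h
bulk <- sapply(tps, function(t)             # simulated gel: uracils/kb
    length(deaminatedSites(truth, t)) / 200)
lesions <- lapply(seq_along(tps), function(i) {
    if (bulk[i] == 0) return(GenomicRanges::GRanges())
    annotateContext(callLesions(
        emitReads(truth, tps[i], 1e5, seed = 42 + i), sim$genome),
        sim$genome)
})
kin <- contextKinetics(lesions, tps, bulk, sim$genome,
                       fitContexts = c("TCG", "TCA", "TCT", "TCC"))
kin$fits$TCG
```

which prints:

```
KineticFit TCG (converged)
  k = 0.1963 /h, plateau = 19.76, t1/2 = 3.531 h
```

The fitted half-lives across the four contexts were 3.53 h (TCG), 9.18 h
(TCA), 8.92 h (TCT) and 13.72 h (TCC) against generator truth of 3.7,
9.7, 10 and 13 h: TCG deaminates roughly three times faster than the
other TCN contexts, and the fit recovers each rate within 15% at this
depth. (The plateau is in dCPDs/kb; this simulation uses a damage
density well above the experimental dose so that a 200 kb genome yields
stable per-context counts.) The enrichment table for the 48 h time point
is `trinucleotideEnrichment(lesions[[4]], sim$genome)`, whose
genome-fraction-weighted mean enrichment is exactly 1.

The same machinery profiles lesions over genes, TFBSs and nucleosome
dyads (`geneMetaprofile`, `siteProfile`, `dyadProfile`,
`enrichmentRatio`, `phaseGroupCompare`), analyses PDB structures
(`parseStructure`, `c4SasaByClass`, `backboneBfactorProfile`) and flags
mutation-frequency outliers (`outlierReport`). `runPipeline()` chains
every stage on a single YAML config and writes TSVs plus a JSON manifest;
`inst/scripts/dcpd.R` is a command-line wrapper over the same functions.

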