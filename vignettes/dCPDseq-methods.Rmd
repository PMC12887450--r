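---
title: "Methods and design of the dCPDseq pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the dCPDseq pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dCPDseq)
```

# Background

UV light produces cyclobutane pyrimidine dimers (CPDs) between adjacent
pyrimidines. When a CPD contains a cytosine, that base deaminates to uracil
orders of magnitude faster than undamaged cytosine; even error-free
replicative bypass of the deaminated lesion (dCPD) fixes a C>T substitution,
the hallmark mutation of sun-exposed skin. dCPDseq analyses genome-wide,
single-nucleotide-resolution maps of these deaminated lesions in
repair-deficient yeast: where the lesions sit, how fast each sequence
context deaminates, and how chromatin — bound transcription factors and
nucleosome geometry — modulates the reaction.

The package covers six analysis stages plus a forward simulator, and each
stage is usable on its own:

1. lesion inference from aligned reads (`callLesions`),
2. trinucleotide-context enrichment, absolute scaling and one-phase
   association kinetics (`trinucleotideEnrichment`,
   `absoluteDcpdFrequency`, `fitOnePhase`),
3. binned gene/TFBS profiles with cellular-vs-naked enrichment
   (`geneMetaprofile`, `siteProfile`, `enrichmentRatio`),
4. nucleosome dyad profiling and rotational/backbone classification
   (`dyadProfile`, `buildPhaseTable`, `phaseGroupCompare`),
5. structural analysis of nucleosome models (`shrakeRupleySasa`,
   `c4SasaByClass`, `backboneBfactorProfile`),
6. damage-vs-mutation regression with outlier detection
   (`outlierReport`),

driven end to end by `runPipeline()` on simulated data with full ground
truth.

# Lesion inference

The library chemistry (photolyase reversal, uracil excision, adapter
ligation at the cleaved end) places the 5' end of each sequencing read
immediately downstream of the uracil on the opposite strand. The decoding
rule is therefore fixed: a plus-strand read starting at position $s$
implies a minus-strand lesion at $s-1$; a minus-strand read ending at $e$
implies a plus-strand lesion at $e+1$. Coordinates are 1-based closed
inside the package (the GRanges convention); every BED file read or
written is 0-based half-open, converted at the boundary by rtracklayer.
Reads whose inferred lesion would fall outside the chromosome are dropped
and tallied, never silently discarded. The rule is validated by a
round-trip property: reads emitted by the simulator from known lesions
decode to exactly the true (chromosome, position, strand) triples.

Duplicate reads are kept by default: lesion tallies are read-weighted, and
collapsing duplicates would conflate library depth with lesion frequency.
A subtelomere filter (`excludeRegions` with `chromEndDistance = 5000`) is
available because chromosome ends in the arrest system used by the assay
undergo resection and single-stranded DNA deaminates faster.

# Context kinetics

For a context universe $C$ (default: all 16 C-centred trinucleotides;
optionally the 12 compatible with CPD formation), the enrichment score of
context $c$ is

$$E_c = \frac{r_c / \sum_{c' \in C} r_{c'}}{g_c / \sum_{c' \in C} g_{c'}}$$

with $r_c$ the lesion reads in $c$ and $g_c$ the genomic occurrences of
$c$ counted on both strands (windows containing N are excluded from both
numerator and denominator). Because both fractions are normalised within
the same universe, the genome-fraction-weighted mean of $E_c$ is exactly 1
— a useful invariant that the tests assert on every dataset.

Multiplying $E_c$ by an independently measured bulk uracil frequency
(alkaline gel assay, uracils per kb) converts relative enrichment into an
absolute dCPD frequency per kb of total DNA, per context and time point.
The default unit is per kb of total DNA, matching the gel; a per-context-
site variant is available (`perSite = TRUE`) and clearly labelled. The
"full" (heat-deaminated) control sample is treated as relative-only by
the pipeline: its gel value saturates, so we do not fit it.

Deamination time courses follow one-phase association kinetics,
$y(t) = P\,(1 - e^{-kt})$, with $t_{1/2} = \ln 2 / k$. The fit
(`fitOnePhase`) is deterministic nonlinear least squares
(Levenberg–Marquardt via minpack.lm): initialisation $P_0 = \max(y)$,
$k_0 = \ln 2 / \mathrm{median}(t > 0)$, bounds $k \in (10^{-6}, 10]$
h$^{-1}$, relative tolerance $10^{-15}$. The $t = 0$ points are included:
they anchor the intercept at the origin exactly as the plotted fits do.
Non-convergence and all-zero input return a flagged object, never a
silent NA. Noise-free curves are recovered to better than six significant
digits; under 2% Gaussian noise on a six-point time course the median
relative error of $k$ stays below 5%.

`breaksPerKbFromLengths` converts number-average fragment lengths from an
alkaline gel into breaks per kb under the Poisson random-breakage model,
$1000\,(1/L_d - 1/L_c)$.

# Feature profiles

Gene metaprofiles divide each gene body into six equal bins — bin $i$
covers $[\lfloor (i-1)L/6 \rfloor, \lfloor iL/6 \rfloor)$ of a gene of
length $L$, a deterministic remainder rule — plus three fixed 167-bp
flanking bins upstream of the TSS and three downstream of the TES.
Minus-strand genes are flipped so bin 1 always abuts the TSS. Counts and
denominators are summed across genes per bin before division
(length-weighted aggregation, i.e. raw-count pooling). The normalisation
denominator everywhere is the count of dipyrimidine-context cytosines:
cytosines with at least one same-strand pyrimidine neighbour, the only
positions that can host a cytosine-containing CPD. Bins with an empty
denominator are reported as missing, never as zero — a zero would fake
suppression.

Cellular-vs-naked enrichment per bin is

$$\mathrm{E}_b = \frac{c_b}{n_b} \cdot \frac{N}{C}$$

with $c_b, n_b$ the bin's lesion counts in the cellular and naked-DNA
samples and $C, N$ each sample's genome-wide total of
dipyrimidine-cytosine-associated lesions. The totals make the ratio
invariant to global down-sampling of either library. Because the two
samples received identical irradiation, sequence-composition and
damage-formation effects cancel; what remains is the cellular modulation
of the deamination reaction itself.

# Nucleosome phase analysis

Dyad profiles tally lesions per offset $-73..+73$ relative to nucleosome
dyads, in three modes: `aggregate` (strands pooled per genomic offset),
`strand` (per-strand columns kept), and `aligned53` (minus-strand offset
$o$ mapped to $-o$ so both strands read 5'→3').

The rotational/backbone classification lives in a `PhaseTable`, a
147-row editable resource (offset, rotational class, per-strand backbone
class) that every analysis takes as an input; the default is constructed,
not measured, and should be replaced by an empirically derived offsets
table before biological use. The default construction:

* minor-out band centres follow the helical period of nucleosomal DNA
  (10.17 bp), anchored so the two positions flanking the dyad axis
  ($\pm 2$) are minor-out — the anchoring implied by the dyad-proximal
  peaks of the assay;
* minor-in centres sit midway between consecutive same-side minor-out
  centres; no centre is placed between $-2$ and $+2$, where a 3-bp band
  cannot fit;
* bands are centre $\pm 1$ (3 bp); everything else is intermediate;
* at intermediate offsets the plus strand is backbone-out 5' (smaller
  coordinate) of the nearest minor-in centre and backbone-in 3' of it;
  the minus strand is mirrored. Offset 0 is equidistant from the
  $\pm 7$ minor-in centres and receives no backbone class (the only such
  tie under the default).

The resulting table partitions all 147 offsets, is mirror-symmetric
(backbone class of $(+, o)$ equals that of $(-, -o)$), and reproduces the
stated strand rule on hand-traced examples. A flag on
`phaseGroupCompare(excludeCore = TRUE)` removes $|o| \le 3$ — the
single-gyre dyad core whose behaviour is known to be exceptional — from
group tests.

Group comparisons pool per-offset enrichment values by class and use a
Mann–Whitney U test implemented in the package: exact by enumeration of
all group assignments when $n_a + n_b \le 12$ (midrank U, so ties are
handled exactly), otherwise a normal approximation with tie and
continuity corrections. Tests are two-sided; directional claims are
reported as medians plus direction rather than one-sided p-values. The
implementation is cross-checked in the tests against both an independent
pairwise-counting enumeration oracle and `wilcox.test`.

`nucleosomeVsLinker` compares dipyrimidine-normalised lesion frequency
inside nucleosomes ($|o| \le 73$) against adjacent linker DNA (default
$|o| \in [74, 93]$), with a rank-sum test over per-nucleosome values;
overlapping windows are reported and can be de-duplicated.

# Structural analysis

The rate-limiting step of cytosine deamination is hydrolytic attack on
the cytosine C4 atom, so the solvent accessible surface area of C4
(SASA$_{C4}$) is the structural correlate of deamination propensity.
`shrakeRupleySasa` implements Shrake–Rupley test-point counting with a
deterministic golden-angle spiral lattice — no random numbers anywhere in
the module, so results are exactly reproducible and a rigid rotation with
a co-rotated lattice leaves every value unchanged to machine precision.
Probe radii: 1.4 Å (water) and 1.1 Å (hydroxide), the two candidate
attacking species. Van der Waals radii are Bondi-style heavy-atom values
(C 1.70, N 1.55, O 1.52, P 1.80, S 1.80 Å), united-atom, since crystal
structures generally lack hydrogens; the table is configurable. At 960
lattice points an isolated sphere is within 1% of $4\pi(r+w)^2$ and
two-sphere configurations are within 1.5% of the spherical-cap closed
form.

`c4SasaByClass` computes SASA for the whole structure (occlusion requires
every atom), extracts cytosine C4 atoms, maps residues to dyad offsets
through an explicit offset-map file (chain, residue → offset, strand; a
generator produces the canonical map for a 147-bp two-chain duplex) and
compares minor-in against minor-out. `backboneBfactorProfile` averages
crystallographic B-factors — a proxy for backbone mobility — over the
phosphate/sugar backbone atoms of each nucleotide, aligns both strands
5'→3' (after alignment the two strands share the plus-strand backbone
class, by the table's mirror symmetry) and compares backbone-out against
backbone-in.

`syntheticDuplexStructure` builds a synthetic, idealized duplex atom
table (flat helix, parameterized twist and rise). It exists to test
parsing, SASA grouping and B-factor aggregation with controlled geometry;
it is not a physical model, and reproducing published structure-derived
numbers requires the actual PDB depositions, which the package reads but
does not ship.

# Damage-vs-mutation regression

`outlierReport` relates per-context C>T mutation fractions to per-context
CPD fractions by ordinary least squares, unweighted (the inputs are
already normalised fractions). Two deliberate choices:

* **Leave-one-out fitting.** The tested context is excluded from the fit
  so a true outlier cannot inflate its own prediction;
  `includeSelf = TRUE` reproduces an all-points fit for comparison.
* **Prediction interval, not mean-response interval.** The "95% interval
  of the predicted value" is read conservatively as the interval for a
  new observation,
  $t_{1-\alpha/2,\,n-2}\, s \sqrt{1 + 1/n + (x_0-\bar x)^2 / S_{xx}}$;
  a switch selects the mean-response interval instead.

The fold enrichment is observed/predicted. Tests verify the closed form
against hand computation, nominal 95% coverage over 1000 simulated
replicates, and recovery of a 3.4-fold inflated context planted among 11
on-line contexts.

# The simulator

`simulateGenomeAndFeatures` + `simulateDamageAndDeamination` +
`emitReads` forward-simulate the study design with full ground truth:

* **Formation.** Every interior dipyrimidine cytosine is a candidate;
  it becomes a CPD with probability `formationProb` × a per-context
  weight × (optionally) a rotational factor elevated at minor-out
  settings. The default `formationProb = 0.0022` is calibrated so the
  simulated cytosine-CPD burden is of the order of the measured plateau
  (~0.6 dCPDs/kb at full deamination) given typical dipyrimidine-cytosine
  density. No per-context formation weights are known for yeast, so the
  default weights are 1 and labelled arbitrary.
* **Deamination.** Each CPD carries one latent exponential deamination
  time with rate $k_{\mathrm{eff}}$ (inverse-CDF from a site-specific
  uniform draw), so deaminated sets are nested over time by construction
  — one physical event per site, not independent Bernoulli draws per
  time point. In cellular mode $k_{\mathrm{eff}}$ multiplies the context
  rate by the cellular modifiers (TFBS suppression within midpoint ± 10
  bp, minor-in multiplier, strand-specific backbone-out multiplier,
  optional nucleosome-wide multiplier); naked mode uses the context rate
  unmodified. The formation draw and the latent uniforms are shared
  between modes, so with all modifiers at 1 the two modes coincide
  exactly — the null scenarios are exactly matched libraries.
* **Rates.** The cellular preset uses the measured TCN half-lives
  (TCG 3.7 h, TCA 9.7 h, TCT 10 h, TCC 13 h) with the remaining contexts
  at mid-range values inside the reported NCT (6–10 h) and NCC (13–26 h)
  windows; the naked preset uses TCG 8.2 h with the other contexts in
  the reported in vitro ranges. Values not individually printed are
  placeholders for simulation only.
* **Reads.** Uniform sampling with replacement from the deaminated set;
  each read is placed so `callLesions` decodes it exactly; lengths are
  uniform in 20–50 bp and irrelevant to decoding by construction.
* Default cellular modifiers (TFBS factor 0.5, minor-in ×1.5,
  backbone-out ×1.4) mirror the direction and rough magnitude of the
  cellular observations and are the recovery targets of the test suite.

**What the simulator does not emulate.** It draws a single formation
realization — one "cell" — whereas a sequencing library aggregates an
ensemble of cells with independent damage draws. Consequences for
validation: per-offset statistics need many CPD sites per offset, so the
profile-validation scenarios use an elevated damage density
(`formationProb = 0.3` on a 250 kb genome with 1400 dyads and 1500 TFBS,
4×10⁶ reads per library) so that each of the 147 dyad offsets aggregates
tens of independent sites. The kinetics-recovery scenario uses a 1 Mb
genome, `formationProb = 0.05` and 2×10⁵ reads per time point, and
recovers the four TCN half-lives within 15% with the correct ordering
(TCG fastest, TCC slowest; TCA and TCT differ by only 3% and are treated
as tied). There is no sequencing-error model, no PCR duplication, no
alignment ambiguity and no UV dose–response; passing tests demonstrate
correctness of the analysis pipeline under the stated generative model,
not robustness to those artefacts in real libraries.

# Numerical and interface choices

* Configuration files are YAML; `runPipeline` derives every stage seed
  from the single root seed and writes a JSON manifest with output MD5s,
  so reruns are byte-identical for deterministic stages.
* All tabular outputs are TSV with a comment header naming units.
* The command-line wrapper `inst/scripts/dcpd.R` exposes the exported
  functions as subcommands (`simulate`, `call-lesions`, `kinetics`,
  `profile`, `nucleosome`, `sasa`, `mutreg`, `run-all`); the R functions
  are the primary interface.
* Degenerate inputs fail loudly: zero assignable reads, empty dyad or
  site lists, constant pooled data in rank tests, negative bulk inputs,
  fragment-length inversions, and malformed BED lines (reported with the
  line number) are all explicit errors or flagged results.

# Known limitations

* The default phase table is a periodic construction anchored at the
  $\pm 2$ minor-out positions; absolute phasing of real nucleosomes
  should come from an empirical offsets table supplied by the user.
* The synthetic duplex structure is geometric scaffolding, not a
  B-DNA/nucleosome model; structure-level biological conclusions require
  real depositions (e.g. yeast nucleosome crystal structures).
* Gene/TFBS aggregation is raw-count (length-weighted) pooling; a
  per-gene equal-weight variant would differ for strongly skewed
  coverage.
* The naked-DNA NCC half-lives are too slow to measure in vitro; the
  preset values there are order-of-magnitude placeholders.
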