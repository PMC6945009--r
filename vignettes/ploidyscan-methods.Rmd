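---
title: "Inferring ploidy, copy number and haplophase composition from depth and allele balance"
author: "ploidyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ploidy, copy number and haplophase composition from depth and allele balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a polyploid cultivar is resequenced and mapped against a haploid
reference assembly, neither its ploidy nor the copy number of individual
genomic segments is directly observable. Two indirect signals carry the
information:

* **Windowed read depth.** A segment present in c copies on a k-ploid
  background accumulates reads in proportion c/k relative to the
  genome-wide average.
* **Allele balance at heterozygous sites.** If a site is heterozygous with
  i of k haplophases carrying the reference allele, the fraction of mapped
  reads supporting the reference concentrates around i/k; sampling noise
  spreads it binomially with the local read depth.

ploidyscan turns both signals into explicit, testable estimates, starting
from a filtered VCF and a depth track rather than from raw reads: mapping
and variant calling (BWA-MEM + GATK HaplotypeCaller style workflows) are
deliberately upstream of the package.

This vignette describes the models, the tunable parameters and their
defaults, the synthetic-data generator used for validation, the numerical
choices, and the limits of what the tests demonstrate.

# Hard filtering

`filterVariants()` applies the standard hard-filter recommendations for
germline short-read call sets. A record is *removed* when an annotation is
strictly beyond its threshold — SNVs on QD < 2.0, FS > 60.0 or MQ < 40;
InDels on QD < 2.0 or FS > 200.0 — so records sitting exactly on a
threshold are kept; this is the literal reading of the filter expressions.
Two additional rules restrict the set to confidently-genotyped short
variants: InDels longer than 100 bp are removed (length cutoffs of this
order are conventional for ~250 nt read data, where longer events are
unreliably resolved), and any variant supported by fewer than five reads
is removed.

"Support" is interpreted as AD_ref + AD_alt, the allele-depth sum, rather
than DP: the AD sum counts reads informative for the genotype, while DP
may include uninformative or filtered reads. A `supportField = "DP"`
switch is provided since the convention differs between pipelines.

Records missing any of QD/FS/MQ are removed with the explicit reason
`missing-annotation` and a warning — silently defaulting a missing
annotation to a passing value would let unvetted calls through. Removal
reasons are assigned by the first failing rule in the fixed order QD, FS,
MQ, length, support; the order is a reporting convention only (the kept
set is order-independent, which the tests verify against a brute-force
evaluation of the predicates).

# Copy-number segments from windowed depth

`windowDepth()` averages depth over fixed windows (default 100 kb, the
same width used for the variant-density track, so all genome-wide tracks
share one coordinate grid; configurable). Positions absent from the track
count as zero coverage — an absent position is an unmapped one.

`normalizeWindows()` divides by the genome-wide baseline, the *median*
window depth over windows with ≤ 10% N-gap content. The median is robust
to the very windows one wants to detect (duplications, deletions,
gap artifacts); gap-rich windows are excluded because their depressed
means would bias the baseline downward.

**N-gap artifacts.** Long runs of ambiguous bases (N) in an assembly
cannot be covered by mapped reads, so they produce windows of near-zero
depth that look exactly like homozygous deletions. `readReference()`
indexes all N-runs ≥ 100 bp (`minGap`; assemblies differ in gap length
distribution, so the floor is configurable), and `maskArtifacts()` flags a
window as `n_artifact` when its copy ratio is ≤ 0.15 *and* ≥ 50% of the
window is gap. Both conditions are required: a zero-coverage window
without gap content is a candidate real deletion and must not be masked.

`segmentCopyNumber()` quantizes each unmasked window to the copy state
c ∈ {0..cMax} whose expected ratio c/k is nearest (cMax = 6 by default;
midpoint ties resolve to the lower state, conservative against false
duplications). Runs of equal state are merged; interior runs shorter than
`minSeg` windows (default 5, i.e. 500 kb) are dissolved into the longer
flanking run to suppress depth-noise blips. Runs touching a chromosome
boundary are exempt from dissolution — they have no second flank to vote
them down, and terminal segments are real features of chromosome-scale
aneuploidy. Artifact windows inherit the state of their flanks so they
never interrupt a segment, but they are reported as `n_artifact`
sub-segments so no N-gap stretch can surface as a deletion call. A
hidden-Markov segmentation would be a natural extension; the threshold
model is preferred here because the events of interest are megabase-scale
steps between a small set of rational levels, where nearest-state
assignment is transparent and directly testable.

# Ploidy and haplophase composition from allele balance

`refAF()` computes the reference-allele frequency AD_ref/(AD_ref+AD_alt)
of each kept SNV with at least `minSupport` informative reads. Sites with
frequency below `invariantCutoff` (default 0.05) are excluded: at such
sites the sample is essentially invariant and only the reference assembly
deviates, so they carry no information about the sample's internal allele
dosage (they would otherwise pile up at AF ≈ 0 and distort the spectrum).
The cutoff is a numerical implementation of that exclusion, set safely
below the lowest dosage mode the package can call (1/6 ≈ 0.17 at
kMax = 6). Only SNVs enter the spectrum by default — allele depths are
most reliably defined for single-base substitutions — with an
`includeIndels` switch.

`buildSpectrum()` bins the frequencies into 100 uniform bins on [0, 1]
(bin width 0.01; fine enough that the closest modes the model must
distinguish, 1/4 vs 1/3, are eight bins apart). `detectPeaks()` smooths
the counts with a 3-bin centered moving average and reports local maxima
whose topographic prominence is at least 5% of the smoothed maximum,
excluding peaks within 0.03 of the edges (residual invariant or
homozygous-alternate sites). Smoothing width and prominence threshold
trade sensitivity against noise peaks; the defaults keep a minor mode
carrying ~10% of sites detectable while rejecting bin-level noise at
realistic site counts (thousands of SNVs).

`inferPloidy()` scores each candidate ploidy k ∈ 2..kMax by the mean
squared distance of detected peaks to the nearest expected mode i/k, plus
a complexity penalty λk (λ = 1e-4). The penalty resolves the nesting of
mode sets — every k = 2 mode is also a k = 4 and k = 6 mode, so without
it the largest k always ties or wins. Its scale is set against the
squared-distance term: a wrong-but-nested model is penalized by
(Δk) × 1e-4, which outweighs the ~1e-5-level residual of a correct fit
but never the ~1e-2 residual of a genuinely wrong mode set. Ties within
1e-6 resolve to the smaller k and are flagged `ambiguous`. This
peak-to-mode geometry mirrors how ploidy is read off an allele-frequency
histogram by eye; a binomial mixture likelihood over the raw frequencies
would use more of the data and is noted as an extension, not required for
the well-separated modes the method targets.

The haplophase composition follows from the dominant peak: if the highest
peak sits at mode i/k, the most common heterozygous configuration has i
reference-like copies, so the region is called i reference-like plus k−i
divergent haplophases. For a triploid with two reference-like haplophases
the divergent haplophase contributes most heterozygous sites, all at
dosage 2/3 — hence the 2/3 peak is the higher one, and its excess over the
1/3 peak grows if divergent-haplophase reads map at a reduced rate.

`segmentPloidy()` makes one global call over the baseline-state segments
and one call per non-baseline segment with at least `minSites` (200)
usable SNVs; depth-based copy number and allele-balance ploidy are
independent witnesses of the same state, so disagreements are *flagged*
in the report, never silently reconciled. Segments with too few sites are
skipped with an explicit `insufficient sites` note.

# Variant landscape

`densityTrack()` counts SNVs and InDels separately per window, anchoring
each variant at its VCF position so each is counted exactly once.

`indelMod3Bias()` compares the fraction of frame-preserving InDels
(length divisible by 3) inside coding sequence against outside. "Inside"
means the affected interval — the deleted bases, or the insertion point —
overlaps a CDS feature; CDS rather than exon or gene-body overlap is used
because frame preservation is only meaningful where a reading frame
exists. The difference is tested two-sided with a continuity-corrected
two-proportion z test, falling back to Fisher's exact test when any
contingency cell is below 10.

`classifyEffects()` is a deliberately minimal effect classifier covering
the three high-impact classes relevant to gene disruption plus `other`:
CDS InDels whose length contribution to the CDS is not divisible by 3 are
`frameshift` (for boundary-spanning InDels, only the CDS-overlapping
portion counts by default; a `whole`-length mode is provided since
annotation tools differ); SNVs creating an in-frame stop before the
annotated stop are `stop_gained`; SNVs destroying the annotated stop are
`stop_lost`. Minus-strand genes are evaluated on the reverse complement
with coordinates mapped accordingly, honoring the phase of the
transcription-first CDS interval. Splice sites, start-loss, missense and
regulatory annotation are out of scope; correctness of the codon
machinery is checked against an independent oracle that applies the edit
to the chromosome sequence, re-extracts and translates the whole CDS, and
diffs the proteins.

# The synthetic-data generator

`simulateGenome()` realizes the generative model the analysis assumes, so
recovery tests have exact ground truth. The default configuration
(`inst/extdata/triploid_default.yaml`) is the package's reference
scenario throughout tests and the acceptance script:

* **Genome**: 3 chromosomes × 2 Mbp. A 1:10 linear scale-down of a
  ~520 Mbp/11-chromosome plant genome keeps a full run in seconds while
  leaving every structure several windows wide.
* **Ploidy**: baseline 3 with 2 reference-like + 1 divergent haplophase.
* **Variant rates** per bp: divergent-haplophase heterozygous SNVs 0.005,
  shared reference-like-haplophase SNVs 0.0005, homozygous-alternate
  sites 0.001 (these exercise the invariant-site exclusion), InDels
  0.0005. The rates are chosen for statistical power at desk scale
  (≥ 25,000 usable SNVs per run), not as an estimate of any real
  cultivar's divergence; the 10:1 divergent-to-shared ratio makes the
  dominant/minor peak asymmetry unmistakable.
* **Duplication**: 600 kb on chromosome 2 (0.8–1.4 Mbp), adding one extra
  reference-like copy — a scaled-down mid-arm segmental duplication,
  placed so that both flanks exceed the minimum segment length.
* **Depth**: 20 reads per haplotype copy (~60× genome-wide), Poisson per
  position (negative binomial optional for overdispersed libraries).
* **Mapping-rate penalty**: divergent-haplophase reads are thinned by
  `divergent_map_rate` = 0.95, applied consistently to depth *and* allele
  depths, so the expected reference-AF modes shift from {1/3, 2/3} to
  {m/(2+m), 2/(2+m)} = {0.322, 0.678}. Reads from a divergent haplotype
  genuinely map at a slightly reduced rate against a biased reference;
  0.95 keeps the shifted modes within ±0.02 of the ideal dosage values,
  consistent with "slight" reduction, while still producing the
  characteristic peak-height asymmetry. The parameter is exposed; setting
  it to 1 recovers the exact i/k modes.
* **N-gaps**: two stretches (200 kb and 100 kb) written as N and excluded
  from read coverage, reproducing pseudo low-coverage artifacts.
* **Genes**: ~90 models of mean CDS length 900 bp, 1–2 exons, proper ORFs
  (ATG…stop) embedded on either strand, so effect classification and its
  oracle run on biologically well-formed models. InDel lengths follow a
  truncated geometric distribution; inside CDS the probability of mod-3
  lengths is multiplied by `cds_mod3_enrichment` = 3, emulating selection
  against frameshifts.
* **Filter annotations**: QD/FS/MQ are *drawn* (95% from passing ranges,
  5% failing), not computed from alignments — the filter's logic, not the
  annotation math, is under test. For the same reason reads themselves are
  never generated; depth and allele depths are sampled directly, which is
  exactly the interface the pipeline consumes.

A `null_diploid.yaml` preset (diploid, no duplication, no mapping
penalty, no mod-3 enrichment) serves as negative control: a single 0.5
peak, no non-baseline segments, no coding bias.

**What the simulation does not emulate** — and therefore what passing
recovery tests do *not* show about real data: alignment and calling
artifacts (multi-mapping, paralog collapse, strand bias that QD/FS/MQ are
meant to catch), GC- and mappability-dependent coverage waves,
position-correlated errors, mosaicism, and divergence concentrated in
haplotype blocks rather than uniform per-bp rates. The tests demonstrate
that the estimators are correct under their stated model; robustness to
real-data violations of that model must be judged separately.

# Numerical and design choices

* **Coordinates.** All internal containers are Bioconductor `GRanges`
  (1-based, closed), the platform convention shared with every upstream
  and downstream Bioconductor tool; BED output/input is converted to
  0-based half-open at exactly one place (`writeBed()`/`readBed()`), and
  VCF positions are 1-based as in the standard.
* **Multi-allelic sites** are split into per-alt records on reading; the
  AF analysis is strictly reference-vs-alternate.
* **Histogram edge case**: AF exactly 1.0 is assigned to the last bin so
  counts are conserved.
* **Tie-breaks**: copy-state midpoints resolve down (conservative);
  ploidy-score ties resolve to the smaller k and are flagged.
* **Degenerate inputs** fail loudly: empty FASTA, duplicate sequence
  names, malformed VCF coordinates/alleles (with line number), depth on
  unknown chromosomes, all-gap windows, regions with too few SNVs.
* **Determinism**: a fixed seed reproduces byte-identical simulator
  output; the pipeline report excludes timestamps and records the seed
  and a config hash.

Problem sizes in the shipped tests (600 kb–6 Mbp genomes, 5–20 seeds,
1000-variant oracle sets) are the package's chosen compromise between
statistical resolution — e.g. ≥ 5,000 heterozygous SNVs per run for
stable spectra, 20 seeds for recovery rates — and a test suite that runs
in minutes on a laptop.

# Known limitations

* Ploidy calls beyond kMax = 6 and mixed/mosaic states are out of scope;
  the model assumes one dominant copy state per region.
* Sub-window breakpoint refinement is not attempted; boundaries are
  window-quantized (±1 window at default settings).
* The effect classifier does not model splice sites, start loss, or
  compound effects of nearby variants, and classifies each variant
  independently.
* Haplotype phasing and phased assembly are explicitly not attempted;
  the haplophase composition reported here is a count, not a
  reconstruction.
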