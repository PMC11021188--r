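---
title: "txbodies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{txbodies: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`txbodies` re-implements, as tested library code, the quantitative analyses
used to study the two micron-scale transcription bodies that form at the
*mir430* locus during zebrafish zygotic genome activation and that
sequester the pause-release kinase CDK9. The package covers five analysis
layers — sub-voxel 3D spot localization, transcription-body classification
and tracking, per-nucleus enrichment statistics, DNA-FISH distance
analysis with Oligopaint probe QC, and conversion-aware (SLAM-seq style)
nascent-read selection — plus a first-class synthetic-data generator that
produces every input with machine-readable ground truth. Raw microscopy
and sequencing data are not redistributable at desk scale, so correctness
is established against simulations and independent oracles, not against
the study's headline numbers.

# Coordinate and unit conventions

Image axes are ordered (z, y, x) everywhere. Voxel indices are 0-based in
all physical conversions: the coordinate of voxel *i* along an axis is
*i* × spacing, with spacings in micrometres per voxel (`voxel_grid()`).
Anisotropy is first-class: axial steps (0.3 um, the z step of the FISH
stacks) differ from lateral pixel sizes, and every distance or sigma is
specified per axis in micrometres and converted through the grid.

Genome positions in the read modules are 1-based and inclusive, matching
SAM and GTF directly. This deliberately trades the 0-based half-open
internal convention common in Python tooling for consistency with R's
1-based indexing; keeping a single convention end to end removes the
translation layer where off-by-one errors breed.

# Spot localization

Detection follows the classic three-stage scheme: difference-of-Gaussians
band-pass filtering, 26-connected local-maxima detection with proximity
merging, then iterative Gaussian-mask refinement **on the raw image** so
that intensity estimates stay unbiased by the filter.

The mask iteration updates the center as a Gaussian-weighted,
background-subtracted centroid with the mask sigma held fixed at the PSF
sigma; on a symmetric noiseless spot the true center is a provable fixed
point. The local background is the median of the fit window's boundary
shell — robust and parameter-free. Defaults: window radius 3 sigma,
tolerance 0.01 voxel, at most 100 iterations; a window whose
background-subtracted mass is not positive yields a flagged non-converged
record rather than an error. The band-pass sigmas default to 0.5x and 3x
the PSF sigma; the original study names only "band-pass filtering" without
cutoffs, so these are declared package defaults (standard
particle-detection practice), both exposed in the API.

Selection for the distance analysis keeps the brightest spots per channel:
20 for gene channels (ten genes per group, diploid nuclei) and 2 for the
locus channel (two alleles). Intensity ties break by ascending (z, y, x)
center, and shortfalls are flagged, never silently padded.

# Transcription-body classification and tracking

Bodies are connected components of above-threshold voxels inside
segmented nuclei, with one fixed threshold per channel per experiment. No
default threshold is shipped: the values used in the original plugin-based
analysis were set manually and are not printed, so the parameter is
required configuration rather than a fake default.

Identity: a body overlapping (at least one voxel) a locus-reporter
(MOVIE) object is a *mir430* body, otherwise ectopic. Because the large
amorphous bodies can fragment under thresholding, fragments overlapping
the same reporter object are first re-merged and counted once.

State: Ser5P (initiation mark) and Ser2P (elongation mark) bodies are
paired one-to-one, greedily by ascending centroid distance up to a pairing
radius; paired bodies are initiating–elongating, unpaired Ser5P initiating,
unpaired Ser2P elongating. Whether the original analysis used overlap or
proximity for this colocalization is unstated; proximity with a
configurable radius was chosen, defaulting to 0.5 um (on the order of the
bodies' size). Greedy matching is deterministic and order-independent; it
equals the exhaustive minimum-distance assignment whenever pairings are
unambiguous, which the tests verify on crafted scenes.

Tracking rules mirror the published analysis: frames at or after
nuclear-envelope breakdown are excluded (breakdown frames are an explicit
input — the original criterion was visual, so inferring it from images
would be pretense); per nucleus, t = 0 is the first frame with a detected
body; nuclei with bodies in exactly one analysed frame are discarded; and
an observed fusion of the two locus bodies does not reduce the reported
body count. The linking radius defaults to 1.0 um, chosen for inter-frame
motion at ~2-minute intervals; it is configuration, not doctrine.

# Enrichment statistics

For each nucleus, with body areas $A_1, A_2$, body mean intensities
$M_1, M_2$, nucleus area $A_N$, nucleus mean $M_N$ and no-primary-control
background $B$:

$$\mathrm{PercentageArea} = 100\,\frac{A_1 + A_2}{A_N}, \qquad
\mathrm{PercentageIntensity} = 100\,\frac{A_1 M_1 + A_2 M_2}{A_N\,(M_N - B)}$$

$$\mathrm{IntensityEnrichment} =
\frac{(A_1 M_1 + A_2 M_2)/(A_1 + A_2)}{M_N - B}$$

Body means are **deliberately uncorrected** in the numerators while the
nucleus mean is background-corrected, exactly as the published formulas
are written; a fully corrected variant exists behind an explicit
`correct_bodies` flag and is labelled non-canonical. The identity
`IntensityEnrichment = PercentageIntensity / PercentageArea` holds
algebraically and is the module's core self-consistency check (tested to
1e-12). Nuclei whose corrected nucleus mean is not positive are excluded
with a reason — never clamped. Areas default to voxel counts (the
statistics are unit-free ratios); whether the original "area" was a 2D
projection or a 3D volume is not stated, so both are supported with voxel
volume as default. `log2(IntensityEnrichment)` is emitted alongside the
ratio, since that is the quantity conventionally tested against zero.

The microRNA-activity sensor ratio is
$(\mathrm{eGFP}_{head} - \mathrm{eGFP}_{bg}) /
 (\mathrm{RFP}_{head} - \mathrm{RFP}_{bg})$,
with the RFP denominator required positive.

# DNA-FISH distances and probe QC

Spots are assigned to nuclei by rounded-center-voxel membership. Distances
are 3D Euclidean in micrometres from each gene spot to the **nearest** of
the (two) selected locus spots in the same nucleus — the study plots
distances "from the locus" without specifying allele pairing, so
nearest-allele is the declared convention and the nearest-allele index is
also emitted for per-allele analyses. Colocalization uses a strict
inequality at the 0.5 um radius (a distance of exactly 0.5 um does not
count). Whether the published fraction pooled spots across nuclei or
averaged per-nucleus fractions is unstated; the pooled value is the
default and both are returned. Nuclei without detected locus spots are
excluded from fractions and reported separately.

Probe QC enforces the Oligopaint design rules: each oligo is a fixed
5'→3' concatenation of six segments (forward priming, RT priming,
gene-specific readout, genomic target, group-specific readout, reverse
priming); assembled length must be 130–137 nt; per-gene density 10 ± 1
probes per kb; genes at least 40 kb with at least 400 probes. Probe
*design* (homology search, off-target filtering) is out of scope — QC
validates libraries, it does not create them.

# Nascent-read selection

The pileup, SNP caller, fragment classifier and counter are deliberate
re-implementations (interval arithmetic and per-base walks) rather than
wrappers, because re-deriving the rules is the point of the module.
Mismatches are always recomputed from the reference FASTA; MD tags serve
only as a cross-check, keeping the classifier independent of aligner tag
dialects. Secondary, supplementary, duplicate and unmapped records are
excluded up front.

SNP consensus: natural variants are called per unconverted
(alkylation-minus) control sample with the five published thresholds —
coverage ≥ 20, variant reads ≥ 5, mean variant base quality ≥ 15, variant
frequency ≥ 0.25, significance ≤ 0.01 — and unioned across samples keyed
by (chrom, pos, alt). The upstream caller's exact significance statistic
is not published; this package uses a one-sided exact binomial tail
against a 1% per-base error null, documented as an approximation and
pluggable.

Fragment classification: the transcript strand comes from the mate flags
(read 2 carries the transcript-sense sequence under RF strandness), so
candidate conversions are genomic T→C on plus-sense fragments and A→G on
minus-sense fragments. Consensus-SNP positions are masked regardless of
allele, bases below the quality cutoff are ignored (default Q20 — the
upstream script's cutoff is unpublished, so the default is surfaced in
every report), and positions covered by both mates count once. A fragment
is labeled (nascent) iff at least one conversion survives. Both masking
and the quality cutoff are provably monotone: enlarging the SNP set or
raising the cutoff can only shrink the labeled set.

Counting follows the published featureCounts configuration re-expressed
as interval arithmetic: both mates mapped, fragment-block/exon-union
overlap ≥ 10 nt, reverse-strand rule, ambiguous (multi-gene) fragments
dropped. Genes with fewer than ten raw reads total across samples are
flagged non-expressed (ten itself passes). Chromosome enrichment is the
set-vs-universe fraction ratio with an upper-tail hypergeometric p-value
and Benjamini–Hochberg correction across chromosomes.

# What the simulator emulates — and what it does not

The generator produces: ellipsoidal non-overlapping nuclei rasterized into
label images; diffraction-limited spots as point-sampled anisotropic 3D
Gaussians; amorphous bodies as unions of overlapping spheres rendered as
piecewise-constant intensity; timelapses with scheduled appearance, fusion
and envelope-breakdown events; and paired-end RF-stranded read sets with
planted conversions, homozygous SNP alleles and uniform sequencing errors,
written as minimal valid SAM with MD/NM tags. Noise defaults to Poisson on
signal-plus-background with optional additive Gaussian read noise —
sCMOS/EMCCD phenomenology without camera specifics, which the study does
not report; noise parameters are therefore configuration, not fixed
constants.

Not emulated: optical PSF physics (no Gibson–Lanni model), chromatin
motion or polymer behaviour, aligner artefacts beyond planted mismatches
(M-only CIGARs; spliced and clipped alignments are exercised with crafted
fixtures instead), amplification duplicates, and spatial intensity
inhomogeneity. A green end-to-end test therefore establishes that the
analysis rules are implemented correctly and recover known truth under the
stated noise model — it does not establish robustness to real-microscope
artefacts or real library chemistry.

Simulation scale in the shipped tests is deliberately modest (tens of
nuclei, thousands of fragments, grids up to ~20×72×72 voxels) to keep the
suite inside its runtime budget; every generator takes explicit size
parameters, so scaling up is a caller's decision, not a code change.

# Numerical and degenerate-input choices

- Maxima ties break toward the lexicographically smallest (z, y, x) index;
  candidate merging keeps the brighter spot within the separation radius.
- The fit window is clipped at image borders; an all-background window
  returns a flagged non-converged record.
- Percentages at timepoints with zero bodies are `NA`, not 0.
- `colocalized_fraction` on an empty record set is an error, not `NaN`.
- Empty reporter channels make every body ectopic (vacuous overlap).
- Determinism: every stochastic function takes an explicit seed and
  produces bit-identical output for identical inputs.

# Known limitations

- The greedy state-pairing is not a global optimal assignment; on
  adversarial near-radius configurations it can differ from the
  minimum-total-distance matching. It is deterministic and matches the
  stated rule.
- The SNP significance model approximates the original tool's unpublished
  test; calls at the p-value margin may differ from the original pipeline.
- Fragment counting drops multi-gene fragments; whether the original
  counting did so is not printed (it is the cited tool's default in the
  mode used).
- Image I/O uses a plain-text volume format rather than TIFF, as no TIFF
  codec is available in the supported dependency set; the format carries
  the same metadata (shape, spacing, channel, frame).
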