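# txbodies

Quantitative analysis of micron-scale **transcription bodies** in early
embryos, and of the nascent transcription they control.

During zebrafish zygotic genome activation, transcription is initially
confined to two large nuclear bodies nucleated by the repetitive *mir430*
miRNA cluster. These bodies concentrate RNA polymerase II (Ser5P-marked
initiating and Ser2P-marked elongating forms) and sequester CDK9, the
catalytic subunit of the pause-release kinase pTEFb — so their presence
shapes when genes elsewhere in the nucleus escape promoter pausing.
`txbodies` provides the analysis toolchain such a study needs, for
microscopists and genomicists alike:

- **simulation with ground truth** — ellipsoidal nuclei, 3D Gaussian
  spots, amorphous bodies, timelapses with fusion/envelope-breakdown
  events, and paired-end RF-stranded read sets with planted T→C
  conversions, SNPs and errors (SAM/FASTA/GTF out);
- **spot localization** — difference-of-Gaussians band-pass, 3D maxima,
  and iterative Gaussian-mask fitting to sub-voxel precision:
  $x_{k+1} = \sum_i (I_i-b)\,G(r_i;x_k,\sigma)\,r_i \,/\, \sum_i (I_i-b)\,G(r_i;x_k,\sigma)$;
- **body classification & tracking** — identity (*mir430* vs ectopic, by
  reporter overlap), state (initiating / initiating–elongating /
  elongating, by Ser5P–Ser2P pairing), and the cell-cycle rules (t = 0 at
  first appearance, envelope-breakdown exclusion, fusion keeps the count);
- **enrichment statistics** — per nucleus,
  `PercentageArea = 100 (A₁+A₂)/A_N`,
  `PercentageIntensity = 100 (A₁M₁+A₂M₂) / (A_N (M_N − B))`,
  `IntensityEnrichment = [(A₁M₁+A₂M₂)/(A₁+A₂)] / (M_N − B)`,
  plus the eGFP/RFP microRNA-activity sensor ratio;
- **DNA-FISH distances** — nucleus assignment, brightest-spot selection
  (20 gene spots, 2 locus alleles), 3D nearest-allele distances,
  colocalization fractions (strict < 0.5 µm), Oligopaint probe QC
  (130–137 nt, 10 ± 1 probes/kb, ≥ 400 probes, ≥ 40 kb);
- **nascent-read selection** — pileup, SNP consensus from unconverted
  controls (coverage ≥ 20, variant reads ≥ 5, quality ≥ 15, frequency
  ≥ 0.25, p ≤ 0.01), strand-aware conversion calling with SNP masking,
  fragment-level exon counting (overlap ≥ 10 nt, reverse-stranded,
  ambiguous dropped), and chromosome-level hypergeometric enrichment with
  BH correction.

## Worked example

Simulate a two-nucleus scene whose first nucleus carries the two
CDK9/Ser2P-positive bodies, then compute the enrichment statistics from
the exact noiseless measurements:

```r
library(txbodies)
g   <- voxel_grid(c(24, 72, 72), c(0.3, 0.15, 0.15))   # (z,y,x), um/voxel
nuc <- gen_nuclei(2, g, seed = 11, radius_um = c(2.2, 2.2, 2.2))
spec <- list(
  list(nucleus = 1, identity = "mir430", channels = c("cdk9", "ser2p"),
       radius_um = 0.5, intensity = 40),
  list(nucleus = 1, identity = "mir430", channels = c("cdk9", "ser2p"),
       radius_um = 0.5, intensity = 40))
sc <- gen_body_scene(nuc, spec, seed = 5, noise_model = "none")
m  <- Filter(function(x) x$nucleus == 1 && x$channel == "cdk9",
             sc$truth$measurements)[[1]]
em <- enrichment_measurement(m$area_body, m$mean_body,
                             m$area_nucleus, m$mean_nucleus, background = 0)
percentage_area(em); percentage_intensity(em); intensity_enrichment(em)
```

prints (this exact run):

```
area occupied by the two bodies: 4.63 %
signal in the two bodies:        19.53 %
intensity enrichment:            4.219 (log2 = 2.077)
```

i.e. the two bodies cover 4.6% of the nuclear volume but hold 19.5% of
the nuclear signal — a 4.2-fold enrichment over a uniform distribution.
Spot detection on a noisy render of the same grid:

```r
tr  <- gen_spot_truth(5, g, seed = 3, amplitude = 100)
img <- gen_spot_image(tr, background = 100, noise_model = "poisson", seed = 4)
detect_spots(img, threshold = 5)
#>       z_um     y_um     x_um intensity converged
#> 1 2.713755 6.171018 6.177882  93.88879      TRUE
#> 2 4.015696 5.434113 5.387925  96.42570      TRUE
#> 3 1.758694 3.637789 5.968884 109.22304      TRUE
#> ... (5 rows: all spots recovered; centers in um, sub-voxel precision)
```

A command-line interface for the main flows (simulation, spot detection,
enrichment, FISH distances, probe QC, nascent-read calling) lives in
`inst/cli/txbodies`; run it with no arguments for usage.

## Documentation

The methods vignette (`vignettes/txbodies-methods.Rmd`) describes the
models, every tunable parameter with its default and rationale, what the
simulator does and does not emulate, and the design decisions taken where
the published methods leave the choice open.
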