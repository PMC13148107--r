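---
title: "Methods: the inverse-expression screen and its quantification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the inverse-expression screen and its quantification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inversepair)
```

## The model

The package operationalises one idea: if two cell-surface molecules
pattern a tissue by mutual exclusion, their expression across the
tissue's neuronal subtypes should be anti-correlated, and that
anti-correlation is strong enough to rank candidate partners for an
orphan receptor. Everything else in the package exists either to
produce the inputs of that screen faithfully (QC, normalisation,
subtype aggregation) or to quantify what a recovered candidate must
then demonstrate (cell-surface binding, inverse spatial expression,
mistargeting penetrance).

The screen works on two aligned subtype-by-gene matrices built from
QC-filtered cells:

- the **intensity** matrix, mean log2(CPM+1) per subtype — the mean is
  taken over log-transformed per-cell values, not log of the mean CPM,
  so a few extreme cells cannot dominate a subtype;
- the **breadth** (expression-fraction) matrix, the proportion of a
  subtype's cells with raw count > 0.

For a target gene, each candidate's columns in the two matrices give
two Pearson coefficients, `r_cpm` and `r_frac`, and the integrated
score is their arithmetic mean. Using both matrices guards against two
failure modes a single matrix has: a gene expressed at high level in a
handful of cells (high intensity, low breadth) and a gene detected
everywhere at trace level (high breadth, low intensity). The score is
bounded in [−1, 1]; a candidate whose subtype profile is an exact
decreasing affine transform of the target's in both matrices scores
exactly −1, which is the screen's theoretical extreme and the quantity
`scripts/acceptance.R` recomputes.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `min_counts` | 100,000 | counts | library-size floor; strictly below is removed |
| `max_mito_frac` | 0.05 | fraction | mitochondrial ceiling; strictly above is removed |
| `mad_k` | 3 | — | ERCC-fraction outlier threshold (median + k·MAD) |
| `min_mean` | 3 | log2(CPM+1) | CSM gate, strict |
| `min_frac` | 0.5 | fraction | CSM gate, strict |
| `top_k` | 10 | genes | shortlist length |
| `dilation_um` | 1.25 | µm | nuclear ROI dilation radius |
| `area_range_um2` | 7.8–23.4 | µm² | control-ROI area gate (inclusive) |
| `min_circ` | 0.9 | — | control-ROI circularity gate, strict |
| `primary_threshold` | 0.20 | fraction | "primary destination" gate, strict |

Boundary semantics follow the printed conventions: a cell with exactly
100,000 counts and exactly 5% mitochondrial content is retained; a
CSM with mean expression exactly 3 is excluded; a glomerulus with
mis-innervation frequency exactly 20% is not a primary destination.

Two genuinely open readings had to be resolved:

- **The CSM gate across subtypes.** "Above both thresholds in at least
  one subtype" can mean both thresholds in the *same* subtype or each
  threshold in *some* subtype. We default to the joint (stricter)
  reading — a partner must be both strongly and broadly expressed
  somewhere — and expose `joint = FALSE` for the disjoint reading.
- **ERCC counts in the CPM denominator.** Spike-ins are not cellular
  transcripts, so they are excluded from the library size and from the
  normalised output; mitochondrial genes are cellular and stay in.
  Both choices are arguments of `normalize_cpm_log()`.

Other numerical choices: Pearson coefficients are computed over all
subtypes (no masking); zero-variance candidate columns make the
coefficient undefined, so those candidates carry `NA` and are excluded
from ranking rather than being assigned a score of 0 (a 0 would be a
substantive claim of "no relationship" the data cannot make);
ranking ties break lexicographically on gene id so results are
reproducible; ipTM averaging uses however many models are supplied,
with five being the expected convention.

## What the synthetic data emulates

`gen_sc_counts()` emulates SMART-seq2 plate data aggregated over
~30–50 PN subtypes with tens of cells each: negative-binomial counts
(default size 2) around subtype-specific gene means, scaled by a
log-normal per-cell library factor (default mean 500,000 counts,
sdlog 0.25 — comfortably above the 100,000-count QC floor, as real
plates mostly are), thinned by independent dropout (default 15%).
Mitochondrial genes and ERCC spike-ins are emitted at per-cell count
fractions drawn from U(0.005, 0.04) and U(0.005, 0.02): mostly-healthy
cells, with the QC gates removing the tail. Mito and spike-in
expected fractions are flat across subtypes — in this generator they
model cell quality, not cell identity.

A planted pair (`caps` → `CSM002` by default) overwrites the target's
subtype means with uniform draws over 0.5–10 expected counts and sets
the partner's profile to `strength · reflected + (1 − strength) · own`,
where `reflected = (max + min) − target`. At strength 1 the planted
mean vectors have Pearson r exactly −1 *pre-sampling*. The 0.5–10
count range is chosen so that the inverse relation remains visible in
both observed matrices: the log transform is informative there, and
the negative-binomial zero probability still varies, so detection
fractions do not saturate. This is the regime in which a mirror-image
partner is realistically detectable; planting at very high expression
would make `r_frac` pure noise because every gene is detected in every
cell.

What the generator deliberately does **not** model: UMI chemistry or
read-level noise, batch or plate effects, doublets, correlated gene
modules, or mean-dependent dropout. Passing tests therefore show that
the implementation computes the screen correctly and recovers planted
signal under idealised noise — not that the screen has any particular
sensitivity on real tissue.

`gen_cell_image()` uses hard disks of uniform intensity on a uniform
background with optional additive Gaussian noise — the simplest model
that exercises Otsu thresholding, nuclear dilation, and the
area/circularity gates with exact ground truth. The default pixel size
is 0.2 µm so that gate-passing ROIs are rasterised at radii ≥ 10 px,
where disk circularity estimates are stable. Z-stacks are identical
replicated planes (projection is tested as an operation, not as 3-D
reconstruction). `gen_gradient_image()` renders two opposing linear
gradients; `gen_clone_table()` draws binomial mistargeting outcomes
with per-glomerulus destination probabilities conditional on
mistargeting, so per-glomerulus tallies never exceed totals.

## Image quantification choices

- **Otsu**: 256 bins over the observed intensity range (8-bit
  heritage), exhaustive search for the cut maximising between-class
  variance, ties taking the lowest cut; the mask is strictly above the
  threshold. The implementation matches both a naive binned exhaustive
  search and an exact unbinned search on bimodal test images.
- **Connectivity**: 8-connected components, the common default of the
  macro environment this reproduces. Touching cells merge into one
  ROI; that is a documented property, not a defect.
- **Circularity**: `4π·area/perimeter²` with a 4-direction Crofton
  (integral-geometry) perimeter. Naive boundary-pixel counting
  systematically misestimates rasterised disk perimeters, making the
  0.9 gate meaningless; the Crofton estimator keeps ideal disks near 1
  (rasterised disks of radius ≥ 10 px score > 0.9, a 100-px line
  scores ≈ 0.03).
- **Dilation**: radius `round(1.25 / pixel_size)` px with a disk
  element; below 1 px a warning is issued and no dilation applied.
  Gates are applied to control ROIs after dilation, in the order the
  procedure prescribes (dilate → exclude FL-overlapping → gate); the
  area/circularity gates are optionally applied to transfected ROIs
  (`gate_transfected`), which the source procedure leaves unstated.

For line profiles, sampling is bilinear at unit spacing along the line
with `width_px` evenly spaced perpendicular offsets; each profile is
min-max normalised per lobe and per channel *before* averaging (the
order of operations in the source procedure), then linearly resampled
to 100 points — the resampling length is not stated anywhere and 100
points comfortably oversamples profiles a few hundred pixels long.
Degenerate (constant) profiles are flagged and returned as zeros
rather than dividing by zero. Glomerular normalisation is a per-ROI
ratio of means (not the mean of per-pixel ratios), which is the
standard depth-attenuation correction and is invariant to joint gain.

## Statistics

Fisher's exact test is two-sided by the probability method (the sum of
hypergeometric probabilities of tables as or less probable than the
observed one, with a 1e-7 relative tie tolerance) — the dominant
convention and the one `stats::fisher.test` implements; the test suite
verifies it against full enumeration on every 2×2 table with margins
≤ 12. BH FDR is applied over exactly the family of p-values submitted
in one call (for penetrance, all pairwise genotype comparisons of one
panel); constructing the family is the caller's responsibility because
figure-level family composition is a reporting decision, not a
computation. The repeated-measures two-way ANOVA requires a balanced
complete subject × condition × construct design and decomposes sums of
squares within subject strata; degenerate fixtures (zero residual
variance) report F = 0, p = 1 by convention when the effect sum of
squares is zero. Pairwise condition contrasts within each construct
are paired t-tests, Šidák-adjusted over constructs.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at
desk scale: 30 subtypes × 30 cells × 2,000 genes for screen
replicates (20 seeded replicates for the planted-recovery check),
2,000 simulated table pairs for the Fisher calibration check, and
images of 256–320 px. These sizes were chosen to make every
distributional assertion comfortably stable at 3-standard-error
tolerances while keeping a full run in tens of seconds.

## Known limitations

- Cluster labels are inputs; feature selection (ICIM), embeddings and
  clustering are out of scope, so `cosine_match()` transfers labels
  between *given* profile sets only.
- The NB + uniform-dropout count model is a stand-in; the empirical
  count distribution of the real plates is not characterised here, and
  none of the acceptance properties depend on it being correct.
- Structure prediction is ingested, never computed: `ingest_iptm()`
  ranks a table you provide.
- The image pipeline assumes max-projected 2-D quantification with
  well-separated cells; no deconvolution, illumination correction, or
  3-D segmentation.
- `fisher.test`'s conservatism means the calibration bound (empirical
  type-I ≤ 0.06 at α = 0.05) is loose by construction; the test is
  exact, not asymptotic.
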