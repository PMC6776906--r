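---
title: "Models and methods behind lysoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lysoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-content siRNA screens of the endolysosomal damage response measure, per
cell, the fraction of LAMP1-positive vesicles that carry a damage marker
(pan-ubiquitin FK2, K48- or K63-linked ubiquitin chains, galectin-3, or a
protein of interest) after treatment with a lysosomotropic agent such as
LLOMe. Hits are genes whose knockdown significantly reduces that fraction.
A companion comparative SILAC proximity-labeling experiment asks which
proteins come near a bait before versus after damage. `lysoscreen`
implements the full quantitative machinery of such a study — image
quantification, per-cell readouts, plate statistics with hit calling, and
the proteomics classification — together with a synthetic-data generator
that plants known ground truth so every stage is testable without any
external data.

## The synthetic world

`generate_field()` renders what the quantification stage assumes: nuclei
and vesicles are uniform-intensity disks convolved with a Gaussian PSF;
cells are the nucleus-seeded Voronoi partition of the field; vesicles are
placed uniformly in the cytoplasm with at least one diameter of clearance
between centers (configurable), which keeps detection ground truth
unambiguous. Each vesicle is independently marker-positive with the
configured `positivity_fraction`, and "damage" or a gene knockdown changes
*only* that fraction (optionally the puncta count) — never morphology,
because the readouts being emulated are colocalization fractions and
puncta counts, not shape features. The camera model is Poisson shot noise
on expected photon counts (`intensity / gain`), Gaussian read noise, and
clipping to the 16-bit range.

Default geometry (a field of 256 px at 0.25 µm/px, nuclei of radius
3 ± 0.3 µm, ~15 vesicles per cell with log-normal radii around 0.5 µm, PSF
σ = 0.2 µm) was chosen once as a realistic spinning-disk configuration;
the screen's original acquisition settings are not on record, so these are
conventions, not claims. What the generator deliberately does **not**
emulate: textured cytoplasm, photobleaching, drift, 3D stacks,
illumination gradients. A green recovery test therefore establishes that
the algorithms are correct on data obeying their stated model, not that
they are robust to every real-microscope artifact.

The plate generator works at two fidelities. `metric` draws per-cell
readouts directly from the distributions the image path realizes
(vesicle counts Poisson, positives binomial at the well's planted
fraction) — fast enough for power studies; `image` renders full fields.
A dedicated test simulates the same wells both ways (zero noise) and
requires the pooled percent-positive readouts to agree within 2
percentage points.

Well-level biology is `p_well = clamp(baseline × gene_effect + ε, 0, 1)`
with ε Gaussian. The stated screen world is baseline 0.8, well SD 0.05,
37 genes in quadruplicate; the planted strong hit multiplies by 0.5
(40% positivity). The time-course profile uses the pulse
`f(t) = base + (peak − base)·((t/t_p)·e^{1 − t/t_p})^k`, which rises from
baseline and peaks exactly at `t_p`: the early markers (K63 chains, p62)
peak at 60 min and the late ones (K48 chains, UBE2QL1-like) at 150 min, so
on the sampling grid {0, 30, 60, 120, 180} the late markers are maximal at
120–180 min — the qualitative ordering the assay is known for.

The SILAC generator exploits the 1:1 heavy/light mixing design: null
proteins have per-replicate log2 H/L ratios centered at 0 (default
SD 0.3), enriched proteins are shifted by their true effect, and
MaxQuant-style contaminant/reverse/site-only decoys are appended. Missing
values are missing-completely-at-random per replicate (detection
probability 0.9 by default); no imputation is performed anywhere because
the analysis contract is simply "≥ 2 contributing replicates".

## Quantification choices

The original screen's detection pipelines (Acapella, CellProfiler) are
unpublished, so this package standardizes on conventional,
parameter-sparse algorithms that can be validated against planted truth:

* **Nuclei** — Otsu threshold on a lightly blurred nucleus channel,
  distance-transform watershed to split touching nuclei, minimum-area
  gate. A blank-field guard requires the threshold to clear the image
  median by 5 robust-noise units (skipped when the background is exactly
  flat, i.e. noise-free renders), so pure noise yields zero nuclei rather
  than noise blobs.
* **Cells** — every pixel goes to the nearest nucleus centroid
  (Euclidean); ties break to the lowest label, deterministically. Cells
  whose nucleus touches the border margin are flagged `edge` and excluded
  from per-cell statistics by default (with a full-field Voronoi partition
  every peripheral *cell* touches the border, so the nucleus — the actual
  source of partial-object bias — carries the flag).
* **Puncta** — multi-scale Laplacian-of-Gaussian with scale-normalized
  responses, detection threshold expressed in median-absolute-deviation
  noise units (making segmentation invariant to positive rescaling of a
  channel), minimum peak separation, and a disk mask of radius √2·σ at the
  best scale. Area gates are exposed as configuration and documented as
  conventions, not facts about the original screen.
* **Measurement** — per-object mean per channel; background is the
  per-cell median of non-object pixels; corrected mean floored at 0.

"Marker-positive vesicle" defaults to the object-overlap criterion (a
detected marker-punctum centroid inside the vesicle disk), which matches
the phrasing "marker-positive LAMP1 vesicles"; an intensity criterion
(corrected marker mean > k robust-noise units) is available, and the
choice is recorded with the result. Per-cell Pearson coefficients are
computed over whole-cell pixels by default; an above-background mode
exists because the original scope of the correlation was not recorded.
Both are implemented, neither claimed as the original.

## Screen statistics

Robust z-scores are `(x − median)/(1.4826 × MAD)` over the plate's
QC-passing (≥ 50 cells), damage-treated library samples. Decisions that
were genuinely open, and how they were fixed:

* The 1.4826 factor (normal-consistency scaling of the MAD) is assumed
  and configurable; "robust z-score" alone does not pin it down.
* Replicates: the four wells of a reagent are collapsed by median into
  one sample before scoring (default); a per-well mode that medians the
  per-well z-scores is provided, since the original choice is unstated.
* Controls are excluded from the reference population by default
  (switchable): non-targeting and ATG5/ATG7 wells sit on the plate but
  "against the whole plate" most plausibly means the library.
* Thresholds are inclusive (z ≤ −2 is a hit). Primary rule: reduction in
  *one or both* stainings. Secondary rule: a single siRNA scores only with
  *both* stainings at threshold; a gene is confirmed with ≥ `min_singles`
  scoring singles (default 1 — the confirmation count is not on record and
  is reported in the output).
* Degenerate plates: MAD = 0 falls back to the plate SD with a warning;
  SD = 0 is an error, never a silent division.

Group comparisons use one-way ANOVA followed by Bonferroni all-pairs
t-tests on the pooled error, or Dunnett's comparison against a control
implemented through the multivariate-t probability (`mvtnorm`), validated
against an external reference implementation on a frozen fixture.

## Proximity proteomics

The enrichment test is a two-sided one-sample Student's t of the
per-protein log2 H/L ratios against 0 — the 1:1 mixing null makes the
one-sample form the natural reading of "t-tests between treatments" for a
within-sample ratio design (a two-sample mode over two ratio sets is also
available). Volcano classes: `enriched_heavy` iff mean log2 ≥ 1.5 and
p < 0.05, `depleted_heavy` symmetrically. The fold boundary is inclusive
(the figure-legend form "≥ 1.5" over the narrative "> 1.5-fold") and the
p boundary exclusive; a figure legend's "P > 0.05" for the significance
threshold is an evident typo and the Methods direction (p < 0.05
significant) is implemented. No multiple-testing correction enters the
classification, matching the stated per-protein rule; a Benjamini-
Hochberg FDR column is emitted for users. Zero-variance proteins are
flagged degenerate: with nonzero mean the p-value is reported as the
limit 0 (flagged, never silently), with zero mean it is undefined and the
protein cannot be called enriched.

## Numerical notes

* All generators route randomness through a seed-scoped RNG: identical
  configuration and seed give bit-identical output, and the caller's RNG
  state is untouched. Derived child seeds stay below 2^31.
* Gaussian blur is an exact separable convolution with per-row kernel
  renormalization at the borders (no dark halo), implemented as two banded
  matrix products and cross-checked against a brute-force convolution.
* The Euclidean distance transform is exact (Felzenszwalb-Huttenlocher);
  the watershed floods in ascending elevation with FIFO tie-breaking and
  seeds pushed in label order, so equal-elevation contests resolve to the
  lowest label, reproducibly.
* TIFF I/O is a deliberately minimal uncompressed baseline codec
  (grayscale, 8/16-bit, little/big-endian read, little-endian write)
  because no TIFF library ships with the supporting stack; it is
  round-trip tested and its files are plain baseline TIFF readable by
  standard tools.

## Known limitations

Segmentation is classical (no learned models, no deconvolution); heavily
overlapping vesicles are out of the placement model's scope by default;
spatial plate effects (edge effects, gradients) are neither simulated nor
corrected, matching the analysis being emulated; and the proteomics module
starts from protein-level tables — peptide-level search and quantification
are upstream and out of scope.
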