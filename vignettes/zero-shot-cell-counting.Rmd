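---
title: "Zero-shot cell counting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot cell counting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorcount)
```

## The problem and the model

Counting fluorescently labeled cells is a routine quantification step in
immunocytochemistry, but manual counts are slow and irreproducible, and
supervised counting models need labeled data that many labs cannot afford
to produce. `fluorcount` implements an annotation-free alternative: treat
counting as *prompt-free instance segmentation followed by centroid
extraction*. No stage is trained on the target data; segmentation quality
comes either from a classical thresholding backend or from a pre-trained
foundation segmenter accessed through an adapter.

The pipeline is `image -> CLAHE -> mask set -> centroids -> count`, and
every stage is a pure function of its inputs and a configuration object,
which is what makes the end-to-end runs byte-reproducible.

## Illumination correction

Fluorescence images are typically unevenly illuminated, which defeats any
global threshold. The preprocessing stage is contrast-limited adaptive
histogram equalization (CLAHE), implemented in R from its defining
equations rather than delegated to an external library, because its exact
arithmetic is part of this package's contract and is verified against an
independent per-pixel reference implementation in the test suite.

The image is divided into non-overlapping square tiles (`tile_size = 8`
pixels by default, i.e. 64-pixel neighborhoods). For each tile with
histogram $H(i)$ over $L = 256$ levels, bins are capped at

$$\beta = \max\!\left(1,\; c \cdot n_\text{tile} / L\right)$$

with clip factor $c \in (0, 1]$ (default $0.8$), and the clipped excess is
redistributed uniformly — $E/L$ added to every bin in a single real-valued
pass, which preserves the histogram sum exactly. The cumulative
probability distribution

$$P(f) = \frac{\sum_{i=0}^{f} H(i)}{\sum_{i=0}^{L-1} H(i)}$$

maps each level to the output intensity
$p = (p_\max - p_\min)\,P(f) + g_\min$. Each pixel's output value is the
bilinear blend of the mappings of the four tiles whose *centers* surround
it; pixels outside the outermost tile centers clamp to the nearest tile
row/column. The blended value is rounded half-up and clamped to
$[g_\min, p_\max]$.

Design choices where conventions genuinely diverge:

* **Clip normalization.** Implementations disagree on what the clip factor
  multiplies. We use the normalized convention
  $\beta = \max(1, c \, n_\text{tile}/L)$, under which $c = 1$ caps every
  bin at the height of a perfectly uniform tile histogram; $c$ is exposed
  in the configuration so other conventions can be emulated by rescaling.
* **Redistribution.** Single-pass uniform redistribution, no re-clipping
  iteration. Because the mapping normalizes by the histogram sum, sum
  preservation is the only property downstream arithmetic relies on.
* **Tile anchors.** Interpolation anchors are tile centers with edge
  clamping — the classical rule; anchoring at tile corners would shift
  every mapping by half a tile.
* **Non-divisible sizes.** The image is symmetric-reflect-padded on the
  bottom and right to tile multiples and cropped after remapping, so
  output dimensions always equal input dimensions.
* **Rounding.** Half-up (not banker's rounding), then clamping; this makes
  the integer output independent of platform rounding mode.

## Mask extraction: a contract, two backends

The segmentation stage is deliberately specified as a *contract* rather
than a model: a backend maps an image to an area-descending list of
binary masks in which the first (largest) mask is the background
candidate. Nothing in the interface accepts points, boxes, or other
prompts, so the pipeline is automation-safe by construction.

* The **reference backend** is classical and self-contained: Otsu
  threshold (polarity chosen so the foreground is the minority class),
  8-connected component labeling, a `min_area` speckle filter, and the
  complement of the components as the background mask. It exists so that
  the full pipeline can run and be tested offline, and as an honest
  classical baseline.
* The **adapter backend** wraps a pre-trained automatic mask generator
  (e.g. the Segment Anything Model run promptlessly). The heavyweight
  model is an optional runtime dependency: the adapter takes either a
  checkpoint path or an injectable generator function, reshapes whatever
  the generator emits to the contract (area sort; background synthesized
  as the complement of the union when absent), and raises a capability
  error naming the missing dependency otherwise. Overlapping masks are
  retained — the counting algorithm iterates all masks, and deduplication
  would silently change its semantics.

## Counting

For each non-background mask $m_i$, the bounding box of its nonzero
pixels is $x_i = \min x$, $y_i = \min y$, $w_i = \max x - x_i$,
$h_i = \max y - y_i$, and the cell's center is
$(x_i + w_i/2,\; y_i + h_i/2)$. The count is the number of centers.

Note the width convention is max-minus-min, not max-minus-min-plus-one: a
single-pixel mask has $w = h = 0$ and its center is the pixel itself.
Centers therefore sit on the midpoint of occupied pixel *indices*, half a
pixel off the area centroid of the box. This off-by-half has no effect on
counts and is kept for fidelity to the counting algorithm as specified;
coordinates are 0-based with $x$ the column and $y$ the row index.

One mask is one cell: merged or overlapping cells inside a single mask are
counted once. This is the method's main known failure mode at high
density (see Limitations).

## Evaluation metrics

With true counts $C_i$ and predictions $\hat C_i$ over $N$ images:

$$\mathrm{MAE} = \frac{1}{N}\sum_i |C_i - \hat C_i|, \qquad
\mathrm{AAE} = \frac{100}{N}\sum_i [\![\,|C_i - \hat C_i| \le T\,]\!]$$

The acceptance band is inclusive at $|C - \hat C| = T$, with $T = 10$
cells by default — a tolerance at the scale a domain expert would accept
for a manual recount. Reports are stratified by density with the boundary
*inclusive* on the low side (true count $\le 100$ is low density), and an
empty stratum is omitted rather than reported as zero. Full precision is
kept in machine output; rounding is for display only.

## The synthetic generator

The generator exists so that every pipeline stage has exact ground truth
without downloading data. Three named profiles emulate the *statistics* of
public cell-counting benchmarks — image size, per-image count mean ± sd,
background polarity, and illumination unevenness:

| profile | size (px) | counts | background |
|---|---|---|---|
| `idcia_like` | 800 × 600 | 83 ± 104 | dark, uneven illumination |
| `vgg_like` | 256 × 256 | 174 ± 64 | dark, small bright blobs |
| `adc_like` | 500 × 500 | 165 ± 44 | bright field, darker cell rims |

Per-image counts are drawn from a **lognormal** distribution
moment-matched to the profile ($\sigma^2_{\log} = \log(1 + s^2/m^2)$,
$\mu_{\log} = \log m - \sigma^2_{\log}/2$), rounded and floored at 1. A
truncated normal cannot carry these moments when the sd exceeds the mean
(83 ± 104), while the lognormal holds them essentially exactly: the floor
at 1 affects a mass of order $10^{-5}$ for the heaviest-tailed profile.

Cells are placed by rejection sampling with a minimum center separation
(budget $10n$ attempts; when placement is infeasible the image holds fewer
cells, the truth records the actual number, and a warning is raised). Each
cell is a Gaussian-shaded disk whose radius equals the shading's half-width
at half-maximum, so on a clean background the disk rim renders at half the
peak intensity and a histogram threshold falls in the wide gap between
background and cell — on noise-free renders the reference backend recovers
the rendered disks pixel-exactly, which the tests assert. The bright-field
mode instead renders a slightly-darker interior with a distinctly dark rim
on a bright background. Illumination unevenness is a smooth sinusoidal
field with random orientation; noise is i.i.d. Gaussian, clamped to
[0, 255].

Determinism: each image's RNG stream is derived from (profile seed, image
index) and applied through a helper that saves and restores the session's
RNG state, so datasets are reproducible image-by-image and generation
never perturbs a user's random numbers.

**What passing tests do and do not show.** The profiles reproduce count
statistics, background polarity, size scales, and illumination
unevenness. They do not simulate antibody-specific staining variability,
z-stack defocus, cell-shape irregularity, clustering of real cell
positions (placement is uniform with a separation floor), or histology
texture. Exact recovery on clean renders validates the *pipeline
algebra* — segmentation-to-count wiring, centroid math, metric
computation — not real-world segmentation accuracy, which is entirely a
property of the chosen backend.

## Problem sizes used in validation

The package's own validation uses: 100 random images up to 32 × 32 for
the CLAHE-versus-reference equivalence; 1,000 random masks for the
bounding-box algebra; 50 clean 128 × 128 synthetic images (~8 cells each)
for exact end-to-end recovery (MAE 0, AAE 100); and 2,000 seeded count
draws per profile for moment recovery within three standard errors. These
sizes give the properties room to fail while keeping the suite quick to
run anywhere.

## Limitations

* The reference backend cannot split touching cells and, on noisy images,
  equalization amplifies background noise until Otsu fragments it; the
  `min_area` filter mitigates speckle but the classical backend is
  honest only at low noise. Quantitative counting on hard real images
  should use the adapter with a pre-trained mask generator.
* One-mask-one-cell counting under-counts overlapping cells and
  over-counts when a backend emits duplicate masks for one cell; an
  optional IoU deduplication was considered and rejected by default to
  keep counting semantics faithful to the mask set.
* The clip-factor convention ($\beta = \max(1, c\,n_\text{tile}/L)$) is
  one of several in circulation; comparisons with other CLAHE
  implementations must normalize conventions first.
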