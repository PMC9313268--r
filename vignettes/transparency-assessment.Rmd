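---
title: "Quantifying tissue transparency: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue transparency: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticlear)
```

## The measurement model

Optical clearing protocols are judged by how transparent they render tissue.
`opticlear` quantifies transparency with a bright-field transmission
measurement: a blank exposure $I_0(x,y)$ (illumination only) and a sample
exposure $I(x,y)$ are acquired with the same optics, and the Beer–Lambert law

$$ I = I_0\, e^{-\mu L} $$

links them through the attenuation coefficient $\mu$ (mm$^{-1}$) and the
light-path length $L$ (mm, the sample thickness). Inverting on a region $R$,

$$ \hat\mu_R = \frac{1}{L}\,
   \ln\!\frac{\overline{I_0}\big|_R}{\overline{I}\big|_R}, $$

with $\overline{\,\cdot\,}|_R$ the region mean. Two conventions deserve
explicit mention:

* **Sign/orientation.** The inverse formula is sometimes written with the
  ratio the other way up, $\ln(I/I_0)/L$, which is negative for any absorbing
  sample. `opticlear` uses $\ln(I_0/I)/L$, the form consistent with the
  forward equation above and with the reading that a *higher* attenuation
  coefficient means a *more opaque* sample. Both readings appear in the
  literature; only the sign differs.
* **Ratio of means, not mean of ratios.** $\hat\mu_R$ takes one logarithm of
  the ratio of region means rather than averaging per-pixel logarithms. This
  matches a bulk measurement of light transmitted through the patch and stays
  well-defined when individual dark pixels approach (or, with read noise,
  cross) zero.

This is an *absorption-style* summary statistic: scattering, refraction and
autofluorescence are all folded into $\mu$. The package makes no attempt at
physically rigorous light transport — the measurement model, not tissue
physics, is what is being implemented.

## The region-sampling protocol

One value of $\hat\mu_R$ from one region would be hostage to local tissue
heterogeneity and illumination structure. The protocol therefore resamples:

| parameter | default | meaning |
|---|---|---|
| `regions_per_run` | 3 | random regions drawn per run |
| `runs_per_image` | 15 | independent runs per image |
| images per sample | 3 | separate acquisitions of the same sample |
| `region_fraction` | 0.15 | region side = 15 % of each image dimension |
| `fraction_mode` | `"linear"` | see below |

yielding $3 \times 15 \times 3 = 135$ individual measurements per sample,
collapsed to mean ± SEM (`run_protocol()`). Protocol conventions, fixed here
because the protocol's verbal description leaves them open:

* **"15 % of the full image size"** is read as 15 % of each *linear*
  dimension (a $0.15H \times 0.15W$ region, aspect-matched to the image). The
  area reading — side $= \sqrt{0.15}$ of each dimension — is available as
  `fraction_mode = "area"`.
* **Rounding:** region sides use half-up rounding with a 1 px floor, so a
  10 px dimension at 0.15 gives 2 px.
* **Placement:** origins are uniform over all valid placements; regions *may*
  overlap, within and across runs. Coordinates are 0-based, row-major,
  origin top-left, half-open extents.
* **Spatial correspondence:** the same pixel coordinates are read from $I_0$
  and $I$, because the blank is a position-dependent illumination field
  (vignetting) rather than a scalar.
* **Degenerate regions:** a region whose mean intensity does not exceed
  $\varepsilon = 10^{-6}$ detector units is discarded and redrawn (up to 10
  attempts) rather than yielding $\pm\infty$. The guard is applied to region
  *means*, not per pixel: flooring individual pixels would bias the mean of
  noisy dark regions upward exactly like clipping (next section).
* **$\hat\mu$ is not clipped at zero.** Noisy near-transparent regions can
  produce slightly negative estimates; keeping them preserves unbiased
  averaging.
* **SEM convention:** sample standard deviation ($n-1$ denominator) over
  $\sqrt{n}$; defined as 0 when $n = 1$.
* **RNG:** one seed drives the whole protocol; each image consumes a
  substream derived by a fixed offset, so appending an image never changes
  the regions drawn on earlier images. All generators are bit-reproducible
  given their seed.

## The synthetic phantoms, and what a green test establishes

No raw imagery accompanies the protocol this package implements, so
validation rests on phantoms whose ground truth is known exactly.

**Transmittance pairs** (`generate_transmittance_pair()`): blank =
`illumination` × a radially symmetric cosine-fourth vignette (strength 0.15
by default — a typical bright-field falloff; 0 at the center, full at the
corners); sample = blank × $e^{-\mu L}$ inside an optional tissue mask.
Defaults are fixed once: 512 × 512 px (no acquisition resolution is
prescribed by the protocol; this is a realistic working size), illumination
200 detector units, Gaussian read noise with sd = 2 % of illumination in the
standard noisy configuration.

Noise is applied *independently to the two exposures* (they are two separate
acquisitions) and Gaussian noise is deliberately **not clipped at zero**: it
models zero-mean read noise after camera offset subtraction. Clipping would
bias region means of dark samples upward — for a sample signal far below the
noise floor, $E[\max(0, X)] \approx \sigma\sqrt{2/\pi} \gg E[X]$ — and would
make attenuation recovery at high $\mu L$ impossible for *any* estimator.
With unclipped noise, region means are unbiased and the protocol recovers
$\mu_{\text{true}}$ within 5 % for $\mu L \in [0.1, 6]$ at the default noise
level (exactly, to $10^{-9}$ relative, without noise). Shot-noise
(`noise_poisson()`) phantoms are nonnegative by construction.

**Fluorescence stacks** (`generate_fluorescence_stack()`): Gaussian nuclei
blobs and straight tubes (vessels) over a constant `background` (default 0;
set ~100 to emulate camera offset + autofluorescence), corrupted by a
multiplicative sinusoidal stripe pattern constant along the illumination
axis and by salt-and-pepper impulses. Impulse corruption replaces an *exact*
count, `round(fraction × n_voxels)` voxels chosen without replacement (half
set to 0, half to the stack maximum), so tests have deterministic counts;
the clean stack and the corrupted indices are retained.

What the phantoms do **not** emulate: scattering and refractive-index
mismatch (the dominant physical effects clearing actually removes), spatial
tissue heterogeneity, depth-dependent light-sheet broadening, detector
nonlinearity, or realistic stripe shadows (which are broadband, not a single
sinusoid). A green recovery test therefore establishes that the *estimator
chain is correct under its own measurement model* — not that the model
captures everything in real cleared-tissue images.

## Group comparison

`compare_conditions()` reproduces the statistics such comparisons are
reported with: per-condition mean ± SEM, one-way fixed-effects ANOVA
($F = MS_{\text{between}}/MS_{\text{within}}$ on $(k-1, N-k)$ df), and
two-sided pairwise post-tests using the pooled $MS_{\text{within}}$ with
p-values multiplied by the number of pairs and capped at 1 (the classic
Bonferroni post-test; independent Welch tests via `pooled = FALSE`).

The unit of replication is a genuine design choice: region-level
measurements from one sample are not independent replicates. The default
`unit = "sample"` aggregates to per-sample means whenever every condition
has ≥ 2 samples, and otherwise falls back to measurement level with an
explicit pseudo-replication warning. Published figures in this area
typically report only "p < 0.001", so numeric equivalence to any particular
experiment cannot be checked; the package's acceptance pipeline instead
re-creates a three-condition experiment (true $\mu$ = 4.0 / 1.5 / 0.5
mm$^{-1}$, $L$ = 2 mm, 3 samples × 3 images) and verifies that every
Bonferroni-adjusted pairwise p-value falls below 0.001.

## Stack processing chain

The visualization chain applies, in order: **3 × 3 median filter** (per
z-plane, reflection padding — removes salt-and-pepper noise), **stripe
removal**, and **linear contrast adjustment** (affine map of the stack-wide
`low`/`high` percentiles, default (1, 99.8), to $[0, \texttt{max\_out}]$
with clipping; percentiles are stack-wide so the adjustment is consistent
across z).

Proprietary destriping tools used in light-sheet practice are unpublished,
so `remove_stripes()` is a documented stand-in from the same artifact class:
a directional Fourier notch. Stripes constant along the illumination axis
concentrate spectral energy on the line of zero frequency along that axis;
the filter attenuates coefficients near that line with a Gaussian taper
(`notch_width` bins, factor `damping`), leaves DC untouched, clips the
inverse transform at zero, and rescales each plane to restore its mean
exactly — clipping of ringing around bright structures would otherwise bias
the mean upward by up to ~0.5 % on content-dense planes. With `damping = 1`
the operator is idempotent whenever clipping is inactive. The notch also
removes genuine image content that is constant along the stripe axis within
a plane; that is the price of any destriper of this family, and `damping`
exists to moderate it.

## Numerical and I/O choices

* Intensities are floating point in memory end to end; integer file exports
  quantize with a recorded scale (16-bit default), and reading restores
  detector units to within half a quantization step.
* The TIFF support is a built-in baseline codec (little-endian,
  uncompressed, gray/RGB, 8/16-bit integer and 32-bit float, multi-page)
  because no TIFF package is available in the target R environment; it was
  cross-validated in both directions against an independent Python TIFF
  implementation. NRRD export (raw encoding, x-fastest as the format
  prescribes) carries voxel spacing for 3-D viewers; RGB inputs collapse to
  Rec. 601 luminance.
* ANOVA and the post-tests are computed from explicit sum-of-squares
  decompositions and are tested to $10^{-10}$ relative agreement against R's
  reference linear-model ANOVA, plus a Kolmogorov–Smirnov uniformity check
  of the null p-value distribution.

## Known limitations

* $\mu$ summarizes all attenuation mechanisms; comparisons across samples
  assume comparable illumination geometry and thickness measurement.
* At $\mu L \gtrsim 6$ with the default noise level the transmitted signal
  sits near the noise floor; individual region estimates become heavy-tailed
  (degenerate-region resampling keeps them finite but introduces selection
  at the extreme), and the 5 % recovery guarantee no longer applies —
  condition *ordering* remains reliable far beyond that point.
* The destriper is a stand-in, not a reconstruction of any proprietary
  algorithm; per-channel application (stripes often affect only the shorter
  wavelength channel) is left to the caller / CLI flags.
* No per-pixel $\mu$ maps, no mixed-effects modeling of the
  region/run/image hierarchy, no interactive 3-D rendering (files are
  exported for external viewers).
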