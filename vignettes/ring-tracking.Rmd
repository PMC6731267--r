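---
title: "Classifying nuclear γH2AX distributions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying nuclear γH2AX distributions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringtrack)
```

## The measurement problem

Phosphorylated H2AX (γH2AX) is the standard imaging marker of DNA-damage
signalling. In most damage contexts it appears as discrete sub-nuclear
foci, but some genotoxins instead drive γH2AX into a contiguous ring at
the nuclear periphery. Distinguishing foci, rings and uniform staining by
eye does not scale to screening experiments with hundreds of cells per
field, and the two patterns respond differently to treatment, so the
population proportions are the quantity of interest. `ringtrack`
implements an automated per-nucleus classifier for 2-D widefield images
(~20× objective): a DAPI channel for segmentation, a γH2AX channel for
phenotype, optionally 53BP1 for colocalization.

## Segmentation model

Nuclei are detected solely from DAPI. The steps, in order:

1. **Gaussian smoothing** (`gaussian_sigma_px`, default 2 px). Implemented
   as separable convolution with a kernel truncated at 3σ and normalised
   to unit mass, with symmetric (reflective) boundary padding — so a
   constant image stays constant and total intensity is conserved, which
   makes the subsequent threshold comparable across fields.
2. **Automatic global threshold.** Exhaustive between-class-variance
   maximisation (Otsu's criterion) on a 256-bin histogram spanning the
   image's own intensity range. Spanning the observed range rather than
   the nominal bit-depth range makes the partition exactly invariant to
   intensity scaling, which is a tested property of the pipeline. When the
   optimum is a plateau (well-separated bimodal histograms), the central
   candidate is taken. Foreground is *strictly above* the threshold, and
   the value is written to the provenance log. A constant image has no
   threshold and raises a degenerate-input error.
3. **Morphological refinement**: `n_dilations` (2) disc dilations
   (`struct_radius_px` = 3), hole filling, `n_erosions` (2) erosions —
   a closing that bridges staining gaps, plus hole filling for
   nucleoli-like voids. Counts and radius are exposed parameters: they are
   acquisition-dependent choices, fixed once per experiment.
4. **8-connected labelling** in row-major scan order. 8-connectivity is
   the conventional choice for blob-like objects; it is also what the
   boundary definition (member pixel with any 8-neighbour outside the
   object) assumes.
5. **Object filters.** Area > 400 px², eccentricity < 0.8, circularity
   4πA/P² > 0.85, and mean DAPI < 2× the median of mean-DAPI over *all*
   candidates of the field. All four are strict inequalities, and the
   median is computed once before any rejection, so the accepted set does
   not depend on candidate order. The first failed rule (in the order
   area, eccentricity, regularity, intensity) is recorded per object. The
   intensity rule removes mitotic/apoptotic debris and saturated clumps;
   it is a *relative* rule and hence scale-invariant like the threshold.

Two measurement conventions matter for the filters. Eccentricity is that
of the ellipse matching the object's second central moments. The
perimeter uses the weighted boundary-configuration estimator
(Vossepoel–Smeulders): border pixels contribute 1, √2 or (1+√2)/2
according to their local contour direction. A naive count of boundary
pixels would understate the perimeter of diagonal contours and inflate
circularity; with the weighted estimator a digital disc of radius 30
measures circularity ≈ 0.92, comfortably above the 0.85 cutoff, while
fragmented debris falls well below it.

A printed form of the regularity rule circulating for this method,
`4·Area²/Perimeter > 0.85`, is dimensionally inconsistent (it grows with
object size, so a fixed 0.85 cutoff cannot act on it); the package
implements the standard dimensionless circularity `4π·Area/Perimeter²`,
whose value is bounded near 1 for discs and matches the scale of the
cutoff. Objects touching the image border are kept by default
(`exclude_border = FALSE` in `seg_params()`), since partial nuclei at the
border still receive well-defined calls; the flag exists for stricter
protocols.

## Phenotype model

The call is a two-stage decision, foci first:

**Foci rule.** Within each nucleus the γH2AX image is binarised with an
adaptive threshold built from local first-order statistics: pixel *p* is
a focus candidate iff `I(p) > (1 + α) · mean(window(p) ∩ nucleus)`, with
α = `adaptive_rel_offset` (0.15) and a `adaptive_window_px` (15 px,
odd) square window clipped to nucleus pixels. Using the *mean* as the
local statistic and a *multiplicative* offset keeps the rule
scale-invariant and robust to high diffuse background — the local mean
rises with background, so only locally contrasted puncta survive.
Candidate components (8-connected) of at least `min_focus_area_px`
(4 px) count as foci; the area floor suppresses single-pixel shot noise.
A nucleus is **FOCI** when `foci_count / area_px > 0.0035` (strict). The
cutoff is in foci per px² at ~20× sampling; at other magnifications it
must be rescaled, which is why it is a parameter
(`foci_density_cutoff`).

**Ring rule.** For non-foci nuclei, a profile of γH2AX intensity is cast
from the centre of mass to *every* boundary pixel (one ray each),
sampled at ≈1 px steps with bilinear interpolation, endpoints included.
Rays are linearly resampled to the longest ray's sample count L and
averaged pointwise into a single radial profile. With the radial axis
split at ⌊0.75·L⌋, the nucleus is **RING** when

&nbsp;&nbsp;&nbsp;&nbsp;`mean(profile[⌊0.75L⌋+1 .. L]) − mean(profile[1 .. ⌊0.75L⌋]) > 0.10 × mean(profile)`

strictly, with the signed difference — a bright centre can never be a
ring. Otherwise the nucleus is **UNIFORM**. "Last quartile" here is the
outermost 25 % of the normalised radial axis, the only reading under
which a peripheral band maps onto a fixed profile segment regardless of
nucleus size. If the averaged profile is identically zero the nucleus is
reported UNIFORM with a QC flag rather than failing the field. For a
strongly concave object whose centroid falls outside the mask, the
nearest interior pixel is used as the ray origin.

Running the foci test first makes the two marked phenotypes mutually
exclusive: a nucleus dense with bright peripheral foci is FOCI, never
RING. Both rules are intensity ratios, so every call is invariant to
multiplying the γH2AX channel by any positive constant — verified in the
tests for factors 0.5, 3 and 10.

**Colocalization.** When a 53BP1 channel is present, the Pearson
product-moment correlation between γH2AX and 53BP1 is computed over each
nucleus's member pixels, on raw intensities (no background subtraction).
"Correlation coefficient" is read as product-moment; rank or
overlap-based coefficients (Spearman, Manders) are out of scope. The
coefficient is reported as undefined — flagged, not an error — for
nuclei under 10 px or with a constant channel. It is computed for every
accepted nucleus and can be filtered downstream; canonical repair foci
give r near 1, while peripheral rings do not co-recruit 53BP1.

## The phantom generator

`generate_field()` renders what the classifier is supposed to see:
non-overlapping elliptical nuclei (semi-axes 18–45 px, i.e. areas
~600–6400 px², matching 20× widefield scale), a flat DAPI interior, and
one of three γH2AX patterns per nucleus — flat base (UNIFORM), base plus
Gaussian puncta (FOCI), or base amplified by `ring_amplitude_ratio`
(2.0) in the outer `ring_band_fraction` (0.25) of the elliptical radial
coordinate (RING). Noise is shot (Poisson at the pixel mean) plus
additive Gaussian read noise, then clipping to the bit-depth range.
Intensities default to a 16-bit scale (DAPI and γH2AX base 10 000,
focus peaks +30 000); the reference noise condition used in the
acceptance tests is Poisson plus Gaussian read noise with sd = 500,
i.e. 5 % of the DAPI level.

Design choices that keep the generator honest as a test instrument:

* **Construction soundness.** Both classification rules hold
  *analytically* before noise: a RING nucleus's radial profile is `base`
  over the first three quartiles and `2×base` over the last, giving a
  peripheral excess of 0.8× the overall mean (threshold: 0.1); FOCI
  nuclei get a per-nucleus focus count drawn uniformly from
  [1.3, 1.7] × 0.0035 × area, so the placed density exceeds the cutoff
  with margin at every permitted nucleus size. A fixed count range is
  also supported (`foci_per_nucleus_range`), but is not the default: any
  single range that guarantees the density cutoff in the largest
  permitted nucleus (≥ ~23 foci) cannot be placed without merging in the
  smallest (~640 px²), which would silently break the ground truth.
* **Shape margins.** The axis-ratio cap defaults to 1.4. Eccentricity
  < 0.8 requires ratio < 1.67 in the continuum, but digitised ellipses
  near that bound measure circularity ≈ 0.86 — inside the filter's noise
  band — so the default keeps phantom eccentricity ≤ ~0.70 and digital
  circularity ≥ ~0.90. Segmentation rejections in recovery tests are
  therefore bugs, not fixtures; filter behaviour itself is tested with
  deliberately constructed boundary objects instead.
* **Placement margins.** Nucleus gaps exceed 16 px: two dilation passes
  with a radius-3 disc reach 12 px, and closer phantoms would merge
  during refinement into a single (rejected) object.
* **Foci spacing.** Focus centres keep ≥ 7.5 px apart and ≥ 15 % of the
  radial coordinate away from the rim, so adaptively detected components
  (radius ~3 px at the default σ = 1.5, amplitude 3× base) stay
  separate and inside the nucleus.
* **Determinism.** All randomness derives from `spec$seed` through a
  local RNG scope; identical specs give bit-identical images and truth
  tables, and the pipeline itself is deterministic, so reruns produce
  byte-identical CSVs.

What the phantom does *not* emulate: chromatin texture, uneven
illumination, optical PSF blur, touching/overlapping nuclei, apoptotic
morphologies, z-structure. Passing the recovery tests therefore
demonstrates that the implementation applies the stated rules correctly
and robustly to noise — not that the rule thresholds are optimal for any
particular microscope; on real data the empirical cutoffs may need
recalibration, which is why every one of them is a parameter.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based (row, col), origin top-left, everywhere
  in the API and output tables.
* Gaussian kernels are truncated at 3σ and renormalised; smoothing and
  its direct-convolution oracle agree to 1e-6.
* The Otsu search, ray resampling and Pearson correlation are each tested
  against independent brute-force oracles (exhaustive histogram split,
  dense linear interpolation, naive two-pass sums).
* Ray sampling uses ⌈len⌉+1 evenly spaced points per ray (spacing ≤ 1 px,
  endpoints preserved); the averaged profile of an analytic cone field
  `I(r) = r/R` on a digital disc matches the closed form to < 1 % RMS for
  R ≥ 20 (tested bound: 2 %).
* Degenerate inputs are classed conditions, not crashes: constant DAPI
  (no threshold), empty candidate list, sub-3×3 nuclei, all-boundary
  objects, zero-signal profiles, constant colocalization channels.
* The per-nucleus CSV has a fixed 17-column schema sorted by
  (`field_id`, `nucleus_id`); summaries are exact integer counts, so the
  summary CSV is re-derivable from the per-nucleus CSV.

## Problem sizes used in validation

The validation suite runs entirely on generated data: a 1024×1024,
60-nucleus field (20 per phenotype) noise-free and under the reference
noise model for end-to-end recovery; 512×512, 12–15-nucleus fields for
the invariance and determinism properties; 100 random 16×16 masks for
the labelling oracle; and discs of radius 20–32 for radial-profile
fidelity. One 1024×1024 field takes a few seconds end to end on a single
CPU.

## Known limitations

Touching nuclei are not split (no watershed); they merge into one object
that the eccentricity/circularity filters usually reject, costing
sensitivity in crowded fields. The foci-density and ring thresholds are
magnification-bound empirical constants. The radial quartile rule assumes
roughly star-convex nuclei; for strongly lobed nuclei rays cross
background and the profile tail underestimates the periphery. The 53BP1
correlation is Pearson on raw intensities and therefore sensitive to
shared background gradients.
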