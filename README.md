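# ringtrack

High-content image analysis of nuclear DNA-damage phenotypes in 2-D
fluorescence microscopy. Some genotoxic insults do not produce the
canonical punctate γH2AX foci but instead concentrate γH2AX in a ring at
the nuclear periphery. `ringtrack` automates the population-scale readout
of that distinction: it segments nuclei from the DAPI channel, classifies
every nucleus's γH2AX distribution as **FOCI**, **RING** or **UNIFORM**,
optionally correlates γH2AX with 53BP1 per nucleus, and reports phenotype
proportions per field and condition. It is aimed at widefield screens at
~20× magnification where hundreds of cells per field must be scored
reproducibly and without manual annotation.

## Method

**Segmentation (DAPI).** The DAPI image is smoothed with a 2-D Gaussian
kernel (σ = 2 px by default), binarised at a globally automatic threshold
(exhaustive between-class-variance maximisation over a 256-bin histogram,
i.e. Otsu's criterion; the threshold is recorded in the provenance log),
and refined by dilation, hole filling and erosion with a disc structuring
element. 8-connected objects are then filtered by four rules, all strict
inequalities:

| filter | keep when | default |
|---|---|---|
| area | A > A_min | A_min = 400 px² |
| eccentricity | e < e_max (moment-matched ellipse) | e_max = 0.8 |
| circularity | 4πA/P² > c_min | c_min = 0.85 |
| intensity | mean DAPI < k · median(mean DAPI over all candidates) | k = 2 |

**Phenotype call (γH2AX), per accepted nucleus.**

1. *Foci rule.* The γH2AX signal is binarised with an adaptive local-mean
   threshold (pixel is a candidate when brighter than (1 + α) × the mean
   over a window clipped to the nucleus; α = 0.15, window 15 px). Foci are
   8-connected components of at least 4 px. If
   `foci_count / area > 0.0035` px⁻², the nucleus is **FOCI**.
2. *Ring rule.* Otherwise, intensity profiles are cast from the centre of
   mass to every boundary pixel, resampled to the longest ray's length and
   averaged. With the radial axis split at ⌊0.75·L⌋, the nucleus is
   **RING** when `mean(last quartile) − mean(first three quartiles)
   > 0.10 × overall mean` — the periphery must be *brighter*; otherwise
   it is **UNIFORM**.

Because the foci test runs first, FOCI and RING are mutually exclusive by
construction. Both rules are ratios of intensities, so calls are invariant
to overall intensity scaling. When a 53BP1 channel is present the
pixelwise Pearson correlation with γH2AX is computed over each nucleus's
member pixels.

**Phantoms.** `phantom_spec()` / `generate_field()` render synthetic
fields — non-overlapping elliptical nuclei with FOCI / RING / UNIFORM
γH2AX patterns, optional 53BP1, and Poisson + Gaussian camera noise —
together with a per-nucleus ground-truth table, so the entire pipeline is
testable without microscope data.

## Worked example

```r
library(ringtrack)

spec <- phantom_spec(n_nuclei = 30, seed = 7,
                     noise_model = list(type = "poisson+gaussian", sd = 500))
g   <- generate_field(spec, condition = "demo")
res <- analyze_field(g$fov)

acc <- res$table[res$table$accepted, ]
table(acc$phenotype)
#>    FOCI    RING UNIFORM
#>      10      10      10

summarize_phenotypes(acc)$per_field
#>  condition field_id n_accepted n_foci n_ring n_uniform prop_foci prop_ring prop_uniform
#>       demo phantom1         30     10     10        10 0.3333333 0.3333333    0.3333333

head(acc[, c("nucleus_id", "area_px", "foci_count", "foci_density",
             "ring_score", "phenotype")], 5)
#>  nucleus_id area_px foci_count foci_density ring_score phenotype
#>           1    2029         11   0.00542139         NA      FOCI
#>           2    3890         23   0.00591260         NA      FOCI
#>           3    4244         24   0.00565504         NA      FOCI
#>           4    2052         11   0.00536062         NA      FOCI
#>           5    2383          1   0.00041964   0.736646      RING
```

All 30 phantom nuclei are accepted and each receives its ground-truth
phenotype despite the shot + read noise. `foci_density` is foci per px²
(FOCI when > 0.0035); `ring_score` is the peripheral excess relative to
the overall profile mean (RING when > 0.10). `run_pipeline()` writes the
per-nucleus CSV, per-field/per-condition summaries, 16-bit label-mask
TIFFs and a provenance log.

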