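# mpdfir

Detection and quantification of nylon microplastic (MP) particles from
optical photothermal infrared (O-PTIR) spectroscopy and discrete-frequency
infrared (DFIR) imaging.

## The problem

Particle-based microplastic counting on membrane filters is reliable when
every particle is chemically identified from a full infrared spectrum, but
that is far too slow for filters carrying many particles: each particle
needs several point spectra, and hyperspectral imaging of even one
480 µm × 640 µm region takes days to weeks. DFIR imaging — acquiring
intensity images at only a few informative wavenumbers — restores
throughput, provided two questions are answered well:

1. **Which wavenumbers?** `mpdfir` trains a full-spectrum linear
   support-vector machine (SVM) on a labelled MP / non-MP spectral library
   and reads wavenumber importance directly off the coefficient vector: for
   a linear decision function *f*(x) = **w**·x + *b*, the importance of
   wavenumber *j* is |w_j|. The top *k* = 4 wavenumbers (subject to a
   ≥ 20 cm⁻¹ pairwise separation) become the DFIR acquisition channels.
2. **How to classify pixels?** A reduced linear SVM is trained on the
   selected wavenumbers (features SNV-normalized across the selected
   values, exactly what an imaged pixel can provide) and applied to every
   masked pixel; each segmented particle is then called MP or non-MP by
   majority vote of its pixels, with ties conservatively to non-MP.

Around this core the package provides the standard spectroscopy
preprocessing chain (standard normal variate, Savitzky–Golay smoothing,
asymmetric-least-squares baseline correction, min–max normalization), a
Pearson-correlation identification rule for sparse regions (MP if any of
three spot-spectrum correlations against the parent plastic exceeds 0.7;
manual review in [0.6, 0.7]; non-MP below), regionprops-style particle
morphometry (area, moment-equivalent ellipse axes, circularity
4πA/P² with a weighted contour-length perimeter), and whole-filter
quantification: counts in nine subsampled 480 µm × 640 µm regions are
extrapolated by the coverage fraction (0.880 % for a 20 mm active
diameter) and normalized per released unit, with classification metrics
(sensitivity, specificity, CCR, Matthews correlation coefficient) and
confusion-matrix reconstruction utilities for validating against published
summary tables.

A seeded synthetic-data module generates class-structured spectra
(nylon amide I/II bands at 1635/1541 cm⁻¹; sharp-carbonyl and
broad-band non-MP classes), DFIR particle scenes with ground truth, and
whole-filter experiments, so the entire pipeline is testable without
instrument data. The intended users are spectroscopists and environmental
analytical chemists building or validating particle-based MP counting
workflows.

## Worked example

```r
library(mpdfir)

# 1. a labelled spectral library (synthetic, seeded)
library_set <- gen_spectra_set(n_mp = 600, n_nonmp = 600, seed = 1)
#> <spectra_set> 1200 spectra x 517 wavenumbers (MP=600, NON_MP=600)

# 2. develop the models: split, train full SVM, select wavenumbers, retrain
run <- run_train_select(library_set, seed = 1)
sort(run$selected_wavenumbers)
#> [1] 1075 1543 1635 1741
run$metrics_reduced
#> <class_metrics> sensitivity 1.0000, specificity 1.0000, CCR 100.00%, MCC 1.0000
```

The selected channels sit on the planted class-contrast bands: the nylon
amide pair (1635, 1541 cm⁻¹), the carbonyl band of the sharp-band non-MP
class (1740 cm⁻¹) and the broad-band non-MP centre (1077 cm⁻¹), each
recovered to within a few grid steps. On this cleanly separable synthetic
library both models classify the held-out third perfectly; on real
libraries the reduced model's metrics are what decides whether four
channels suffice.

```r
# 3. apply to a DFIR image stack of one subsampled region
scene <- gen_scene(n_particles = 12, wavenumbers = run$selected_wavenumbers,
                   seed = 2)
result <- run_classify_image(scene$stack, scene$mask, run$reduced_model)
head(result$particles[, c("id", "class", "mp_vote_fraction", "area_um2",
                          "length_um", "width_um", "circularity")], 4)
#>   id  class mp_vote_fraction area_um2 length_um  width_um circularity
#> 1  1 NON_MP                0     1392  47.02871 37.800694   0.9473787
#> 2  2 NON_MP                0      132  17.64630  9.748256   1.0000000
#> 3  3     MP                1     1780  48.05174 47.268390   0.9634851
#> 4  4     MP                1      376  29.44453 16.435046   0.9217140
mp_all_ratio(result$particles)
#> [1] 0.4166667
```

Each row is one segmented particle: its majority-vote class, the fraction
of its pixels voting MP, and its morphometry in physical units (2 µm
pixels). The MP/All ratio is the score used to compare contamination-
reduction treatments (`compare_treatments()` runs the paired or Welch
t-test).

```r
# 4. whole-filter quantification: counts -> filter total -> per teabag
round(100 * coverage_fraction(filter_layout()), 3)
#> [1] 0.88
per_unit(quant_estimate(319, 43.7), 3)
#> <quant_estimate> filter total 319.0 +/- 43.7
#>   per unit (n = 3): 106.3 +/- 14.6
```

A filter estimated to carry 319 ± 43.7 MP particles from steeping three
teabags corresponds to 106.3 ± 14.6 particles released per teabag.

A command-line front end wrapping the same functions ships in
`inst/cli/mp-dfir` (subcommands `simulate`, `train-select`,
`classify-image`, `identify`, `quantify`, `show-config`).

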