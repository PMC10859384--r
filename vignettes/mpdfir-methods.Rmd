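---
title: "Methods: microplastic detection from O-PTIR spectra and DFIR images"
author: "mpdfir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microplastic detection from O-PTIR spectra and DFIR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Counting microplastic (MP) particles on a membrane filter by infrared
microscopy faces a throughput wall. Full-range optical photothermal infrared
(O-PTIR) point spectra are reliable but slow — each particle needs several
25-second spectra — and hyperspectral imaging of even a single
480 µm × 640 µm region at 2 µm resolution is prohibitively slow. Discrete
frequency infrared (DFIR) imaging breaks the wall by acquiring intensity
images at only a handful of informative wavenumbers, at the price of needing
(i) a principled way to pick those wavenumbers and (ii) a classifier that
turns a few per-pixel intensities into a reliable MP / non-MP call.

`mpdfir` implements that workflow for the binary task *nylon MP vs.
everything else*, end to end:

1. **Development path** — preprocess a labelled library of full-range
   spectra, train a full-spectrum linear support-vector machine (SVM),
   read off coefficient-based wavenumber importance, select a small set of
   discriminative wavenumbers, and train a reduced SVM on them.
2. **Application path** — classify every masked pixel of a multi-channel
   DFIR stack with the reduced model, call each segmented particle by
   majority vote of its pixels, measure particle morphometry, and
   extrapolate subsampled counts to whole-filter and per-product (e.g.
   per-teabag) release figures.
3. A **correlation-based identification** path for sparse regions (fewer
   than ~5 particles), where full point spectra are compared to the parent
   plastic by Pearson correlation under a thresholded decision rule.

Everything runs on synthetic data with known ground truth, generated by the
package itself, so each stage is testable without instrument access.

# Spectra and preprocessing

Spectra live on an ascending wavenumber grid, by default 769–1801 cm⁻¹ at a
2 cm⁻¹ step (517 points), the tunable range of a QCL-based O-PTIR
instrument. File readers accept descending acquisition order and
canonicalize it, recording the original order in the metadata.

The preprocessing steps are standard chemometric operations; each is exposed
individually and as an ordered, serializable `preprocess_spec`:

* **SNV** (`snv`) — per-spectrum centring and scaling to unit sample
  standard deviation. Removes multiplicative scatter and additive offsets
  exactly: `snv(a*x + b) = snv(x)` for `a > 0`. It is the only
  normalization applied before discriminant training.
* **Savitzky–Golay smoothing** (`savgol_smooth`) — least-squares polynomial
  convolution with polynomial order 3 and 7 side points (15-point window)
  by default, the settings used for point-spectrum identification. Edges
  are handled by mirror-reflect padding, which preserves the spectrum
  length without extrapolating a trend; consequently the filter reproduces
  polynomials up to its order exactly in the interior but not in the outer
  `side_points` samples.
* **Baseline correction** (`baseline_als`) — asymmetric least squares:
  a baseline `z` minimizes `Σ w_i (y_i - z_i)² + λ Σ (Δ²z)²` with weights
  iteratively set to `p` above the fit and `1 - p` below it. Defaults
  `λ = 1e5`, `p = 0.01`, 10 iterations, all exposed. Commercial instrument
  software exposes only an opaque single-number baseline "strength"; ALS
  was chosen because it is standard, parameterizable and documented.
  Properties the tests pin down: a pure offset is removed essentially
  completely, a planted unit-height peak on a linear ramp is recovered
  within 10 %, an on-grid peak apex does not move, and a second application
  changes the result by well under 5 % of its range.
* **Min–max normalization** (`minmax_normalize`) — rescale to [0, 1],
  used before visual spectrum comparison.

Degenerate inputs (constant spectra) raise classed errors rather than
returning NaNs.

# Correlation-based identification

For a particle with three spot spectra, each spot is preprocessed
(default: smooth → baseline-correct → min–max) and correlated against the
identically preprocessed parent-plastic reference. The decision rule on the
three correlation coefficients is:

* any `r > 0.7` → **MP**;
* otherwise `max(r)` in `[0.6, 0.7]` → **MANUAL_REVIEW**;
* otherwise → **NON_MP**.

Both comparisons are strict inequalities, so an `r` of exactly 0.7 or 0.6
falls into the review band — the literal reading of a
"greater than 0.7 / smaller than 0.6" rule. The review band is encoded only
as a flag: the judgement it requests is human by definition. Fewer than
three spots are accepted with a warning, since small particles may not
offer three distinct measurement spots. The correlation can optionally be
restricted to the selected discriminative wavenumbers; the default is the
full grid, and both modes are provided because either is defensible for
sparse-region identification.

# The discriminant models

## Full-spectrum model and wavenumber importance

The full model is a linear-kernel soft-margin SVM (`e1071::svm`, cost
`C = 1` by default) on SNV-treated spectra. A linear kernel is not a tuning
choice but a structural one: only a linear decision function
`f(x) = w·x + b` has one weight per wavenumber, which is what
coefficient-based importance plots and wavenumber selection require. The
weight vector is reconstructed from the support vectors, and its sign is
normalized so MP scores positive. No feature standardization beyond the
per-spectrum SNV is applied — a second normalization would reshape the
importance profile.

Importance is `|w_j|` per wavenumber; signed weights are retained for
plotting. Selection (`select_wavenumbers`) greedily takes the `k = 4`
highest-importance wavenumbers subject to a pairwise separation of at least
20 cm⁻¹, so a single broad peak cannot claim several adjacent grid points;
with separation 0 it reduces to a plain top-k. An infeasible constraint
reports the achievable count.

## Train/test convention

Splits are stratified per class: `floor(train_fraction * n)` spectra to
training (default two thirds), remainder to test, reproducibly under a
seed. The floor-then-remainder rounding is this package's own documented
convention; published per-class totals from rounded statistics cannot
always be reproduced exactly, and `reconstruct_confusion` exists precisely
to recover integer confusion matrices from printed rounded values (it
enumerates candidate class totals and, when several survive, disambiguates
with the printed CCR).

Metrics are sensitivity, specificity, CCR (a percentage) and the Matthews
correlation coefficient, kept at full precision internally and printed at
4 / 4 / 2 / 4 decimals. An MCC with a zero denominator factor is reported
as undefined, never silently zeroed.

## Reduced model features: a deliberate deviation

The reduced model's features required a genuine design decision. Training
spectra are full-range, so one could SNV the full spectrum and then extract
the four selected wavenumbers. But an application pixel in a DFIR stack
carries *only* the four channel intensities — the full-spectrum SNV is
unavailable to it, and the only normalization a pixel can reproduce is SNV
across its own four values. We implemented both and measured the
consequence: features normalized in those two ways live in affinely
incompatible spaces, and a model trained on full-spectrum-SNV features
collapses to roughly chance accuracy when applied to channel-wise-SNV
pixels. The package therefore trains reduced models on
**SNV-across-the-extracted-values** features by default
(`feature_mode = "snv_extracted"`), making training and pixel application
consistent by construction; `"snv_full"` is retained for comparison, and
`classify_pixels` warns when asked to apply such a model to pixels. With
the consistent default, particle-level accuracy on synthetic scenes is at
ceiling (the end-to-end test demands ≥ 95 %).

A constant pixel vector, whose SNV is undefined, falls back to a zero
feature vector so the model bias decides; a decision score of exactly zero
is labelled NON_MP. Ties and degenerate cases always resolve *against* MP,
the conservative direction for a contamination count.

# Imaging: segmentation, voting, morphometry

Masks are user-supplied (the instrument workflow draws them manually on the
optical image); `threshold_mask` is provided as an explicit stand-in, not a
claim about manual masking practice. Segmentation is connected components
with 8-connectivity by default (4 available), discarding components below
`min_pixels = 2`: at 2 µm pixels, any real particle of a few µm spans
several pixels, so singletons are near-certainly noise. Ids are assigned in
raster-scan order (row-major, origin top-left) and are contiguous from 1.

A particle's class is the majority vote of its pixel labels, with ties to
NON_MP. The vote fraction is reported alongside, so borderline particles
are visible downstream.

Morphometry follows the regionprops conventions:

* **area** = pixel count × pixel size²;
* **length / width** = major / minor axis of the moment-equivalent ellipse,
  `4·sqrt(eigenvalue)` of the second central moment matrix with the 1/12
  per-pixel extent correction — a solid axis-aligned rectangle of side `L`
  then gets an axis of exactly `2L/√3`;
* **circularity** = `4π·area / perimeter²`, with the perimeter from a
  weighted contour-length estimator: border pixels (those removed by a
  4-neighbourhood erosion) contribute 1, √2, or (1+√2)/2 depending on their
  local border configuration. A naive crack-boundary count overestimates
  the perimeter of curved outlines by ~27 %, pushing a digital disk's
  circularity down to ~0.6; the weighted estimator keeps it above 0.9 for a
  15-pixel-radius disk. Discretization can still push tiny blobs slightly
  above 1, so circularity is capped at 1.
* a single-pixel particle is reported as length = width = pixel size with
  circularity 1, by convention.

Morphometry is exactly scale-equivariant: scaling the pixel size by `c`
multiplies areas by `c²` and axes by `c` and leaves circularity unchanged.

Stacks are written as one 32-bit multi-page TIFF page per wavenumber with a
JSON sidecar carrying channel wavenumbers, pixel size and the per-channel
offset/scale used to store pages in [0, 1]; writing the same stack twice
produces byte-identical files.

# Quantification

The subsampling geometry is a `filter_layout`: by default a 25 mm filter
whose 2.5 mm outer polypropylene ring leaves a 20 mm active diameter,
subsampled by nine 480 µm × 640 µm regions on a centred 3 × 3 grid with
6 mm spacing. The geometric coverage fraction is

> 9 × (0.480 × 0.640 mm²) / (π × 10² mm²) = 0.880 %.

Reported coverages for this geometry sometimes differ slightly (e.g.
0.87 %), because the reference area actually used is not always stated; a
`coverage_override` lets the user impose such an external figure, and its
use is flagged with a warning rather than applied silently. The
extrapolation itself is deliberately transparent: subsample counts across
replicate filters are summarized as mean ± sd and divided by the coverage;
replicates are the unit of uncertainty and the sd scales by the same factor
as the mean (no Poisson correction is layered on top). Per-unit release
divides by the number of source units (e.g. three teabags per filter) and
prints to one decimal. Note that a subsample mean of 8.7 particles at
0.87 % coverage extrapolates to 1000 per filter by this formula — the
package computes what the formula says and leaves any externally reported
pairing of numbers to the reader's judgement.

The microsphere representativeness check converts extrapolated counts to
mass with `count · ρ · πd³/6`, using the supplier density (1.13 g/cm³
for nylon spheres) and, absent a stated mean, the midpoint (17.5 µm) of the
15–20 µm diameter range; the ratio of estimated to deposited mass flags
overestimation when above 1.

Treatment comparisons on MP/All ratios use `stats::t.test`: paired for
before/after measurements of the same regions, Welch two-sample otherwise
(the safer default when only a "normal t-test" is specified; the pooled
version is available). Zero-variance comparisons return the distributional
limit (t = 0, p = 1 for identical groups) instead of failing.

# The synthetic generator

The generator emulates the three particle classes observed on
nylon-release filters, as Gaussian band sums:

| template | bands (centre / σ / amplitude) |
|---|---|
| MP (nylon) | 1635/8/1.0, 1541/8/0.9 (amide I/II), minor 1464/6/0.10, 1416/6/0.08, 1370/6/0.08 |
| non-MP type I | 1740/12/1.0 (sharp carbonyl, within 1700–1800 cm⁻¹) |
| non-MP type II | broad 1000–1200 cm⁻¹ envelope: 1077/60/0.7 + 1077/15/0.5 |

Each generated spectrum is `scatter × bands + baseline + noise` with
scatter uniform in [0.7, 1.3], a random linear baseline (offset up to 0.1,
tilt up to ±0.05) and Gaussian noise of sd 0.02 — a signal-to-noise ratio
consistent with multi-scan-averaged point spectra. No published amplitude
or noise statistics exist for such libraries, so these defaults are the
package's own and are labelled as such.

Two generator choices deserve explanation. First, amplitudes are
deliberately calibrated so that the four class-contrast bands (1635, 1541,
1740, 1077 cm⁻¹) dominate the between-class differences — the selection
pipeline is supposed to be able to recover them, and that recoverability is
what the property tests assert. Second, the type II band is a composite
(wide base plus narrower core at the same centre) rather than a single
σ = 60 Gaussian: a lone broad Gaussian has an essentially flat top, the SVM
weight profile across it is equally flat, and the importance argmax then
wanders tens of cm⁻¹ between seeds — no amplitude choice fixes that. The
composite gives the envelope curvature at its centre while still reading as
one broad band. (Per-spectrum band-centre jitter was tried instead and
rejected: it turns the weight profile into derivative-like lobes on the
band flanks, which is worse.)

Note that the carbonyl *template* sits at 1740 cm⁻¹; a selection pipeline
run on synthetic data therefore recovers a wavenumber near 1740, i.e. a
band in the carbonyl flank region, not any particular published pick within
that region.

Scenes place non-overlapping disks, ellipses and rectangles (primary radius
4–12 px) in a 240 × 320 px region at 2 µm pixels; particle pixels carry the
class template evaluated at the channel wavenumbers with per-pixel
multiplicative jitter (0.8–1.2) plus noise, background carries a low level
(0.02) plus noise, and ground-truth label maps and classes are returned.
Filter experiments drop particles uniformly on the active disk and count
them in the layout regions.

What the generator does **not** emulate: photothermal signal physics,
detector drift, band shapes beyond Gaussians (no Lorentzian/Voigt wings),
correlated noise, overlapping or touching particles, out-of-focus
morphology, alcohol/temperature treatment effects on spectra, and the
within-particle spectral heterogeneity of real weathered MPs. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
behave as designed under controlled conditions — not that a model trained
on this generator would transfer to instrument data.

# Numerical choices and problem sizes

* Default generator class sizes for model studies: 600 spectra per class;
  property tests run 20 seeds of the full pipeline (a few seconds each),
  scene tests 10–20 seeds of 20-particle scenes, and the extrapolation
  round trip plants 100 000 particles per seed. These sizes give the
  binomial/stochastic assertions comfortable margins while keeping the
  suite quick.
* Oracle equivalence tolerances: Pearson vs direct summation and metrics vs
  textbook formulas at 1e−12; SNV affine invariance at 1e−10; SG cubic
  reproduction at 1e−9 (interior).
* Determinism: every stochastic function takes an integer seed;
  identical seeds produce bit-identical spectra, scenes, models and files.
  Model JSON is written with 17 significant digits so doubles round-trip
  exactly.
* Tie-breaks: decision score 0 → NON_MP; pixel-vote ties → NON_MP;
  selection ties resolve by sort order (stable, descending importance).

# Known limitations

* Binary nylon-vs-rest only; extending to multiple polymer classes would
  need a multi-class decision scheme and per-class wavenumber selection.
* The reduced model's four-channel feature space is information-poor by
  design; particles chemically similar to nylon in those four bands only
  would be misclassified, which the full-spectrum correlation path exists
  to catch.
* No optical-to-IR image registration; masks are assumed aligned to the
  stack.
* The manual-masking step of the instrument workflow is replaced by a
  threshold stand-in for testing.
* Reference spectral libraries of real particles are not redistributable
  here; all claims verified by the test suite concern synthetic data.
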