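---
title: "Structural-color histology: the optical model, separation metrics and synthetic sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-color histology: the optical model, separation metrics and synthetic sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noscolor)
```

## The problem

A nanocavity-on-silicon (NOS) slide is a silicon wafer carrying a
nanometer-scale Si₃N₄ film. The film forms a lossy optical cavity whose
reflected color depends sensitively on whatever sits on top of it: mounting
an unstained tissue section changes the local optical path, and regions of
different refractive index (RI) or thickness take on visibly different
structural colors. Healthy colorectal epithelium clusters near RI 1.27 and
cancerous epithelium near 1.37, so a slide tuned to the right cavity
thickness converts that invisible contrast into color contrast — a
stain-free alternative to H&E.

`noscolor` implements the computational core of this idea end to end:

1. a **forward optical model** (transfer-matrix reflectance → CIE 1931
   tristimulus → CIELAB/sRGB) for the air/tissue/Si₃N₄/Si stack;
2. **point-cloud separation statistics** for CIELAB pixel clouds
   (KDE-based intersection-over-union, Frobenius norm of density grids,
   Chamfer distance), with the 5×5 group comparison and its two-sample
   t-test;
3. **agreement and classifier statistics** (Cohen's κ, consistency rate,
   confusion-matrix metrics, ROC/AUC);
4. a seeded **synthetic section generator** that renders RI/thickness
   fields through the same optics, so the whole analysis is testable with
   no real slide images.

## The optical forward model

Reflectance is computed with the characteristic-matrix (Abelès) method for
a coherent planar multilayer over a semi-infinite substrate. Conventions
that matter:

* complex index `ñ = n − ik` with `e^{+iωt}` time dependence; the single
  oracle-pinned consequence is that absorbing layers attenuate,
* the silicon substrate is treated as optically semi-infinite — it is
  opaque across the visible, so no back-surface term exists,
* default normal incidence, unpolarized (mean of s and p intensities);
  oblique angles use Snell's law with the principal complex square root,
* the spectral grid is 360–830 nm at 1 nm.

Material dispersion ships as CSV tables (`wavelength_nm,n,k`). The bundled
silicon and PECVD-nitride tables are smooth synthetic approximations at
literature-typical values (files are named `*_synthetic.csv` to make their
provenance unambiguous); tissue is modelled as a non-dispersive real index,
matching how a single RI value summarizes a tissue class.

The color chain integrates `R(λ)` against a 2° standard-observer
color-matching table bundled as CSV. That table is generated from the
published piecewise-Gaussian analytic fits to the CIE 1931 observer, with
the three channels rescaled to a common integral — a property the true
observer has by construction, and which places the equal-energy white at
chromaticity (1/3, 1/3) exactly.

**Illuminant.** The tristimulus definitions used for slide color integrate
reflectance directly against the color-matching functions, which is
equivalent to an equal-energy illuminant; `illuminant = "E"` is therefore
the default for the spectral chain. A smooth Planckian 6500 K
"daylight-like" alternative (`planck6500`) is available; it is an
approximation, not the CIE D65 table. Image-side conversions
(sRGB ↔ CIELAB for extracted pixel clouds) use the standard D65/2°
constants, exactly as common image-processing toolboxes do.

**Green slide.** The six fabrication cavities (85, 111, 158, 197, 243,
268 nm) render, under this model, as blue, gray-blue, yellow, purple,
green-teal and yellow-green respectively; the green slide used for tissue
simulations is therefore taken to be the 243 nm cavity, and
`slide_config()` defaults to it. The cavity thickness is a plain argument
for anyone modelling a different slide.

**Sensitivity scans.** `jnd_fraction_scan()` finds the smallest fractional
change of tissue RI or thickness whose color shift reaches a CIELAB ΔE*ab
threshold (default 2.3, the classical just-noticeable difference). The
scan evaluates a coarse 64-point grid per direction to bracket the first
crossing, then bisects to a relative tolerance of 1e-3; both directions
are reported with their minimum. Because ΔE(δ) is continuous but not
monotone, the bracket-first strategy returns the *first* crossing, which
keeps the scan monotone in the threshold. On the default green slide at
the 500 nm / n = 1.37 baseline the RI scan lands at ~2.5%, consistent with
the few-percent sensitivity the slide is designed for; the thickness scan
at the same baseline is of the same order (roughly 1–3% depending on the
baseline thickness, because the interference fringes make sensitivity
thickness-dependent).

## Separation metrics

Pixel clouds are extracted from 81 × 81-pixel regions (6561 points) and
converted to CIELAB with a* and b* clamped to [−128, 127].

* **KDE-IoU.** Each cloud's density is estimated with a product-Gaussian
  KDE evaluated *exactly* at every node of a regular 3D grid (no binning
  approximation; the implementation is a tensor contraction checked
  against a brute-force double loop at 1e-10). The IoU is
  Σ min(p_A, p_B) / Σ max(p_A, p_B) over the grid: 1 for identical
  distributions, → 0 for disjoint ones, and invariant to the cell-volume
  factor. Defaults: Scott's rule per axis (σ_d = sd_d · n^(−1/7), shared
  across clouds as the per-axis maximum so densities are comparable),
  64³ grid spanning the joint extent plus 3 bandwidths of padding. Both
  are configurable; grids on different axes are refused rather than
  resampled.
* **Frobenius norm** of the density difference is applied to the two KDE
  grids on their shared axes (clouds themselves have no common indexing,
  so the density grids are the equal-dimension arrays the norm needs).
* **Chamfer distance** first min–max normalizes each axis over the joint
  cloud so all axes contribute equally, averages exact nearest-neighbor
  distances in both directions (ties broken by first index, optional
  per-point weights), and rescales by the root-mean-square of the kept
  per-axis ranges — a convention under which two single-point clouds
  recover their plain Euclidean distance. Axes with zero joint range are
  dropped and recorded.
* **Group comparison.** `group_iou_comparison()` computes all pairwise
  IoUs between two groups of clouds on one shared grid (5 + 5 clouds give
  the 25-pair protocol), and `compare_group_iou()` applies a two-sided
  independent-samples t-test (Student's, pooled variance — the default of
  the common statistics packages) to two such sets.

## Agreement and classifier statistics

`cohens_kappa()` implements the marginal-product chance correction
(P₀ − P_e)/(1 − P_e) on a K × K confusion matrix; `consistency_rate()` is
P₀. Both raters constant on the same class makes P_e = 1 and κ undefined;
this is an error, not a 0. Multi-label image determinations reduce to a
primary class by a configurable priority (default: cancerous > healthy >
non-epithelial, i.e. an epithelial call dominates).

`binary_metrics()` reports accuracy, precision, recall and F1, flagging
zero-denominator metrics as undefined rather than coercing them to 0.
`roc_curve()` sweeps thresholds over the unique scores (ties grouped,
curve anchored at (0,0) and (1,1)) and `auc()` integrates trapezoidally,
which makes it exactly the Mann–Whitney pairwise-win probability with ties
counted ½ — pinned against that oracle, and cross-checked against an
independent ROC implementation. `permutation_null_auc()` gives the exact
chance-level calibration by averaging the AUC over label permutations.

## The synthetic generator

`section_spec()` describes a section: a class map (default: healthy left
half, cancerous right half), per-class RI models, a thickness model, the
slide, and sensor noise. Fields are built from spatially correlated
standard-normal textures (Gaussian correlation length `smooth_sigma_px`,
default 1.5 px) pushed through exact marginal transforms, so smoothing
changes the spatial grain but never the per-pixel distributions:

* **RI**: class mean ± sd (defaults 1.27/1.37, sd 0.02) truncated to
  [1.0, 1.6];
* **thickness**: the interface supports both forms a section study needs.
  The default is `thickness_dist = "normal"` with mean 0.5 µm and sd
  20 nm — one section at the featured simulation condition, with local
  texture at the scale of measured surface roughness. The
  `"uniform"` mode draws the per-pixel marginal exactly uniform on a
  range (e.g. 0.3–1 µm, the measured across-section population range).

The choice of a *fixed nominal thickness per section* is deliberate and is
the one genuinely open design decision here. An ideal-slab model has a
wrapping degeneracy: the CIELAB trajectory over thickness is a loop, so at
specific thicknesses a +0.1 RI shift lands back near the starting color
and the class contrast collapses; and if per-pixel thickness spans the
whole 0.3–1 µm population range, both class manifolds sweep the loop and
overlap almost completely. Neither regime reflects the measured data
structure, where per-region clouds are tight and well separated — which is
only consistent with locally stable thickness. The population range
remains available as the `"uniform"` mode and is the right choice when the
quantity of interest marginalizes over sections.

Rendering maps the fields through the forward model via a bilinear
(RI × thickness) lookup table (default 64 × 64 nodes; the maximum
interpolation error against exact rendering at random probe points is
measured and carried in the output), adds Gaussian sensor noise in sRGB
(default sd 0.01) and clips to [0, 1]. A **glass mode** renders the same
fields through a deliberately simple weak-contrast proxy — the
wavelength-flat two-interface Fresnel transmittance
T = (1 − ((n−1)/(n+1))²)² — labelled synthetic-only: it is a contrast
model for paired experiments, not an optical model of a glass slide.

`make_labeled_tiles()` cuts class-pure, grid-aligned, non-overlapping
tiles from per-"subject" sections whose seeds are derived disjointly for
train and test, emulating a patient-level split.
`baseline_tile_classifier()` is a deliberately shallow stand-in for the
deep tile classifiers used on real data: nearest-centroid (or logistic)
on per-tile mean and sd of L*, a*, b*. `simulate_raters()` draws two
conditionally independent raters from a row-stochastic confusion model
for exercising the agreement statistics.

## Experiments and problem sizes

`run_comparison_experiment()` renders one section under both modes,
samples 5 + 5 non-overlapping class-pure regions, extracts clouds,
computes the pairwise metric tables per mode and the between-mode t-test,
and writes CSV/JSON reports. `ordering_experiment()` repeats it across
seeds and applies an exact binomial sign test to "NOS IoU below glass
IoU". `run_screening_experiment()` builds the tile datasets, scores
held-out tiles, and reports the confusion matrix, accuracy / precision /
recall / F1, κ, consistency, ROC and AUC.

The default experiment scale is deliberately desk-sized: 160 × 120-px
sections, 27-px regions and a 32³ KDE grid, which keeps a 20-seed ordering
experiment under a minute while leaving the 81-px / 64³ protocol available
through the configuration. Under these defaults the test suite verifies
the qualitative results the synthetic study is designed to show: the
structural-color rendering separates the classes far more than the glass
proxy (sign test over 20 seeds), the baseline classifier saturates on the
default class gap, and the null calibrations (independent raters' κ,
label-permuted AUC) sit at chance.

## What passing tests do and do not show

The generator emulates the *statistical* structure the analysis assumes —
class-wise RI clustering, locally stable thickness with texture, sensor
noise, patient-level splits — not histomorphology: there are no glands,
nuclei, staining artifacts, scanner stitching seams, or spatial RI
covariance estimated from real tissue (that covariance is not
characterized; the correlation length is a free texture parameter). Green
tests therefore demonstrate that the pipeline's mathematics and wiring are
correct and that the qualitative contrast mechanism behaves as designed
under the stated conditions — they do not certify diagnostic performance
on real slides, and the real-data quantities (mean IoU values, κ = 0.983,
CNN accuracy) are intentionally not reproduced.

Other known limitations: the slab model's phase-wrapping degeneracy at
specific thickness/RI combinations (real sections with rough interfaces
and finite illumination apertures are less coherent); the synthetic
dispersion tables are approximations, so absolute colors (and the exact
JND percentage) carry their uncertainty; and the color-only baseline
classifier degrades when sections span a wide thickness range — the
uniform population mode makes that confound visible, and a morphology-free
feature set cannot overcome it.
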