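# noscolor

Structural-color modelling and colorimetric separation statistics for
nanocavity-on-silicon (NOS) histology.

A NOS slide is a silicon wafer coated with a nanometer-scale Si₃N₄ film.
The film is a lossy optical nanocavity: its reflected color shifts with
the refractive index (RI) and thickness of whatever is mounted on it, so
an unstained tissue section produces color contrast directly from its
physical properties. Healthy colorectal epithelium clusters near RI 1.27
and cancerous epithelium near 1.37; on a well-chosen cavity this RI gap
becomes a clearly visible color difference, making stain-free histology
possible. This package is for researchers modelling such slides and
analyzing the resulting images: it provides the optical forward model,
the color-distribution separation metrics, the diagnostic-agreement and
classifier statistics, and a synthetic data generator so the whole
analysis runs without real slide images.

## What is inside

**Optical forward model** — transfer-matrix (Abelès) reflectance of the
air/tissue/Si₃N₄/Si stack at 1 nm resolution over 360–830 nm, integrated
against CIE 1931 2° color-matching functions:

    X = ∫ R(λ) x̄(λ) dλ,  Y = ∫ R(λ) ȳ(λ) dλ,  Z = ∫ R(λ) z̄(λ) dλ,
    (x, y) = (X, Y) / (X + Y + Z)

then on to CIELAB (L\*, a\*, b\*), ΔE\*ab color differences, and sRGB for
rendering. `jnd_fraction_scan()` bisects for the smallest fractional RI or
thickness change reaching a just-noticeable ΔE\*ab (default 2.3).

**Separation metrics** — CIELAB point clouds from 81×81-pixel regions,
compared by the density-based intersection-over-union

    IoU = Σ_Ω min(p_A, p_B) / Σ_Ω max(p_A, p_B)

with exact 3D Gaussian-kernel densities on a shared grid, plus the
Frobenius norm of the density difference and the bidirectional Chamfer
distance, and the 5×5 group comparison with a two-sided
independent-samples t-test.

**Agreement & classifier statistics** — Cohen's κ = (P₀ − P_e)/(1 − P_e)
with P₀ from the confusion-matrix diagonal and P_e from the marginal
products; consistency rate; accuracy/precision/recall/F1 with explicit
undefined-metric flags; ROC by tie-grouped threshold sweep; trapezoidal
AUC (equal to the Mann–Whitney pairwise statistic).

**Synthetic sections** — seeded RI/thickness fields per tissue class,
rendered to RGB through the slide optics (or a weak-contrast "glass"
proxy), with labeled tile datasets, patient-level splits, simulated
raters, and a shallow color-feature baseline classifier.

## Worked example

```r
library(noscolor)

# Color of healthy vs cancerous tissue (500 nm section) on the green slide
healthy <- simulate_slide_color(tissue_n = 1.27, tissue_thickness_nm = 500)
cancer  <- simulate_slide_color(tissue_n = 1.37, tissue_thickness_nm = 500)
healthy
#> <nos_color> (x,y)=(0.2657, 0.3320)  L*a*b*=(51.20, -20.75, -7.66)  sRGB=(0.254, 0.519, 0.527)
cancer
#> <nos_color> (x,y)=(0.2750, 0.3019)  L*a*b*=(46.73, -8.27, -12.89)  sRGB=(0.314, 0.454, 0.517)
delta_e(healthy$lab, cancer$lab)
#> [1] 14.25618
```

The RI gap of 0.1 moves the color by ΔE ≈ 14 — about six just-noticeable
differences, the contrast the slide is designed to create. How small a
change is still visible?

```r
jnd_fraction_scan("tissue_n")
#> <jnd_scan> tissue_n: 2.507% fractional change reaches delta-E 2.30 (+2.542% / -2.507%)
```

A ~2.5% RI perturbation already produces a just-noticeable color shift.
The end-to-end synthetic experiment renders a section under both the NOS
optics and the glass proxy, extracts 5 healthy + 5 cancerous pixel clouds,
and compares their CIELAB overlap:

```r
run_comparison_experiment(run_config())
#> <nos_report> comparison experiment, seed 1
#>   mean healthy-vs-cancer IoU: NOS 0.1455, glass 0.3442
#>   two-sided t-test (glass vs NOS): t = 28.415, p = 1.12e-31
```

Healthy and cancerous color distributions overlap far less on the NOS
slide (mean IoU 0.15 over the 25 region pairs) than in the weak-contrast
glass rendering (0.34): the structural-color readout separates the
classes. `run_screening_experiment()` runs the tile-classification
analogue and reports the confusion matrix, κ, and ROC/AUC.

A thin CLI wrapper ships in `inst/cli/nos.R`
(`Rscript inst/cli/nos.R simulate --tissue-n 1.37 --out spectrum.csv`).

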