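---
title: "The OMLIT optical model: multilayer interference contrast for sections on tape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The OMLIT optical model: multilayer interference contrast for sections on tape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omlitr)
```

## The imaging problem

Optical multilayer interference tomography (OMLIT) images ultrathin,
heavy-metal-stained resin sections under reflected monochromatic LED light.
The sections sit on a polycarbonate collection tape — bare or pre-coated with
a thin metal film — which in turn sits on conductive carbon tape over a
silicon wafer. Because the section is far thinner than the wavelength, the
reflected intensity is governed by thin-film interference across the whole
stack, and differences in stain density between a cell body and the
surrounding neuropil translate into intensity contrast. Which coating
material and thickness, section thickness and LED line give the best contrast
is a design question that can be answered in silico; `omlitr` provides the
optical engine, the configuration sweep, a synthetic "phantom" tissue
generator to render ground-truth images, and the ROI-pair contrast
measurement used to validate renderings against the model.

## The optical model

A stack is a lossless semi-infinite incident medium (air), an ordered list of
plane-parallel layers, and a semi-infinite substrate that may absorb (silicon
in the visible). Each material carries a complex refractive index
$\tilde n = n + ik$, $k \ge 0$, interpolated linearly in wavelength from a
dispersion table; no extrapolation is permitted outside a material's sampled
range.

For a coherent layer of thickness $d$ at wavelength $\lambda$, with
propagation angle $\theta$ from the complex Snell law (branch chosen so waves
decay into absorbers) and optical admittance $\eta = \tilde n\cos\theta$
(s-polarization) or $\tilde n/\cos\theta$ (p), the layer's characteristic
matrix is

$$M = \begin{pmatrix} \cos\delta & i\sin\delta/\eta \\ i\eta\sin\delta &
\cos\delta\end{pmatrix}, \qquad \delta = \frac{2\pi \tilde n d
\cos\theta}{\lambda},$$

with determinant 1. The stack amplitude follows from
$(B, C)^\top = \left(\prod_j M_j\right)(1, \eta_{sub})^\top$ and
$r = (\eta_0 B - C)/(\eta_0 B + C)$, $R = |r|^2$, $T = 4\eta_0\,
\mathrm{Re}(\eta_{sub})/|\eta_0 B + C|^2$, $A = 1 - R - T$. The matrix
formalism is written in the $e^{i(\omega t - kz)}$ time convention, in which
an absorbing layer enters with a conjugated phase thickness; the package
stores $k \ge 0$ user-side and conjugates internally, so lossless closed
forms keep their textbook signs. Unpolarized results are the mean of s and p.

Two independent routes compute the same reflectance: the matrix product
above, and a bottom-up Parratt-style recursion over interface Fresnel
coefficients with phase factors $e^{2i\delta}$. The two implementations share
no code beyond the dispersion lookup and agree to about $10^{-15}$ on
randomized absorbing stacks at oblique incidence; the test suite pins this at
$10^{-9}$ over 100 seeded stacks of up to 6 layers.

### Incoherent thick layers

The 50 µm tape and the carbon tape are orders of magnitude thicker than an
LED coherence length, so their interference fringes are not observable.
Such layers are flagged `incoherent` and handled by averaging the fully
coherent reflectance over a uniform round-trip phase offset in that layer:
64 midpoint samples over one half-period, a fixed, documented quadrature that
reproduces the textbook incoherent-slab summation
$R = (R_1 + R_2 - 2R_1R_2)/(1 - R_1R_2)$ to better than $10^{-9}$ (the suite
requires $10^{-6}$). Coherence flags are per-layer and user-overridable.

### Numerical choices

* **Phase cap.** The imaginary part of a phase thickness is capped at
  magnitude 40 (round-trip attenuation $e^{-80}$), preventing complex-cosine
  overflow for opaque layers such as 100 µm of carbon tape. The Parratt
  recursion needs no cap and cross-checks the capped matrix path.
* **Opacity truncation.** When a layer's round-trip attenuation falls below
  $e^{-40}$, nothing below it can return; the sweep kernel truncates the
  stack there and treats that layer as the substrate (exact to $\sim
  10^{-17}$, and it removes one 64-sample phase dimension per opaque
  incoherent layer).
* **Bandwidth and aperture averaging.** `spectral_angular_average()` applies
  a Gaussian spectral average (given FWHM, truncated at $\pm 2\,$FWHM,
  16-point Gauss–Legendre) and a uniform-pupil-irradiance average over the
  illumination cone up to $\arcsin(\mathrm{NA})$ (weight
  $\sin\theta\cos\theta$, 8 points). Both collapse exactly to the
  single-point evaluation at FWHM = NA = 0. At the 2x objective's NA = 0.06
  the angular correction to a bare interface is below 1% relative — at
  normal-incidence workflows it is safely negligible.
* **Ties in sweeps** are broken toward thinner section, then thinner coating.

## Contrast and configuration sweeps

`omlit_contrast()` builds two stacks differing only in the section layer's
material — `stained_cell` versus `stained_tissue` — and reports
$C = \max(R_{cell}, R_{surround}) / \min(R_{cell}, R_{surround}) \ge 1$.
The ratio is symmetric under swapping the two roles and mirrors how bright
and dark regions are compared in normalized images; Michelson contrast
$(R_{hi} - R_{lo})/(R_{hi} + R_{lo})$ is available via `mode = "michelson"`
for workflows that prefer a bounded measure. A contrast is undefined
(an error, not `Inf`) if a reflectance is exactly zero.

`contrast_sweep()` evaluates $C$ on a dense grid — defaults: section
thickness 10–300 nm and coating thickness 10–400 nm in 5 nm steps, at the
four LED lines 390/470/555/630 nm. The grid covers both the ultrathin
regime used for correlative electron microscopy (30–100 nm) and the
sub-micron regime relevant for faster, thicker sectioning. The sweep kernel
is the same characteristic-matrix arithmetic vectorized over the grid and
the incoherent phase dimension; a pointwise cross-check against the scalar
path is part of the suite. Each sweep annotates its per-wavelength optimum
and the *reduced thickness*: the smallest grid coating thickness whose
best-over-section contrast reaches 95% (configurable) of that wavelength's
optimum — the conventional parenthetical annotation for optima that sit at
the top of the coating grid. `optimum_report()` collects one row per
(coating material, wavelength), and `estimate_period()` extracts the
dominant fluctuation period of contrast versus section thickness from peak
spacings (peaks located between rising crossings of a 40%/60% hysteresis
band, which tolerates a few percent of noise).

The fluctuation period is the interference order spacing
$\lambda/(2 n_{section})$ at normal incidence, so the period is proportional
to wavelength — the acceptance suite verifies the $630{:}390$ period ratio to
within 10% on a synthetic lossless section over an opaque substrate.

## The bundled material library

The dispersion constants the original instrument designers used are not
published, so the bundled library (`omlit_materials()`) is assembled from
standard published tabulations where those exist — Johnson & Christy for
silver, copper and chromium, Aspnes & Studna for silicon, a Sellmeier fit
for polycarbonate — sampled at 340–680 nm so that bandwidth averaging at the
outer LED lines stays inside the interpolation range. The stained materials
are documented synthetic placeholders: weakly absorbing dielectrics with
`stained_cell` carrying higher $n$ and $k$ than `stained_tissue` to represent
heavier heavy-metal deposition in somata, plus `*_post` variants with
elevated $k$ standing in for uranyl acetate/lead citrate poststaining
(a material substitution, not a chemistry model), and a near-lossless
`resin` for vessel lumina. Every entry carries a provenance note
(`material_provenance()`), and user libraries loaded with
`read_material_library()` override the bundle entirely.

```{r}
omlit_materials()
```

## The phantom generator

`generate_phantom()` builds a seeded 3D label volume emulating what the
reflected-light modality actually resolves in cortex: somata (spheres placed
by rejection sampling, disjoint by construction), each with a concentric
nucleus and 1–3 nucleoli, non-branching vessels crossing the volume, and
persistent-random-walk neurite processes. Default geometry follows the
tissue scale: soma diameters 5–14 µm, vessels 3–6 µm across, isotropic
voxels of 500 nm. What it deliberately does **not** emulate: organelle-scale
content, stain-density texture within a class (a per-label jitter would be
guesswork; intensity inside a class is constant before noise), curvature of
real vasculature, and anisotropic section compression. Consequently a
passing render/measure round trip demonstrates the *consistency* of the
optical model, renderer and metric — not that real tissue will show the
predicted absolute contrast, which depends on the true optical constants.

`slice_phantom()` collapses a slab of voxel planes to one section by
per-pixel majority vote, ties resolved toward the deeper structure
(nucleolus > nucleus > cytoplasm > vessel lumen > neuropil) so thin deep
structures are never swallowed by their surroundings. An optical
linear-mixing mode was considered and rejected for the default because crisp
ground truth is what makes the metric tests exact; majority labels keep the
noiseless render piecewise-constant.

`render_section()` computes one reflectance per label present (section layer
material taken from a label→material map) and applies
$I = \mathrm{gain}\cdot R + \mathrm{offset}$, optional scaled-Poisson shot
noise, and additive Gaussian read noise, all under a caller-supplied seed.
`add_defects()` overlays the artifact classes that plague imperfect
coatings — straight scratches, jagged cracks, peeling specks — as seeded
intensity offsets with the affected pixel mask attached, so tests can assert
exactly which pixels changed.

## ROI-pair contrast measurement

`normalize_image()` rescales so the 0.1 and 99.9 percentiles map to 0 and 1
(robust to isolated hot pixels; plain min–max available).
`sample_roi_pairs()` draws $n$ pairs (default 50) of 11 × 11 px squares —
the cell ROI entirely inside cell-body labels, its surround partner entirely
inside neuropil within 6 ROI-widths, centres of distinct pairs at least two
ROI-widths apart — deterministically per seed. `measure_contrast()` computes
each pair's brighter/darker mean-brightness ratio and averages per pair
(not pooled), reporting mean, SD and $n$; degenerate pairs (a zero region
mean) are excluded and counted. Fixed squares rather than hand-drawn regions
were chosen for reproducibility; hand-drawn ROIs can be imported from the
documented 0-based CSV format (`read_roi_pairs()`).

On a noiseless rendered section this measurement returns the model contrast
*exactly* (the suite pins the agreement at $10^{-9}$ over 50 pairs), with
Gaussian noise the 50-pair mean stays within three standard errors of the
noiseless value, and injected defects strictly inflate the per-pair SD.

## Reproducibility

Every stochastic operation takes an explicit seed and restores the caller's
RNG state. The pipeline entry points (`run_render()`, `run_measure()`) fan a
single global seed out to per-stage child seeds (a fixed affine map modulo
$2^{31}-1$) so stages can be re-run independently; reruns are byte-identical
down to the emitted TIFF/CSV/JSON, and each run writes its resolved
configuration next to its outputs. Problem sizes used by the test suite —
quasi-2D phantoms of $320 \times 320 \times 10$ voxels at 1 µm with 60
somata, 100 randomized stacks, full-resolution default sweeps — were chosen
so the whole suite exercises every code path in a few minutes on one core.

## Known limitations

* **Unconstrained ratio-contrast optima are null-seeking.** On a dense
  (section × coating) grid the optimizer has two independent knobs: coating
  transparency tunes the *magnitude* of the light returned from below the
  section, and section thickness tunes its *phase*. For whichever of the two
  section materials absorbs less, a near-perfect destructive cancellation
  (critical coupling, as in lossy anti-reflection absorbers) is therefore
  reachable for essentially any coating metal and wavelength, driving that
  stack's reflectance toward the incoherent background floor ($\sim 10^{-4}$
  from the tape interfaces) and the contrast ratio toward $10^2$–$10^3$.
  Which material/wavelength "wins" such a sweep is then decided by how close
  a grid point lands to a null — not by mirror quality — and is extremely
  sensitive to the assumed stain constants. Rankings of coating materials
  (e.g. silver's advantage in the blue, copper improving toward the red as
  its reflectivity rises past the interband edge) are recovered by this
  engine in the *opaque-coating regime* — thick-coating configurations, or
  sweeps restricted to the thin-section range — but are **not** stable
  properties of the unconstrained global argmax with placeholder constants.
  Finite LED bandwidth (tens of nm) lifts the nulls and caps ratios near
  $10^1$, which is the scale instrument measurements actually report;
  bandwidth-averaged single evaluations are available via `fwhm_nm`.
* Absolute contrast predictions inherit the placeholder stained-material
  constants; treat them as relative design guidance until measured $n, k$
  values are loaded.
* The model is specular only: no surface roughness, scattering, or
  vectorial high-NA image formation, and no anisotropic or magnetic media.
* The renderer maps each label to one material; partial-volume optical
  mixing within a slab is not modelled in the default pipeline.
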