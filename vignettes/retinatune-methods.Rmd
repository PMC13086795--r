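---
title: "Models and methods behind retinatune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retinatune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinatune)
```

`retinatune` analyses the graded expression of visual pigments across a
butterfly retina from three data streams: intracellular recordings,
immunolabelled sections, and hyperspectral eyeshine images. This vignette
documents the models, the tunable parameters, the synthetic-data generator,
and the design choices made where the problem left the design open. No
empirical claim is made here beyond what the package's tests and examples
compute themselves.

## Absorbance templates

Spectral sensitivities are modelled with the Govardovskii-family A1
alpha-band template,

$$S_\alpha(\lambda) = \left[e^{69.7(a-x)} + e^{28(0.922-x)} +
e^{-14.9(1.104-x)} + 0.674\right]^{-1},\qquad x = \lambda_{max}/\lambda,$$

with $a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}$, and an
optional beta band
$S_\beta = 0.26\,\exp[-((\lambda - \lambda_{m\beta})/b)^2]$ with
$\lambda_{m\beta} = 189 + 0.315\,\lambda_{max}$ and
$b = -40.5 + 0.195\,\lambda_{max}$. Templates are normalized so the
*continuous* peak equals 1 (located by `optimize()`), which keeps values on
any evaluation grid in $[0, 1]$ with the grid point nearest
$\lambda_{max}$ at $\ge 0.999$ on a 1 nm grid.

The beta band is **off by default** for fitting: the two-template
decomposition is restricted to 400–600 nm, where the beta band (below
~400 nm) is irrelevant; it is **on** in generator spectra so that UV-range
shoulders look realistic. Whether the original fits included a beta band is
not documented; with the 400–600 nm window the choice does not matter
numerically, which is why the simpler default was taken.

## Hill (Naka–Rushton) fits and the reverse transformation

Intensity runs cover 4 to 0 optical-density units in 0.2 OD steps; relative
intensity is $I = 10^{-OD} \in [0,1]$, so the fitted half-saturation $K$ is
expressed on that attenuation scale. The fit minimizes unweighted squared
error of $V(I) = V_{max} I^n/(I^n + K^n)$ with $V_{max}$ profiled out
analytically (it enters linearly once $n, K$ are fixed) and the remaining
two parameters optimized by bounded quasi-Newton ($n \in [0.5, 3]$,
$K \in [10^{-6}, 1]$, $V_{max} \in (\max V, 3\max V]$) followed by a
Nelder–Mead polish — the polish matters because quasi-Newton line searches
stall on the zero-residual data used by the exactness tests. Recovery on
exact data is ~1e-9 relative; under 2% multiplicative noise the Hill
exponent is recovered within ±0.1 and the median relative error of $K$ is
below 5% (both frozen from 100-seed Monte-Carlo runs).

The reverse Hill transformation inverts sub-saturating depolarizations into
relative sensitivities, $s(\lambda) = (r/(V_{max}-r))^{1/n}$, assuming
iso-quantal stimulation. Three numerical guards apply:

* responses at or above $V_{max}$ raise a saturation error naming the
  wavelength; responses above $0.98\,V_{max}$ are excluded with a warning
  (the inversion diverges there);
* hyperpolarizing responses in a nominally dark-adapted scan are excluded
  with a polarity warning (they belong to `isolate_opponent_unit()`);
* up and down sweeps are averaged **on the sensitivity scale**, because the
  inversion is nonlinear and averaging voltages first would bias the
  result.

Whether the original analysis used direct amplitude inversion or
criterion-response interpolation is not stated; direct inversion is
implemented. For opponent isolation the host cell's Hill parameters are
reused for the sign-inverted hyperpolarizations — a documented
simplification, since the inhibitory unit's own nonlinearity is not
observable from these recordings.

## Polarization typing

Sensitivities from a polarization run are fit with
$s(\varphi) = c_0 + c_1 \cos 2(\varphi - \varphi_{max})$, which is linear in
$(\cos 2\varphi, \sin 2\varphi)$ and therefore solved exactly.
$PS = (c_0+c_1)/(c_0-c_1)$; $\varphi_{max}$ is reported modulo 180°.
Classes use symmetric ±22.5° bins around the three microvillar
orientations: vertical [67.5°, 112.5°), horizontal [0°, 22.5°) ∪
[157.5°, 180°), diagonal otherwise. Flat profiles ($c_1/c_0 < 0.05$) and
nonphysical fits ($c_0 \le c_1$) are flagged indeterminate.

## Two-template decomposition and classification

The 445 + 545 nm decomposition is a two-variable non-negative least squares
problem solved exactly in closed form: take the unconstrained solution if
feasible, otherwise the better of the two single-template fits. The test
suite keeps an independent brute-force grid search
($[0,2]^2$ at 0.001 resolution) as an oracle. Amplitudes are fit to the
max-normalized sensitivity without SEM weighting (per-wavelength errors are
not modelled), and negative amplitudes are not allowed — identifiability of
the published ratios does not require them.

Classification uses the printed thresholds (> 1.1 blue-dominant, < 0.9
green-dominant, in between balanced). The printed rule leaves ratios
exactly 0.9 or 1.1 unassigned (strict inequalities on both sides); they are
assigned to the middle class so the rule is a total partition — a
measure-zero choice.

Cells with a secondary UV peak are excluded from class averages and
gradient statistics. The exclusion criterion is not quantified upstream, so
the package uses an invented, exposed constant: a local maximum in
[300, 400) nm reaching ≥ 0.6 of the global maximum (`theta_uv`).

The dorso-ventral gradient is summarized per elevation bin (default bins
ventral < −20°, equatorial −20°…+10°, dorsal > +10°, matching the
equatorial band used in the source protocol) and tested with Spearman rank
correlation of ratio against elevation; the p-value comes from 10,000
seeded permutations.

## Mosaic typing and strip densities

R1&2 cells take one of five states (U, B, L, UL, BL); U&B co-expression is
never observed and is rejected. Ommatidial types are canonical unordered
pairs in the fixed order U < B < L < UL < BL; five states give the full
15-type space. For strip profiles the types collapse to four categories:
`nonL` (both cells U or B — non-red ommatidia), `L`, `UL`, `BL`. The single
mixed UL/BL type is assigned to **UL** (configurable): the four-category
partition forces a choice the source never states, and UL is the rarer
class — sending UL/BL to BL would erase the UL panel's only distinctive
type. Strips are ten equal-width horizontal bands spanning the section's
bounding box along the dorso-ventral axis (bounding box rather than convex
hull; also unstated upstream), strip 1 dorsal-most. Empty strips report
missing fractions, not zeros. When states are called from label
intensities, per-channel Otsu thresholds are used by default (the upstream
protocol classifies visually; Otsu keeps the pipeline unsupervised), with
the cut placed mid-way across the empty gap between intensity classes so
borderline values do not straddle it; residual U/B double positives are
resolved toward the stronger channel and reported.

## Eyeshine analysis

Light-adapted background frames are Gaussian-filtered (σ = 1 px) and
subtracted from the dark-adapted frames, clipping at zero; this removes
smooth artefacts and the punctate corneal lens reflections. The R channel
is the pixelwise median of the 675 and 653 nm frames, G the median of
635, 622, 610 and 594 nm; the 575 nm frame is acquired but never mapped
(kept for QC), matching the printed channel assignment.

Lattice detection replaces the original detection/classification tools
(an ommatidia-detection algorithm plus a trained pixel classifier) with a
deterministic difference-of-Gaussians band-pass (σ = spacing/4 and
spacing), local maxima with 0.8 × spacing minimum separation, greedy
non-maximum suppression, and subpixel centroid refinement. Feature-level
equivalence with a trained classifier cannot be claimed — only functional
equivalence on synthetic data, which the closed-loop tests establish.

Detection runs by default on the pixelwise median of the **background**
frames: every facet shows a lens reflection there, so dark ommatidia —
which never appear in the eyeshine and are pure local minima, invisible to
any maxima detector on the cleaned image — are still found as lattice
positions. This mirrors the two-stage logic of the original pipeline
(lattice segmentation first, type classification second). The relative
detection floor (0.08 of the strongest band-pass response) was frozen from
a seeded benchmark before the acceptance tests were written.

Classification averages R and G over a disk of radius 0.4 × spacing (an
invented, exposed constant). An ommatidium is dark when R+G falls below
`theta_dark` (default 0.2) times a reference intensity — the image's own
95th percentile of R+G, or, when background detection is used, twice the
95th percentile of the background median, which anchors the intensity
scale even for images that are entirely dark. Otherwise the redness index
R/(R+G) decides red (≥ 0.6) versus non-red. Redness is a ratio, so
red/non-red calls are invariant to uniform intensity scaling; dark calls
are relative to the image-wide reference, so dimming one spot against an
unchanged image flips it to dark while a global rescale changes nothing —
both behaviours are asserted in the tests. Fractions are computed per
image (the last category as the exact complement, so the three fractions
sum to exactly 1 in floating point) and then averaged across replicate
eyes per elevation.

## The synthetic generator: what it emulates, and what not

The generator's defaults state the world the analysis assumes:

* **Hill parameters**: $V_{max} \sim N(40, 4)$ mV, $n \sim N(1, 0.1)$,
  $K \sim \mathrm{lognormal}(\log 0.1, 0.2)$ — typical insect photoreceptor
  V–log I values; stimulus strength is set so peak responses reach
  $0.7\,V_{max}$ (sub-saturating).
* **Gradients**: logistic in elevation with midpoint −5° (inside the
  −20°…+10° equatorial band) and slope 15°. The amplitude ratio runs from
  1.6 (ventral) to 0.2 (dorsal), spanning all three ratio classes; the
  eyeshine red-ommatidium probability runs from 0.6 (ventral) to 0.1
  (dorsal), the printed extremes of the red fraction.
* **Opponency**: post-nonlinearity subtraction,
  $r = \mathrm{Hill}(I_0 g_e S_{exc}) - w\,\mathrm{Hill}(I_0 g_i S_{inh})$,
  with weight $w = 0.3$; no equation is given upstream, and subtraction
  reproduces the sign-inverting adapted responses. The R9 red unit is a
  545 nm template seen through a long-pass screening pigment (logistic
  cut-on at 600 nm, 10 nm edge), peaking near 605 nm; dorsal green cells
  get an extra 445 nm inhibitory unit ($w = 0.15$); Y cells receive the R9
  term with positive sign (excitation). The magnitudes of R9 and dorsal
  blue inhibition are not quantified upstream — these weights are
  placeholders and labelled as such. Adaptation acts as a Weber-type gain
  $g_u = 1/(1 + \sum_a I_a S_u(\lambda_a)/K)$ per unit.
* **Mosaics**: 40 × 50 hexagonal lattice (2000 ommatidia) mapped onto
  elevations −60°…+60°; L-class membership follows the 0.1–0.6 logistic,
  each R1&2 in an L ommatidium expresses L with probability 0.7
  (conditioned on at least one), an L-expressing cell is BL with the
  elevation-dependent probability (0.05–0.8) or UL at a constant 3% rate,
  and non-L cells split U:B evenly. Label intensities are state indicators
  with 10% multiplicative noise over a 5% background.
* **Eyeshine stacks**: 14 × 16 lattice, 12 px spacing, Gaussian spots
  (σ = 3 px), amplitudes U(0.7, 1), 5% pixel noise, a smooth ramp+blob
  background, and a 0.3-amplitude lens glint at every facet in all frames.
  Dark probability 0.05; marginals are P(dark) = p_dark,
  P(red) = (1 − p_dark)·p_red(e).

What the generator does **not** emulate: waveguide/self-screening optics,
metarhodopsin photoproducts, receptor noise spectra, sex differences,
cross-elevation stitching, and the spatial correlations of real mosaics
(states are drawn independently given elevation). A green closed-loop test
therefore establishes that the pipeline recovers the statistical structure
it assumes — not that real retinas satisfy that structure.

## Numerical and testing choices

* Seeds: every stochastic operation takes an explicit seed; identical
  configuration and seed give byte-identical outputs.
* The eyeshine acceptance check uses three replicate eyes per elevation
  (the upstream study averaged 19), keeping the binomial sampling error of
  the recovered fractions well inside the ±0.05 closed-loop tolerance at
  ~670 effective ommatidia per elevation.
* The 50-seed end-to-end monotonicity property is run scaled down (10
  seeds, 8 × 8 lattice, 5 elevations) to keep the default test run within
  its time budget.
* Degenerate inputs: empty adaptation scans without hyperpolarizations
  raise an empty-opponent error; all-zero amplitude compositions, blank
  images, degenerate bounding boxes and single-bin gradients all raise
  typed errors rather than returning silent zeros.

## Known limitations

* The fitted $K$ is only identified up to the stimulus strength of the
  intensity run (attenuation scale); this does not affect sensitivities,
  which depend on $V_{max}$ and $n$ alone.
* The intensity-based detector cannot find dark ommatidia without
  background glints; on data lacking light-adapted frames,
  `detect_on = "eyeshine"` recovers only red and non-red lattice sites.
* Opponent-unit spectra are recovered through the host cell's
  nonlinearity; their amplitudes are therefore qualitative, and only peak
  positions and shapes are interpreted.
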