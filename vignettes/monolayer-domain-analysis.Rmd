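---
title: "Methods: nanoscale domain analysis of lipid monolayer AFM/KPFM images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale domain analysis of lipid monolayer AFM/KPFM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monodomain)
```

## The measurement problem

A Langmuir–Blodgett monolayer of mixed phosphatidylcholines — a fluid
phase (DOPC-rich) and a gel phase (DPPC-rich), optionally doped with a
cationic gemini surfactant — phase-separates into nanoscale domains. AFM
reports the film as a height map $h(x, y)$ in nm; frequency-modulated
KPFM reports the contact potential difference $V(x, y)$ in mV over the
same area. Three quantities summarise such a pair of images:

* the **surface coverage** $f$ of the higher (gel-phase) domains,
* the **height contrast** $\Delta h$ between the phases, and
* the **potential contrast** $\Delta V$.

Only differences are physically meaningful in KPFM — the probe shifts
every absolute potential — so the package works exclusively with
contrasts.

## Interpreting $\Delta V$: the electrostatic models

A uniform monolayer of aligned molecular dipoles produces a surface
potential given by the Helmholtz relation in the monolayer literature's
practical units,
$$V[\mathrm{mV}] = \frac{12\pi\,\mu_\perp[\mathrm{mD}]}{A[\mathrm{\unicode{x212B}}^2]},$$
with $\mu_\perp$ the normal dipole component per molecule and $A$ the
area per molecule. `dipole_sheet_potential()` and
`dipole_from_potential()` implement this forward and inverse, verbatim in
these units rather than in SI, because the tabulated literature values
are the quantities a user will feed in and compare against.
`table3_fixture()` bundles published $(\pi, A, V, \mu_\perp)$ rows for
DOPC and DPPC and `table3_check()` recomputes every model-derived cell,
flagging disagreement beyond one unit in the last printed digit.

Adding a divalent cationic surfactant contributes, in the simplest
picture, an infinite charged sheet:
$$V_{\text{sheet}} = \frac{z\,\sigma}{2\epsilon_0},$$
with $z$ the probe height and $\sigma$ the surface charge density.
`gemini_number_density()` inverts this for $\sigma$ and divides by the
$2e$ molecular charge to give molecules per m². Two deliberate choices:

* The compact published shorthand $\sigma = \epsilon_0 V / z$ omits the
  factor 2 of the strict inversion and mixes charge with number density;
  the package inverts the sheet equation explicitly and exposes the
  literal shorthand separately (`charged_sheet_sigma_literal()`) so both
  conventions are auditable.
* The surfactant-per-lipid ratio (`gs_per_lipid()`) is exposed with the
  probe height $z$ as a free parameter and is asserted nowhere: $z$
  during an FM-KPFM scan is instrument-specific and unpublished for the
  motivating measurements, and the ratio is proportional to $1/z$.

## The synthetic generator

`monolayer_spec()` defines the ground truth; `generate_mask()` and
`render_pair()` realise it. The generator is the package's test bed: it
produces the study conditions, not a fit to any instrument.

* **Domain geometry.** `morphology = "disks"` places non-overlapping
  disks and regular 5–8-gons (randomly rotated) by random sequential
  adsorption, radii lognormal (log-sd 0.3) with the scale set by
  `coverage` and `n_domains`; placement stops when the realised coverage
  is within 0.01 of target. `"coagulated"` thresholds a
  Gaussian-smoothed white-noise field (correlation length ≈ 8 px) at the
  coverage quantile, giving irregular jointly-coagulated blobs.
* **Artifacts.** A tilt plane (defaults 0.002/0.004 nm px⁻¹, i.e. 1–2 nm
  across a 5 µm scan); deposition streaks — about one smooth full-length
  ridge per 20 scan lines, Gaussian cross-profile 1.5–4 px wide,
  amplitude ~0.05 nm — aligned with one axis; white Gaussian noise per
  channel (defaults $\sigma_h$ = 0.05 nm, $\sigma_V$ = 20 mV); and, on
  the potential channel only, an isotropic Gaussian tip blur (default
  σ = 20 nm = 2 px at the default 10 nm px⁻¹), reflecting the
  longer-range electrostatic averaging of KPFM relative to contact AFM.
* **Presets.** `control_like_spec()` (Δh 0.33 nm, ΔV 336 mV, disks,
  f = 0.27), `gs12_like_spec()` (0.28 nm, 304 mV, disks, f = 0.27) and
  `gs16_like_spec()` (0.57 nm, 658 mV, coagulated, f = 0.40) reproduce
  the measured contrasts of the three studied films. The two surfactant
  coverages are the package's own choices — the short-tail surfactant
  measurably leaves the domain structure unchanged (hence the control's
  coverage), while the long-tail one coagulates domains and increases
  coverage — since no coverage was published for those films.
* **Determinism.** All randomness derives from `spec$seed`; the
  mask-generation and rendering streams are offset so the same truth can
  be re-rendered. Blur uses separable convolution with half-sample
  symmetric reflection padding; that operator is symmetric and
  row-stochastic, hence doubly stochastic, so the channel mean is
  preserved to machine precision — a property the tests assert.

What the generator does **not** emulate: 1/f scan-line noise, feedback
overshoot at step edges, tip convolution of the *topography*, line-tension
domain shapes, or spatial variation of the true contrasts. Passing the
recovery tests therefore shows the estimators are unbiased under additive
white noise, smooth streaks, tilt and Gaussian potential blur — not that
they are robust to every instrument pathology.

## Levelling

`level_image()` removes a least-squares plane (`order = 1`) or mean
(`order = 0`). With `per_line = TRUE` it performs a **masked flatten**,
the standard treatment for phase-separated probe images, because two
naive alternatives are measurably biased:

* a plane fitted to all pixels is pulled by the domains whenever they
  cluster toward one side of the frame, leaving column-direction
  residuals comparable to the streak amplitude;
* a plain per-row median shears every scan line that is majority
  high-phase down by $\Delta h$, destroying the bimodal histogram (on
  coagulated films at f = 0.40 this cost 9 percentage points of
  coverage in development measurements).

The masked flatten classifies pixels with Otsu's threshold, refits the
plane on matrix-phase pixels only, subtracts per-row medians of each
row's matrix-phase pixels (rows with fewer than 8 such pixels inherit
interpolated offsets), and refines the classification once. It is
deterministic and needs no tuning.

## Coverage estimation

`histogram_threshold()` implements the minimum-between-peaks rule with
two safeguards. The histogram (256 bins by default — standard practice
for 512² scans) is smoothed by a moving average that starts at 5 bins and
widens until at most two significant local maxima survive (the classical
successive-smoothing minimum method); maxima below 1% of the tallest peak
are ignored, since a handful of outlier pixels otherwise forces runaway
smoothing. The threshold is the lowest bin strictly between the two
peaks. A `not_bimodal` condition is raised when fewer than two peaks
survive, when they are closer than 10 bins, or when the valley is
shallower than 80% of the lower peak — the signature of a single-phase
image, where "the two highest bumps" would otherwise be noise ripples on
one mode.

`coverage_particle()` labels the connected components of the thresholded
mask (8-connectivity by default, via 4-connected labelling plus merging
of diagonally adjacent labels), removes particles below `min_area`
(default 4 pixels), and sums the retained area. On noise-free two-level
images, both estimators return the ground-truth fraction exactly, and
they agree exactly with each other when filtering is disabled — the
tests assert both.

`model_average()` combines the two estimates as their mean with margins
added in quadrature, rounded to integer percent as such tables are
conventionally printed; the quadrature rule is an inference from how the
published combined margins behave, not a published formula.

For a single image pair the report's coverage margins come from the
spread of the four image-quadrant estimates (t-interval, n = 4) — the
desk-scale analogue of averaging repeated experiments.

## Cross-section contrasts

`sample_boundary_profiles()` draws `n_profiles` (default 100, matching
common practice of ~100 measurements per sample) random boundary pixels
of the segmentation mask and lays profiles of `length` (default 400 nm)
perpendicular to the local boundary, oriented by the gradient of the
smoothed mask. Two admission rules make random placement behave like an
analyst choosing clean cross sections:

* the mask must flip exactly once along the line (the step estimator's
  stated precondition);
* outside a window around that crossing the line must keep
  `clearance_px` (default 8 px ≈ 3 tip-blur widths, tested against a
  blurred-mask clearance field) away from all other boundaries —
  otherwise the blur tails of laterally nearby domains leak into the
  low-side plateau and bias $\Delta V$ low by 0.3–1.5%.

`step_delta()` classifies samples against the profile midrange, excludes
a central fraction (default `exclusion = 0.3`) around **every** class
transition and at the profile ends, and returns
`median(high) − median(low)`. The default exclusion clears 3 standard
deviations of the default tip blur on the default geometry (±6 px of an
80-sample, 40 px profile); a 20% window was measured to leave a −2.7 mV
blur residual. Transition-wise (not single-crossing) exclusion matters
because a profile that pierces a small domain exits through a second
blurred boundary; end trimming matters because a profile ending just
short of a boundary carries its blur tail without any detectable class
flip. Medians rather than means make the per-profile estimate robust to
streak ridges and stray outliers, and the whole estimator is exactly
equivariant under affine rescaling.

`aggregate_contrast()` summarises per-profile steps as mean ±
$t_{1-\alpha/2,\,n-1}\, s/\sqrt{n}$ (default 95%). A t-interval is used
because $n$ is finite and no distributional claim beyond approximate
normality of the per-profile steps is needed.

In the full pipeline (`run_analysis()`), the segmentation mask and the
profile geometry come from the *topography* channel (higher
signal-to-noise in the synthetic model) and are reused on the potential
channel, mirroring how AFM and KPFM image the same sample area; height
steps are measured on the levelled topography, potential steps on the
raw potential map, which needs no levelling and whose raw cross sections
are the conventional KPFM readout.

## Numerical and interface choices

* **File formats.** ASCII matrix (Gwyddion-style, `#` header keys
  `pixel_size_nm`/`channel`/`units`, 9 significant digits — round trips
  to < 1e-8 relative) and uncompressed IEEE-float TIFF written by the
  package itself. The TIFF writer defaults to 64-bit samples so the
  read–write round trip is bit-exact for double data (32-bit is
  available); general-purpose R TIFF writers clamp values outside [0, 1]
  and cannot carry nm/mV-scale floats.
* **Coordinates.** Row 1 is the top scan line; the column index is the
  fast axis; pixel `[i, j]` is centred at
  `((i − 0.5)·pixel_size, (j − 0.5)·pixel_size)`. Profile endpoints use
  pixel coordinates with integer values at pixel centres; interpolation
  is bilinear.
* **Degenerate inputs.** Constant images level to zero with a warning
  and raise `not_bimodal` when thresholded; constant profiles raise
  `no_step`; contrasts require at least two profiles. Errors are
  classed conditions (`validation_error`, `parse_error`, `not_bimodal`,
  `no_step`) so pipelines can react specifically; the CLI maps them to
  exit code 1 (runtime failures to 2).
* **Determinism.** Every stochastic entry point takes a seed and
  restores the caller's RNG state; `run_analysis()` is bit-reproducible
  for a fixed config and embeds a config hash in the report provenance.

## Problem sizes and validation

The test suite validates the estimators at the scales a desk run
affords: module-level properties on 128²–256² images (coverage recovery
within ±0.02 of truth across 20 seeds; monotonicity of recovered
coverage in the generator coverage), and full-pipeline parameter
recovery on 512² images for all three film presets across 10 seeds each,
requiring the pooled $\Delta h$ and $\Delta V$ to lie within three
standard errors of the generator truth and the recovered $\Delta V$
ordering (long-tail surfactant > control > short-tail surfactant) to
match the measured ordering. The noise-free limb of the suite asserts
exactness, not closeness.

## Known limitations

* The step estimator assumes two well-separated plateaus; films with a
  continuum of heights (three-phase coexistence, partial tilt order)
  violate the bimodal assumption and will be rejected rather than
  quantified.
* Coverage margins from four quadrants understate uncertainty when the
  domain pattern is strongly non-stationary across the frame.
* The charged-sheet interpretation ignores image charges, dielectric
  discontinuities and the tip's transfer function; it is an
  order-of-magnitude tool, which is also why the surfactant-per-lipid
  ratio is left parameterised in the probe height.
* Profile admission preferentially samples large, isolated domains; if
  the true contrast varied with domain size, the estimate would weight
  large domains — the generator's contrasts are uniform, so the tests
  cannot detect such weighting.
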