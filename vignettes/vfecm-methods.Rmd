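---
title: "Methods: windowed quantification of vocal-fold ECM microanatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed quantification of vocal-fold ECM microanatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfecm)
```

# Scope and model

The vocal-fold lamina propria (LP) is a layered connective-tissue body
whose collagen and elastin arrangement varies with depth (superficial SLP,
vocal-ligament transitions SVLT/IVLT, mid MID, deep DEEP). `vfecm`
quantifies that arrangement from two imaging channels:

* **SHG-like images** (second harmonic generation; collagen-specific)
  analyzed per 50 × 50 px window for fiber orientation, anisotropy and
  GLCM texture, plus fibrillar morphometrics;
* **OCT B-scans**, whose signal decays with depth according to the
  single-scattering Beer–Lambert model, analyzed for relative attenuation
  coefficients and layer thicknesses.

All windowed stages share one grid: 50-px windows with a 5-px gap (10% of
the window edge) between window *edges*, so adjacent windows never
overlap; edge windows that do not fit are dropped rather than padded,
because padding would bias both texture statistics and gradient energy.
Window origins are 1-based, row-major.

# Fiber orientation and anisotropy

Each window is first mapped to 8-bit gray scale (global min–max), then the
structure tensor is formed from the products of partial derivatives
$g_x, g_y$, each product field convolved with a Gaussian $K_\sigma$
($\sigma$ = 2 px, a standard deviation — chosen to match fiber diameters
of a few pixels) and averaged over the window:

$$S_T = \begin{pmatrix} K_\sigma * g_x^2 & K_\sigma * g_x g_y \\
K_\sigma * g_y g_x & K_\sigma * g_y^2 \end{pmatrix}, \qquad
\theta = \tfrac{1}{2}\,\mathrm{atan2}\!\left(2 J_{xy},\, J_{yy} - J_{xx}\right),\qquad
A = \frac{\lambda_{\max} - \lambda_{\min}}{\lambda_{\max} + \lambda_{\min}}.$$

Design notes:

* **Gradients** are analytic derivatives of interpolating cubic splines
  fitted along rows and columns (Forsythe–Malcolm–Moler end conditions),
  exact for polynomial profiles up to cubic. This keeps the noiseless
  stripe case exactly unidirectional ($g_x \equiv 0$, hence $A = 1$ to
  machine precision).
* **atan2 instead of an arctan quotient** resolves the quadrant and
  zero-denominator ambiguities; the two agree wherever the quotient is
  defined. Angles are counterclockwise-positive in the (col, −row) frame,
  so fibers parallel to the image horizontal — anatomically, the
  epithelium surface — give $\theta = 0$, and results are reported in
  (−90°, 90°]. Mapping to an anatomical frame on tilted acquisitions is a
  caller-side rotation.
* **One (θ, A) pair per window**: the smoothed tensor components are
  averaged over the window before eigen-analysis, since a single value per
  window position is what downstream statistics consume.
* **Smoothing boundaries**: the Gaussian kernel is truncated at 3σ with
  reflective boundaries inside each window, avoiding edge ringing on
  50-px windows.
* **Region aggregation**: orientations are axial (period 180°), so a
  plain mean is ill-defined near ±90°. Windows are centered on the
  circular mean of doubled angles, deviations wrapped into (−90°, 90°],
  and the arithmetic mean/SD taken there; e.g. {+89°, −89°} averages to
  ±90°, not 0°. Degenerate (constant) windows are flagged, excluded and
  counted.

Validation: θ recovered within 0.01° on noiseless phantoms at five
construction angles, eigen-consistency against direct 2 × 2
eigendecomposition to 1e-6 rad, A ≡ 1 on unidirectional scenes, A bounded
in [0, 1] on arbitrary windows, and mean A decreasing with both window
size (isotropic noise) and phantom orientation dispersion.

# GLCM texture

The co-occurrence matrix $P_{d,\theta}(i,j)$ is computed on per-window
min–max quantized images (8 levels by default — the common toolbox
default; configurable) for offsets $d \in \{1, 2\}$ px along 0/45/90/135°.
Counts are **symmetrized** (transpose added) so that opposite directions
are not double-counted when four angles already span 180°, then
normalized. The three features are averaged over all 8 (d, angle)
combinations into one value per window:

* contrast $\sum (i-j)^2 p(i,j) / (L-1)^2$, normalized to [0, 1];
* entropy $-\sum p \log_2 p$ — reported in **bits**; the base is
  configurable and recorded, since conventions differ;
* inverse difference moment $\sum p / (1 + (i-j)^2)$.

A constant window yields the degenerate triple (0, 0, 1), flagged. The
implementation is verified cell-by-cell against a brute-force double loop
over all pixel pairs (tolerance 1e-12) and against closed forms
(checkerboard → contrast 1, entropy 1 bit, IDM 0.5; uniform $P$ → entropy
$2\log_2 L$). OCT texture uses the same operations on the 5-frame-averaged
B-scan.

# OCT attenuation and layer segmentation

The processing chain is: average 5 consecutive frames → normalize by the
99.9th-percentile intensity (robust to isolated hot pixels; the constant
is recorded for auditability) → detect the surface → extract a depth
profile → fit and segment.

* **Surface detection** takes, per column, the first sample above an
  adaptive threshold (median of the air region + 6 MAD), with the air
  region estimated from rows above the first coarse rise of the row-mean
  profile; failed columns are interpolated from neighbors and the line is
  median-filtered. The threshold rule is this package's choice — surface
  finding is auxiliary plumbing, not part of the attenuation model.
* **The 45° midline** from the vocal-fold edge is sampled by bilinear
  interpolation, optionally averaging `n_avg` parallel lines to suppress
  residual speckle (the analogue of profile averaging across a volume).
  The edge column must be supplied by the caller (default: lateral
  midpoint); the anatomical edge cannot be inferred from pixels alone.
* **Fitting**: unweighted OLS of $\ln I$ on *physical* depth
  $z = \text{path} \cdot \cos(\text{angle}) / n$ in mm, with $n = 1.384$,
  so $\mu_t = -\text{slope}/2$ is in true mm⁻¹ (the factor 2 is round-trip
  attenuation). Coefficients are *relative*: no confocal or sensitivity
  roll-off correction is applied, and negative fitted values are flagged,
  never clamped. Nonpositive samples are dropped before taking logs.
* **Layer segmentation** minimizes the total squared error of per-segment
  straight-line fits to the log profile by dynamic programming over all
  breakpoint placements (minimum 5 samples per segment) — an exact
  optimum, O(K·L²) with cumulative-sum segment costs, comfortably fast at
  profile lengths up to a few thousand samples. Segment lengths converted
  by the cosine/index rule give physical layer thicknesses, which are
  additive by construction.

Validation: noiseless exponentials recover $\mu_t \in \{0, 0.15, 0.31,
0.54\}$ mm⁻¹ to 1e-9; breakpoints land within 2 samples of 3-layer phantom
truth; the segmentation SSE is never beaten by random breakpoint choices;
with exponential speckle and 1000-column averaging recovery is within 5%.

# Morphometrics

* **Fenestration fraction**: Otsu binarization (via `EBImage`); the
  fraction is void/(void + collagen) over the whole window, matching a
  volume-fraction reading. Otsu is scale-invariant, so the measure is
  unaffected by linear intensity rescaling. Constant windows fall back to
  a fixed threshold and are flagged.
* **Fiber diameter**: median over ≥ 10 stations of the FWHM of the
  intensity profile perpendicular to a supplied centerline (half-maximum
  crossings located by linear interpolation). On a Gaussian ridge of
  standard deviation $\sigma_g$ this returns $2.355\,\sigma_g$ by
  construction, which makes the generator (FWHM-parameterized) and the
  estimator self-consistent. Automatic fiber tracing is out of scope:
  centerlines come from phantom truth in tests and from the caller on
  real images.
* **Waviness**: the centerline is projected on its principal axis, the
  transverse displacement linearly detrended and uniformly resampled;
  local extrema with magnitude ≥ 20% of the displacement SD mark peaks
  and valleys. Period = mean peak-to-peak spacing; amplitude = mean
  absolute extremal displacement (half peak-to-valley). The *global*
  (bundle-scale) variant first applies a moving-average low-pass with
  cut-off 3× the local period — the scale-separation rule is this
  package's documented choice, validated on a superposition of 18 µm and
  97 µm sinusoids.
* **Layer thickness**: successive boundary differences × pixel pitch,
  with the cosine/index correction applied for OCT-derived boundaries.

# Synthetic phantoms: what they emulate, and what they do not

The generators define the validation conditions and are first-class,
tested code. All randomness flows from one integer seed through
stage-specific sub-seeds, so generators are pure functions of their spec
and sub-stages are independently reproducible; ambient RNG state is saved
and restored.

**Fiber phantoms** render Gaussian-cross-section ridges (FWHM = the
specified diameter) whose centerlines follow
$v(u) = c + a\sin(2\pi u/\lambda)$ in a frame rotated by the dominant
orientation — so a phantom at angle φ *is* the 0° phantom rotated by φ,
giving exact rotation-equivariance fixtures without interpolation.
Fenestrations are zeroed elliptical holes (axes 3–10 px, aspect ≤ 3,
dart-throwing placement) accumulated until the void fraction is within one
percentage point of target. Defaults: 0.43 µm/px pitch (a ~440 µm field on
1024 px), 2.1 µm diameter, λ = 18 µm — magnitudes typical of superficial
LP collagen. Additive Gaussian noise is a stand-in for detector noise; no
PSF, depth sectioning, or fiber crossing statistics of real tissue are
modeled. Recovery tests therefore show estimator correctness on scenes
satisfying the model assumptions, not performance on real tissue.

The fenestration-recovery condition uses a *dense* mesh (800 fibers of
4 µm on 300² px) so that the uncarved background is fully
collagen-covered, emulating the dense mid-LP lacework in which
fenestrations are defined; on sparse scenes Otsu correctly counts
inter-fiber gaps as void, which is a property of the scene rather than an
estimator error.

**OCT phantoms** build laterally homogeneous layered media: below a flat
surface the mean profile is $I_0 \exp(-2\int \mu_t\,dz)$ with piecewise-
constant $\mu_t$ (the last layer extends to the bottom of the scan), depth
converted from optical pitch through $n = 1.384$. Speckle is multiplicative
unit-mean exponential intensity noise, i.i.d. per pixel and frame — the
standard first-order statistics of fully developed speckle — so frame and
lateral averaging behave like real speckle reduction ($\sigma/\sqrt{k}$),
while spatial speckle correlation, sensitivity roll-off, motion and
refraction at tilted interfaces are deliberately not modeled. Default
layer truth (thicknesses 293.3/837.6/653.2 µm, $\mu_t$ = 0.31/0.54/0.15
mm⁻¹) represents a realistic SLP/MID/DEEP scenario. Rows above the surface
carry weak detector noise so surface detection has a genuine air region to
estimate.

A law-of-large-numbers check confirms the speckle model: the mean over
8000 A-lines × 5 frames matches the noiseless profile within 2% at every
depth. (At exactly 1000 A-lines the per-depth standard error of
unit-exponential speckle is ~3%, so a 2% everywhere-bound genuinely
requires the larger ensemble.)

# Statistics

Per-window values (50 per region in the reference protocol) are compared
across regions by one-way ANOVA and Tukey's range test; unbalanced groups
use the Tukey–Kramer adjustment (`stats::TukeyHSD`). Three significance
tiers are reported (P < 0.05, < 0.01, < 0.001), the last being the
"extremely significant" convention; the ANOVA F is verified against a
hand sums-of-squares oracle to 1e-10 and Tukey p-values against a
permutation oracle on a two-group fixture. Summary tables emit per-region
mean ± SD for the SHG layout (thickness, fiber OD, orientation,
anisotropy, fenestration fraction) and the OCT layout (thickness, μ_t);
absent features are emitted empty, never fabricated, and CSV round-trips
reproduce the in-memory table exactly.

# Problem sizes and numerical choices

Test phantoms are sized for tight feedback: 110–300 px SHG scenes
(9–30 windows), 600-sample A-lines, 400–1000 columns for speckle
averaging, 8000 A-lines for the law-of-large-numbers check. Key
tolerances: structure-tensor exactness cases at 1e-6–1e-12; GLCM oracle at
1e-12; noiseless attenuation at 1e-9; stochastic recovery at 2–10%
depending on the averaging each scenario supports. Degenerate inputs
(constant windows, all-noise B-scans, straight centerlines, non-monotone
boundaries) return flagged results or errors rather than numbers without
meaning.

Known limitations: no automatic fiber tracing; no per-pixel orientation or
attenuation maps (windowed/per-layer only); no polarization-resolved
contrasts; phantoms are 2D and do not model optical sectioning or speckle
correlation; the anatomical edge column and any image-rotation
preprocessing are caller responsibilities.
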