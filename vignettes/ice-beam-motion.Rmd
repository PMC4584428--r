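---
title: "Quantifying beam-induced motion of water from dose-fractionated Thon rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beam-induced motion of water from dose-fractionated Thon rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icemotion)
```

## The physical picture

A bright-field cryo-EM image of an amorphous specimen shows Thon rings:
concentric oscillations of the power spectrum following the squared
contrast-transfer function (CTF).  Amorphous ice produces a strong
scattering band near 3.7 Å (planes of next-nearest-neighbour oxygen atoms
of tetrahedrally coordinated water), so its Thon rings are concentrated in
a band around u = 1/3.7 Å⁻¹.

During an exposure the beam continuously rearranges the water: radiolysis
products recombine and reorient the network, so each incident electron sees
a slightly different configuration.  The package models this as a Gaussian
Markov process: after a fluence of $d$ electrons/Å², each molecule's
position has moved by an isotropic Gaussian step with per-axis variance
$d\,\sigma_0^2$.  The single physical parameter $\sigma_0^2$ (Å² per
e⁻/Å², per axis) sets everything else:

* the Fourier component of the structure at frequency $u$ decorrelates
  between exposures $i$ and $j$ as $\exp(-\alpha_u |i-j| d)$ with
  $\alpha_u = 2\pi^2 \sigma_0^2 u^2$ (`alpha_u()`, `frame_correlation()`);
* summing $M$ frames of fluence $d$ each gives the closed-form expected
  power spectrum of `spectrum_discrete()`, with limits $M^2 d^2 F_0^2$
  (rigid specimen) and $M d^2 F_0^2$ (uncorrelated frames);
* in the continuous-motion limit ($M \to \infty$, $Md = D$) the spectrum
  becomes $2F_0^2[\alpha_u D + e^{-\alpha_u D} - 1]/\alpha_u^2$
  (`spectrum_continuous()`).

## The measurement

The observable is $W_{M,m}(u)$: the sum of the $M/m$ noise-whitened power
spectra obtained by summing the movie's frames in consecutive blocks of
$m$ (`block_sum_nwps()`).  Its background is $\Gamma_M = Md/\mathrm{DQE}(0)$
per Fourier pixel independent of $m$, while its noise grows as $\sqrt m$
(`predicted_background()`, `predicted_noise()`).  The ring signal above
background at a chosen frequency grows with the block fluence $md$ as

$$W_{M,m}(u) - \Gamma_M \;\propto\; g(z), \qquad
  g(z) = \frac{z + e^{-z} - 1}{z}, \qquad z = \alpha_u\, m\, d ,$$

linear at small $z$ and saturating towards a plateau.  Fitting this
saturation curve over the divisors $m$ of $M$ with two parameters —
$\sigma_0^2$ and a scale — recovers the motion parameter
(`block_series()`, `fit_sigma0()`).  The scale absorbs the total fluence,
the electron-optical terms, and the scattering strength and thickness of
the film, none of which need to be known.

Because the signal grows as $g(z)$ while the noise grows as $\sqrt z$, the
ring signal-to-noise is maximal at the root of
$\tfrac{d}{dz}[g(z)/\sqrt z] = 0$, i.e. $1.5 - 0.5z = e^{-z}(z + 1.5)$,
which `snr_optimum_z()` brackets to $z^\ast = 2.1491$.  (The companion
description of this optimum divides by $z$ rather than $\sqrt z$ in one
place; only the $g(z)/\sqrt z$ objective actually has its stationary point
at 2.149, and the $\sqrt z$ form is what the $\sqrt m$ noise growth
implies, so that is what is implemented.)  The optimal fluence per image
at frequency $u$ is then $d_\mathrm{opt} = z^\ast/(2\pi^2\sigma_0^2 u^2)$
(`optimal_dose()`), about 4.0 e⁻/Å² at $u = 1/3.7$ Å⁻¹ for
$\sigma_0^2 = 0.37$.

## Detector model and whitening

The detector's response to one electron has mean gain $\bar g$ and
variance $\sigma_g^2$, giving $\mathrm{DQE}(0) = \bar g^2/(\bar g^2 +
\sigma_g^2)$; the default $\bar g = 1$, $\sigma_g^2 = 1$ reproduces the
DQE(0) ≈ 0.5 of the detector used for the analysed exposures.  Per-electron
gains are gamma distributed (the distribution is constrained only through
its first two moments; a gamma is the natural non-negative choice), and
the point spread is applied after the per-pixel noise by Fourier
multiplication, mirroring a charge-diffusion-dominated sensor whose DQE
does not fall with its MTF.

The noise power spectrum is modelled as a radially symmetric falling
transfer function $B(|u|) = \exp(-\sum_j \beta_j |u|^j)$, $\beta_j \ge 0$,
plus its first-order aliased replicas, rescaled to $N(0) = 1$
(`evaluate_nps()`).  Whitening, $W(u) = S(u)/N(u)$, makes the
specimen-free background flat with exponentially distributed values of
mean and SD $\Gamma = d/\mathrm{DQE}(0)$ (`background_stats()` checks both
the SD/mean ratio and a Kolmogorov–Smirnov distance).  `fit_nps_model()`
fits the same family to a measured specimen-free spectrum (least squares
on log power) and warns when the whitened residual shows structured radial
deviation, which indicates specimen contamination of the calibration data.

## Thickness and blur extrapolations

Defocus varies through a film of thickness $t$, damping the ring
*modulation* (not the band amplitude) by $\sin\xi/\xi$ with
$\xi = \pi\lambda u^2 t$ (`thickness_envelope()`): averaging
$\mathrm{CTF}^2$ over the defocus spread gives
$\tfrac12(1 - \tfrac{\sin\xi}{\xi}\cos 2\gamma)$, so the oscillation rides
on an undamped band.  At $t = 1250$ Å and $u = 1/3.7$ Å⁻¹ with 300 keV
electrons, $\xi = 5.65$ and the modulation is about 10%, with a node
expected at $u = 1/\sqrt{\lambda t}$; absence of a node out to $u$ bounds
the thickness below $1/(\lambda u^2)$ (`first_node_thickness()`, ≈700 Å at
1/3.7 Å⁻¹).  A burn-through count converts to thickness at ~100 Å per
170 e⁻/Å² (`thickness_from_burnthrough()`).

The fitted motion extrapolates to embedded macromolecules as
pseudo-Brownian blur: the total MSD rate is $3\sigma_0^2$
(`msd_3d_rate()`), the water RMS displacement after fluence $D$ is
$\sqrt{3\sigma_0^2 D}$, and a particle with diffusion coefficient
$D_w/R$ moves $1/\sqrt R$ as far (`particle_rms()`).  The blur B-factor
uses the per-axis convention $B = 8\pi^2\langle u_x^2\rangle =
8\pi^2\,\mathrm{rms}^2/3$ (`blur_bfactor()`); B conventions differ by a
factor 3 between per-axis and total variance, so this choice is stated
wherever a B value is reported.  The Stokes–Einstein
$MW^{1/3}$ rule gives $R \approx 17.7$ for a bare 100 kDa particle;
hydration and shape push the physical ratio into the 20–40 range, so
`particle_rms()` accepts an explicit `diffusion_ratio` (30, the midpoint,
reproduces the ≈1 Å / ≈25 Å² values quoted for hexokinase).

## The simulators

Two generators produce movies with the statistical structure the analysis
assumes, so every stage is testable without microscope data.

**Spectral simulator** (`simulate_movie_spectral()`).  The structure
component of each frame is synthesised directly in Fourier space: a
stationary Gaussian field on a radial band centred at 1/3.7 Å⁻¹ (Gaussian
profile, σ = 0.04 Å⁻¹), modulated by the defocus-averaged transfer
$\tfrac12(1 - \tfrac{\sin\xi}{\xi}\cos2\gamma)$, evolving across frames as
an AR(1) chain with per-frequency correlation $e^{-\alpha_u d}$.  Each
frame's fluence is subdivided into `substeps` AR steps whose average forms
the frame (default 16).  This detail matters quantitatively: molecules
move *during* a frame, and the saturation-curve model is the
continuous-motion limit.  A frozen-frame AR(1) simulation fitted with
$g(z)$ would overestimate $\sigma_0^2$ by ~50% at the default exposure
(2.33 e⁻/pixel/frame); 16 substeps reduce the residual model bias below
0.3%.  With `substeps = 1` the simulator realizes exactly the
discrete-frame covariance of `spectrum_discrete()`, which is what the
particle simulator produces and what the oracle-equivalence tests use.

**Particle simulator** (`simulate_movie_particle()`).  An explicit point
process: scatterers are placed in a 3D slab by sequential rejection with a
hard core at 0.85×3.7 Å and a preference for neighbours at 3.7 Å, giving
a pair-correlation peak at the ice spacing; each frame projects them with
a Gaussian footprint (deposited on a 2× oversampled grid to keep binning
alias noise negligible), filters by the CTF (or its defocus-averaged
square root), and displaces every scatterer by the per-frame Gaussian
step.  It is the physics oracle: it knows nothing of the closed forms it
is tested against.  Its number density (2×10⁻⁴ Å⁻³) is a sparse surrogate
for real water — simulating 0.033 Å⁻³ would be five hundred times the
points for no statistical benefit at these image sizes — with the render
contrast compensating.

Both simulators then pass the expected intensity through the stochastic
detector (Poisson counts × gamma gains, NPS-shaped blur).  Expected
intensities are clamped at zero; at the default structure amplitude the
clamp touches ~0.3% of pixels and its rectification power is orders of
magnitude below the shot noise.

What the generators do **not** emulate: per-pixel gain-map errors and the
frame-to-frame readout correlations of real hardware (the anchor-shift
correction `anchor_shift()` exists for real data but is off by default for
simulations), radiolysis mass loss (a slowly decaying scale factor),
charging, stage drift, and multiple/inelastic scattering in thick ice.
Passing tests therefore demonstrate the statistical machinery and the
estimator, not robustness to those instrumental effects.

## Numerical choices

* Frequencies are cycles/pixel internally; conversion to Å⁻¹ happens once,
  in `radial_average()`.  `dose_to_fluence()` is the single place where
  e⁻/pixel becomes e⁻/Å².
* The DC term is excluded from every statistic; radial bins are half-open
  `[lo, hi)`, one Fourier pixel wide by default, and for even sizes the
  Nyquist row/column enters once.
* Background statistics use one member of each Hermitian pair of Fourier
  coefficients, so the pooled values are independent; circular-average
  noise predictions divide by $\sqrt{\mathrm{count}/2}$ for the same
  reason.
* `spectrum_discrete()` evaluates its inner difference by an exact power
  series when $\alpha_u m d < 0.5$, avoiding the catastrophic cancellation
  of the closed form near zero decorrelation; `g_of_z()` and
  `spectrum_continuous()` switch to series below $z = 10^{-4}$.
* `fit_sigma0()` profiles out the linear scale on a 60-point log grid over
  $\sigma_0^2 \in [10^{-3}, 10]$ and polishes with Levenberg–Marquardt on
  log parameters (positivity by construction, deterministic given data).
  Weights are the Eq.-(9)-style predictions per circular-average bin.
  A series with no point exceeding 3× its error, or a fitted curve that is
  flat to 0.1% over the measured $m$ range, is reported unidentifiable.
* The anchor band is the top 10% of frequency bins rather than the single
  Nyquist bin: on a square grid the literal last annulus holds only a
  handful of Fourier pixels and a constant estimated from it would be
  noisier than the signal being corrected.
* The CTF sign convention is $-[\sqrt{1-A^2}\sin\gamma + A\cos\gamma]$,
  underfocus positive, so ring maxima are bright; amplitude contrast
  defaults to 0 for pure ice and Cs to 0 (secondary at 7070 Å defocus for
  u ≤ 1/2.08 Å⁻¹).

## Study conditions and problem sizes

The default `sim_config()` reproduces the acquisition geometry of the
analysed exposures — 1.04 Å pixels, 300 kV, 7070 Å defocus, 120 frames at
2.33 e⁻/pixel/frame (or 0.85 for the slower exposure), DQE(0) = 0.5,
thickness 1250 Å — at a 256² field, a desk-scale stand-in for the 4k
detector.  The whitened structure amplitude (`f0_peak = 1.2` per e⁻/pixel,
ring power ≈ 3.9 counts² per frame against a background of 4.66) is a
loose calibration: no absolute contrast scale for ice is available, so it
was chosen once to give a plateau-to-background ratio of ~3 in the
block-summed curves, comparable to the measured curves' appearance, and
the parameter-recovery experiments hold at the resulting signal-to-noise.
The test suite exercises reduced sizes (mostly 128², 8–16 frames; the
recovery and background-statistics checks run at 256² and 120/24 frames),
chosen as the smallest grids at which the statistical tolerances are
meaningful.

## Known limitations

* $\sigma_0^2$ estimates from single movies carry a few-percent systematic
  floor (background-subtraction correlations across $m$, band-averaged
  decorrelation rates); the recovery experiments bound the combined bias
  at the study conditions to a few percent of the generative value.
* The saturation-curve fit assumes a single dominant frequency band; no
  joint multi-band fit is provided.
* The NPS fit family (monotone exponential-polynomial radial basis) covers
  smooth falling transfer functions; a detector with non-monotone NPS
  structure would need a different basis.
* MRC I/O is deliberately minimal: mode-2 float, square frames, no
  extended headers.
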