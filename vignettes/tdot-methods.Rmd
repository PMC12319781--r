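---
title: "Models and methods in tdot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tdot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tdot` is a desk-scale computational model of a multiplexed, dual-wavelength
(690 / 905 nm) time-domain optical brain-imaging system. This vignette
records the models it implements, the assumptions behind them, the
parameters that matter, and the numerical and design choices that were
genuinely open.

## Forward model

Light propagation is modeled with the diffusion approximation in a
semi-infinite homogeneous medium. The time-resolved surface reflectance
uses the extrapolated-boundary realization of the Robin boundary
condition: an isotropic point source at depth $z_0 = 1/\mu_s'$, a
zero-fluence plane at $z = -z_b$ with $z_b = 2AD$, $D = 1/(3\mu_s')$, and
the internal-reflection parameter $A(n)$ from the Groenhuis polynomial.
Conventions: distances in mm, times in ps, $v = c/n$ with the medium's own
refractive index, photon time origin at pulse emission, and $D$
independent of $\mu_a$ (the modern convention, which makes the absorption
scaling $R(t;\mu_a+\delta) = R(t;\mu_a)e^{-\delta v t}$ exact).

Assumptions and limits:

* validity requires source–detector separations of at least a few
  transport mean free paths ($\rho \gtrsim 3/\mu_s'$); shorter channels
  are flagged, not refused;
* no non-diffusive (e.g. clear cerebrospinal-fluid) regions, no
  radiative-transfer corrections;
* curved heads are handled only through per-module rigid placements of
  locally flat modules; all quantitative tests run on slab or
  semi-infinite media.

The time-integral of the implementation is cross-checked against the
closed-form continuous-wave reflectance, and the curve itself against an
independent 1-D finite-difference diffusion solver (the lateral dimensions
separate as Gaussians when $D$ is homogeneous, so a 1-D solver in depth is
an exact oracle up to discretization).

## Sensitivity kernels and two-layer media

Voxel-level sensitivities use the first-order Born expansion: the
absorption kernel of a channel is the time convolution of the
source-to-voxel and voxel-to-detector Green's functions of the
homogeneous reference medium, with both optodes represented as isotropic
points at depth $z_0$ (adjoint construction; reciprocity holds by
symmetry). Scattering kernels use the gradient-product Born term with
$\partial D/\partial\mu_s' = -3D^2$; the weak dependence of $z_0$ and the
boundary term on $\mu_s'$ is neglected, so only the absorption kernels
carry quantitative oracle tests. Two-layer media are realized as
voxelized slabs with layered baseline properties over a homogeneous
reference (rather than a stacked-slab Green's function): the inversion
mathematics downstream is identical, and the voxel basis is what the
reconstruction uses anyway.

Time-resolved kernels are mapped to the three data types by moment
propagation: $J_N = \sum_t J(t)$,
$J_{m_1} = (\sum_t t J(t) - m_1 J_N)/N$,
$J_V = (\sum_t (t-m_1)^2 J(t) - V J_N)/N$. Because the mapping is the
standard construction rather than a quoted derivation, it is verified
against finite differences of two forward runs (bulk absorption
perturbations, tolerances 2–5%), and the full stacks against the layered
1-D solver (10%). The quadrature bias of the kernel convolution shrinks
with the time bin; oracle tests therefore use 5–10 ps bins, while
reconstruction stacks use 20 ps bins where a few percent bias is
immaterial relative to regularization bias.

## Virtual instrument

The synthetic-data generator emulates the measurement chain so every
downstream stage is testable without instrument data:

* **IRF**: exponentially modified Gaussian per wavelength, parameterized
  by FWHM (240 / 270 ps at 690 / 905 nm) and exponential tail constant
  (292 / 265 ps); the Gaussian width is solved numerically from the
  requested FWHM. Thermal drift from cold start follows a saturating
  exponential (time constant 2400 s) with total FWHM drift +45 / +35 ps;
  centroid drift (+20 ps) and intensity drift (−5%) are not separately
  published figures and are our realism choices.
* **Multiplexing**: 3.5 ms integration, 38 laser states, 76 histograms
  per full cycle; all rates are pure functions of these numbers.
* **DTOF formation**: measurement $=$ TPSF $\circledast$ IRF, scaled by a
  coupling gain fixed by the *inclusion-free* medium at the target count
  level (so absorbing targets genuinely remove photons), then Poisson
  shot noise. Histogram bin width is configurable; measurement-like data
  default to 25–50 ps, model curves to 10 ps.
* **Scenes**: the MEDPHOT-style grid spans $\mu_s' \in \{0.5, 1.0, 1.5,
  2.0\}$ mm⁻¹ × $\mu_a \in \{0.005, 0.015, 0.025\}$ mm⁻¹ (the published
  phantom calibration values are not public; these cover the
  physiological range of head tissue). Depth-scan occlusions are
  emulated as volume-matched local absorption increases applied through
  the Born kernel — truly opaque targets violate the linearization, so
  only contrast *curves* are meaningful, not absolute equivalence.
* **Task sessions**: block paradigms (breath hold 6×20 s holds
  interleaved with 6×30 s paced blocks at a 6 s cycle; auditory 8 story
  + 7 noise 20 s blocks after 10 s rest; finger tapping 10 blocks per
  side, 17.3 s with 13 trials of 0.75 s / 0.5 s ITI) drive deep-layer
  HbO/HbR responses (block wave ⊛ canonical HRF) per labeled region;
  superficial physiology (cardiac 1.1 Hz with respiratory sinus
  arrhythmia, respiration 0.25 Hz, Mayer 0.1 Hz, slow drift) is shared
  across channels. A fraction (0.3) of the physiological oscillation is
  also placed in the deep layer: cerebral vasculature carries systemic
  pulsatility — that is what makes heart-rate extraction from long
  channels possible — and a deep layer free of any physiology would be
  an idealization no real recording satisfies.
* **Noise in feature space**: channel moment time series carry Gaussian
  noise with the exact Poisson moment variances ($\mathrm{var}(N) = N$,
  $\mathrm{var}(m_1) = V/N$, $\mathrm{var}(V) = (m_4^c - V^2)/N$), which
  is faster than resampling full histograms and accurate at the
  $10^5$-count level the generator defaults to.

What the generator does **not** emulate: motion artifacts beyond injected
spikes/steps, hair- or coupling-dropout statistics beyond a per-channel
gain, detector afterpulsing and dead time, wavelength crosstalk, and any
head-shaped geometry. Passing tests therefore demonstrate correctness of
the algorithms under the stated physics, not performance on real heads.

## Characterization metrics

The DNL, afterpulse-ratio, responsivity, contrast/CNR and stability
normalizations are direct transcriptions of their definitions and are
tested by direct arithmetic. Width metrics interpolate the 50/10/1%
crossings linearly and fit the tail decay log-linearly between 50% and
0.05% of the peak. The absolute-property fit uses Levenberg–Marquardt on
log-parameters (positivity without constraints) with Poisson weights
$1/\sqrt{\text{model}}$ inside the window from 80% of the peak on the
rising edge to 0.1% on the falling edge; the amplitude is a third free
parameter, the start values default to the middle of the physiological
range, and non-convergence is flagged, never silent. No time-shift
parameter is fitted because simulation and model share an absolute time
axis; fitting real data with uncalibrated delays would need one.

The depth-scan analysis reports, per measurand, the deepest depth at
which $|CNR| \ge 2$. Two count levels matter: the count-matched protocol
variant ($10^6$ per accumulation, the function default) and the
1-s-accumulation variant at instrument-scale count rates ($\sim 10^8$),
which is what the gate-level analysis needs — IRF deconvolution amplifies
high-frequency noise roughly tenfold at the gate level, so late-gate
detectability at $10^6$ counts is noise-limited rather than
physics-limited.

## Hemodynamic pipeline

Per channel and wavelength, feature changes (relative intensity,
$\Delta m_1$, $\Delta V$) are inverted through the 3×2 layered
sensitivity matrix by least squares. The solve is inverse-variance
weighted with the Poisson feature noise; without weighting, the variance
row dominates by numeric scale ($\sim$ps² against a relative intensity)
and the layer estimates inherit the noisiest feature. The deep-layer
$\Delta\mu_a$ at both wavelengths is mapped to $\Delta$HbO/$\Delta$HbR
through the extinction matrix (vendored Gratzer/Prahl tabulation,
converted to mm⁻¹µM⁻¹; all chromophore tests are round trips and do not
depend on the tabulation's accuracy).

Conditioning stages, in order: TDDR motion correction, cubic-spline
spike repair, 100-s moving-average detrend, short-channel regression.
Numerical choices worth recording:

* **TDDR** iterates Tukey-biweight weights (tuning constant 4.685 on
  MAD-standardized centered derivatives, tolerance $10^{-6}$, max 50
  iterations) and re-integrates, preserving the mean. When the sampling
  rate is known it operates on the <0.5 Hz component and reattaches the
  high-frequency residual, as in the original formulation. We add a
  *repair gate*: if no derivative receives zero weight, the input is
  returned unchanged. The soft reweighting has an expected
  influence-function slope of about 0.77 on artifact-free Gaussian
  derivatives, i.e. it shrinks everything, including 20–25% of a block
  response; a repair stage should be the identity on records with
  nothing to repair, which also matches its intended behavior on clean
  signals.
* **Spike repair** flags samples adjacent to derivative outliers
  (robust z > 5) but confirms a flag only when the sample itself
  deviates from the local median of clean neighbors, so the samples
  flanking a spike are untouched; boundary spikes get the nearest clean
  value.
* **Short-channel regression** uses the *superficial-layer* solution of
  the 8.5 mm channels as the nuisance regressor. In a linear simulation
  the short channels' deep-layer estimate contains the task signal by
  construction (the solve is exact in expectation), so regressing the
  raw short-channel signal would subtract brain activity; the
  superficial solution is the quantity that is actually scalp-dominated.
* Amplitude-recovery checks fit the GLM with the unmodified design; the
  pipeline recovers injected 1 µM block amplitudes within the stated
  20% band without design-matched filtering.

Heart rate uses a 0.5–2.5 Hz band-pass and a short-time spectral ridge
with parabolic interpolation; confidence is the fraction of band power
within ±0.15 Hz of the ridge.

## GLM and epochs

The canonical HRF is the double-gamma (peak 6 s, undershoot 16 s, ratio
1/6; only "canonical" is specified upstream, this is the common
parameterization). Drift columns: intercept, linear term, and a cosine
basis up to 1/128 Hz. Contrast inference is ordinary least squares with
$t = c^\top\beta / \sqrt{\hat\sigma^2 c^\top (X^\top X)^{-1} c}$,
$\mathrm{dof} = n - \mathrm{rank}(X)$; rank-deficient designs fall back
to a pseudoinverse with a warning. No multiple-testing correction is
applied to channel maps by default. Epoching windows [−5, 30] s around
block onsets, baselines each epoch by its own [−5, −1] s mean, and drops
epochs that extend outside the recording (with a warning) rather than
padding.

## Reconstruction

Jacobian stacks hold (data types × channels) rows by (voxels × {μa, μs′})
columns; intensity rows are relative (d$N$/$N$), so the unknown per-channel
coupling gain cancels. Each data-type block is normalized to [−1, 1] by
its maximum absolute entry and the same factors are applied to the data,
giving the data types equal weight. Inversion uses the wide-form
Tikhonov pseudoinverse $X = J^\top(JJ^\top+\lambda I)^{-1}Y$ via Cholesky
factorization (never an explicit inverse), with
$\lambda = 0.1\,\lVert JJ^\top\rVert_F$ by default (not optimized,
configurable). Time series are reconstructed differentially at 1 Hz —
each sample against the previous one — and the increments are
cumulatively integrated so voxel time courses are relative to the first
frame; whether to integrate was an open choice, and cumulative
integration is ours (it makes the voxel time course directly comparable
to the injected waveform and to channel-space epochs). Both μa and μs′
columns are retained in the stack; chromophore mapping uses only Δμa,
with Δμs′ kept as a nuisance estimate.

Problem sizes: package tests and the acceptance checks run a single
18-channel module over a 16×16×8 voxel basis at 4 mm spacing with 20 ps
kernels, and 10-block sessions of 400 one-second frames; these sizes
make every oracle comparison exhaustive while keeping the full suite in
the minutes range. The same code paths scale to denser layouts
unchanged.

## Known limitations

* The Born kernels linearize around a homogeneous reference; strong or
  extended perturbations (true black occlusions, large Δμa fields)
  violate first-order accuracy — by design only contrast shapes and
  orderings are asserted for such scenes.
* Reconstruction depth accuracy is limited by the well-known depth bias
  of linear DOT; localization tests assert voxel-scale (≤ 8 mm)
  agreement, not exact centroids.
* The session container is a plain-text directory (CSV/JSON/TSV); no
  HDF5 binding is required, at the cost of compactness for very large
  DTOF stacks.
* Whole-head module placements are illustrative
  (`demo_headset_layout()`); printed per-module coordinates of any
  physical headset are not reproduced, so whole-head channel counts are
  not asserted quantities.
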