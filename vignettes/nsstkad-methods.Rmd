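---
title: "Shearlet-domain ultrasound denoising: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shearlet-domain ultrasound denoising: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsstkad)
```

## The problem

B-mode ultrasound images carry strong granular interference (speckle) and
acquisition noise that obscure small structures — in renal imaging, the
fine edges of calculi and the dark acoustic shadows behind them. Spatial
filters (median, mean, Wiener) trade noise suppression against edge
blurring. This package implements a transform-domain approach that treats
the two failure modes separately: directional high-frequency content is
denoised by adaptive hard thresholding in a shift-invariant shearlet
frame, and the low-frequency approximation — where residual low-frequency
noise survives any band thresholding — is smoothed by an edge-preserving
anisotropic diffusion whose conductivity is computed in a Gaussian-kernel
feature space.

## The nonsubsampled shearlet transform

`nsst_filterbank()` builds frequency-domain analysis windows on the exact
DFT grid of the target image:

* a **radial Meyer pyramid**: smooth low-pass profiles with cut-offs at
  dyadic radii $\pi/2^j$ define bandpass annuli
  $B_j = \sqrt{L_{j-1}^2 - L_j^2}$ (a nonsubsampled Laplacian pyramid
  realised in the Fourier domain);
* **angular Meyer wedges**: per scale, $d$ smooth windows in orientation
  (angle modulo $\pi$, spacing $\pi/d$) whose squares sum to one; they
  tile the two frequency cones of the cone-adapted shearlet system, and
  the window for direction $k$ and its counterpart $d/2 + 1 - k \pmod d$
  are mirror images across the frequency diagonal.

The transition profile is the standard Meyer polynomial
$\nu(t) = t^4(35 - 84t + 70t^2 - 20t^3)$, which satisfies
$\nu(t) + \nu(1 - t) = 1$; adjacent squared windows therefore sum to one
and the whole bank satisfies the partition of unity
$L_R^2 + \sum_{j,k} |U_{j,k}|^2 = 1$ at every frequency (machine
precision; the shipped check `partition_residual()` certifies $<10^{-6}$).
Analysis and synthesis use the same windows, so the frame is tight:
`nsst_inverse(nsst_forward(x))` reproduces `x` to round-off, and subband
energies sum exactly to the image energy.

Two discrete-grid choices matter:

* On even-sized grids the $\pm\pi$ Nyquist identification breaks the
  evenness of the continuous angular windows, which would leak energy into
  imaginary parts. Each directional window is therefore symmetrised in
  squared magnitude with its frequency-negated copy; this preserves the
  partition of unity exactly and keeps coefficients of real images real
  (the conjugate product in the subband-variance statistic then reduces to
  a plain square).
* Filtering is periodic (native to the FFT). Border artifacts are expected
  within a few pixels of the frame and the metrics take a `crop` argument
  (8 pixels by default in the benchmark) to exclude them.

Defaults are 3 scales with (8, 8, 4) directions, finest first — enough
directional selectivity for oriented edges while keeping a 256×256 image
denoisable in about a second. The printed dilation/shear constants of the
textbook construction are not exposed as tunables; the bank is fully
determined by the shape, scale count and direction counts.

## Thresholding the high-frequency subbands

The scale weight
$$W(r) = \alpha \, \frac{\ln(r + 1)}{r}, \qquad r = 1 \text{ finest},$$
is strictly decreasing, so the finest scale — where the noise-to-signal
ratio is worst — receives the largest threshold. The global noise level
$\phi$ is estimated robustly as $\mathrm{median}(|c|)/0.6745$ pooled over
the finest directional subbands (`estimate_global_noise_std()`); for
white image noise of standard deviation $\sigma$, each subband receives
noise variance $\sigma^2 \cdot \overline{|U_{j,k}|^2}$, and the bank
stores these **noise gains**, so $\phi$ is mapped into any subband as
$\phi_{j,k} = \phi \sqrt{g_{j,k} / \bar g_1}$.

Three threshold rules are available (`threshold_params(rule = ...)`):

* **`universal` (default).**
  $S_{j,k} = \theta \,\frac{W(r,\alpha)}{W(1,1)}\, \phi_{j,k}
  \sqrt{2 \ln Z}$, with $Z$ the subband coefficient count. The
  normalisation leaves the finest scale at the full universal threshold —
  the classic choice for *hard* thresholding, which needs thresholds of a
  few noise standard deviations to clear noise-dominated bands — and
  attenuates coarser scales, where the signal-to-noise ratio improves, to
  preserve structure.
* **`bayes`.** $S = \theta\, W(r)\, \phi^2 / \sigma_\text{signal}$ with
  $\sigma_\text{signal} = \sqrt{\max(\bar{c^2} - \phi^2, 0)}$ and
  $S = \infty$ for subbands at or below the noise floor. This
  BayesShrink-style rule is calibrated for soft thresholding; under hard
  thresholding its thresholds (of order one noise standard deviation)
  retain roughly a quarter of pure-noise coefficients, and in our
  benchmarks it consistently trailed the plain global-threshold baseline.
  It is kept as an option precisely because that comparison is
  instructive.
* **`literal`.** $S = \theta\, W(r)\, \phi \sqrt{\bar{c^2}}$, the direct
  product form. Its ratio of threshold to noise level grows with both
  signal energy and noise level, so it over-smooths textured images at
  high noise and under-smooths at low noise; also kept for comparison.

The rule choice was settled by comparing the three candidates on the
synthetic corpus (phantoms and textured targets, $\sigma \in \{5, 15,
25\}$, multiple seeds) and frozen; the universal rule dominated on all
three quality metrics. Hard thresholding itself (`hard_threshold()`)
keeps a coefficient exactly when $|c| \ge S$ — it is idempotent, and
$S = 0$ / $S = \infty$ are the identity / full suppression.

Defaults $\alpha = 1$, $\theta = 1$: with the per-subband noise
calibration in place there is no evidence the extra degrees of freedom
help, and unit values keep the rule interpretable.

## Kernel anisotropic diffusion of the low band

With the Gaussian kernel $F(a,b) = \exp(-(a-b)^2 / 2h^2)$, the squared
feature-space distance between neighboring gray values is
$F(a,a) + F(b,b) - 2F(a,b) = 2 - 2F(a,b)$ (the kernel identity requires
the minus sign: identical pixels must have zero distance). The per-pixel
gradient modulus
$$\|\nabla\Phi(J)\|_u = \Big[\tfrac{1}{|\lambda_u|} \sum_{v \in \lambda_u}
\big(2 - 2F(J_u, J_v)\big)\Big]^{1/2} \in [0, \sqrt 2]$$
saturates for large gray differences, which is what makes the scheme
robust to speckle spikes: an outlier cannot drive unbounded diffusivity
contrast. The conductivity is
$$c = \exp\!\Big(-\frac{\phi_F^2 \,\|\nabla\Phi\|^2}{4\tau^2}\Big),$$
with $\phi_F^2$ the local $w \times w$ sample variance normalised by its
global mean (a dimensionless modulator: mean 1, zero on constants — the
normalisation stops raw intensity variance from dominating the exponent)
and $\tau$ the median absolute deviation of the modulus field, floored at
$10^{-6}$ of the input's dynamic range so constant inputs do not divide
by zero. The squared-modulus exponent keeps the argument dimensionless in
the Perona–Malik sense; a literal first-power variant is available
(`kad_params(exponent = "literal")`). $\tau$, $\phi_F^2$ and the modulus
are recomputed every iteration so the threshold tracks the shrinking
gradient distribution; re-estimating per iteration costs one median per
sweep and removes a tuning constant.

The explicit update averages per-edge fluxes with conductivities
evaluated at edge midpoints (mean of the two endpoint fields), which
makes the scheme symmetric and hence **exactly conservative**; boundaries
are zero-flux (replicated ghost pixels). For $\Delta t \le 0.25$ the
update is a convex combination, giving a discrete extremum principle:
output values never leave the input range. With $h \to \infty$ the
conductivity is identically 1 and the scheme reduces to linear heat
diffusion — the test suite checks this against the exact DFT solution of
the five-point heat scheme.

Defaults: $\Delta t = 0.15$ (safely inside the stability bound),
10 iterations, 4-neighborhood, $w = 5$. The bandwidth defaults to
$1.5\times$ the noise standard deviation of the matrix being diffused:
inside the pipeline that is the global estimate $\phi$ mapped into the
low band through the bank's noise gains; used stand-alone, it is the
image-domain MAD estimator `estimate_noise_sd()` (2×2 diagonal high-pass,
unit noise gain).

## The pipeline and its baselines

`denoise(img, denoise_config("proposed"))` chains: NSST analysis →
universal-rule hard thresholding of all directional subbands → KAD of the
low subband → NSST synthesis. The comparison baselines isolate single
ingredients:

* `lpnd` — the same radial pyramid without the directional split, with
  classic Perona–Malik diffusion (exponential conductivity, per-iteration
  robust contrast parameter) run on each band;
* `nsst_only` — the transform with one global hard threshold $3\theta\phi$
  for every subband and no diffusion (the traditional shearlet denoiser);
* `kda_only` — kernel diffusion applied directly in the image domain;
* `median` / `none` — a 3×3 median filter and the identity, as controls.

All methods are deterministic given their configuration, and
`run_benchmark()` sweeps the full (image × σ × method × seed) grid.

## What the synthetic data does and does not emulate

`make_phantom()` reproduces the *geometry and contrast ordering* of renal
stone sonography — elliptical organ, hyperechoic (bright) stone disc,
hypoechoic shadow column below it, softened borders — and
`make_natural_test_image()` provides smooth shading, high-contrast step
edges and periodic stripes that stress edge and texture preservation the
way classic photographic test images do. The quantitative protocol is
additive Gaussian white noise at σ ∈ {5, 15, 25} on the 0–255 scale;
`add_speckle_noise()` supplies a unit-mean Gamma multiplicative model
(fully-developed-speckle approximation) for qualitative demonstration.

None of this is a physical ultrasound simulation: there is no
point-spread function, log compression, attenuation with depth, or
spatially correlated speckle. Passing benchmarks on this corpus shows the
method's *relative* behavior (noise-level monotonicity, ordering against
baselines, edge preservation) under controlled conditions; it does not
certify absolute performance on clinical images.

## Numerical choices and degenerate inputs

* Intensities are floating point on the 0–255 scale throughout; clipping
  happens only at I/O (`read_gray()` / `write_gray()`) and when a noise
  generator is asked for a displayable image.
* Perfect reconstruction is asserted at $10^{-6}$ max-abs (observed:
  $\sim 10^{-13}$ on 0–255 data); the partition of unity at $10^{-6}$
  (observed: $\sim 10^{-15}$).
* Constant images: zero gradient everywhere, so diffusion is a fixed
  point; the MAD floor keeps $\tau > 0$; the noise estimate is 0 and the
  bandwidth falls back to a tiny positive value, freezing diffusion
  rather than dividing by zero. A clean (noiseless) phantom passes the
  full pipeline essentially unchanged (PSNR ≫ 50 dB).
* A subband at or below the noise floor under the `bayes` rule is fully
  suppressed (`S = Inf` sentinel) — hard thresholding treats that
  sentinel exactly (all zeros).
* EPI is undefined (returns `NA`) when either Laplacian field has zero
  variance, i.e. for constant images.
* Seeded generators save and restore the caller's RNG state, so they are
  pure functions of their arguments.

## Validation problem sizes

The shipped test suite exercises: transform properties at 64–128 pixels
(20 random round trips, linearity, tight-frame energy); diffusion
conservation and extremum bounds on 5 seeded 128² phantoms; brute-force
oracles for the kernel-gradient and local-variance fields at 32²; and the
benchmark on four 256² synthetic images (two textured, two phantoms) ×
σ ∈ {5, 15, 25} × 5 noise seeds × 4 methods. These sizes were chosen so
the whole suite runs in a few minutes on a laptop while keeping every
Monte-Carlo tolerance comfortably away from its sampling noise.

## Known limitations

* The frequency-domain construction requires the filter bank to match the
  image shape exactly; very small images (below $2^{R+2}$ pixels per
  side) cannot host $R$ scales.
* Periodic filtering wraps content across opposite borders; for images
  with strong frame-edge structure, pad before denoising or rely on the
  metric `crop`.
* The speckle model is uncorrelated and unit-mean — adequate for
  demonstrating multiplicative-noise behavior, not for simulating any
  particular transducer.
* The clinical module reproduces outcome-count arithmetic and a
  two-proportion comparison; it does not implement survival, laboratory
  or demographic analyses.
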