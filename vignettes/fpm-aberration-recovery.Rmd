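---
title: "Aberration-corrected Fourier ptychography: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aberration-corrected Fourier ptychography: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmflow)
```

## The imaging model

Fourier ptychographic microscopy records a stack of low-resolution
intensity images $I_n(r)$ of a thin sample $o(r)$ under oblique
plane-wave illumination from an LED array. An LED at lateral offset
$(x, y)$ mm, a distance $h$ mm below the sample, illuminates with
direction sines $\sin\theta_x = x/\sqrt{x^2+y^2+h^2}$ (exact geometry,
not the small-angle $x/h$ — the difference matters at the array edge),
giving the spatial frequency $k_n = (\sin\theta_x, \sin\theta_y)/\lambda$
in cycles/µm. Tilted illumination shifts the object spectrum, the
objective low-passes it with the coherent transfer function (CTF), and
the camera detects intensity:

$$ I_n(r) \;=\; \bigl|\, \mathcal F^{-1}\{\, C(k)\, O(k - k_n) \,\}\,\bigr|^2 . $$

All frequencies in the package are cycles/µm, so the CTF support is the
disk $|k| < \mathrm{NA}/\lambda$; the angular wavenumber
$k_0 = 2\pi/\lambda$ appears only inside phase expressions (defocus).
Aberrations multiply the CTF by a phase:
$C(k) = c(k)\, e^{\,i \sum_i c_i Z_i(k)}$ with Zernike polynomials
$Z_i$ on the pupil disk, mapped by $\rho = |k|\lambda/\mathrm{NA}$
(clipped to 1 on the boundary ring) and zero outside the support.

**Grid conventions.** Every frequency-domain array uses the centered
layout (zero frequency at pixel $\lfloor n/2\rfloor + 1$) and unitary
transforms ($1/\sqrt{N}$ each way), so pupil windows are contiguous
sub-matrices, Parseval's identity is exact, and every adjoint in the
gradient derivation is an inverse transform. Detector downsampling is
Fourier-domain decimation: the low-resolution image is the inverse
transform of the $m\times m$ pupil window of the $M\times M$
high-resolution spectrum ($u = M/m$ the upsampling factor). Each
$k_n$ is quantized to the nearest integer frequency pixel; the residual
(always below half a pixel) is recorded on the stack for diagnostics.
A window that would leave the high-resolution grid raises an error
naming the LED.

## Zernike conventions and the defocus calibration

Terms are indexed by $(n, m)$ with $n - |m| \ge 0$ and even; $m > 0$
carries $\cos(m\theta)$, $m < 0$ carries $\sin(|m|\theta)$. Two
normalizations are available: `"unit"` (no prefactor; defocus is
$2\rho^2 - 1$) and `"noll"` orthonormal prefactors
($\sqrt{2(n+1)}$ for $m \ne 0$, $\sqrt{n+1}$ for $m = 0$). The default is `"unit"` because the
field's customary defocus calibration numbers are quoted in that
convention: the paraxial pupil phase of a defocus plane $z$ is
$-k_0 z (\mathrm{NA}\,\rho)^2/2$, whose least-squares projection onto
$2\rho^2 - 1$ over the disk is exactly $-k_0 z\,\mathrm{NA}^2/4$ —
$-1.476$ rad at $z = 50$ µm, NA 0.1, $\lambda$ 532 nm, linear in $z$.
`defocus_to_zernike()` evaluates the projection by radial quadrature
(2048 midpoint nodes by default; the paraxial result agrees with the
closed form to $10^{-6}$) and also offers the exact defocus phase
$k_0 z(\sqrt{1 - (\mathrm{NA}\rho)^2} - 1)$, which differs from the
paraxial projection by under 1 % at NA 0.1. Which of the two a given
published calibration used is rarely stated; at this aperture it is
immaterial.

## The classical baseline

`reconstruct_classic()` is Gerchberg–Saxton-style spectrum stitching:
per LED, predict the low-resolution field
$g_n = \mathcal F^{-1}\{C\,O(k-k_n)\}$, replace its modulus by
$\sqrt{I_n}$ (keeping phase; the phase of a zero-modulus pixel is 0 by
convention, so no NaN arises), transform back, and write the patch into
the spectrum window — dividing by the pupil where $|C| > 10^{-12}$, so
pixels outside the support are untouched and a noiseless stack
generated from $(O, C)$ is an exact fixed point of a sweep with that
same $C$. No relaxation or conjugate-pupil weighting is applied: this
arm is deliberately the plain baseline, run with the ideal binary CTF
when it plays the "no aberration correction" role. Initialization is
the Fourier-zero-padded square root of the most axial LED image; with
unitary transforms the embedded spectrum needs no rescaling.

## The aberration-correcting engine

`train_inn_iwf()` (front-end: `fpm_fit(..., method = "iwf")`) carries
the object as real/imaginary maps $(O_r, O_i)$ and the pupil as a CTF
amplitude map plus Zernike phase coefficients. Per LED:

1. $\varphi_l = O(k \mp k_n) \odot C(k)$ on the pupil window;
2. WFM: $a = \mathcal F^{-1}\varphi_l$, then
   $\varphi_m = \varphi_l - \Delta\,\mathcal F\{(|a|^2 - y)\odot a\}$ —
   one Wirtinger-Flow gradient step on the intensity misfit
   $\||a|^2 - y\|^2$ (the applied correction is exactly $-\Delta/4$
   times its real/imaginary gradient under the unitary convention);
3. WFN: $\varphi_h = \mathcal F\{\sqrt{y}\,
   e^{\,i\,\angle \mathcal F^{-1}\varphi_m}\}$, imposing the measured
   modulus;
4. loss $= \operatorname{mean}|\varphi_h - \varphi_l|^2$ over pixels
   and LEDs.

Measured intensities are normalized to unit mean before training
($\Delta = 1$ on that scale); the returned object absorbs the scale
back. The measured image and the $\varphi$ grids coincide in this
geometry, so the intensity-upsampling step (Fourier zero-padding of
$\sqrt I$, then re-squaring; nearest/bilinear available) is the
identity by default.

**Gradients.** R has no automatic differentiation, so all gradients
are hand-derived Wirtinger adjoints; under the unitary convention every
transform's adjoint is its inverse, and the test suite validates every
parameter block against central finite differences ($10^{-4}$
relative on small instances).

**A structural identity.** Because the sampling operator is a unitary
inverse transform, the WFM step rescales the spatial field by the
pointwise *real* factor $1 - \Delta(|a|^2 - y)$: it changes magnitudes,
not phases. Consequently the gradient flowing back through the
WFM→WFN chain cancels identically, and the end-to-end gradient equals
the gradient with $\varphi_h$ treated as a fixed target. The
`detach_target` option is therefore a no-op in exact arithmetic; it is
kept for interface completeness, and the identity is itself covered by
the finite-difference tests in both modes.

**Optimization and the alternating-update schedule.** Sample epochs
and pupil epochs alternate, touching only their own parameter block
(bit-exact isolation, tested). Two sample rules exist:

* `"projection"` (default): per-LED relaxed magnitude-replacement
  write-backs with the *current* aberrated pupil. This is gradient
  descent on the same spectral loss in the pupil-window metric with the
  natural unit step, and converges in a handful of sweeps where
  fixed-step gradient descent needs thousands.
* `"gradient"`: full-batch descent on the Wirtinger gradients (SGD or
  Adam). Retained for analysis — the monotone-loss property test runs
  in this mode at small rates.

Pupil epochs always use full-batch gradients. The pupil loss landscape
is nearly flat while the sample estimate is poor and sharply curved
once it is good (measured curvature varies by more than two orders of
magnitude over training), so no single plain-GD step size works: the
default pupil optimizer is Adam (`lr_pupil = 0.05`). A corollary,
relevant to testing: Adam's normalized steps do not *stay* at an exact
stationary point — vanishing gradients are rescaled up to the learning
rate — so stationarity ("a stack simulated from the truth keeps the
truth fixed") is asserted under the plain-GD rule, where it holds to
$10^{-8}$.

With the projection sample rule, the AU schedule becomes an EM-like
outer iteration: converge the sample under the current pupil, then
re-fit the pupil under the current sample. Empirically each round
roughly halves the pupil bias that the sample had absorbed, and six
rounds suffice at the benchmark scale. The default schedule
(`iwf_au_schedule()`) is 6 rounds of 10 sample + 30 pupil epochs, then
10 final sample epochs under the recovered pupil — 250 epochs, a few
seconds at the standard benchmark size.

The CTF amplitude $c(k)$ is a learnable block (projected non-negative
after each step) but is *frozen at the ideal binary CTF by default*:
letting it drift interacts badly with the pupil-deconvolution
write-back (division by small amplitudes amplifies noise), and the
package's aberration scenarios are phase-only. Zernike order defaults
to $n \le 4$ (15 terms).

## What the synthetic data emulate — and what they do not

`make_phantom()` builds complex objects with *independent* amplitude
and phase patterns (smoothed random blobs, two-tone bars, checkers, or
a user-supplied grayscale file), emulating the common practice of using
two unrelated photographs for amplitude and phase. Hard-edged patterns
are softened by a 1.5-px Gaussian so their spectral energy sits at
scales a synthesized aperture can resolve, as it does for photographs;
amplitude spans [0.2, 1], phase spans $[-\pi/2, \pi/2]$ by default.
Everything is deterministic given the seed.

The standard benchmark (`make_benchmark_case()`) uses a 64×64
high-resolution grid with 0.32 µm object-plane sampling, $u = 4$, and
a 9×9 LED grid at 7 mm pitch, 100 mm below the sample. The pitch is
chosen so that the 9×9 grid spans the same ±28 mm half-aperture as a
15×15 grid at 4 mm pitch: the desk-scale scan preserves the full
angular aperture (hence the synthetic NA) and merely samples it more
coarsely, while a full 15×15 × 4 mm scan also fits the same grids (225
images; used for the acquisition-count check). On this geometry the
uncorrected baseline degrades from ~26 dB amplitude PSNR at focus to
~16/12/10 dB at 25/50/75 µm defocus — the qualitative structure of a
defocus sweep — and pupil-corrected reconstruction recovers most of the
loss at 25–50 µm.

Simulations are noiseless by default (optional Poisson shot noise at a
configurable photon budget plus Gaussian read noise, seeded). The
generator does **not** model partially coherent illumination, LED
position or intensity miscalibration, sample thickness, or real tissue
structure — so passing tests demonstrate correctness of the algorithms
on data matching the forward model, not robustness to every
experimental nuisance.

## Numerical choices and degenerate inputs

* Phase of a zero-modulus pixel is 0 (`Arg(0+0i)` in R), so magnitude
  replacement never produces NaN; the WFN phase factor falls back to 1
  where $|b| \le 10^{-12}$ and its backward gradient is zeroed there.
* Projection write-backs divide by the pupil only where
  $|C| > 10^{-3}$ (binary-CTF support in the default configuration).
* Wave-vector quantization: nearest integer pixel; sub-pixel residuals
  stored, not compensated.
* Stopping: fixed epoch/sweep counts by default; the classical engine
  also stops at relative spectrum change $< 10^{-6}$.
* Adam: $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-8}$;
  exactly zero gradient gives exactly zero step.
* PSNR assumes unit-range images (no peak term); amplitudes are each
  normalized to [0, 1] before comparison because the global intensity
  scale is not identifiable from intensity-only data, and phases are
  affinely aligned to the reference range because a global phase offset
  is likewise unidentifiable. SSIM constants default to
  $C_1 = 10^{-4}$, $C_2 = 9\times10^{-4}$ ($k_1 = 0.01, k_2 = 0.03$,
  $L = 1$); a strictly equal-constants variant is available. Global
  SSIM evaluates the statistic from whole-image moments; windowed SSIM
  (7×7 uniform windows) is the default for table-style comparisons, as
  is customary.

## Known limitations

* **Large defocus.** At 75 µm ($|c| \approx 2.2$ rad across a
  3.9-pixel pupil radius) the recovery landscape develops competing
  attractors and the coefficient is recovered only for some phantoms;
  reconstruction quality still degrades monotonically with defocus, as
  expected physically.
* **Gauge freedoms.** Pupil tip/tilt ($n = 1$) is equivalent to an
  object translation and is freely taken up by the optimizer; constant
  phase ($n = 0$) is likewise unobservable. Compare reconstructions
  modulo these modes.
* **Scale.** The recovered object's intensity scale is fixed only up
  to the normalization constant; `evaluate_reconstruction()` works on
  normalized amplitudes.
* **Problem sizes.** The shipped tests and benchmark run at 64×64 /
  9×9 LEDs (the package's standard desk-scale conditions, minutes of
  total runtime); the geometry accepts larger grids and the full-scan
  LED count is exercised at 15×15.

## Reproducibility

Every stochastic path (phantoms, noise) takes an explicit integer
seed; default initializations are deterministic. `write_stack()` /
`write_reconstruction()` record geometry, scales, configuration and
seeds in JSON sidecars sufficient to re-run a fit bit-identically, and
the CLI (`inst/cli/fpm.R`) writes the same metadata for every run.
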