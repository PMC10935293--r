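# fpmflow

Fourier ptychographic microscopy (FPM) turns a cheap low-NA objective
into a high-resolution quantitative phase microscope: an LED array
illuminates the sample from many angles, the camera records one
low-resolution intensity image per LED, and a reconstruction algorithm
stitches the corresponding pupil-sized patches of the object spectrum
into a high-resolution complex field. In practice the objective is
aberrated — defocus above all — and the stitched image degrades badly
unless the pupil function is recovered along with the object.

`fpmflow` is an R package for people who simulate and analyse FPM data:
it implements the full forward imaging model, the classical
alternating-projection reconstruction, and an aberration-correcting
reconstruction that parameterizes the pupil phase with Zernike
polynomials and fits object and pupil jointly by Wirtinger-Flow
gradient descent with an alternating-update (AU) schedule.

## The model

For the *n*-th LED with illumination wave vector
**k**ₙ = (sin θₓ, sin θᵧ)/λ, the camera records

> Iₙ(r) = | F⁻¹{ C(k) · O(k − kₙ) } |²,

where O(k) is the object spectrum and C(k) the coherent transfer
function (CTF), a disk of radius NA/λ. Aberrations enter as
C(k) = c(k)·exp(i Σᵢ cᵢ Zᵢ(k)) with Zernike polynomials Zᵢ on the pupil
disk; the (n = 2, m = 0) term is defocus, with unit-normalized
polynomial 2ρ² − 1. A defocus plane at distance z maps to the
coefficient −k₀ z NA²/4 (k₀ = 2π/λ): about −1.48 rad at z = 50 µm for
NA = 0.1, λ = 532 nm.

The aberration-correcting engine carries the object as learnable
real/imaginary maps and the pupil as Zernike phase coefficients. Per
LED it forms the pupil-window spectrum φₗ = O(k∓kₙ)·C(k), applies a
Wirtinger-Flow intensity-misfit correction
φₘ = φₗ − Δ·F{(|a|² − y)⊙a} with a = F⁻¹φₗ, re-imposes the measured
modulus φₕ = F{√y · exp(i∠F⁻¹φₘ)}, and minimizes the spectral
self-consistency loss mean|φₕ − φₗ|². Sample epochs and pupil epochs
alternate with separate step rules (the AU schedule).

## Worked example

Simulate a defocused acquisition (64×64 phantom, 9×9 LED grid spanning
the same 28 mm half-aperture as a 15×15 grid at 4 mm pitch, z = 50 µm)
and reconstruct with and without aberration correction:

```r
library(fpmflow)

bench <- make_benchmark_case(z = 50, seed = 1)
bench$stack
#> <fpm_stack> 81 images of 16 x 16
#>   9 bright-field / 72 dark-field LEDs, noiseless

fit <- fpm_fit(bench$stack, method = "iwf")
fit
#> FPM reconstruction (method: iwf)
#>   object: 64 x 64 complex field from 81 images
#>   final loss: 0.06423 after 250 epochs
#>   leading pupil terms (rad): Z(1,-1) = +1.589, Z(2,+0) = -1.389, ...

defocus_to_zernike(50, bench$system)   # injected coefficient
#> [1] -1.476312

evaluate_reconstruction(bench$truth, fit$object)
#>   psnr_amp  ssim_amp psnr_phase ssim_phase    mse_amp
#> 1 17.96367 0.4137304   17.91755  0.9062222 0.01598209

baseline <- fpm_fit(bench$stack, method = "classic")  # ideal-CTF arm
evaluate_reconstruction(bench$truth, baseline$object)
#>   psnr_amp   ssim_amp psnr_phase ssim_phase    mse_amp
#> 1 11.95415 0.04598091   13.07338  0.6418636 0.06376543
```

The recovered defocus coefficient (−1.389 rad) sits within 6 % of the
injected −1.476 rad; the tip/tilt terms Z(1,±1) are gauge freedoms (a
pupil tilt is an object translation) and do not affect image quality.
Correcting the pupil buys ~6 dB of amplitude PSNR over the uncorrected
baseline on this scenario. `coef()`, `fitted()`, `residuals()`,
`predict()`, `simulate()` and `plot()` work on the fit object as on any
R model.

A command-line interface wrapping the same functions lives at
`inst/cli/fpm.R`:

```sh
Rscript inst/cli/fpm.R calibrate-defocus --z-um 50
Rscript inst/cli/fpm.R simulate --out run1 --defocus-um 50 --seed 1
Rscript inst/cli/fpm.R reconstruct --stack run1/stack.tiff --out run1/rec
Rscript inst/cli/fpm.R evaluate --truth run1/truth --estimate run1/rec
```

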