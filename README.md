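# tgvpois

Restoration of blurred, Poisson-noise-corrupted grayscale images — the
photon-limited setting of fluorescence microscopy, astronomy and low-dose
imaging, where each observed pixel is a count `f_i ~ Poisson((Ku)_i)` with
`K` a known point-spread-function (blur) operator and `u ≥ 0` the clean
image.

The package minimizes, jointly over the image `u` and an auxiliary vector
field `p`,

    β Σ_i [(Ku)_i − f_i log(Ku)_i]  +  (λ/2)‖u‖²₂
      +  α₁‖∇u − p‖₁  +  α₀‖ε(p)‖₁  +  ι≥0(u)

i.e. a Kullback–Leibler (Poisson) data-fidelity term plus second-order
total generalized variation (TGV²) — which suppresses the staircase
artifacts that plain total variation produces on smooth intensity ramps
while keeping edges sharp — augmented with a small quadratic regularizer
and a nonnegativity constraint.  `ε(p)` is the symmetrized gradient of `p`,
a per-pixel symmetric 2×2 tensor.

The minimizer is computed by a split Bregman / ADMM iteration in which
every sub-problem is exact: a pointwise closed-form root for the Poisson
proximal step, isotropic soft-thresholding for the vector and tensor
shrinkage steps, FFT-diagonalized linear solves for `u` and `p` under
periodic boundaries (conjugate gradients under symmetric boundaries), and a
nonnegative projection.  Also included:

* PSF builders (`gaussian_psf`, `box_psf`, `motion_psf`) and an exact
  blur/adjoint operator pair (`blur_operator`, `apply_blur`);
* quality metrics (`snr`, `psnr`, `relerr`, `mse`, `ssim`,
  `metrics_report`);
* a synthetic module (`make_phantom`, `degrade`, `make_fixture_suite`)
  that generates clean phantoms and degrades them by blur + pixelwise
  Poisson draws, fully seeded;
* PNG/TIFF I/O and a command-line tool (`inst/cli/tgvpois`) with
  `restore`, `simulate` and `metrics` subcommands.

## Worked example

```r
library(tgvpois)
u <- make_phantom(64, 64, "ramp_disks", seed = 1)   # clean phantom, 0..255
K <- blur_operator(gaussian_psf(5, 2), dim(u))      # Gaussian blur, size 5, sd 2
f <- degrade(u, K, seed = 2)                        # f ~ Poisson(Ku)
res <- restore(f, K, solver_preset("test1"))        # β=54 λ=0.001 α=(16,9)
res
#> restoration_result: 64x64 image, 39 iterations, converged (rel change 9.32e-04 <= tol 1.00e-03)
metrics_report(u, f)       # degraded input
#> metric        value
#> SNR         17.9660
#> PSNR        22.0128
#> RELERR       0.1264
#> MSE        409.0713
#> SSIM         0.3623
metrics_report(u, res$u)   # restored
#> metric        value
#> SNR         24.3986
#> PSNR        28.4454
#> RELERR       0.0603
#> MSE         93.0121
#> SSIM         0.8849
```

The restoration gains ~6.4 dB PSNR and lifts SSIM from 0.36 to 0.88 on
this fixture: the solver removes most of the Poisson noise and deconvolves
the blur while keeping the disk edges sharp and the background ramp smooth
(no staircasing).  `res$history` records per-iteration relative change,
objective value and the four splitting-constraint residuals.

The same run from the shell:

```sh
tgvpois simulate --out-dir fx --seed 1 --sizes 64
tgvpois restore --input fx/gaussian_64_degraded.tif --output restored.tif \
        --psf gaussian:5,2 --preset test1 --bits 16 \
        --reference fx/gaussian_64_clean.tif
```

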