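# nsstkad

Edge-preserving denoising of grayscale medical ultrasound images, built
around two complementary ideas:

1. **Nonsubsampled shearlet transform (NSST).** A shift-invariant,
   multiscale, multidirectional frame built from Meyer-type radial and
   angular windows in the frequency domain. The squared analysis windows
   form a partition of unity, so the frame is tight and
   forward → inverse reconstruction is exact to floating-point rounding.
   Directional high-frequency subbands are denoised by **scale-weighted
   hard thresholding**: with scale weight `W(r) = α·ln(r+1)/r` (largest at
   the finest scale `r = 1`), each subband gets the universal threshold

   ```
   S_jk = θ · (W(r, α) / W(1, 1)) · φ_jk · sqrt(2 · ln Z)
   ```

   where `φ_jk` is the subband's noise standard deviation — the global
   MAD estimate `φ = median(|c|)/0.6745` from the finest subbands, mapped
   through the filter bank's known noise gains — and `Z` the subband size.

2. **Kernel anisotropic diffusion (KAD).** The low-frequency subband is
   smoothed by an explicit diffusion scheme whose conductivity
   `c = exp(−φ_F²·‖∇Φ(J)‖² / 4τ²)` is computed from distances in a
   Gaussian-kernel feature space, `‖∇Φ(J)‖_u = [mean_v (2 − 2F(J_u,J_v))]^½`
   with `F(a,b) = exp(−(a−b)²/2h²)`, bounded by √2 so speckle spikes
   cannot blow up the diffusivity; `φ_F²` is the normalised local
   variance and `τ` a per-iteration MAD of the gradient field. The scheme
   conserves the image mean exactly and obeys a discrete extremum
   principle.

The package is aimed at researchers evaluating despeckling/denoising
algorithms: it ships the full pipeline, four comparison baselines
(Laplacian-pyramid Perona–Malik diffusion, plain global-threshold
shearlet denoising, image-domain kernel diffusion, median filtering),
PSNR/SSIM/EPI quality metrics, a factorial benchmark driver, and a fully
procedural synthetic-data module (ultrasound-like kidney phantoms with a
hyperechoic stone and acoustic shadow; textured natural-image stand-ins;
Gaussian and multiplicative speckle noise) so everything runs with zero
downloads. A small clinical module computes treatment-effectiveness rates
from stone-outcome counts and compares two groups with a two-proportion
test.

## Worked example

```r
library(nsstkad)

clean <- make_phantom(size = 256)                       # noiseless kidney phantom
noisy <- add_gaussian_noise(clean, sigma = 15, seed = 1)
out   <- denoise(noisy, denoise_config("proposed"))

round(rbind(noisy    = unlist(quality_report(clean, noisy, crop = 8)),
            denoised = unlist(quality_report(clean, out,   crop = 8))), 3)
#>          psnr_db  ssim   epi
#> noisy     24.689 0.286 0.078
#> denoised  37.422 0.949 0.685
```

The pipeline lifts the phantom from 24.7 dB to 37.4 dB PSNR while
restoring structural similarity (SSIM 0.29 → 0.95) and edge preservation
(EPI, the correlation of Laplacian high-pass fields, 0.08 → 0.69) — the
stone's bright rim and its acoustic shadow survive where a plain smoother
would blur them. An 8-pixel border is excluded from scoring because the
transform filters periodically.

The clinical helpers reproduce outcome-count arithmetic:

```r
g2 <- outcome_table(22, 12, 4)
g2
#> Stone outcomes: 22 disappeared, 12 reduced, 4 unchanged (n = 38); effective rate 89.47%
compare_rates(outcome_table(25, 20, 7), g2)$p_value
#> [1] 0.7544
```

A thin command-line front end lives in `inst/cli/nsstkad.R`
(`phantom`, `noise`, `denoise`, `bench`, `metrics`, `rate`, `compare`
subcommands over PNG/TIFF files).

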