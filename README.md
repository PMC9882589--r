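# ktemap

Joint k-space / echo-time reconstruction for quantitative MRI T2 mapping.

## What it does and for whom

Multi-echo T2 mapping estimates the transverse relaxation time T2(x) from
T2-weighted images acquired at a ladder of echo times, under the
mono-exponential model

    f(x, TE_i) = f(x, TE_0) · exp(−(TE_i − TE_0) / T2(x)).

The conventional two-step pipeline inverts each echo's k-space independently
(FFT) and then fits the decay pixel by pixel, so every echo carries its full
acquisition noise into the fit. `ktemap` instead reconstructs all echo images
and the T2 map **jointly**, by solving

    min_{f, T2}  Σ_i ½‖S F A_i f_i − g_i‖² + R[v_i]
    s.t.  f_i = f_0 exp(−(TE_i − TE_0)/T2),   v_i = f_i,

with S the Cartesian line-sampling operator, F the unitary 2D DFT, A_i fixed
unit-modulus phase maps, and R an image prior realized as a plug-and-play
denoiser (non-local means by default; the registry accepts any denoiser). The
problem is solved by ADMM: exact transform-domain solves for the echo images,
a conjugate-gradient solve for the first echo under undersampling, a weighted
log-linear least-squares update for T2, the denoising step, and dual ascent
on the multipliers, stopped when the mean relative image change drops below
1% (checked from iteration 4). The same package ships the two-step baseline,
a compressed-sensing baseline with 1D total variation (monotone FISTA, exact
taut-string prox), a k-space-only ablation, a digital 14-vial relaxometry
phantom simulator with known ground truth, and ROI evaluation tools.

It is aimed at quantitative-MRI researchers who want a reproducible,
inspectable implementation of decay-constrained joint reconstruction and its
standard comparisons on synthetic (or their own Cartesian) multi-echo data.

## Worked example

Simulate a noisy fully sampled acquisition of the 14-vial phantom, run the
joint reconstruction and the two-step baseline, and compare per-vial T2:

```r
library(ktemap)

ph  <- make_vial_phantom(c(128, 128))              # calibrated 8.75–853 ms vials
te  <- te_ladder("fse11")                          # 11–176 ms, 11 ms spacing
acq <- acquisition_config(te = te, noise_sd = 2, seed = 7)
g   <- simulate_acquisition(ph, acq)

fit <- joint_reconstruct(g)
fit
#> <kte_fit:joint> 16 echoes on 128 x 128, 7 iterations (converged), sigma = 1.67234

ref <- two_step_recon(g)
cmp <- compare_methods(
  list(joint    = roi_stats(fit$t2, ph$roi_masks, truth = ph$t2_truth),
       two_step = roi_stats(ref$t2, ph$roi_masks, truth = ph$t2_truth)),
  reference = "two_step")
cmp[cmp$label %in% c("vial01", "vial07", "vial14"), ]
#> # A tibble: 6 × 8
#>   label      n   mean      sd  truth rel_error method   sd_ratio
#>   <chr>  <int>  <dbl>   <dbl>  <dbl>     <dbl> <chr>       <dbl>
#> 1 vial01   102   8.93   0.146   8.75   0.0208  joint       0.181
#> 2 vial01   102   9.16   0.806   8.75   0.0464  two_step    1
#> 3 vial07   102  82.8    0.765  82.2    0.00704 joint       0.359
#> 4 vial07   102  82.8    2.13   82.2    0.00790 two_step    1
#> 5 vial14   104  867.   45.0   853      0.0164  joint       0.321
#> 6 vial14   104  873.  140.    853      0.0238  two_step    1
```

Both methods recover the vendor T2 values to a couple of percent, but the
joint reconstruction tightens the pixelwise spread substantially — `sd_ratio`
is the joint-to-two-step standard-deviation ratio per vial (0.18–0.36 here).
The noise level was estimated from the data itself (σ ≈ 1.67 against a
generating σ = 2 after the conservative-free estimate; pass `sigma=` to
override). `plot(fit)` draws the per-iteration convergence curve and
`plot(fit$t2)` the T2 map.

Undersampled reconstructions use the same interface:

```r
mask <- make_mask(128, discard_fraction = 0.25, seed = 1)  # central 10% kept
gu   <- simulate_acquisition(ph, acq, mask)
fitu <- joint_reconstruct(gu)
```

A command-line front end covering simulate / recon / baseline / evaluate,
with HDF5 k-space and NIfTI image I/O plus JSON run manifests, lives at
`inst/cli/ktemap.R`.

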