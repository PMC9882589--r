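---
title: "Joint k-space / echo-time reconstruction for T2 mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint k-space / echo-time reconstruction for T2 mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktemap)
```

## The problem

Quantitative T2 mapping acquires T2-weighted images at a ladder of echo times
$TE_0 < TE_1 < \dots$ and fits, pixel by pixel, the mono-exponential decay

$$ f(x, TE_i) = f(x, TE_0)\, e^{-(TE_i - TE_0)/T_2(x)} . $$

The conventional *two-step* pipeline reconstructs each echo image from its own
k-space data by inverse FFT and then fits the decay. Every echo is thereby
denied the information carried by the others, and the pixelwise fit inherits
the full acquisition noise.

`ktemap` instead solves a single optimization problem over all echo images and
the T2 map jointly:

$$ \min_{f, T_2} \sum_i \tfrac12 \lVert S F A_i f_i - g_i \rVert^2 + R[v_i]
\quad \text{s.t.} \quad f_i = f_0 e^{-(TE_i-TE_0)/T_2},\; v_i = f_i , $$

where $g_i$ is the measured k-space of echo $i$, $F$ the unitary 2D DFT, $A_i$
a fixed unit-modulus phase map, $S$ the Cartesian line-sampling operator, and
$R$ an image prior realized as a plug-and-play denoiser. The decay constraint
couples the echoes ("TE-space"), the data term anchors them to k-space, and
the prior shapes each image spatially.

## The ADMM iteration

The augmented Lagrangian (penalty $\rho$, multipliers $y_i$ for the decay
constraint and $z_i$ for the splitting $v_i = f_i$) is minimized by cycling:

1. **Echo images** $f_i,\ i>0$ (`update_f_i`): a quadratic subproblem. After
   the change of variables $h = A_i f_i$ the normal equations are diagonal in
   k-space with per-line denominator $S + 2\rho$, so the exact solution costs
   two unitary transforms. The result is projected to a magnitude image (real
   part, negatives clipped) — the model treats $f$ as a magnitude, and the
   projection is stated as an explicit design step.
2. **First-echo image** $f_0$ (`update_f_0`): each later echo back-projects an
   expected image at $TE_0$ through the decay factors
   $e_i = e^{-(TE_i-TE_0)/T_2}$. The data term is diagonal in k-space but the
   decay terms are diagonal pixelwise, so the system is only jointly diagonal
   under full sampling (where the update is elementwise). Under undersampling
   the symmetric positive-definite normal equations are solved exactly by
   conjugate gradients (relative tolerance `1e-12`, at most 400 iterations —
   in practice a few dozen); each CG step is two transforms.
3. **T2 map** (`fit_t2_wls`): the weighted log-linear fit described below.
4. **Auxiliary images** $v_i$ (`update_v`): the plug-and-play denoising step,
   by default applied directly to $f_i$, the form the method was published
   with. The variant that minimizes the $v$-subproblem of the Lagrangian
   exactly — denoising $f_i - z_i/\rho$ — is available as
   `recon_config(pnp_shift = TRUE)`. (Minimizing
   $R[v] + z^\top(v - f) + \tfrac{\rho}{2}\lVert v-f\rVert^2$ gives the prox
   at $f - z/\rho$; the opposite sign turns the multiplier loop into positive
   feedback and diverges, which is easy to reproduce.)
5. **Multipliers** (`update_multipliers`): $y_i \mathrel{+}= \rho\,(f_i - f_0
   e_i)$ and $z_i \mathrel{+}= \rho\,(v_i - f_i)$.

Iterations stop when the mean relative intensity change (MRC) of the images
between successive iterates falls below $\epsilon$ (default 1%), checked from
iteration 4 onward because the statistic typically rises before it falls.
Convergence of the plug-and-play iteration is not guaranteed, so a hard cap
(`max_iter`, default 50) is always enforced. $\rho = 0.5$ is the default and
was robust across everything we ran.

### Stopping-rule details

MRC is the mean over foreground pixels and echoes of
$|f^{new} - f^{old}| / (|f^{old}| + \text{floor})$. The foreground is the
Otsu-based mask of the first-echo initialization. Inside the solver the floor
is $\max(\sigma, 10^{-3}\max f)$: the decay constraint and the denoiser drive
sub-noise pixels toward zero, and intensity changes below the noise level are
meaningless — on scanner magnitude data the Rician floor keeps $|f|$ near or
above $\sigma$, so an unfloored MRC never meets this regime. The exported
`mrc()` keeps the generic $10^{-3}\max f$ floor as its default.

## The weighted T2 fit

With $x_i = TE_i - TE_0$ and $y_i = \log(f_i/f_0)$, the decay model is the
line $y_i = -x_i / T_2$ through the origin, and the fit minimizes
$\sum_i w_i (y_i + x_i \beta)^2$ over the rate $\beta = 1/T_2$, clamped to
`t2_clamp` (default 1–5000 ms, covering the phantom's 8–853 ms range and
CSF). The weights follow a first-order uncertainty argument: the log-domain
uncertainty of echo $i$ is the width $\log\frac{f_i+\sigma}{f_i-\sigma}$, so

$$ w_i \propto \frac{x_i}{\log\left((f_i+\sigma)/(f_i-\sigma)\right)}, $$

normalized to sum to one per pixel. As $\sigma \to 0$ this tends to
$w_i \propto x_i f_i$, which is what `sigma = 0` uses.

Three guard rules matter in practice, all visible in the tests:

- **Noise-floor truncation.** The first-order width is only meaningful at
  decent SNR — the same condition under which magnitude noise is
  approximately Gaussian (SNR > 3). Echoes are therefore kept only while
  $f_i > 3\sigma$, and because the true decay is monotone the train is
  truncated at the first sub-threshold echo: later echoes are dropped even if
  noise pushes them back above the cut. Without this rule a single late
  pure-noise excursion receives a weight growing with $x_i$ and can bias a
  9 ms vial to 40 ms.
- **No-signal pixels.** A pixel with no echo above the cut carries no decay
  information. It is assigned the clamp *minimum* rather than an arbitrary
  fallback, so the decay constraint relaxes its later echoes toward zero.
  This materially suppresses aliasing: with arbitrary long-T2 fallbacks the
  TE-space constraint copies background artifacts across echoes instead of
  cancelling them.
- **Positivity floor.** Signals are floored at $10^{-6}\max f_0$ before the
  logarithm; pixels whose echoes all sit at the floor are flagged and pinned
  at the clamp maximum. The floor perturbs only vials whose signal decays
  below it within the ladder (worst case ~$10^{-4}$ ms on the 8.75 ms vial).

`fit_t2_wls` agrees with a brute-force grid minimizer of the same weighted
objective to machine precision (the acceptance suite asserts 0.1 ms median
over 500 noisy pixels).

## Noise estimation

$\sigma$ serves both as the denoiser strength and as the fit uncertainty. It
is estimated once, from the first-echo zero-filled magnitude: Otsu's threshold
removes the background, the foreground is tiled into non-overlapping 5×5
patches, and $\sigma$ is the mode — the center of the tallest
Freedman–Diaconis histogram bin — of the patch standard deviations. Otsu
always splits a histogram, so the split is accepted as background removal
only when the dim class is substantially darker than the bright class (mean
ratio < 0.5); otherwise the whole image is foreground (a noisy but fully
occupied field of view). The optional conservative variant halves the
estimate to preserve detail. Estimated once and held fixed; the estimate is
within a few percent of the generating value in simulation, and the
`--sigma` override exists for when it is not trusted.

## The plug-and-play denoiser

The prior is a registry of denoisers with the contract
`f(image, sigma) -> image`, `sigma = 0` being a no-op. The default, `nlm`, is
a non-local means written in C++: 5×5 patches, an 11×11 search window,
noise-compensated patch distances and weights
$\exp(-\max(d^2 - 2\sigma^2, 0)/(0.4\sigma)^2)$. The constants were fixed by
a small grid over the h-factor and search radius on a pure denoising task
(noisy phantom image vs clean, mean squared error) and not revisited.
`gaussian-blur`, `median`, and `identity` are also registered — `identity`
turns the solver into plain constrained least squares and enables the exact
fixed-point tests. `register_denoiser()` accepts user plug-ins.

Patch-based denoisers have a scale: structures at or below the patch size get
averaged into their surroundings, and the multiplier feedback then compounds
the shrinkage over iterations. Vials should sit comfortably above the patch
scale (the default phantom radius at 128×128 is 7 pixels against a 5×5
patch); the baselines test file demonstrates the comparison at that regime.

## Sampling, phase, and formats

- **Undersampling** acts on whole phase-encode lines (array rows):
  `make_mask` always keeps the central 10% of lines and discards a fraction
  of the rest uniformly at random. Both counts use round-half-to-even; the
  central block centers with ties toward the lower index; masks are
  deterministic per seed and the kept count is seed-independent.
- **Phase maps** are estimated once from the zero-filled images,
  $A_i = \exp(i\,\mathrm{arg}\, \mathrm{IFFT}(g_i))$, with zero-magnitude
  pixels assigned phase 1, and held fixed through the iteration.
- **Fourier convention** is unitary in both directions, so Parseval holds
  with constant 1 and k-space noise sd equals image-domain noise sd; the
  simulator's noise level is therefore directly comparable to image
  intensities.
- **Containers**: k-space travels in HDF5 (`/kspace_real`, `/kspace_imag`,
  `/te_ms`, `/mask`; the HDF5 bindings carry no complex dtype, so real and
  imaginary parts are separate datasets), images and T2 maps in NIfTI
  (float32 on disk, identity affine for synthetic data; doubles in memory).

## Baselines

- `two_step_recon`: magnitude of the per-echo inverse transform, then the
  same `fit_t2_wls` — differences against the joint method isolate the
  reconstruction stage.
- `cs_tv_recon`: per-echo compressed sensing with 1D total variation along
  the phase-encode direction, solved by monotone FISTA with the exact 1D TV
  prox (a direct taut-string algorithm in C++); the objective never
  increases. The default weight is a calibrated relative value
  (4×10⁻³ of the peak zero-filled intensity).
- `kspace_pnp_recon`: the ablation — the same ADMM/PnP machinery with the
  decay constraint removed. Without the TE coupling the stopping statistic
  typically stalls; if MRC has not decreased by iteration 4 the iteration is
  stopped there, and the T2 map is fitted post hoc.

## The synthetic phantom: what it emulates and what it does not

`make_vial_phantom` lays out 14 circular vials on two concentric rings with
uniform proton density and the calibrated T2 ladder 8.75–853 ms of a
commercial relaxometry phantom; `te_ladder("fse11")` is the matching
fast-spin-echo protocol (11–176 ms at 11 ms spacing — 16 echoes, the
protocol's echo-train length; a 32-echo ladder at 14.4 ms spacing is the
second preset). `simulate_acquisition` composes the decay model, a phase
pattern (none, planar ramp, or seeded smooth polynomial), the encoding
operator, and i.i.d. complex Gaussian k-space noise with per-echo seeded
substreams. `make_brain_like_phantom` provides a three-compartment analogue
(CSF ~1700 ms, gray ~118 ms, white ~95 ms) for three-ROI evaluation.

The generator reproduces the measurement chain the method addresses —
Fourier encoding, line undersampling, complex noise (hence Rician magnitude
statistics), smooth phase. It does **not** simulate echo-train physics
(stimulated echoes, B1 errors, T1 contamination), partial-volume rims beyond
pixelation, multi-coil reception, or spatially varying noise. Passing tests
therefore validate the optimization and its implementation, not robustness
to those confounds; the ROI statistics erode each region by one pixel to
keep pixelated rims out of the summaries.

Default study conditions used by the tests and the acceptance script: a
128×128 grid, the 16-echo ladder, noise at 2% of the peak first-echo
intensity (SNR 50, "moderate"), ten seeds where variability matters. These
sizes keep a full joint reconstruction near 15–25 s.

## Numerical and design notes

- The solver state is deterministic given data, configuration, and seed;
  reruns are bit-identical.
- Long T2 values are intrinsically fragile on a short ladder: at T2 = 853 ms
  the 176 ms ladder spans only 12% of the decay, so a 1% image bias maps to
  roughly 10% in T2 — visible in undersampled comparisons for the longest
  vials in either direction.
- The published closed forms for the image updates contain typos (stray
  transposes, an `f_b`); both updates here are derived directly from the
  subproblems, and the unit tests assert minimizer optimality against random
  perturbation probes and a fixed-point property at the ground truth.
- The degenerate single-echo first-image update drops the decay terms and is
  tested against its closed form.
- ROI standard deviations use the sample (n−1) convention.

## Known limitations

The MRC threshold transfers imperfectly across data sets (the stopping rule
is a heuristic); the decay model is 2-parameter mono-exponential (no offset,
no multi-component T2); phase is single-coil and fixed; the undersampled
problem relies entirely on the denoiser and TE coupling for regularization,
and short-T2 vials show the largest undersampling deviations, consistent
with the method's published behavior.
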