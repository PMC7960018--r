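---
title: "Sparse slice-to-volume reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse slice-to-volume reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsesvr)
```

# The problem

Fetal-brain MRI is acquired as stacks of thick 2D slices (SSFSE-style, one
slice per shot) in several orientations, because a full 3D acquisition is
too slow for a moving fetus. Each slice is sharp in-plane but the subject
may move between slices, so the stacks are mutually inconsistent, and the
acquisition can further be *sparsely sampled* — a large fraction of pixels
deliberately or accidentally missing. `sparsesvr` reconstructs a single
isotropic 3D volume from such data by interleaving rigid slice
registration, a point-spread-function (PSF) super-resolution update, robust
EM rejection of motion-corrupted measurements, and an adaptive steering
kernel regression that fills and denoises sparsely covered voxels while
preserving edges.

# Acquisition model

A measured slice relates to the underlying (unknown) intensities by

$$ \mathrm{vec}(I'_j) \;=\; S'_j\,e^{-B_j}\,\mathrm{vec}(I^s_j), $$

where $S'_j>0$ is a per-slice scale, $B_j$ a smooth bias exponent (field
inhomogeneity is multiplicative), and $I^s_j$ the sparsely sampled slice
(invalid pixels are flagged in a validity mask and never used).
`correct_slice()` applies this correction. Bias and scale are carried as
known simulation parameters; during reconstruction of real data they
default to identity, since their estimation is a separate problem this
package does not attempt.

Geometry is a single affine chain: pixel index $p_s = (i,j,0,1)^T$ of slice
$j$ maps to a continuous voxel coordinate of the reconstruction grid by

$$ p_r = W_r^{-1}\, T_{\mathrm{global}}\, T_{\mathrm{local}}\, W_s\, p_s, $$

with $W_s, W_r$ the slice/volume world affines, $T_{\mathrm{global}}$ the
stack-to-template pose and $T_{\mathrm{local}}$ the per-slice motion
correction. Conventions, fixed once and used everywhere: voxel and pixel
centers sit at integer 0-based indices; world units are millimetres; Euler
angles are intrinsic Z-Y-X; `nearest_voxel()` rounds halves away from zero.

# Motion scoring and template choice

Stacking the vectorized slices of one stack as columns of $D$, slices of a
motion-free stack are strongly linearly correlated, so $D$ is nearly
low-rank. With $\delta_r = \|D - D_r\|_F / \|D\|_F$ the relative error of
the best rank-$r$ approximation (truncated SVD), the stack-motion surrogate
is $\mu = \delta_{r^*} r^*$ where $r^*$ is the smallest rank with
$\delta_{r^*} < \beta$. The stack with minimal $\mu$ becomes the
registration template. $\beta$ defaults to 0.1 (no reference value is
published; the ranking is insensitive to $\beta$ over a broad range because
$\delta_r$ curves of stacks with different motion rarely cross). Invalid
pixels enter $D$ as zeros so the matrix shape is constant across removal
ratios; at assessment time bias and scale are usually still unknown, so raw
intensities are used.

# PSF volume update

The slice profile is modelled as a separable 3D Gaussian whose FWHM equals
the slice thickness through-plane and the pixel spacing in-plane
(`sigma_from_fwhm()`, $\sigma = \mathrm{FWHM}/2.355$). One text passage
elsewhere equates $\sigma_z$ itself with the thickness; the FWHM statement
is the cited physical model and is the one implemented. The kernel is
truncated at 2$\sigma$ per axis (<2% tail mass).

Scatter: every valid pixel adds its corrected intensity into all voxels
within the truncated support of its mapped position, weighted by the PSF
evaluated in the slice frame; the weights accumulate in a parallel volume.
Gather: voxels divide accumulated intensity by accumulated weight. The
printed update rule is purely additive, which diverges under repeated
iteration; the weighted-mean normalization is the standard reading and is
what `gather_volume()` does. Voxels with zero accumulated weight are
*unknown* and are the primary target of the steering update below.

Simulation (`simulate_slices()`) is the adjoint: each simulated pixel is
the PSF-weighted average of known voxels in its footprint, and residuals
$e^* = I' - I^{ss}$ on valid pixels drive both the robust statistics and
the final correction.

# Robust EM outlier model

Residuals are modelled as a two-component mixture: zero-mean Gaussian
inliers ($\sigma$) and uniform outliers over the observed residual range
($U = 1/\mathrm{range}$, the only range available). The E-step computes
pixel posteriors $p_{ij}$, the M-step the posterior-weighted $\sigma$ and
the inlier fraction $c$; iteration stops at relative changes below $10^{-4}$
or 50 iterations, warm-started across outer iterations. Slice quality is
$p^{\mathrm{slice}}_j = \sum_i p_{ij}^2 / N_j$; slices below 0.5 are
excluded from the PSF update. Initialization ($\sigma$ = sample sd,
$c = 0.9$) and the threshold are package defaults; none are published.
$\sigma$ is floored at $0.02\,\mathrm{sd}(e^*)$: noise-free synthetic data
contains exact-zero background residuals on which an unfloored EM collapses
to a point mass and outlaws every structured pixel.

# Steering kernel regression

The core adaptive update models the volume locally by a second-order Taylor
polynomial and fits it at every voxel by weighted least squares over the
known voxels of a $k_s^3$ window,

$$ \hat B = (X_F^T W X_F)^{-1} X_F^T W Y, $$

with design rows $[1, d^T, \mathrm{vech}^T(dd^T)]$. The weights are the
*steering* kernel

$$ K_s(d) = \frac{\sqrt{\det C_i}}{2\pi h_s^2}
   \exp\!\Big(-\frac{d^T C_i\, d}{2 h_s^2}\Big), $$

whose covariance $C_i$ adapts to the local structure: starting from
gradients estimated by a classical (isotropic Gaussian) kernel regression,
per-voxel gradient outer products are summed over a $w^3$ analysis window,
eigendecomposed ($C = U\,\mathrm{diag}(s)\,U^T$), and rebuilt with

$$ a_k = \frac{s_k + \lambda}{\prod_{j \ne k}(s_j+\lambda)^{1/2}}, \qquad
   \gamma = \Big(\frac{\prod_k (s_k+\lambda)^{1/2}}{L}\Big)^{\alpha}, \qquad
   C_i = \gamma\, U\,\mathrm{diag}(a)\,U^T . $$

This elongates the kernel along edges (fast decay across, slow decay
along), is isotropic in flat regions, always SPD, and reduces to a
scale-insensitive kernel at $\alpha = 0$ (where $\prod a_k = 1$). The
construction itself is not printed in full anywhere; this eigenvalue
elongation/scaling form follows the steering-kernel literature the
parameters are named after, and its flat-region and isotropic limits are
regression-tested in closed form.

Two deliberate numerical choices:

* **Gradient normalization.** The covariance analysis operates on gradients
  divided by the volume's dynamic range. With raw 0–255 intensities the
  gradient energy dwarfs $\lambda = 2$, $\gamma$ exceeds 1 at edges, and
  larger $\alpha$ *sharpens* — the opposite of the documented behavior. On
  dimensionless gradients $\gamma < 1$ everywhere, so larger $\alpha$
  means larger footprints and more smoothing, monotonically; $\lambda = 2$
  is then a meaningful regularizer.
* **Fallbacks.** Windows with fewer than 10 known voxels, or
  normal-equation systems with condition number above $10^{10}$, fall back
  to the order-0 weighted mean with zero gradient; voxels with no known
  neighbor keep their previous estimate and are reported.

The update runs `iterations = 3` refits (gradients, covariances and
estimates are recomputed each time), after which simulated slices and
residuals are refreshed and the robust combined correction

$$ X^{n+1}(p_r) = \frac{\sum \mathrm{PSF}\cdot p^{\mathrm{slice}}_j p_{ij}
   \, e^*}{\sum \mathrm{PSF}} + X^n(p_r) $$

is scattered into the volume. Normalizing by the *plain* PSF weights (not
the robustness-weighted ones) makes low-posterior pixels contribute
proportionally smaller corrections; with all posteriors zero or all
residuals zero the volume is unchanged, and in the near-delta-PSF limit a
single unit residual moves its voxel by exactly one unit.

Defaults ($k_c = 5$, $h_c = 2$, $k_s = 7$, $h_s = 0.5$, $w = 3$,
$\lambda = 2$, $\alpha = 0.4$, 3 refits) follow the reference protocol.
Offsets are measured in voxel units of the isotropic grid.

# Rigid registration

No registration toolkit is prescribed, so both registrations are
implemented here with a normalized-cross-correlation (NCC) dissimilarity —
insensitive to the per-slice scale factor of the acquisition model — and a
derivative-free Powell-style coordinate descent with step halving.
Volume-to-volume (stack to template) runs coarse-to-fine over a 3-level
mean-pooled pyramid; out-of-field samples are excluded from the metric, and
solutions with less than 10% overlap are flagged unconverged.

Slice-to-volume registration compares the observed valid pixels against the
slice simulated from the volume at the candidate pose. Four safeguards,
each of which measurably prevented a failure mode on synthetic data, are
applied and documented here because they shape behavior:

* a box trust region (default ±15°, ±10 mm) around the initial pose —
  per-slice fetal motion is physiologically bounded and the NCC landscape
  of a single 2D slice has spurious distant minima;
* a coarse-to-fine schedule in PSF width (2.5× widened kernel first);
* low-structure and overlap guards: slices whose valid-pixel standard
  deviation is below 8% of the volume's dynamic range, or whose candidate
  pose slides more than 15% of valid pixels out of the field, keep their
  current pose;
* update damping: pose updates are only accepted when they improve the
  dissimilarity by at least `min_gain` (default 0.01). On an imperfect
  consensus volume, micro-gains are discretization noise and accumulate
  into a pose random walk over the outer iterations.

# The outer loop

Each of the `outer_iterations` (default 3) runs: PSF volume update over
included slices → EM on the residuals, slice exclusion → steering kernel
regression update → slice-to-volume registration against the steered
volume → residual refresh at the refined poses → robust combined update.
Registering *before* the combined update matters: the combined step
scatters each slice's own residual at its current pose, so registering
afterwards would anchor every slice where it already is. The reconstruction
grid is isotropic at the template's in-plane spacing, axis-aligned over the
template stack's bounding box. The whole pipeline is deterministic for a
fixed configuration.

# The synthetic acquisition generator

`generate_phantom()` builds a deterministic nested-ellipsoid object
(background 10, shell ~120 azimuthally modulated, interior 60, two lobes
200/170, bright core 235, plus a low-amplitude smooth texture) in [0, 255].
The shell modulation is deliberate: a rotationally symmetric shell would
leave in-plane slice rotation unidentifiable, which no real brain exhibits.
`simulate_stack()` samples it through the acquisition chain: PSF-weighted
resampling at a uniformly drawn per-slice rigid motion (applied about the
slice center), multiplication by $e^{B}/S'$ with a low-order-polynomial
bias exponent and a uniform per-slice scale, additive Gaussian noise, and
exact `round(p·m)`-count random pixel removal per slice
(`sparse_sample()`), independently per slice.

Default study conditions, chosen once: 1 mm in-plane spacing, 3 mm slice
thickness, axial + coronal + sagittal stacks, motion up to 5°/3 mm per
slice, noise sd 2 (~1% of the intensity range), bias amplitude 0.3, scale
in [0.9, 1.1]. Trend experiments over removal ratios use zero motion with
noise sd 2 so that the sparsity effect is isolated.

The pose-recovery experiment uses the *motion-burst* regime: most slices
still, every fifth slice displaced by a rigid burst of up to 3°/2 mm —
the discrete-movement corruption the robust statistics are designed for.
The sound consensus formed by the still slices re-registers the corrupted
ones (median target-registration error roughly halves over three outer
iterations) while still slices do not move. When instead *every* slice
carries independent uniform motion at desk scale, the consensus degrades in
proportion and registration against it is neutral at best: slices register
near-perfectly against the true volume under the same amplitudes, so this
is a property of the desk-scale consensus (motion amplitude a large
fraction of the 32 mm head), not of the registration machinery.

What the generator does *not* emulate: T2 relaxation and k-space effects,
spin-history artifacts, through-plane motion within a single slice, and
anatomy-specific texture. Passing tests therefore demonstrate the
algorithmic properties of the pipeline — sparsity robustness, outlier
rejection, pose refinement, edge-preserving interpolation — not clinical
image quality.

# Problem sizes

The test suite and the acceptance script run reconstructions at 64³ voxels
(removal sweeps, three stacks of 1 mm × 3 mm slices) and 16–32³ for unit
and behavioral fixtures; these sizes make each full pipeline run take on
the order of one to three minutes on a single core while leaving every
algorithmic path exercised. Larger volumes change cost roughly linearly in
voxel count (the steering window dominates).

# Known limitations

* Bias field and scale are not estimated from data; they are corrected only
  when known (as in simulation).
* Registration capture range is local; stacks must overlap substantially
  and per-slice motion beyond the trust region is handled by exclusion, not
  recovery.
* The uniform outlier density is tied to the observed residual range, so a
  single extreme residual widens it.
* SSIM can be negative on anticorrelated content; `mssim()` reports the
  plain mean without clamping.
* Anisotropic reconstruction grids and non-rigid motion are out of scope.
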