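# sparsesvr

Slice-to-volume reconstruction (SVR) for sparsely sampled, motion-corrupted
multi-stack MRI, with an adaptive steering kernel regression volume update.

Fetal-brain MRI (and other moving-subject MRI) is acquired as stacks of
thick 2D slices in several orientations; the subject moves between slices,
and sparse sampling — whether deliberate, to shorten acquisition, or from
data loss — removes a large fraction of pixels. `sparsesvr` rebuilds a
single isotropic 3D volume from such data. It is aimed at image-analysis
researchers who want a complete, inspectable, CPU-only reference pipeline
with a synthetic acquisition simulator for controlled experiments.

The pipeline, per outer iteration after low-rank template selection and
rigid stack-to-template registration:

1. **PSF volume update** — every valid pixel is scattered into the volume
   through a separable 3D Gaussian point-spread function (FWHM = slice
   thickness through-plane, = pixel spacing in-plane); voxels are the
   PSF-weighted means of their measurements.
2. **Robust EM outlier rejection** — residuals between acquired and
   simulated slices are modelled as a Gaussian-inlier / uniform-outlier
   mixture $P(e^*) = c\,N_\sigma(e^*) + (1-c)\,U$; pixel posteriors
   $p_{ij}$ and slice scores $p^{slice}_j = \sum_i p_{ij}^2/N_j$ exclude
   motion-corrupted slices.
3. **Steering kernel regression** — every voxel is re-estimated by an
   order-2 local polynomial fit $\hat B = (X_F^T W X_F)^{-1} X_F^T W Y$
   over the known voxels of a $k_s^3$ window, weighted by the
   structure-adaptive kernel
   $K_s(d) \propto \sqrt{\det C_i}\,\exp(-d^T C_i d / 2h_s^2)$ whose
   covariance elongates along local edges (estimated from gradient
   structure tensors, eigenvalue-regularized by $\lambda$ and the structure
   sensitivity $\alpha$). This fills unknown voxels and denoises the rest
   while preserving edges.
4. **Rigid slice-to-volume registration** refines each slice's 6-DOF pose
   by normalized cross-correlation, followed by a robust residual
   correction weighted by $p^{slice}_j\,p_{ij}$.

The synthetic module simulates the whole forward process: nested-ellipsoid
phantoms, per-slice rigid motion, multiplicative bias `exp(-B)`, per-slice
intensity scaling, additive noise, and exact-count random pixel removal
from 10% to 90%.

## Worked example

```r
library(sparsesvr)

# ground truth and a 3-stack acquisition with 70% of pixels removed
gt  <- generate_phantom(c(48, 48, 48), spacing = 1, seed = 42)
cfg <- acquisition_config(removal_proportion = 0.7, seed = 42,
                          motion_rotation_deg = 0, motion_translation_mm = 0)
sim <- simulate_acquisition(gt, cfg)
sim$stacks[[1]]
#> <svr_stack> axial: 16 slices of 48x48, spacing 1 mm, thickness 3 mm

# low-rank motion scores: mu = delta_r * r, smaller = less motion
assess_stacks(sim$stacks)
#>   stack orientation r_star       mu beta
#> 1     1       axial     14 0.736587  0.1
#> 2     2     coronal     12 1.123050  0.1
#> 3     3    sagittal     14 1.008143  0.1

res <- reconstruct(sim$stacks, pipeline_config())
res
#> <svr_result> template stack 1, 48 slices (0 excluded), 48x48x46 grid

evaluate_reconstruction(res, gt)
#>      rmse     mssim n_windows window_size dynamic_range
#> 1 16.1154 0.8319791     70560           7      234.5363
```

The stack with the smallest motion surrogate `mu` (here the axial one)
becomes the registration template. The final report compares the
reconstruction against the ground truth resampled on the reconstruction
grid: the root-mean-square intensity error (`rmse`, in intensity units of
the 0–255 phantom) and the mean structural similarity (`mssim`, 1 = perfect)
over all 7³ windows. Disabling the steering update
(`pipeline_config(use_steering = FALSE)`) on the same acquisition raises
the RMSE by about 25% — at this 70% removal level the printed improvement is

```r
rmse_improvement(m_psf_only$rmse, m_full$rmse)
#> 20.06  (percent RMSE reduction attributable to the steering update)
```

A thin CLI wraps the same functions
(`inst/exec/sparsesvr simulate|assess|reconstruct|evaluate|ablate`).

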