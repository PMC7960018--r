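#' Synthetic acquisition configuration
#'
#' Parameters of the forward acquisition simulator: multi-orientation stacks
#' of thick slices sampled from a ground-truth volume through the Gaussian
#' slice PSF, each slice perturbed by a random rigid motion, modulated by a
#' smooth multiplicative bias field and a per-slice intensity scale,
#' corrupted by additive Gaussian noise, and sparsely sampled by random pixel
#' removal.
#'
#' Defaults emulate an SSFSE-like fetal protocol at desk scale: 1 mm in-plane
#' spacing, 3 mm slice thickness, per-slice motion up to 5 degrees / 3 mm,
#' noise standard deviation 2 (about 1% of the 0-255 range), bias amplitude
#' 0.3 in the exponent, per-slice scale between 0.9 and 1.1.
#'
#' @param orientations character vector of stack orientations, subset of
#'   "axial", "coronal", "sagittal".
#' @param slice_thickness through-plane size (mm).
#' @param in_plane_spacing pixel size (mm).
#' @param motion_rotation_deg,motion_translation_mm per-slice motion bounds;
#'   each rigid parameter is drawn uniformly in +/- the bound.
#' @param noise_sigma additive Gaussian noise standard deviation (intensity).
#' @param bias_amplitude maximum |B| of the simulated bias exponent.
#' @param scale_range range of the per-slice scale S'.
#' @param removal_proportion fraction of pixels removed per slice, in [0, 1).
#' @param seed integer seed; fixed seed gives byte-identical acquisitions.
#' @return A list of class `acquisition_config`.
#' @export
acquisition_config <- function(orientations = c("axial", "coronal", "sagittal"),
                               slice_thickness = 3,
                               in_plane_spacing = 1,
                               motion_rotation_deg = 5,
                               motion_translation_mm = 3,
                               noise_sigma = 2,
                               bias_amplitude = 0.3,
                               scale_range = c(0.9, 1.1),
                               removal_proportion = 0,
                               seed = 1L) {
  stopifnot(slice_thickness > 0, in_plane_spacing > 0,
            removal_proportion >= 0, removal_proportion < 1,
            noise_sigma >= 0, bias_amplitude >= 0,
            length(scale_range) == 2, all(scale_range > 0))
  structure(list(orientations = orientations,
                 slice_thickness = slice_thickness,
                 in_plane_spacing = in_plane_spacing,
                 motion_rotation_deg = motion_rotation_deg,
                 motion_translation_mm = motion_translation_mm,
                 noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 scale_range = scale_range,
                 removal_proportion = removal_proportion,
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

# orthonormal slice axes (in-plane e1, e2; normal n = e1 x e2) per orientation
orientation_axes <- function(orientation) {
  switch(orientation,
         axial    = cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
         coronal  = cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)),
         sagittal = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
         stop("unknown orientation: ", orientation))
}

#' Simulate one stack of motion-corrupted slices
#'
#' Each slice is a PSF-weighted resampling of the ground truth under a random
#' per-slice rigid motion (drawn uniformly within the configured bounds,
#' applied about the slice center), then modulated by `exp(B)/S'` (so that
#' [correct_slice()] recovers the clean intensities) and additive Gaussian
#' noise.  The true per-slice transforms are returned alongside the stack.
#'
#' @param gt ground-truth [recon_volume()] covering the field of view.
#' @param cfg an [acquisition_config()].
#' @param orientation "axial", "coronal" or "sagittal".
#' @param stack_id identifier stored on the slices.
#' @param seed RNG seed for this stack (defaults to `cfg$seed`).
#' @return A list with `stack` (a [svr_stack()]), `transforms` (list of true
#'   per-slice [rigid_transform()]s) and `clean` (the noise/bias/scale-free
#'   stack).
#' @export
simulate_stack <- function(gt, cfg, orientation, stack_id = 1L,
                           seed = cfg$seed) {
  axes <- orientation_axes(orientation)
  d <- dim(gt$voxels)
  sp3 <- if (length(gt$spacing) == 1) rep(gt$spacing, 3) else gt$spacing
  extent <- d * sp3                       # mm per world axis
  center_w <- as.numeric(gt$world %*% c((d - 1) / 2, 1))[1:3]
  ext_axes <- abs(t(axes) %*% extent)     # extent along slice axes
  n <- max(2, round(ext_axes[1] / cfg$in_plane_spacing))
  h <- max(2, round(ext_axes[2] / cfg$in_plane_spacing))
  k <- max(1, round(ext_axes[3] / cfg$slice_thickness))
  spec <- psf_spec(in_plane_fwhm = cfg$in_plane_spacing,
                   through_plane_fwhm = cfg$slice_thickness)
  rot_amp <- cfg$motion_rotation_deg * pi / 180
  tra_amp <- cfg$motion_translation_mm
  Wgt_inv <- solve(gt$world)
  out <- with_seed(seed, {
    slices <- vector("list", k)
    clean_slices <- vector("list", k)
    transforms <- vector("list", k)
    for (s in seq_len(k)) {
      origin <- center_w - axes[, 1] * cfg$in_plane_spacing * (n - 1) / 2 -
        axes[, 2] * cfg$in_plane_spacing * (h - 1) / 2 -
        axes[, 3] * cfg$slice_thickness * ((k - 1) / 2 - (s - 1))
      Ws <- diag(4)
      Ws[1:3, 1] <- axes[, 1] * cfg$in_plane_spacing
      Ws[1:3, 2] <- axes[, 2] * cfg$in_plane_spacing
      Ws[1:3, 3] <- axes[, 3] * cfg$slice_thickness
      Ws[1:3, 4] <- origin
      # rigid motion about the slice center
      ang <- runif(3, -rot_amp, rot_amp)
      tra <- runif(3, -tra_amp, tra_amp)
      slice_ctr <- as.numeric(Ws %*% c((n - 1) / 2, (h - 1) / 2, 0, 1))[1:3]
      Tj <- transform_about(rigid_transform(ang, tra), slice_ctr)
      transforms[[s]] <- Tj
      A <- Wgt_inv %*% Tj$matrix %*% Ws
      Sm <- Tj$matrix[1:3, 1:3] %*% axes      # moved slice axes in world
      M <- t(Sm) %*% gt$world[1:3, 1:3]       # voxel offset -> slice-frame mm
      sim <- cpp_simulate_slices(gt$voxels, 0 + (gt$weights > 0),
                                 list(c(n, h)), list(A[1:3, , drop = FALSE]),
                                 list(M), sigma = spec$sigma,
                                 support = spec$support_radius)[[1]]
      if (all(is.na(sim)))
        stop(sprintf("slice %d motion pushed it fully outside the phantom", s))
      sim[is.na(sim)] <- 0
      clean_slices[[s]] <- svr_slice(sim, cfg$in_plane_spacing,
                                     cfg$slice_thickness, world = Ws,
                                     stack_id = stack_id, slice_index = s)
      bias <- simulate_bias_field(n, h, cfg$bias_amplitude)
      scl <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
      obs <- exp(bias) / scl * sim +
        matrix(rnorm(n * h, 0, cfg$noise_sigma), n, h)
      obs <- pmax(obs, 0)
      slices[[s]] <- svr_slice(obs, cfg$in_plane_spacing, cfg$slice_thickness,
                               world = Ws, scale = scl, bias = bias,
                               stack_id = stack_id, slice_index = s)
    }
    list(slices = slices, clean = clean_slices, transforms = transforms)
  })
  list(stack = svr_stack(out$slices, orientation_tag = orientation),
       clean = svr_stack(out$clean, orientation_tag = orientation),
       transforms = out$transforms)
}

# smooth low-order 2D polynomial bias exponent, scaled to max |B| = amplitude
simulate_bias_field <- function(n, h, amplitude) {
  if (amplitude == 0) return(matrix(0, n, h))
  u <- seq(-1, 1, length.out = n)
  v <- seq(-1, 1, length.out = h)
  co <- runif(6, -1, 1)
  B <- outer(u, v, function(x, y)
    co[1] * x + co[2] * y + co[3] * x * y + co[4] * x^2 + co[5] * y^2 + co[6])
  B * amplitude / max(abs(B))
}

# rigid transform applied about an arbitrary center point
transform_about <- function(t, center) {
  Tc <- diag(4); Tc[1:3, 4] <- center
  Tc_inv <- diag(4); Tc_inv[1:3, 4] <- -center
  rigid_from_matrix(Tc %*% t$matrix %*% Tc_inv)
}

#' Random pixel removal (sparse sampling)
#'
#' Marks exactly `round(proportion * n * h)` pixels, chosen uniformly without
#' replacement, as invalid.  Pixel values under the removed mask are left
#' untouched but are never used downstream.
#'
#' @param slice a [svr_slice()].
#' @param proportion fraction of pixels to remove, in [0, 1).
#' @param seed integer seed.
#' @return The slice with an updated `valid_mask`.
#' @export
sparse_sample <- function(slice, proportion, seed = 1L) {
  if (proportion < 0 || proportion >= 1)
    stop("removal proportion must be in [0, 1)")
  m <- length(slice$pixels)
  n_remove <- round(proportion * m)
  if (n_remove > 0) {
    idx <- with_seed(seed, sample.int(m, n_remove))
    slice$valid_mask[idx] <- FALSE
  }
  slice
}

#' Simulate a full multi-stack sparse acquisition
#'
#' Runs [simulate_stack()] for every configured orientation and applies
#' [sparse_sample()] independently to every slice, deriving per-slice seeds
#' from `cfg$seed`.
#'
#' @param gt ground-truth [recon_volume()].
#' @param cfg an [acquisition_config()].
#' @return A list with `stacks` (list of [svr_stack()]), `clean_stacks`,
#'   `transforms` (list of per-stack lists of true [rigid_transform()]s) and
#'   `ground_truth` (the input volume).
#' @export
simulate_acquisition <- function(gt, cfg) {
  stacks <- list(); clean <- list(); transforms <- list()
  for (o in seq_along(cfg$orientations)) {
    sim <- simulate_stack(gt, cfg, cfg$orientations[o], stack_id = o,
                          seed = cfg$seed + 1000L * o)
    st <- sim$stack
    if (cfg$removal_proportion > 0) {
      for (s in seq_along(st$slices))
        st$slices[[s]] <- sparse_sample(st$slices[[s]],
                                        cfg$removal_proportion,
                                        seed = cfg$seed + 1000L * o + s)
    }
    stacks[[o]] <- st
    clean[[o]] <- sim$clean
    transforms[[o]] <- sim$transforms
  }
  list(stacks = stacks, clean_stacks = clean, transforms = transforms,
       ground_truth = gt)
}
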