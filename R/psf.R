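#' Gaussian slice point-spread-function specification
#'
#' The slice profile is modeled as a separable 3D Gaussian whose full width
#' at half maximum equals the slice thickness through-plane and the pixel
#' spacing in-plane.  The kernel is truncated at `support_radius` standard
#' deviations per axis.
#'
#' @param in_plane_fwhm FWHM (mm) along the two in-plane axes.
#' @param through_plane_fwhm FWHM (mm) along the slice-select axis.
#' @param support_radius truncation radius in units of sigma (>= 1).
#' @return A list of class `psf_spec` with `sigma = c(sx, sy, sz)` (mm).
#' @export
psf_spec <- function(in_plane_fwhm, through_plane_fwhm, support_radius = 2) {
  stopifnot(support_radius >= 1)
  sx <- sigma_from_fwhm(in_plane_fwhm)
  sz <- sigma_from_fwhm(through_plane_fwhm)
  structure(list(sigma = c(sx, sx, sz), support_radius = support_radius),
            class = "psf_spec")
}

#' Gaussian sigma from full width at half maximum
#'
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, approximately `fwhm / 2.3548`.
#'
#' @param fwhm full width at half maximum (> 0).
#' @return The Gaussian standard deviation.
#' @examples
#' sigma_from_fwhm(2.3548)  # ~= 1
#' @export
sigma_from_fwhm <- function(fwhm) {
  if (any(fwhm <= 0)) stop("fwhm must be > 0")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Unnormalized PSF weight at an offset
#'
#' Product Gaussian `exp(-dx^2/(2 sx^2) - dy^2/(2 sy^2) - dz^2/(2 sz^2))`,
#' in (0, 1].  The global scale is irrelevant: weights are normalized at the
#' gather step.
#'
#' @param dx,dy,dz offsets (mm) in the slice frame.
#' @param spec a [psf_spec()].
#' @return The weight.
#' @export
psf_weight <- function(dx, dy, dz, spec) {
  s <- spec$sigma
  exp(-dx^2 / (2 * s[1]^2) - dy^2 / (2 * s[2]^2) - dz^2 / (2 * s[3]^2))
}

# per-slice mapping matrices for the C++ kernels:
#  A: pixel index (i, j) -> continuous voxel coordinate (3x4)
#  M: voxel-index offset -> mm offsets in the (moved) slice frame (3x3)
slice_maps <- function(slice, t_global, t_local, volume) {
  Tt <- t_global$matrix %*% t_local$matrix
  A <- solve(volume$world, Tt %*% slice$world)
  ax <- slice$world[1:3, 1:3]
  ax <- sweep(ax, 2, sqrt(colSums(ax^2)), "/")     # unit slice axes
  Sm <- Tt[1:3, 1:3] %*% ax                        # moved axes in world
  M <- t(Sm) %*% volume$world[1:3, 1:3]
  list(A = A[1:3, , drop = FALSE], M = M)
}

known_mask <- function(volume) 0 + (volume$weights > 0)

#' Scatter slice pixels into the reconstruction volume through the PSF
#'
#' Every valid pixel adds its corrected intensity into all voxels whose
#' centers fall within `support_radius * sigma` of its mapped position (per
#' slice-frame axis), weighted by the Gaussian PSF and an optional per-pixel
#' multiplier; the weights accumulate alongside.  [gather_volume()] then
#' divides accumulated intensities by accumulated weights.
#'
#' @param slice a [svr_slice()] (corrected internally via [correct_slice()]).
#' @param t_global,t_local [rigid_transform()]s.
#' @param volume a [recon_volume()] accumulator (raw sums in `voxels`).
#' @param spec a [psf_spec()].
#' @param pixel_weight optional matrix of per-pixel multipliers.
#' @return The updated accumulator volume.
#' @export
scatter_slice_to_volume <- function(slice, t_global, t_local, volume, spec,
                                    pixel_weight = NULL) {
  scatter_slices(list(slice), list(t_global), list(t_local), volume, spec,
                 pixel_weights = if (is.null(pixel_weight)) NULL
                                 else list(pixel_weight))
}

#' @rdname scatter_slice_to_volume
#' @param slices list of slices; `t_globals`, `t_locals` and (optionally)
#'   `pixel_weights` are parallel lists.
#' @param t_globals,t_locals lists of [rigid_transform()]s.
#' @param pixel_weights optional list of per-pixel multiplier matrices.
#' @param values optional list of matrices scattered in place of the
#'   corrected pixel intensities (used by the robust residual update).
#' @export
scatter_slices <- function(slices, t_globals, t_locals, volume, spec,
                           pixel_weights = NULL, values = NULL) {
  n <- length(slices)
  vals <- vector("list", n); masks <- vector("list", n)
  pw <- vector("list", n); As <- vector("list", n); Ms <- vector("list", n)
  for (s in seq_len(n)) {
    sl <- correct_slice(slices[[s]])
    vals[[s]] <- if (is.null(values)) sl$pixels else values[[s]]
    masks[[s]] <- sl$valid_mask
    if (!is.null(pixel_weights)) pw[[s]] <- pixel_weights[[s]]
    mp <- slice_maps(sl, t_globals[[s]], t_locals[[s]], volume)
    As[[s]] <- mp$A; Ms[[s]] <- mp$M
  }
  out <- cpp_scatter_slices(vals, masks, pw, As, Ms, dim(volume$voxels),
                            spec$sigma, spec$support_radius)
  if (out$n_oob > 0 && out$n_oob == sum(vapply(masks, sum, numeric(1))))
    warning("all pixels fell outside the reconstruction field of view")
  volume$voxels <- volume$voxels + out$accum
  volume$weights <- volume$weights + out$wsum
  volume
}

#' @rdname scatter_slice_to_volume
#' @export
gather_volume <- function(volume) {
  w <- volume$weights
  v <- volume$voxels
  v[w > 0] <- v[w > 0] / w[w > 0]
  v[w <= 0] <- 0
  volume$voxels <- v
  volume
}

#' Forward-simulate slices from the reconstructed volume
#'
#' Each simulated pixel is the PSF-weighted average of the known voxels in
#' its mapped footprint (the adjoint of the scatter).  Residuals
#' `e* = corrected observed - simulated` are returned on valid pixels;
#' pixels with an empty footprint are `NA` and excluded.
#'
#' @param volume a gathered [recon_volume()] (weights mark known voxels).
#' @param slices list of observed [svr_slice()]s.
#' @param t_globals,t_locals parallel lists of [rigid_transform()]s.
#' @param spec a [psf_spec()].
#' @return A list with `simulated` (list of matrices) and `residuals`
#'   (list of matrices, `NA` where invalid or unsimulated).
#' @export
simulate_slices <- function(volume, slices, t_globals, t_locals, spec) {
  n <- length(slices)
  shapes <- vector("list", n); As <- vector("list", n); Ms <- vector("list", n)
  for (s in seq_len(n)) {
    shapes[[s]] <- dim(slices[[s]]$pixels)
    mp <- slice_maps(slices[[s]], t_globals[[s]], t_locals[[s]], volume)
    As[[s]] <- mp$A; Ms[[s]] <- mp$M
  }
  sim <- cpp_simulate_slices(volume$voxels, known_mask(volume), shapes, As,
                             Ms, spec$sigma, spec$support_radius)
  res <- vector("list", n)
  for (s in seq_len(n)) {
    corr <- correct_slice(slices[[s]])
    r <- corr$pixels - sim[[s]]
    r[!corr$valid_mask] <- NA
    res[[s]] <- r
  }
  list(simulated = sim, residuals = res)
}
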