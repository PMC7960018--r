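#' Slice, stack and reconstruction-volume containers
#'
#' A `svr_slice` is a single 2D acquisition: an `n x h` pixel grid with a
#' validity mask (false where pixels were removed by sparse sampling), the
#' in-plane pixel spacing and through-plane slice thickness (mm), a world
#' affine mapping the homogeneous 0-based pixel index `c(i, j, 0, 1)` to
#' world millimetres, a per-slice intensity scale `S'` and an additive-in-the-
#' exponent bias field `B` (the acquisition model is
#' `corrected = S' * exp(-B) * observed`).
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param spacing in-plane pixel size (mm, > 0).
#' @param thickness through-plane size (mm, > 0).
#' @param world 4x4 affine, pixel index (0-based) to world mm.  Default:
#'   axis-aligned with the in-plane/through-plane spacings, origin 0.
#' @param valid_mask logical matrix, same shape as `pixels`.
#' @param scale dimensionless `S'` (> 0).
#' @param bias bias field `B`: a scalar or matrix matching `pixels`.
#' @param stack_id,slice_index identifiers.
#' @return An object of class `svr_slice`.
#' @export
svr_slice <- function(pixels, spacing, thickness, world = NULL,
                      valid_mask = NULL, scale = 1, bias = 0,
                      stack_id = 1L, slice_index = 1L) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("slice pixels must be finite")
  stopifnot(spacing > 0, thickness > 0)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  valid_mask <- as.matrix(valid_mask)
  if (!identical(dim(valid_mask), dim(pixels)))
    stop("valid_mask shape must equal pixels shape")
  if (is.null(world)) {
    world <- diag(c(spacing, spacing, thickness, 1))
  }
  stopifnot(all(dim(world) == c(4, 4)))
  if (length(bias) == 1) bias <- matrix(bias, nrow(pixels), ncol(pixels))
  structure(list(pixels = pixels, valid_mask = valid_mask, spacing = spacing,
                 thickness = thickness, world = world, scale = scale,
                 bias = as.matrix(bias), stack_id = stack_id,
                 slice_index = slice_index),
            class = "svr_slice")
}

#' @rdname svr_slice
#' @param slices list of `svr_slice` sharing spacing and thickness.
#' @param orientation_tag one of "axial", "coronal", "sagittal", "other".
#' @export
svr_stack <- function(slices, orientation_tag = "other") {
  stopifnot(length(slices) >= 1)
  sp <- vapply(slices, `[[`, numeric(1), "spacing")
  th <- vapply(slices, `[[`, numeric(1), "thickness")
  if (length(unique(sp)) != 1 || length(unique(th)) != 1)
    stop("all slices in a stack must share spacing and thickness")
  structure(list(slices = slices,
                 orientation_tag = match.arg(orientation_tag,
                                             c("axial", "coronal", "sagittal",
                                               "other"))),
            class = "svr_stack")
}

#' @rdname svr_slice
#' @param voxels 3D numeric array of intensities.
#' @param weights 3D array of accumulated PSF coefficients (>= 0); zero marks
#'   voxels with no data.
#' @export
recon_volume <- function(voxels, spacing, world = NULL, weights = NULL) {
  stopifnot(length(dim(voxels)) == 3, all(spacing > 0))
  if (is.null(weights)) weights <- array(0, dim(voxels))
  if (!identical(dim(weights), dim(voxels)))
    stop("voxels and weights must have the same shape")
  if (any(weights < 0)) stop("weights must be non-negative")
  sp3 <- if (length(spacing) == 1) rep(spacing, 3) else spacing
  if (is.null(world)) world <- diag(c(sp3, 1))
  stopifnot(all(dim(world) == c(4, 4)))
  structure(list(voxels = voxels, weights = weights, spacing = spacing,
                 world = world),
            class = "recon_volume")
}

#' @export
print.svr_stack <- function(x, ...) {
  s1 <- x$slices[[1]]
  cat(sprintf("<svr_stack> %s: %d slices of %dx%d, spacing %.3g mm, thickness %.3g mm\n",
              x$orientation_tag, length(x$slices), nrow(s1$pixels),
              ncol(s1$pixels), s1$spacing, s1$thickness))
  invisible(x)
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("<recon_volume> %s voxels, spacing %s mm, %.1f%% with data\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              100 * mean(x$weights > 0)))
  invisible(x)
}

#' Bias and scale correction of an acquired slice
#'
#' Applies the multiplicative acquisition model in reverse: the corrected
#' intensities are `scale * exp(-bias) * pixels`, element-wise.  The validity
#' mask is unchanged.
#'
#' @param slice a [svr_slice()].
#' @return The corrected slice (scale reset to 1, bias to 0).
#' @examples
#' s <- svr_slice(matrix(c(5, 7), 1), spacing = 1, thickness = 1,
#'                scale = 2, bias = log(2))
#' correct_slice(s)$pixels  # back to 5, 7
#' @export
correct_slice <- function(slice) {
  if (!is.finite(slice$scale) || slice$scale <= 0)
    stop(sprintf("slice %d of stack %s: scale must be finite and > 0",
                 slice$slice_index, slice$stack_id))
  if (!all(is.finite(slice$bias)))
    stop(sprintf("slice %d of stack %s: non-finite bias field",
                 slice$slice_index, slice$stack_id))
  slice$pixels <- slice$scale * exp(-slice$bias) * slice$pixels
  slice$scale <- 1
  slice$bias <- matrix(0, nrow(slice$pixels), ncol(slice$pixels))
  slice
}

#' Map a pixel index to a continuous voxel coordinate
#'
#' Chains the slice world affine, the local (slice motion) and global (stack
#' pose) rigid transforms, and the inverse volume world affine:
#' `W_r^{-1} T_global T_local W_s p_s`.
#'
#' @param p_s homogeneous pixel index, `c(i, j, 0, 1)` (0-based).
#' @param slice a [svr_slice()].
#' @param t_global,t_local [rigid_transform()]s (stack pose, slice motion).
#' @param volume a [recon_volume()].
#' @return Continuous 0-based voxel coordinate (length 3).
#' @export
map_pixel_to_voxel <- function(p_s, slice, t_global, t_local, volume) {
  Wr <- volume$world
  if (abs(det(Wr)) < 1e-12) stop("singular volume world affine")
  p <- solve(Wr, t_global$matrix %*% t_local$matrix %*% slice$world %*% p_s)
  as.numeric(p[1:3] / p[4])
}

#' Nearest voxel center
#'
#' Rounds each component of a continuous voxel coordinate to the nearest
#' integer index, with halves rounding away from zero.  Coordinates outside
#' the volume bounds are flagged so the caller can skip the contribution.
#'
#' @param coord continuous voxel coordinate (length 3).
#' @param dim optional volume dimensions; when given, the result carries an
#'   `out_of_field` attribute.
#' @return Integer voxel index (0-based), possibly with attribute
#'   `out_of_field`.
#' @export
nearest_voxel <- function(coord, dim = NULL) {
  stopifnot(all(is.finite(coord)))
  idx <- as.integer(sign(coord) * floor(abs(coord) + 0.5))
  if (!is.null(dim)) {
    attr(idx, "out_of_field") <- any(idx < 0L | idx > dim - 1L)
  }
  idx
}

# base world affine of a stack: slice 1's world with the through-plane step
# in the third column (slices are assumed parallel and evenly spaced)
stack_base_world <- function(stack) {
  stack$slices[[1]]$world
}

#' Collapse a stack into a 3D volume on its native anisotropic grid
#'
#' Used to register whole stacks to the template.  Invalid pixels enter as 0.
#'
#' @param stack a [svr_stack()].
#' @param corrected apply [correct_slice()] first (default TRUE).
#' @return A [recon_volume()] with the stack's native spacing.
#' @export
stack_to_volume <- function(stack, corrected = TRUE) {
  sl <- stack$slices
  if (corrected) sl <- lapply(sl, correct_slice)
  d <- c(dim(sl[[1]]$pixels), length(sl))
  vox <- array(0, d)
  wt <- array(0, d)
  for (k in seq_along(sl)) {
    p <- sl[[k]]$pixels
    p[!sl[[k]]$valid_mask] <- 0
    vox[, , k] <- p
    wt[, , k] <- sl[[k]]$valid_mask * 1
  }
  recon_volume(vox, spacing = c(sl[[1]]$spacing, sl[[1]]$spacing,
                                sl[[1]]$thickness),
               world = stack_base_world(stack), weights = wt)
}

#' NIfTI input/output for stacks, masks and volumes
#'
#' Stacks are stored one file per stack with slices along the third axis and
#' the stack's world affine in the header; validity masks are parallel 0/1
#' NIfTI files.  Reconstructed volumes are written with their world affine.
#'
#' @param stack a [svr_stack()].
#' @param path output `.nii`/`.nii.gz` path.
#' @param mask_path optional path for the validity mask.
#' @export
write_stack <- function(stack, path, mask_path = NULL) {
  sl <- stack$slices
  d <- c(dim(sl[[1]]$pixels), length(sl))
  arr <- array(0, d)
  msk <- array(1L, d)
  for (k in seq_along(sl)) {
    arr[, , k] <- sl[[k]]$pixels
    msk[, , k] <- sl[[k]]$valid_mask * 1L
  }
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(stack_base_world(stack), code = 2L)
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    m <- RNifti::asNifti(msk)
    RNifti::sform(m) <- structure(stack_base_world(stack), code = 2L)
    RNifti::writeNifti(m, mask_path)
  }
  invisible(path)
}

#' @rdname write_stack
#' @param orientation_tag stored on the returned stack.
#' @export
read_stack <- function(path, mask_path = NULL, orientation_tag = "other") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  world <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  pd <- RNifti::pixdim(img)
  msk <- if (!is.null(mask_path)) as.array(RNifti::readNifti(mask_path)) > 0.5
         else array(TRUE, dim(arr))
  nrm <- world[1:3, 3] / sqrt(sum(world[1:3, 3]^2))
  slices <- lapply(seq_len(dim(arr)[3]), function(k) {
    w <- world
    w[1:3, 4] <- world[1:3, 4] + (k - 1) * world[1:3, 3]
    svr_slice(arr[, , k], spacing = pd[1], thickness = pd[3], world = w,
              valid_mask = msk[, , k], slice_index = k)
  })
  svr_stack(slices, orientation_tag = orientation_tag)
}

#' @rdname write_stack
#' @param volume a [recon_volume()].
#' @param weights_path optional path for the accumulated-weights companion.
#' @export
write_volume <- function(volume, path, weights_path = NULL) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::sform(img) <- structure(volume$world, code = 2L)
  RNifti::writeNifti(img, path)
  if (!is.null(weights_path)) {
    w <- RNifti::asNifti(volume$weights)
    RNifti::sform(w) <- structure(volume$world, code = 2L)
    RNifti::writeNifti(w, weights_path)
  }
  invisible(path)
}

#' @rdname write_stack
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  recon_volume(as.array(img), spacing = pd[1:3],
               world = matrix(as.numeric(RNifti::xform(img)), 4, 4))
}
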