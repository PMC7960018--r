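# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Deterministic nested-ellipsoid phantom
#'
#' Builds a ground-truth volume with the gross anatomy of a brain-like test
#' object: a bright outer shell around a mid-intensity interior, two
#' high-intensity inner lobes, and a low-amplitude smooth texture.  Smooth
#' regions abut sharp boundaries so edge-adaptive (steering) kernels are
#' exercised.  Intensities lie in [0, 255].
#'
#' @param shape integer(3), voxel grid dimensions (each >= 16).
#' @param spacing isotropic voxel size in mm.
#' @param seed integer; the same seed reproduces the volume exactly.
#' @return A [recon_volume()] whose `weights` are all 1 (fully known).
#' @examples
#' ph <- generate_phantom(c(32, 32, 32), spacing = 1, seed = 7)
#' range(ph$voxels)
#' @export
generate_phantom <- function(shape, spacing = 1, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("phantom shape must have 3 dimensions, each >= 16")
  ctr <- (shape - 1) / 2
  ux <- (seq_len(shape[1]) - 1 - ctr[1]) / (0.46 * shape[1])
  uy <- (seq_len(shape[2]) - 1 - ctr[2]) / (0.46 * shape[2])
  uz <- (seq_len(shape[3]) - 1 - ctr[3]) / (0.46 * shape[3])
  U <- list(
    x = array(rep(ux, times = shape[2] * shape[3]), shape),
    y = array(rep(rep(uy, each = shape[1]), times = shape[3]), shape),
    z = array(rep(uz, each = shape[1] * shape[2]), shape))
  # outer ellipsoid, slightly anisotropic; the shell intensity is modulated
  # azimuthally so that single slices pin down in-plane rotation (a purely
  # rotationally symmetric shell would leave slice poses unidentifiable)
  r2 <- (U$x / 1.00)^2 + (U$y / 0.88)^2 + (U$z / 0.94)^2
  phi <- atan2(U$y, U$x)
  vox <- array(10, shape)                      # background
  shell <- r2 <= 1
  vox[shell] <- 120 + 26 * cos(phi[shell]) + 16 * sin(2 * phi[shell])
  vox[r2 <= 0.70] <- 60                        # interior
  lob1 <- ((U$x - 0.28) / 0.34)^2 + (U$y / 0.30)^2 + (U$z / 0.38)^2
  lob2 <- ((U$x + 0.28) / 0.34)^2 + (U$y / 0.30)^2 + (U$z / 0.38)^2
  vox[lob1 <= 1] <- 200                        # lobes
  vox[lob2 <= 1] <- 170
  core <- (U$x / 0.12)^2 + (U$y / 0.14)^2 + ((U$z - 0.1) / 0.12)^2
  vox[core <= 1] <- 235
  # smooth low-amplitude texture from a few random-phase cosines
  tex <- with_seed(seed, {
    t <- array(0, shape)
    for (q in 1:4) {
      f <- runif(3, 1.5, 4.5)
      ph <- runif(3, 0, 2 * pi)
      t <- t + cos(f[1] * pi * U$x + ph[1]) * cos(f[2] * pi * U$y + ph[2]) *
        cos(f[3] * pi * U$z + ph[3])
    }
    t
  })
  vox <- vox + 6 * tex * (r2 <= 1)
  vox <- pmin(pmax(vox, 0), 255)
  recon_volume(vox, spacing = spacing, weights = array(1, shape))
}

#' Two-half-space edge phantom
#'
#' A sharp planar edge between two constant intensities, used to probe
#' edge preservation of the steering kernel regression.
#'
#' @param shape integer(3) grid dimensions.
#' @param low,high the two intensities.
#' @param axis axis (1-3) normal to the edge plane.
#' @return A [recon_volume()].
#' @export
generate_edge_phantom <- function(shape, low = 50, high = 200, axis = 1) {
  shape <- as.integer(shape)
  vox <- array(low, shape)
  half <- seq_len(shape[axis]) > shape[axis] / 2
  idx <- slice.index(vox, axis)
  vox[half[idx]] <- high
  recon_volume(vox, spacing = 1, weights = array(1, shape))
}
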