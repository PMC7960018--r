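# Shared fixtures and independent brute-force oracles used across tests.

# a flat slice with given pixel matrix on a default axis-aligned world
make_slice <- function(pixels, spacing = 1, thickness = 1, ...) {
  svr_slice(as.matrix(pixels), spacing = spacing, thickness = thickness, ...)
}

# small noise-free, motion-free acquisition of the standard phantom
make_static_acquisition <- function(shape = c(32, 32, 32), removal = 0,
                                    noise = 0, seed = 5) {
  gt <- generate_phantom(shape, spacing = 1, seed = 7)
  cfg <- acquisition_config(motion_rotation_deg = 0, motion_translation_mm = 0,
                            noise_sigma = noise, bias_amplitude = 0,
                            scale_range = c(1, 1),
                            removal_proportion = removal, seed = seed)
  sim <- simulate_acquisition(gt, cfg)
  list(gt = gt, sim = sim, cfg = cfg)
}

# brute-force weighted least squares via the explicit pseudo-inverse
wls_oracle <- function(XF, w, y) {
  A <- matrix(0, ncol(XF), ncol(XF))
  b <- numeric(ncol(XF))
  for (r in seq_len(nrow(XF))) {         # explicit accumulation loops
    A <- A + w[r] * outer(XF[r, ], XF[r, ])
    b <- b + w[r] * XF[r, ] * y[r]
  }
  as.numeric(MASS::ginv(A) %*% b)
}

# independent scatter oracle: double loop over pixels and every voxel
scatter_oracle <- function(slice, t_global, t_local, dimv, world_r, spec) {
  sl <- correct_slice(slice)
  Tt <- t_global$matrix %*% t_local$matrix
  ax <- sl$world[1:3, 1:3]
  ax <- sweep(ax, 2, sqrt(colSums(ax^2)), "/")
  Sm <- Tt[1:3, 1:3] %*% ax
  accum <- array(0, dimv); wsum <- array(0, dimv)
  s <- spec$sigma; sup <- spec$support_radius
  for (i in seq_len(nrow(sl$pixels))) for (j in seq_len(ncol(sl$pixels))) {
    if (!sl$valid_mask[i, j]) next
    pw <- Tt %*% sl$world %*% c(i - 1, j - 1, 0, 1)    # pixel world pos
    for (q1 in seq_len(dimv[1])) for (q2 in seq_len(dimv[2]))
      for (q3 in seq_len(dimv[3])) {
        vw <- world_r %*% c(q1 - 1, q2 - 1, q3 - 1, 1) # voxel world pos
        d <- as.numeric(t(Sm) %*% (vw[1:3] - pw[1:3]))
        if (any(abs(d) > sup * s)) next
        wgt <- exp(-d[1]^2 / (2 * s[1]^2) - d[2]^2 / (2 * s[2]^2) -
                     d[3]^2 / (2 * s[3]^2))
        accum[q1, q2, q3] <- accum[q1, q2, q3] + wgt * sl$pixels[i, j]
        wsum[q1, q2, q3] <- wsum[q1, q2, q3] + wgt
      }
  }
  list(accum = accum, wsum = wsum)
}

# nearest-known-neighbor fill (baseline for hole filling)
nn_fill <- function(voxels, known) {
  d <- dim(voxels)
  kn <- which(known > 0, arr.ind = TRUE)
  out <- voxels
  for (lin in which(known == 0)) {
    at <- arrayInd(lin, d)
    d2 <- (kn[, 1] - at[1])^2 + (kn[, 2] - at[2])^2 + (kn[, 3] - at[3])^2
    out[lin] <- voxels[kn[which.min(d2), , drop = FALSE]]
  }
  out
}
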