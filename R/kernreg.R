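#' Steering kernel regression configuration
#'
#' Tunable parameters of the adaptive volume update.  Defaults follow the
#' reference protocol: classical window `k_c = 5` with bandwidth `h_c = 2`,
#' steering window `k_s = 7` with bandwidth `h_s = 0.5`, covariance analysis
#' window `w = 3`, regularization `lambda = 2`, structure sensitivity
#' `alpha = 0.4`, and 3 steering refits.  Windows are odd voxel counts;
#' bandwidths and offsets are in voxel units of the isotropic grid.
#'
#' @param k_c,k_s classical/steering kernel window sizes (odd, >= 3).
#' @param h_c,h_s classical/steering bandwidths (> 0).
#' @param w covariance analysis window (odd, >= 3).
#' @param alpha structure sensitivity in [0, 0.5].
#' @param lam regularization added to the covariance eigenvalues (> 0).
#' @param order Taylor order of the local fit (2).
#' @param iterations number of steering refits.
#' @return A list of class `kr_config`.
#' @export
kr_config <- function(k_c = 5, h_c = 2.0, k_s = 7, h_s = 0.5, w = 3,
                      alpha = 0.4, lam = 2.0, order = 2, iterations = 3) {
  stopifnot(k_c %% 2 == 1, k_c >= 3, k_s %% 2 == 1, k_s >= 3,
            w %% 2 == 1, w >= 3, h_c > 0, h_s > 0,
            alpha >= 0, alpha <= 0.5, lam > 0, iterations >= 1)
  structure(list(k_c = k_c, h_c = h_c, k_s = k_s, h_s = h_s, w = w,
                 alpha = alpha, lam = lam, order = order,
                 iterations = iterations),
            class = "kr_config")
}

#' Half-vectorization of a symmetric 3x3 matrix
#'
#' Stacks the upper-triangular entries row-wise:
#' `vech([[a,b,c],[b,d,e],[c,e,f]]) = c(a, b, c, d, e, f)`.
#'
#' @param S symmetric 3x3 matrix (tolerance 1e-9).
#' @return Numeric vector of length 6.
#' @export
vech <- function(S) {
  stopifnot(is.matrix(S), all(dim(S) == c(3, 3)))
  if (max(abs(S - t(S))) > 1e-9) stop("vech requires a symmetric matrix")
  c(S[1, 1], S[1, 2], S[1, 3], S[2, 2], S[2, 3], S[3, 3])
}

# inverse of vech: rebuild the symmetric matrix
vech_inverse <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3, byrow = TRUE)
}

# order-2 design row for an offset d (voxel units)
design_row <- function(d) {
  c(1, d, vech(tcrossprod(d)))
}

#' Weighted local polynomial solve
#'
#' Solves the weighted least-squares system `B = argmin ||Y - XF B||^2_W`
#' via a QR factorization of the weighted design (no explicit inverse).
#' Ill-conditioned systems (condition number above 1e10) fall back to the
#' order-0 weighted mean with zero gradient.
#'
#' @param XF `L x 10` design matrix (rows `[1, d, vech(d d^T)]`).
#' @param w `L` non-negative kernel weights with positive sum.
#' @param y `L` known values.
#' @return A list: `beta` (length 10; entry 1 is the voxel estimate, entries
#'   2-4 the gradient), `order` (2, or 0 after fallback).
#' @export
solve_local <- function(XF, w, y) {
  stopifnot(nrow(XF) == length(w), length(w) == length(y), sum(w) > 0)
  if (nrow(XF) >= 10) {
    sw <- sqrt(w)
    Xw <- XF * sw
    d <- svd(Xw, nu = 0, nv = 0)$d
    if (d[1] > 0 && d[1] / max(d[length(d)], .Machine$double.xmin) <= 1e10) {
      qrx <- qr(Xw)
      beta <- unname(qr.coef(qrx, y * sw))
      if (all(is.finite(beta))) return(list(beta = beta, order = 2L))
    }
  }
  beta <- c(sum(w * y) / sum(w), rep(0, 9))
  list(beta = beta, order = 0L)
}

#' Classical kernel regression at one voxel
#'
#' Order-2 local polynomial fit of the known voxels in a `k_c^3` window
#' around the query, weighted by the isotropic Gaussian kernel
#' `exp(-|d|^2 / (2 h_c^2))`.  Used for the initial gradient field of the
#' steering iteration.
#'
#' @param values 3D array of voxel values.
#' @param known logical/numeric 3D array marking known voxels.
#' @param at integer voxel index (1-based, length 3).
#' @param k_c window size (odd).
#' @param h_c bandwidth (voxel units).
#' @return A list: `beta0` (value estimate), `beta1` (gradient), `L`
#'   (neighbors used), `order`.
#' @export
classical_kr <- function(values, known, at, k_c = 5, h_c = 2.0) {
  d <- dim(values)
  r <- k_c %/% 2
  lo <- pmax(at - r, 1); hi <- pmin(at + r, d)
  idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  keep <- known[idx] > 0
  idx <- idx[keep, , drop = FALSE]
  L <- nrow(idx)
  if (L == 0) return(list(beta0 = NA_real_, beta1 = rep(0, 3), L = 0L,
                          order = NA_integer_))
  offs <- sweep(idx, 2, at)
  wts <- exp(-rowSums(offs^2) / (2 * h_c^2))
  XF <- t(apply(offs, 1, design_row))
  if (L == 1) XF <- matrix(XF, nrow = 1)
  fit <- solve_local(XF, wts, values[idx])
  list(beta0 = fit$beta[1], beta1 = fit$beta[2:4], L = L, order = fit$order)
}

#' Naive gradient covariance over an analysis window
#'
#' Sum of gradient outer products over the `w^3` window centered at `at`
#' (clipped at the volume borders); symmetric positive semidefinite.
#'
#' @param grad list of 3D arrays `gx`, `gy`, `gz`.
#' @param at integer voxel index (1-based).
#' @param w window size (odd).
#' @return A list: `C` (3x3 matrix), `L` (number of samples).
#' @export
naive_covariance <- function(grad, at, w = 3) {
  d <- dim(grad$gx)
  r <- w %/% 2
  lo <- pmax(at - r, 1); hi <- pmin(at + r, d)
  idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  G <- cbind(grad$gx[idx], grad$gy[idx], grad$gz[idx])
  list(C = crossprod(G), L = nrow(idx))
}

#' Regularized steering covariance
#'
#' Eigendecomposes the naive covariance `C = U diag(s) U'` and rebuilds it
#' with elongations `a_k = (s_k + lam) / prod_{j != k} (s_j + lam)^{1/2}`
#' and footprint scale `gamma = (prod_k (s_k + lam)^{1/2} / L)^alpha`, i.e.
#' `C_i = gamma * U diag(a) U'`.  The result is symmetric positive definite,
#' isotropic in flat regions and scale-insensitive at `alpha = 0`.
#'
#' @param C_naive symmetric PSD 3x3 matrix.
#' @param alpha structure sensitivity in [0, 0.5].
#' @param lam regularization (> 0 unless `C_naive` is nonsingular).
#' @param L number of gradient samples in the analysis window.
#' @return Symmetric positive definite 3x3 matrix.
#' @export
regularize_covariance <- function(C_naive, alpha, lam, L) {
  if (lam <= 0 && abs(det(C_naive)) < 1e-12)
    stop("lam must be > 0 when the naive covariance is singular")
  eg <- eigen((C_naive + t(C_naive)) / 2, symmetric = TRUE)
  s <- pmax(eg$values, 0) + lam
  a <- c(s[1] / sqrt(s[2] * s[3]),
         s[2] / sqrt(s[1] * s[3]),
         s[3] / sqrt(s[1] * s[2]))
  gamma <- (sqrt(prod(s)) / max(L, 1))^alpha
  gamma * eg$vectors %*% diag(a) %*% t(eg$vectors)
}

#' Steering kernel weight
#'
#' `K_s(d) = sqrt(det C) / (2 pi h^2) * exp(-d' C d / (2 h^2))` for the
#' offset `d = Xi - X` in voxel units.  The printed normalizer is kept
#' verbatim; any global kernel scale cancels in the weighted least squares.
#'
#' @param Xi,X voxel coordinates (length 3).
#' @param C_i symmetric positive definite 3x3 steering covariance.
#' @param h_s steering bandwidth.
#' @return The kernel weight.
#' @export
steering_weight <- function(Xi, X, C_i, h_s) {
  ev <- eigen((C_i + t(C_i)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("steering covariance must be positive definite")
  d <- as.numeric(Xi - X)
  sqrt(det(C_i)) / (2 * pi * h_s^2) *
    exp(-as.numeric(t(d) %*% C_i %*% d) / (2 * h_s^2))
}

#' Iterative steering kernel regression volume update
#'
#' Runs the adaptive update on a gathered volume: an initial classical
#' kernel regression provides value and gradient fields; each of
#' `cfg$iterations` refits re-estimates per-voxel gradient covariances from
#' the current gradients, regularizes them, and re-estimates every voxel
#' (known voxels from known neighbors; unknown voxels filled) by steering-
#' weighted order-2 local regression.
#'
#' @param volume a gathered [recon_volume()]; voxels with zero accumulated
#'   weight are treated as unknown.
#' @param cfg a [kr_config()].
#' @return The volume with updated voxels, plus attributes `n_unfilled`
#'   (voxels left unknown) and `ops` (neighbor visits per steering sweep).
#' @export
steering_update_volume <- function(volume, cfg = kr_config()) {
  known <- known_mask(volume)
  Y <- volume$voxels
  init <- cpp_classical_kr_field(Y, known, cfg$k_c, cfg$h_c)
  est <- init$beta0
  gx <- init$gx; gy <- init$gy; gz <- init$gz
  # the covariance analysis acts on dimensionless gradients (intensities
  # normalized to unit dynamic range) so that lambda and alpha are
  # scale-free; the fitted values stay in native units
  rng <- diff(range(Y[known > 0]))
  gscale <- if (rng > 0) 1 / rng else 1
  ops <- numeric(0)
  n_unfilled <- init$n_empty
  for (it in seq_len(cfg$iterations)) {
    cv <- cpp_covariance_field(gx * gscale, gy * gscale, gz * gscale, cfg$w)
    rg <- cpp_regularize_field(cv$cxx, cv$cxy, cv$cxz, cv$cyy, cv$cyz,
                               cv$czz, cv$L, cfg$alpha, cfg$lam)
    sw <- cpp_steering_field(Y, known, est, rg$cxx, rg$cxy, rg$cxz,
                             rg$cyy, rg$cyz, rg$czz, cfg$k_s, cfg$h_s)
    est <- sw$beta0
    gx <- sw$gx; gy <- sw$gy; gz <- sw$gz
    ops <- c(ops, sw$ops)
    n_unfilled <- sw$n_unfilled
  }
  volume$voxels <- est
  attr(volume, "n_unfilled") <- n_unfilled
  attr(volume, "ops") <- ops
  volume
}

#' Robust residual-based combined volume update
#'
#' Scatters the slice residuals `e*` back into the volume with weights
#' `PSF x p_slice x p_pixel`, normalizes by the plain accumulated PSF
#' weights, and adds the correction to the current voxels.  Pixels with low
#' inlier posterior therefore contribute proportionally smaller corrections;
#' excluded slices contribute nothing.
#'
#' @param volume current [recon_volume()] (voxel values, not raw sums).
#' @param slices observed [svr_slice()]s.
#' @param t_globals,t_locals parallel lists of [rigid_transform()]s.
#' @param residuals list of residual matrices from [simulate_slices()].
#' @param posteriors list of per-pixel inlier posterior matrices.
#' @param slice_probs numeric vector of slice probabilities.
#' @param include logical inclusion flags per slice.
#' @param spec a [psf_spec()].
#' @return The volume with corrected voxels.
#' @export
combined_update <- function(volume, slices, t_globals, t_locals, residuals,
                            posteriors, slice_probs, include, spec) {
  keep <- which(include)
  if (length(keep) == 0) return(volume)
  acc <- recon_volume(array(0, dim(volume$voxels)), volume$spacing,
                      volume$world)
  vals <- list(); pws <- list(); sls <- list(); tg <- list(); tl <- list()
  for (ii in seq_along(keep)) {
    s <- keep[ii]
    r <- residuals[[s]]
    pw <- posteriors[[s]] * slice_probs[s]
    bad <- !is.finite(r) | !is.finite(pw)
    r[bad] <- 0; pw[bad] <- 0
    sl <- slices[[s]]
    sl$valid_mask <- sl$valid_mask & !bad
    sls[[ii]] <- sl; vals[[ii]] <- r; pws[[ii]] <- pw
    tg[[ii]] <- t_globals[[s]]; tl[[ii]] <- t_locals[[s]]
  }
  num <- scatter_slices(sls, tg, tl, acc, spec, pixel_weights = pws,
                        values = vals)
  den <- scatter_slices(sls, tg, tl,
                        recon_volume(array(0, dim(volume$voxels)),
                                     volume$spacing, volume$world),
                        spec, values = vals)
  corr <- array(0, dim(volume$voxels))
  pos <- den$weights > 0
  corr[pos] <- num$voxels[pos] / den$weights[pos]
  volume$voxels <- volume$voxels + corr
  volume
}
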