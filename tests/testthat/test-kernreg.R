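test_that("vech follows the row-wise upper-triangular ordering", {
  S <- matrix(c(1, 2, 3, 2, 4, 5, 3, 5, 6), 3, 3)
  expect_identical(vech(S), c(1, 2, 3, 4, 5, 6))
  expect_identical(vech(diag(3)), c(1, 0, 0, 1, 0, 1))
  # rebuild from the half-vectorization reproduces the matrix
  expect_identical(sparsesvr:::vech_inverse(vech(S)), S)
  A <- S; A[1, 2] <- 99
  expect_error(vech(A), "symmetric")
})

test_that("classical kernel regression is exact on constants and planes", {
  d <- c(7, 7, 7)
  known <- array(1, d)
  # constant field
  cst <- array(5.5, d)
  fit <- classical_kr(cst, known, c(4, 4, 4))
  expect_equal(fit$beta0, 5.5, tolerance = 1e-9)
  expect_equal(fit$beta1, rep(0, 3), tolerance = 1e-9)
  # linear ramp 2x + 3y - z (offsets in voxel units)
  idx <- as.matrix(expand.grid(1:7, 1:7, 1:7))
  lin <- array(2 * idx[, 1] + 3 * idx[, 2] - idx[, 3], d)
  fit2 <- classical_kr(lin, known, c(4, 4, 4))
  expect_equal(fit2$beta1, c(2, 3, -1), tolerance = 1e-9)
  expect_equal(fit2$beta0, as.numeric(2 * 4 + 3 * 4 - 4), tolerance = 1e-9)
})

test_that("classical regression matches a brute-force WLS oracle", {
  skip_if_not_installed("MASS")
  set.seed(77)
  for (trial in 1:20) {
    vals <- array(runif(125, 0, 100), c(5, 5, 5))
    known <- array(runif(125) > 0.3, c(5, 5, 5)) * 1
    at <- c(3, 3, 3)
    fit <- classical_kr(vals, known, at, k_c = 5, h_c = 2)
    idx <- as.matrix(expand.grid(1:5, 1:5, 1:5))
    idx <- idx[known[idx] > 0, , drop = FALSE]
    if (nrow(idx) < 10) next
    offs <- sweep(idx, 2, at)
    w <- exp(-rowSums(offs^2) / (2 * 4))
    XF <- t(apply(offs, 1, function(o) c(1, o, o[1]^2, o[1] * o[2],
                                         o[1] * o[3], o[2]^2, o[2] * o[3],
                                         o[3]^2)))
    beta <- wls_oracle(XF, w, vals[idx])
    expect_equal(fit$beta0, beta[1], tolerance = 1e-8)
    expect_equal(fit$beta1, beta[2:4], tolerance = 1e-8)
  }
})

test_that("the classical field kernel agrees with per-voxel calls", {
  set.seed(5)
  vals <- array(runif(6^3, 0, 10), c(6, 6, 6))
  known <- array(runif(6^3) > 0.4, c(6, 6, 6)) * 1
  fld <- sparsesvr:::cpp_classical_kr_field(vals, known, 5L, 2)
  for (at in list(c(2, 3, 4), c(1, 1, 1), c(6, 5, 2))) {
    fit <- classical_kr(vals, known, at, k_c = 5, h_c = 2)
    if (is.na(fit$beta0)) next
    expect_equal(fld$beta0[at[1], at[2], at[3]], fit$beta0, tolerance = 1e-9)
    expect_equal(c(fld$gx[at[1], at[2], at[3]], fld$gy[at[1], at[2], at[3]],
                   fld$gz[at[1], at[2], at[3]]), fit$beta1, tolerance = 1e-9)
  }
})

test_that("naive covariance equals the loop-built outer-product sum", {
  # flat region: zero matrix
  z <- list(gx = array(0, c(5, 5, 5)), gy = array(0, c(5, 5, 5)),
            gz = array(0, c(5, 5, 5)))
  expect_equal(naive_covariance(z, c(3, 3, 3), 3)$C, matrix(0, 3, 3),
               ignore_attr = TRUE)
  # pure x-ramp: diag(L, 0, 0)
  rx <- list(gx = array(1, c(5, 5, 5)), gy = array(0, c(5, 5, 5)),
             gz = array(0, c(5, 5, 5)))
  cv <- naive_covariance(rx, c(3, 3, 3), 3)
  expect_equal(cv$C, diag(c(27, 0, 0)), ignore_attr = TRUE)
  expect_identical(cv$L, 27L)
  # random gradients: brute-force sum
  set.seed(12)
  g <- list(gx = array(rnorm(125), c(5, 5, 5)),
            gy = array(rnorm(125), c(5, 5, 5)),
            gz = array(rnorm(125), c(5, 5, 5)))
  got <- naive_covariance(g, c(2, 4, 3), 3)$C
  ora <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 3:5) for (k in 2:4) {
    v <- c(g$gx[i, j, k], g$gy[i, j, k], g$gz[i, j, k])
    ora <- ora + outer(v, v)
  }
  expect_equal(got, ora, tolerance = 1e-12, ignore_attr = TRUE)
  # field version agrees
  cf <- sparsesvr:::cpp_covariance_field(g$gx, g$gy, g$gz, 3L)
  expect_equal(cf$cxx[2, 4, 3], ora[1, 1], tolerance = 1e-12)
  expect_equal(cf$cyz[2, 4, 3], ora[2, 3], tolerance = 1e-12)
})

test_that("covariance regularization is SPD with the stated limits", {
  lam <- 2; L <- 27
  # flat region: isotropic kernel with the closed-form scale
  C0 <- regularize_covariance(matrix(0, 3, 3), alpha = 0.4, lam = lam, L = L)
  expect_equal(C0, (lam^3)^(0.4 / 2) / L^0.4 * diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # isotropy is preserved: C = s I stays proportional to I
  Cs <- regularize_covariance(5 * diag(3), alpha = 0.3, lam = lam, L = L)
  expect_equal(Cs[1, 1], Cs[2, 2], tolerance = 1e-12)
  expect_lt(max(abs(Cs - Cs[1, 1] * diag(3))), 1e-12)
  # alpha = 0 removes the scale factor: det == prod(a_k) == 1
  set.seed(3)
  G <- matrix(rnorm(30), 10, 3)
  Ca <- regularize_covariance(crossprod(G), alpha = 0, lam = lam, L = L)
  expect_equal(det(Ca), 1, tolerance = 1e-9)
  # SPD for random PSD inputs
  for (i in 1:10) {
    G <- matrix(rnorm(30), 10, 3)
    Cr <- regularize_covariance(crossprod(G), alpha = 0.4, lam = lam, L = L)
    ev <- eigen(Cr, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_lt(max(abs(Cr - t(Cr))), 1e-12)
  }
  expect_error(regularize_covariance(matrix(0, 3, 3), 0.4, 0, 27), "lam")
})

test_that("steering weights follow the stated closed form", {
  expect_equal(steering_weight(c(0, 0, 0), c(0, 0, 0), diag(3), 1),
               1 / (2 * pi), tolerance = 1e-12)
  expect_equal(steering_weight(c(1, 1, 0), c(0, 0, 0), diag(3), 1),
               exp(-1) / (2 * pi), tolerance = 1e-9)
  # elongated covariance decays faster along its large axis
  C <- diag(c(4, 0.25, 1))
  wx <- steering_weight(c(1, 0, 0), c(0, 0, 0), C, 0.5)
  wy <- steering_weight(c(0, 1, 0), c(0, 0, 0), C, 0.5)
  expect_lt(wx, wy)
  expect_error(steering_weight(c(1, 0, 0), c(0, 0, 0), diag(c(1, 1, -1)), 1),
               "positive definite")
})

test_that("solve_local is exact on quadratics and weight-scale invariant", {
  skip_if_not_installed("MASS")
  set.seed(21)
  offs <- as.matrix(expand.grid(-2:2, -2:2, -1:1))
  XF <- t(apply(offs, 1, function(o) c(1, o, o[1]^2, o[1] * o[2],
                                       o[1] * o[3], o[2]^2, o[2] * o[3],
                                       o[3]^2)))
  bq <- c(2, 1, -1, 0.5, 0.2, -0.3, 0.1, 0.4, -0.2, 0.15)
  y <- as.numeric(XF %*% bq)
  w <- runif(nrow(XF), 0.5, 2)
  fit <- solve_local(XF, w, y)
  expect_identical(fit$order, 2L)
  expect_lt(sqrt(sum((y - XF %*% fit$beta)^2)), 1e-8)
  fit7 <- solve_local(XF, 7 * w, y)
  expect_equal(fit$beta, fit7$beta, tolerance = 1e-10)
  # random L = 25 systems match the explicit pseudo-inverse oracle
  for (i in 1:10) {
    sel <- sample(nrow(XF), 25)
    yr <- rnorm(25); wr <- runif(25, 0.1, 1)
    got <- solve_local(XF[sel, ], wr, yr)
    expect_equal(got$beta, wls_oracle(XF[sel, ], wr, yr), tolerance = 1e-8)
  }
  # degenerate neighborhoods fall back to the weighted mean
  small <- solve_local(XF[1:3, ], c(1, 2, 1), c(5, 6, 7))
  expect_identical(small$order, 0L)
  expect_equal(small$beta[1], (5 + 12 + 7) / 4)
})

test_that("kernel-scale invariance: global weight scaling leaves fits alone", {
  set.seed(31)
  vals <- array(runif(7^3, 0, 50), c(7, 7, 7))
  vol <- recon_volume(vals, 1, weights = array(rbinom(7^3, 1, 0.6), c(7, 7, 7)))
  # h_s enters only through the weights; scaling all steering weights by any
  # constant must not change the estimates.  Compare a direct local solve
  # with scaled weights at several voxels.
  cl <- sparsesvr:::cpp_classical_kr_field(vals, sparsesvr:::known_mask(vol),
                                           5L, 2)
  cov <- sparsesvr:::cpp_covariance_field(cl$gx, cl$gy, cl$gz, 3L)
  rg <- sparsesvr:::cpp_regularize_field(cov$cxx, cov$cxy, cov$cxz, cov$cyy,
                                         cov$cyz, cov$czz, cov$L, 0.4, 2)
  at <- c(4, 4, 4)
  idx <- as.matrix(expand.grid(1:7, 1:7, 1:7))
  idx <- idx[vol$weights[idx] > 0, , drop = FALSE]
  offs <- sweep(idx, 2, at)
  w <- vapply(seq_len(nrow(idx)), function(r) {
    q <- idx[r, ]
    C <- sparsesvr:::vech_inverse(c(rg$cxx[q[1], q[2], q[3]],
                                    rg$cxy[q[1], q[2], q[3]],
                                    rg$cxz[q[1], q[2], q[3]],
                                    rg$cyy[q[1], q[2], q[3]],
                                    rg$cyz[q[1], q[2], q[3]],
                                    rg$czz[q[1], q[2], q[3]]))
    steering_weight(idx[r, ], at, C, 0.5)
  }, numeric(1))
  XF <- t(apply(offs, 1, function(o) c(1, o, o[1]^2, o[1] * o[2],
                                       o[1] * o[3], o[2]^2, o[2] * o[3],
                                       o[3]^2)))
  b1 <- solve_local(XF, w, vals[idx])$beta
  b2 <- solve_local(XF, 1e3 * w, vals[idx])$beta
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("steering update leaves a smooth fully-known field nearly fixed", {
  d <- c(20, 20, 20)
  idx <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  v <- array(100 * exp(-rowSums(sweep(idx, 2, c(10.5, 10.5, 10.5))^2) /
                         (2 * 5^2)), d)
  vol <- recon_volume(v, 1, weights = array(1, d))
  up <- steering_update_volume(vol, kr_config())
  expect_lte(max(abs(up$voxels - v)), 0.01 * diff(range(v)))
})

test_that("steering fill beats nearest-neighbor on a sparse smooth phantom", {
  set.seed(9)
  d <- c(16, 16, 16)
  idx <- as.matrix(expand.grid(1:16, 1:16, 1:16))
  v <- array(100 * exp(-rowSums(sweep(idx, 2, c(8.5, 8.5, 8.5))^2) /
                         (2 * 4^2)), d)
  known <- array(rbinom(prod(d), 1, 0.2), d)   # 80% unknown
  vol <- recon_volume(v * known, 1, weights = known)
  up <- steering_update_volume(vol, kr_config())
  base <- nn_fill(v * known, known)
  expect_lt(rmse(up$voxels, v), rmse(base, v))
})

test_that("steering preserves the edge better than isotropic classical fill", {
  set.seed(3)
  ep <- generate_edge_phantom(c(20, 20, 20))
  noisy <- ep
  noisy$voxels <- noisy$voxels + array(rnorm(20^3, 0, 4), dim(ep$voxels))
  noisy$weights <- array(rbinom(20^3, 1, 0.3), dim(ep$voxels))
  noisy$voxels[noisy$weights == 0] <- 0
  blur_width <- function(vox) {
    prof <- apply(vox, 1, mean)
    lo <- min(prof) + 0.25 * diff(range(prof))
    hi <- min(prof) + 0.75 * diff(range(prof))
    xc <- function(level) {
      i <- min(which(prof >= level))
      (i - 1) + (level - prof[i - 1]) / (prof[i] - prof[i - 1])
    }
    xc(hi) - xc(lo)
  }
  st <- steering_update_volume(noisy, kr_config())
  cl <- sparsesvr:::cpp_classical_kr_field(noisy$voxels,
                                           sparsesvr:::known_mask(noisy),
                                           5L, 2.0)
  expect_lte(blur_width(st$voxels), blur_width(cl$beta0))
})

test_that("the combined robust update obeys its degenerate limits", {
  acq <- make_static_acquisition(c(16, 16, 16))
  st <- acq$sim$stacks[[1]]
  spec <- psf_spec(1, 3)
  id <- rigid_identity()
  n <- length(st$slices)
  ids <- replicate(n, id, simplify = FALSE)
  vol <- gather_volume(scatter_slices(st$slices, ids, ids,
                                      recon_volume(array(0, c(16, 16, 16)), 1),
                                      spec))
  sims <- simulate_slices(vol, st$slices, ids, ids, spec)
  ones <- lapply(sims$residuals, function(r) { r[] <- 1; r })
  zeros <- lapply(sims$residuals, function(r) { r[] <- 0; r })
  # all-zero posteriors: no change
  v1 <- combined_update(vol, st$slices, ids, ids, sims$residuals, zeros,
                        rep(1, n), rep(TRUE, n), spec)
  expect_equal(v1$voxels, vol$voxels, tolerance = 1e-12)
  # zero residuals: no change
  v2 <- combined_update(vol, st$slices, ids, ids, zeros, ones,
                        rep(1, n), rep(TRUE, n), spec)
  expect_equal(v2$voxels, vol$voxels, tolerance = 1e-12)
  # single-pixel residual, full probabilities, near-delta PSF:
  # the nearest voxel moves by exactly that residual
  specd <- structure(list(sigma = rep(0.05, 3), support_radius = 12),
                     class = "psf_spec")
  sl <- make_slice(matrix(0, 5, 5))
  msk <- matrix(FALSE, 5, 5); msk[3, 3] <- TRUE
  sl$valid_mask <- msk
  res <- matrix(0, 5, 5); res[3, 3] <- 2.5
  vold <- recon_volume(array(1, c(5, 5, 5)), 1,
                       weights = array(1, c(5, 5, 5)))
  v3 <- combined_update(vold, list(sl), list(id), list(id), list(res),
                        list(matrix(1, 5, 5)), 1, TRUE, specd)
  expect_equal(v3$voxels[3, 3, 1], 1 + 2.5, tolerance = 1e-6)
  off <- v3$voxels; off[3, 3, 1] <- 1
  expect_equal(off, array(1, c(5, 5, 5)), tolerance = 1e-9,
               ignore_attr = TRUE)
})
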