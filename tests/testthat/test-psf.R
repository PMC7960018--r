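test_that("psf_weight matches the closed-form Gaussian values", {
  spec <- psf_spec(1, 3)
  s <- spec$sigma
  expect_equal(psf_weight(0, 0, 0, spec), 1.0)
  expect_equal(psf_weight(s[1], 0, 0, spec), exp(-1 / 2))
  expect_equal(psf_weight(s[1], s[2], s[3], spec), exp(-3 / 2))
  # symmetry and monotonicity per axis
  expect_equal(psf_weight(0.7, 0, 0, spec), psf_weight(-0.7, 0, 0, spec))
  offs <- seq(0, 3, by = 0.25)
  expect_true(all(diff(psf_weight(offs, 0, 0, spec)) < 0))
  expect_true(all(diff(psf_weight(0, 0, offs, spec)) < 0))
})

test_that("sigma_from_fwhm inverts the half-maximum condition", {
  expect_equal(sigma_from_fwhm(2.3548), 1.0, tolerance = 1e-4)
  expect_equal(sigma_from_fwhm(1), 0.42466, tolerance = 1e-4)
  fwhm <- 3
  spec <- psf_spec(1, fwhm)
  expect_equal(psf_weight(0, 0, fwhm / 2, spec), 0.5, tolerance = 1e-6)
  expect_error(sigma_from_fwhm(0), "fwhm")
})

test_that("near-delta PSF scatters a single pixel to its nearest voxel", {
  vol <- recon_volume(array(0, c(4, 4, 4)), 1)
  # sigma -> 0 limit; support wide enough (0.6 voxel) to reach the nearest
  # center only
  spec <- structure(list(sigma = rep(0.05, 3), support_radius = 12),
                    class = "psf_spec")
  px <- matrix(0, 3, 3); px[2, 2] <- 7
  msk <- matrix(FALSE, 3, 3); msk[2, 2] <- TRUE
  sl <- make_slice(px, valid_mask = msk)
  sl$world[1:3, 4] <- c(0.2, -0.3, 1.1)     # off-grid pose
  out <- gather_volume(scatter_slice_to_volume(sl, rigid_identity(),
                                               rigid_identity(), vol, spec))
  expect_equal(out$voxels[1 + 1, 1 + 1, 1 + 1], 7, tolerance = 1e-6)
  expect_equal(sum(out$weights > 0), 1L, ignore_attr = TRUE)
})

test_that("gathering a uniform slice reproduces the constant exactly", {
  vol <- recon_volume(array(0, c(6, 6, 4)), 1)
  spec <- psf_spec(1, 2)
  sl <- make_slice(matrix(3.25, 6, 6), thickness = 2)
  sl$world[3, 4] <- 1.5
  out <- gather_volume(scatter_slice_to_volume(sl, rigid_identity(),
                                               rigid_identity(), vol, spec))
  covered <- out$weights > 0
  expect_true(any(covered))
  expect_equal(out$voxels[covered], rep(3.25, sum(covered)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scatter matches the dense double-loop oracle at a skew pose", {
  spec <- psf_spec(1.2, 2.5)
  px <- matrix(seq(10, 90, length.out = 9), 3, 3)
  sl <- svr_slice(px, spacing = 1.2, thickness = 2.5)
  sl$valid_mask[3, 1] <- FALSE
  tg <- rigid_transform(c(0.2, -0.1, 0.15), c(0.5, 0.3, 1.0))
  tl <- rigid_transform(c(-0.05, 0.1, 0.0), c(0.2, -0.4, 0.1))
  vol <- recon_volume(array(0, c(4, 4, 4)), 1)
  got <- scatter_slice_to_volume(sl, tg, tl, vol, spec)
  ora <- scatter_oracle(sl, tg, tl, c(4, 4, 4), vol$world, spec)
  expect_equal(got$voxels, ora$accum, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(got$weights, ora$wsum, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("scatter is linear in the slice intensities", {
  spec <- psf_spec(1, 2)
  base <- recon_volume(array(0, c(5, 5, 5)), 1)
  mk <- function(px) {
    sl <- make_slice(px, thickness = 2)
    sl$world[3, 4] <- 2
    gathered <- scatter_slice_to_volume(sl, rigid_identity(),
                                        rigid_identity(), base, spec)
    gathered$voxels
  }
  set.seed(8)
  p1 <- matrix(runif(25, 0, 10), 5, 5)
  p2 <- matrix(runif(25, 0, 10), 5, 5)
  expect_equal(mk(2 * p1 + 3 * p2), 2 * mk(p1) + 3 * mk(p2),
               tolerance = 1e-9)
})

test_that("simulation is the adjoint of scatter and exact on constants", {
  # constant volume -> every simulated pixel equals the constant
  volc <- recon_volume(array(4.5, c(8, 8, 8)), 1,
                       weights = array(1, c(8, 8, 8)))
  spec <- psf_spec(1, 2)
  sl <- make_slice(matrix(0, 8, 8), thickness = 2)
  sl$world[3, 4] <- 3.2
  id <- rigid_identity()
  sim <- simulate_slices(volc, list(sl), list(id), list(id), spec)
  expect_equal(sim$simulated[[1]], matrix(4.5, 8, 8), tolerance = 1e-12)
  # scatter with a near-delta PSF then simulate: residuals vanish
  specd <- structure(list(sigma = rep(0.05, 3), support_radius = 2),
                     class = "psf_spec")
  px <- matrix(seq(1, 64), 8, 8)
  slp <- make_slice(px)
  vol <- gather_volume(scatter_slice_to_volume(slp, id, id,
                                               recon_volume(array(0, c(8, 8, 8)), 1),
                                               specd))
  sim2 <- simulate_slices(vol, list(slp), list(id), list(id), specd)
  expect_lt(max(abs(sim2$residuals[[1]])), 1e-6 * diff(range(px)))
  # observed == simulated gives identically zero residuals
  slq <- slp; slq$pixels <- sim2$simulated[[1]]
  sim3 <- simulate_slices(vol, list(slq), list(id), list(id), specd)
  expect_equal(max(abs(sim3$residuals[[1]])), 0, tolerance = 1e-12)
})
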