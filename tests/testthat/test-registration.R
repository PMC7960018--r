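# moving volume = the same phantom posed differently in world space (its
# header affine composed with the inverse of `t_true`), so the registration
# must recover exactly `t_true` and the metric is interpolation-free at the
# solution
make_moved <- function(ph, rot = c(0, 0, 0), tra = c(0, 0, 0)) {
  d <- dim(ph$voxels)
  ctr <- as.numeric(ph$world %*% c((d - 1) / 2, 1))[1:3]
  t_true <- sparsesvr:::transform_about(rigid_transform(rot, tra), ctr)
  mov <- ph
  mov$world <- solve(t_true$matrix) %*% ph$world
  list(moving = mov, t_true = t_true)
}

test_that("self-registration stays at identity", {
  ph <- generate_phantom(c(24, 24, 24), seed = 2)
  rr <- register_volume_to_volume(ph, ph)
  expect_true(rr$converged)
  expect_lt(max(abs(rr$transform$rotation)), 1e-3)
  expect_lt(max(abs(rr$transform$translation)), 0.05)
  expect_lte(rr$final_metric, rr$initial_metric)
})

test_that("known translations and rotations are recovered", {
  ph <- generate_phantom(c(32, 32, 32), seed = 2)
  mv <- make_moved(ph, tra = c(2, 0, 0))
  rr <- register_volume_to_volume(mv$moving, ph)
  expect_equal(rr$transform$translation, mv$t_true$translation,
               tolerance = 0.1 / 2)
  expect_lt(max(abs(rr$transform$rotation - mv$t_true$rotation)),
            0.2 * pi / 180)
  mv2 <- make_moved(ph, rot = c(3 * pi / 180, 0, 0))
  rr2 <- register_volume_to_volume(mv2$moving, ph)
  expect_lt(max(abs(rr2$transform$rotation - mv2$t_true$rotation)),
            0.2 * pi / 180)
  expect_lt(max(abs(rr2$transform$translation - mv2$t_true$translation)), 0.1)
})

test_that("the optimizer never worsens the metric and is equivariant", {
  ph <- generate_phantom(c(24, 24, 24), seed = 4)
  mv <- make_moved(ph, rot = c(0, 0.02, 0), tra = c(1, -0.5, 0))
  rr <- register_volume_to_volume(mv$moving, ph)
  expect_lte(rr$final_metric, rr$initial_metric)
  # pre-compose the moving volume with rigid R, initialize at R^-1:
  # the composed solution matches the original one
  R <- sparsesvr:::transform_about(
    rigid_transform(c(0, 0, 0.05), c(1, 0, 0)),
    as.numeric(ph$world %*% c((dim(ph$voxels) - 1) / 2, 1))[1:3])
  mov2 <- mv$moving
  mov2$world <- solve(R$matrix) %*% mov2$world
  rr2 <- register_volume_to_volume(mov2, ph, init = R)
  expect_lt(max(abs(rr2$transform$matrix %*% solve(R$matrix) -
                      rr$transform$matrix)), 0.15)
})

test_that("slice-to-volume registration recovers simulated poses", {
  acq <- make_static_acquisition(c(32, 32, 32))
  st <- acq$sim$stacks[[1]]
  spec <- psf_spec(1, 3)
  id <- rigid_identity()
  n <- length(st$slices)
  ids <- replicate(n, id, simplify = FALSE)
  vol <- gather_volume(scatter_slices(st$slices, ids, ids,
                                      recon_volume(array(0, c(32, 32, 32)), 1),
                                      spec))
  # slice simulated from the volume at identity: near-identity recovery
  sl <- st$slices[[5]]
  sim <- simulate_slices(vol, list(sl), list(id), list(id), spec)
  sl$pixels <- sim$simulated[[1]]
  rr <- register_slice_to_volume(sl, vol, spec = spec)
  expect_true(rr$converged)
  expect_lt(max(abs(rr$transform$rotation)), 1e-2)
  expect_lt(max(abs(rr$transform$translation)), 0.1)
  # known 1.5 mm in-plane shift, simulated from the volume itself
  shift <- rigid_transform(translation = c(1.5, 0, 0))
  sim2 <- simulate_slices(vol, list(st$slices[[5]]), list(id), list(shift),
                          spec)
  sl2 <- st$slices[[5]]
  sl2$pixels <- sim2$simulated[[1]]
  rr2 <- register_slice_to_volume(sl2, vol, spec = spec)
  expect_equal(rr2$transform$translation[1], 1.5, tolerance = 0.2)
  expect_lt(max(abs(rr2$transform$translation[2:3])), 0.2)
  # same shift with 50% of pixels removed
  sl3 <- sparse_sample(sl2, 0.5, seed = 21)
  rr3 <- register_slice_to_volume(sl3, vol, spec = spec)
  expect_equal(rr3$transform$translation[1], 1.5, tolerance = 0.4)
  # too few valid pixels: skipped, not registered
  sl4 <- sl2
  sl4$valid_mask[] <- FALSE
  sl4$valid_mask[1:20] <- TRUE
  rr4 <- register_slice_to_volume(sl4, vol, spec = spec)
  expect_false(rr4$converged)
  expect_identical(rr4$n_evals, 0L)
})
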