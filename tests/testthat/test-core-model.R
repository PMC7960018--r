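test_that("rigid transforms are orthonormal, invertible and round-trip", {
  set.seed(1)
  for (i in 1:20) {
    ang <- runif(3, -pi / 2 + 0.05, pi / 2 - 0.05)
    tra <- runif(3, -10, 10)
    t1 <- rigid_transform(ang, tra)
    R <- t1$matrix[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_lt(max(abs(t1$matrix %*% rigid_invert(t1)$matrix - diag(4))), 1e-9)
    # matrix -> parameters recovers angles and translations
    t2 <- rigid_from_matrix(t1$matrix)
    expect_equal(t2$rotation, ang, tolerance = 1e-6)
    expect_equal(t2$translation, tra, tolerance = 1e-6)
  }
})

test_that("transform text serialization round-trips", {
  t1 <- rigid_transform(c(0.2, -0.1, 0.3), c(1.5, -2, 0.25))
  f <- tempfile(fileext = ".txt")
  write_transform(t1, f)
  t2 <- read_transform(f)
  expect_lt(max(abs(t1$matrix - t2$matrix)), 1e-12)
})

test_that("correct_slice applies scale * exp(-bias) and keeps the mask", {
  s0 <- make_slice(matrix(c(5, 7), 1), scale = 1, bias = 0)
  expect_identical(correct_slice(s0)$pixels, s0$pixels)   # identity case
  s1 <- make_slice(matrix(c(5, 7), 1), scale = 2, bias = log(2))
  expect_equal(correct_slice(s1)$pixels, matrix(c(5, 7), 1))  # 2*e^-ln2 = 1
  s2 <- make_slice(matrix(exp(1)), scale = 1, bias = 1)
  expect_equal(correct_slice(s2)$pixels, matrix(1))
  msk <- matrix(c(TRUE, FALSE), 1)
  s3 <- make_slice(matrix(c(5, 7), 1), valid_mask = msk, scale = 3, bias = 0.5)
  expect_identical(correct_slice(s3)$valid_mask, msk)
  expect_error(correct_slice(make_slice(matrix(1), scale = -1)), "scale")
  s4 <- make_slice(matrix(1)); s4$bias[1, 1] <- NaN
  expect_error(correct_slice(s4), "bias")
})

test_that("pixel-to-voxel mapping follows the affine chain", {
  vol <- recon_volume(array(0, c(8, 8, 8)), 1)
  sl <- make_slice(matrix(0, 8, 8))
  id <- rigid_identity()
  expect_equal(map_pixel_to_voxel(c(2, 3, 0, 1), sl, id, id, vol), c(2, 3, 0))
  tl <- rigid_transform(translation = c(1, 0, 0))
  expect_equal(map_pixel_to_voxel(c(2, 3, 0, 1), sl, id, tl, vol), c(3, 3, 0))
  # round trip through the inverse chain returns the original pixel index
  tg <- rigid_transform(c(0.3, 0.1, -0.2), c(2, -1, 0.5))
  tl <- rigid_transform(c(-0.1, 0.2, 0.05), c(0.3, 1, -2))
  p <- map_pixel_to_voxel(c(4, 5, 0, 1), sl, tg, tl, vol)
  chain <- solve(vol$world) %*% tg$matrix %*% tl$matrix %*% sl$world
  back <- solve(chain, c(p, 1))
  expect_equal(as.numeric(back), c(4, 5, 0, 1), tolerance = 1e-9)
  bad <- vol; bad$world[1, 1] <- 0; bad$world[1, 2] <- 0; bad$world[1, 3] <- 0
  bad$world[2, 1] <- 0; bad$world[3, 1] <- 0
  expect_error(map_pixel_to_voxel(c(0, 0, 0, 1), sl, id, id, bad), "singular")
})

test_that("composition of the transform chain is associative", {
  vol <- recon_volume(array(0, c(8, 8, 8)), 0.7)
  sl <- make_slice(matrix(0, 8, 8), spacing = 1.1, thickness = 2.3)
  tg <- rigid_transform(c(0.2, -0.15, 0.1), c(1, 2, -1))
  tl <- rigid_transform(c(0.05, 0.1, -0.3), c(-0.5, 0.25, 1.5))
  t_total <- rigid_compose(tg, tl)
  p1 <- map_pixel_to_voxel(c(3, 4, 0, 1), sl, tg, tl, vol)
  p2 <- map_pixel_to_voxel(c(3, 4, 0, 1), sl, t_total, rigid_identity(), vol)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("nearest_voxel rounds halves away from zero and flags bounds", {
  expect_identical(nearest_voxel(c(2.4, 3.6, 0.0)), c(2L, 4L, 0L))
  expect_identical(nearest_voxel(c(2.5, 3.5, 1.5)), c(3L, 4L, 2L))
  expect_identical(nearest_voxel(c(-0.2, 0.2, 0.0)), c(0L, 0L, 0L))
  inb <- nearest_voxel(c(2.4, 0, 0), dim = c(4L, 4L, 4L))
  expect_false(attr(inb, "out_of_field"))
  oob <- nearest_voxel(c(4.6, 0, 0), dim = c(4L, 4L, 4L))
  expect_true(attr(oob, "out_of_field"))
  expect_error(nearest_voxel(c(NA, 0, 0)))
})

test_that("container invariants are enforced", {
  expect_error(make_slice(matrix(c(1, Inf), 1)), "finite")
  expect_error(svr_slice(matrix(1), spacing = 0, thickness = 1))
  expect_error(svr_slice(matrix(1), spacing = 1, thickness = 1,
                         valid_mask = matrix(TRUE, 2, 2)), "shape")
  expect_error(svr_stack(list(make_slice(matrix(1), spacing = 1),
                              make_slice(matrix(1), spacing = 2))),
               "share")
  expect_error(recon_volume(array(0, c(2, 2, 2)), 1,
                            weights = array(-1, c(2, 2, 2))), "non-negative")
})

test_that("stacks and volumes survive a NIfTI round trip", {
  acq <- make_static_acquisition(c(16, 16, 16))
  st <- acq$sim$stacks[[1]]
  st$slices <- lapply(st$slices, function(s) {
    s$valid_mask[1:3, 1] <- FALSE; s
  })
  f <- tempfile(fileext = ".nii.gz"); fm <- tempfile(fileext = ".nii.gz")
  write_stack(st, f, fm)
  st2 <- read_stack(f, fm, orientation_tag = st$orientation_tag)
  expect_equal(length(st2$slices), length(st$slices))
  expect_equal(st2$slices[[1]]$pixels, st$slices[[1]]$pixels,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(st2$slices[[2]]$valid_mask, st$slices[[2]]$valid_mask)
  expect_equal(st2$slices[[3]]$world, st$slices[[3]]$world, tolerance = 1e-4)
  vol <- acq$gt
  fv <- tempfile(fileext = ".nii.gz")
  write_volume(vol, fv)
  vol2 <- read_volume(fv)
  expect_equal(vol2$voxels, vol$voxels, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(vol2$world, vol$world, tolerance = 1e-4)
})
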