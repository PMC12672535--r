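test_that("virtual slice extraction matches direct orthogonal indexing", {
  ph <- small_phantom()
  vol <- ph$volume
  d <- dim(vol$data)
  cz <- floor(d[1] / 2) + 1
  s0 <- extract_virtual_slice(vol, slice_pose())
  expect_equal(unclass(s0), vol$data[cz, , ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # out-of-plane translation
  s10 <- extract_virtual_slice(vol, slice_pose(tz = 10))
  expect_equal(unclass(s10), vol$data[cz + 10, , ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # rx = 90 degrees maps the central y-slice onto the slice plane with a
  # reversed z axis: row i samples z = cz + oc - i at y = cy
  s90 <- extract_virtual_slice(vol, slice_pose(rx = 90),
                               out_shape = c(d[1], d[3]))
  cy <- floor(d[2] / 2) + 1
  cz <- floor(d[1] / 2) + 1
  oc <- floor(d[1] / 2) + 1
  direct <- vol$data[, cy, ]
  rows <- 2:(d[1] - 1)
  expect_lt(max(abs(s90[rows, ] - direct[cz + oc - rows, ])), 1e-9)
})

test_that("fully external planes are flagged", {
  ph <- small_phantom()
  expect_warning(extract_virtual_slice(ph$volume, slice_pose(tz = 1000)),
                 "outside")
})

test_that("mutual information agrees with hand-computed joint histograms", {
  # 4x4 pair with a hand-countable 2x2 joint histogram:
  # joint counts: (a=0,b=0)=6, (0,1)=2, (1,0)=2, (1,1)=6
  a <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1), 4)
  b <- matrix(c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 1, 1, 1, 1, 1, 1), 4)
  p <- c(6, 2, 2, 6) / 16
  mi_hand <- sum(p * log2(p / c(0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5,
                                0.5 * 0.5)))
  expect_equal(mutual_information(a, b, bins = 2), mi_hand,
               tolerance = 1e-12)
  # MI(X, X) = H(X) for two equiprobable values
  x <- matrix(rep(c(0, 1), 8), 4)
  expect_equal(mutual_information(x, x, bins = 4), 1.0, tolerance = 1e-12)
  # independence from a constant image
  expect_equal(mutual_information(x, matrix(5, 4, 4), bins = 4), 0)
  # symmetry and non-negativity on random pairs
  set.seed(6)
  for (i in 1:5) {
    u <- matrix(runif(64), 8)
    v <- matrix(runif(64), 8)
    expect_equal(mutual_information(u, v, 8), mutual_information(v, u, 8),
                 tolerance = 1e-12)
    expect_gte(mutual_information(u, v, 8), 0)
  }
  expect_error(mutual_information(a, b, bins = 2,
                                  mask = matrix(FALSE, 4, 4)),
               "empty")
})

test_that("MI is invariant under intensity inversion (binning-exact bijection)", {
  ph <- small_phantom()
  cz <- floor(dim(ph$volume$data)[1] / 2) + 1
  sl <- ph$volume$data[cz, , ]
  set.seed(8)
  img <- sl + matrix(rnorm(length(sl), 0, 0.02), nrow(sl))
  expect_equal(mutual_information(sl, img, 64),
               mutual_information(sl, invert_contrast(img), 64),
               tolerance = 1e-9)
})

test_that("registering from the true pose is a fixed point", {
  ph <- registration_phantom()
  vol <- ph$volume
  truth <- slice_pose(rx = 3, tz = 5)
  img <- extract_virtual_slice(vol, truth, dim(vol$data)[2:3])
  attr(img, "mask") <- NULL
  res <- register_slice(vol, img,
                        init = list(pose = truth,
                                    affine = inplane_affine()),
                        sched = reg_schedule(pyramid_factors = c(2, 1),
                                             max_sweeps = 10L))
  expect_true(res$converged)
  expect_lt(abs(res$pose$rx - 3), 0.5)
  expect_lt(abs(res$pose$tz - 5), 0.5)
})

test_that("registration recovers pose and shear from a zero init", {
  ph <- registration_phantom()
  vol <- ph$volume
  set.seed(1)
  truth <- slice_pose(rx = 4, ry = -3, tx = 5, ty = -4, tz = 6)
  aff <- inplane_affine(k = 0.10)
  img <- lymphomorph:::sample_view(vol$data, truth, aff, c(128L, 128L))
  img <- img + matrix(rnorm(length(img), 0, 0.01), nrow(img))
  attr(img, "mask") <- NULL
  res <- register_slice(vol, img,
                        sched = reg_schedule(pyramid_factors = c(4, 2, 1)))
  expect_lt(abs(res$pose$rx - 4), 1)
  expect_lt(abs(res$pose$tz - 6), 2)
  expect_lt(abs(res$affine$k - 0.10), 0.02)
  # deterministic: same inputs, bit-identical result
  res2 <- register_slice(vol, img,
                         sched = reg_schedule(pyramid_factors = c(4, 2, 1)))
  expect_identical(res$trace, res2$trace)
  expect_identical(unclass(res$pose), unclass(res2$pose))
})

test_that("trace MI is non-decreasing within each pyramid level", {
  ph <- registration_phantom()
  vol <- ph$volume
  set.seed(22)
  img <- lymphomorph:::sample_view(vol$data, slice_pose(rx = 4, tz = 5),
                                   inplane_affine(), c(128L, 128L))
  img <- img + matrix(rnorm(length(img), 0, 0.01), nrow(img))
  attr(img, "mask") <- NULL
  res <- register_slice(vol, img,
                        sched = reg_schedule(pyramid_factors = c(4, 2, 1)))
  for (lev in unique(res$trace$level)) {
    mi <- res$trace$mi_bits[res$trace$level == lev]
    expect_true(all(diff(mi) >= -1e-12),
                label = paste("monotone trace at level", lev))
  }
})

test_that("full-resolution reapplication preserves scale-1 inputs and nodes", {
  ph <- small_phantom()
  vol <- ph$volume
  img <- extract_virtual_slice(vol, slice_pose())
  attr(img, "mask") <- NULL
  res <- register_slice(vol, img,
                        sched = reg_schedule(pyramid_factors = c(2, 1),
                                             max_sweeps = 4L))
  out <- reapply_full_res(res, img, vol)
  # identity affine at ratio 1: both outputs equal the inputs
  if (abs(res$affine$sx - 1) < 1e-9 && abs(res$affine$k) < 1e-9) {
    expect_equal(out$ct_slice_upscaled, unclass(img), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # node preservation on a checkerboard at 4x upscale
  chk <- outer(rep(c(0, 1), length.out = nrow(img)),
               rep(c(0, 1), length.out = ncol(img)),
               function(a, b) as.numeric(xor(a, b)))
  res$img_shape <- dim(chk)
  hi <- matrix(0, 4 * nrow(chk), 4 * ncol(chk))
  res2 <- res
  res2$img_shape <- dim(chk)
  up <- reapply_full_res(res2, hi, vol)$ct_slice_upscaled
  expect_error(reapply_full_res(res, matrix(0, nrow(chk) * 2 + 1,
                                            ncol(chk) * 2), vol),
               "integer")
})

test_that("upscaled slice conserves the mean and hits lattice nodes", {
  ph <- small_phantom()
  vol <- ph$volume
  img <- extract_virtual_slice(vol, slice_pose())
  attr(img, "mask") <- NULL
  res <- register_slice(vol, img,
                        sched = reg_schedule(pyramid_factors = c(2, 1),
                                             max_sweeps = 2L))
  hi <- matrix(0, 2 * nrow(img), 2 * ncol(img))
  up <- reapply_full_res(res, hi, vol)$ct_slice_upscaled
  # node-aligned upscale: hi pixel (2i-1, 2j-1) equals lo pixel (i, j)
  sl <- extract_virtual_slice(vol, res$pose, res$img_shape)
  expect_equal(up[seq(1, nrow(hi), 2), seq(1, ncol(hi), 2)],
               unclass(sl), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(abs(mean(up) - mean(sl)) / abs(mean(sl)), 1e-2)
})

test_that("region refinement recovers an in-plane crop offset", {
  ph <- registration_phantom()
  vol <- ph$volume
  base_pose <- slice_pose(rx = 3, tz = 4)
  full <- lymphomorph:::sample_view(vol$data, base_pose, inplane_affine(),
                                    c(128L, 128L))
  attr(full, "mask") <- NULL
  prior <- register_slice(vol, full,
                          init = list(pose = base_pose,
                                      affine = inplane_affine()),
                          sched = reg_schedule(pyramid_factors = c(2, 1),
                                               max_sweeps = 6L))
  # a crop of the overview: offset by (+8, +6) px from centre
  zoom <- full[33:96 + 8, 33:96 + 6]
  res <- refine_region(vol, zoom, prior,
                       sched = reg_schedule(pyramid_factors = c(2, 1)))
  # plane orientation frozen
  expect_equal(res$pose$rx, prior$pose$rx)
  expect_equal(res$pose$tz, prior$pose$tz)
  # recovered in-plane shift equals the crop offset within a pixel
  expect_lt(abs((res$pose$ty - prior$pose$ty) - 8), 1.1)
  expect_lt(abs((res$pose$tx - prior$pose$tx) - 6), 1.1)
})
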