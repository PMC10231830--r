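textured_phantom <- function(seed = 5, size = 96) {
  generate_phantom(phantom_config(size = c(size, size),
                                  n_elastic_fibers = 3,
                                  n_collagen_fibers = 4, n_nuclei = 8,
                                  seed = seed))$evg_rgb
}

rotation_about_center <- function(deg, ctr, scale = 1) {
  a <- deg * pi / 180
  r <- scale * matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  cbind(r, c(ctr, ctr) - r %*% c(ctr, ctr))
}

test_that("an image matched against itself yields zero-displacement matches", {
  img <- textured_phantom()
  m <- detect_and_match(img, img)
  expect_gte(length(m$scores), 3)
  expect_equal(m$fixed_points, m$moving_points)
  # uncorrelated noise images carry no stable matches
  set.seed(1)
  n1 <- rgb_image(array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3)))
  n2 <- rgb_image(array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3)))
  expect_error(detect_and_match(n1, n2), "match|keypoint")
})

test_that("matches across a 5-degree rotation reflect the true transform", {
  img <- textured_phantom()
  A <- rotation_about_center(5, 47.5)
  rot <- warp_affine(img, affine_transform(A), c(96, 96))
  m <- detect_and_match(img, rot)
  expect_gte(length(m$scores), 3)
  # displacement of matched moving points under the inverse rotation should
  # land on the fixed points
  inv <- cbind(solve(A[, 1:2]), -solve(A[, 1:2]) %*% A[, 3])
  mapped <- cbind(inv[1, 1] * m$moving_points[, 1] +
                    inv[1, 2] * m$moving_points[, 2] + inv[1, 3],
                  inv[2, 1] * m$moving_points[, 1] +
                    inv[2, 2] * m$moving_points[, 2] + inv[2, 3])
  disp <- sqrt(rowSums((mapped - m$fixed_points)^2))
  expect_lt(median(disp), 2)
})

test_that("MSAC recovers exact and outlier-contaminated affines", {
  set.seed(42)
  n <- 60
  mov <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  a <- 5 * pi / 180; s <- 1.05
  A <- matrix(c(s * cos(a), -s * sin(a), 7,
                s * sin(a), s * cos(a), -3), 2, 3, byrow = TRUE)
  fix <- cbind(A[1, 1] * mov[, 1] + A[1, 2] * mov[, 2] + A[1, 3],
               A[2, 1] * mov[, 1] + A[2, 2] * mov[, 2] + A[2, 3])
  # noiseless correspondences -> recovered within 1e-6
  t0 <- estimate_affine_msac(feature_match_set(fix, mov, rep(0, n)),
                             seed = 1)
  expect_lt(max(abs(t0$matrix - A)), 1e-6)
  # identity correspondences -> identity matrix
  ti <- estimate_affine_msac(feature_match_set(mov, mov, rep(0, n)),
                             seed = 1)
  expect_equal(ti$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-9)
  # 30% gross outliers -> < 0.5 px mean residual on true inliers
  out_idx <- sample(n, 18)
  fix2 <- fix
  fix2[out_idx, ] <- fix2[out_idx, ] + matrix(runif(36, 15, 60), 18, 2)
  t1 <- estimate_affine_msac(feature_match_set(fix2, mov, rep(0, n)),
                             seed = 1)
  pred <- cbind(t1$matrix[1, 1] * mov[, 1] + t1$matrix[1, 2] * mov[, 2] +
                  t1$matrix[1, 3],
                t1$matrix[2, 1] * mov[, 1] + t1$matrix[2, 2] * mov[, 2] +
                  t1$matrix[2, 3])
  res <- sqrt(rowSums((pred - fix)^2))
  expect_lt(mean(res[-out_idx]), 0.5)
  expect_gte(t1$inlier_count, n - length(out_idx))
  # reproducible bit-for-bit under a fixed seed
  t2 <- estimate_affine_msac(feature_match_set(fix2, mov, rep(0, n)),
                             seed = 1)
  expect_identical(t1$matrix, t2$matrix)
  expect_error(estimate_affine_msac(
    feature_match_set(fix[1:2, ], mov[1:2, ], rep(0, 2))), "at least 3")
})

test_that("affine warping interpolates and fills out-of-bounds with zero", {
  img <- textured_phantom(seed = 7, size = 64)
  ident <- affine_transform(cbind(diag(2), c(0, 0)))
  expect_equal(warp_affine(img, ident, c(64, 64))$data, img$data)
  # integer translation is an exact pixel shift
  tr <- affine_transform(cbind(diag(2), c(3, 2)))
  shifted <- warp_affine(img, tr, c(64, 64))
  expect_equal(shifted$data[3:64, 4:64, ], img$data[1:62, 1:61, ])
  expect_true(all(shifted$data[1:2, , ] == 0))
  # warp round trip approximately identity away from borders (smooth image,
  # so the double bilinear resampling error stays small)
  yy <- matrix(seq_len(64), 64, 64); xx <- t(yy)
  smooth <- array(0, c(64, 64, 3))
  smooth[, , 1] <- 120 + 60 * sin(xx / 9) * cos(yy / 11)
  smooth[, , 2] <- 120 + 60 * cos(xx / 7)
  smooth[, , 3] <- 120 + 60 * sin((xx + yy) / 13)
  smooth_img <- rgb_image(smooth)
  A <- rotation_about_center(5, 31.5, scale = 1.05)
  inv <- cbind(solve(A[, 1:2]), -solve(A[, 1:2]) %*% A[, 3])
  there <- warp_affine(smooth_img, affine_transform(A), c(64, 64))
  back <- warp_affine(there, affine_transform(inv), c(64, 64))
  core <- 12:52
  expect_lt(mean(abs(back$data[core, core, ] - smooth[core, core, ])), 2)
  expect_error(affine_transform(rbind(c(1, 1, 0), c(1, 1, 0))), "singular")
})

test_that("overlay renders fixed as magenta and registered as green", {
  img <- textured_phantom(seed = 8, size = 48)
  ov <- overlay_check(img, img)
  expect_equal(ov$data[, , 1], ov$data[, , 2])  # identical inputs -> gray
  expect_equal(ov$data[, , 1], ov$data[, , 3])
  black <- rgb_image(array(0, dim(img$data)))
  ov2 <- overlay_check(img, black)
  expect_true(all(ov2$data[, , 2] == 0))        # pure magenta
  expect_gt(max(ov2$data[, , 1]), 0)
  # a shifted pair produces channel disagreement near edges
  tr <- affine_transform(cbind(diag(2), c(4, 0)))
  ov3 <- overlay_check(img, warp_affine(img, tr, dim(img$data)[1:2]))
  expect_gt(max(abs(ov3$data[, , 1] - ov3$data[, , 2])), 20)
  expect_error(overlay_check(img, textured_phantom(size = 32)), "shape")
})

test_that("end-to-end registration recovers a known synthetic affine", {
  img <- textured_phantom(seed = 5)
  A <- rotation_about_center(5, 47.5)
  inv <- cbind(solve(A[, 1:2]), -solve(A[, 1:2]) %*% A[, 3])
  moving <- warp_affine(img, affine_transform(A), c(96, 96))
  res <- register_pair(img, moving, seed = 3)
  expect_lt(max(abs(res$transform$matrix[, 1:2] - inv[, 1:2])), 0.01)
  expect_lt(max(abs(res$transform$matrix[, 3] - inv[, 3])), 1)
  # residual property: mean inlier transfer error below the tolerance
  expect_lt(registration_residual(res$transform, res$matches), 3)
  # transform JSON round-trip
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "t.json")
  write_transform(res$transform, p)
  expect_equal(read_transform(p)$matrix, res$transform$matrix,
               tolerance = 1e-12)
})
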