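test_that("MSE/RMSE/PSNR match closed forms and a loop oracle", {
  a <- random_rgb(3, 3, seed = 1)
  expect_equal(mse_rmse(a, a), list(mse = 0, rmse = 0))
  expect_equal(psnr(a, a), Inf)
  # constant difference of 255
  lo <- rgb_image(array(0, c(3, 3, 3)))
  hi <- rgb_image(array(255, c(3, 3, 3)))
  expect_equal(mse_rmse(lo, hi), list(mse = 65025, rmse = 255))
  expect_equal(psnr(lo, hi), 0)
  # triple-loop oracle on a random pair, to 1e-12
  b <- random_rgb(3, 3, seed = 2)
  acc <- 0
  for (x in 1:3) for (y in 1:3) for (z in 1:3) {
    acc <- acc + (a$data[x, y, z] - b$data[x, y, z])^2
  }
  expect_equal(mse_rmse(a, b)$mse, acc / 27, tolerance = 1e-12)
  # PSNR = 20 dB when MSE = 255^2 / 100
  g1 <- array(0, c(4, 4, 3))
  g2 <- array(sqrt(65025 / 100), c(4, 4, 3))
  expect_equal(psnr(g1, g2), 20, tolerance = 1e-12)
  # psnr strictly decreases as mse increases
  expect_gt(psnr(a, a$data + 1), psnr(a, a$data + 2))
  expect_error(mse_rmse(a, random_rgb(4, 3)), "shapes differ")
})

test_that("global SSIM matches the printed closed forms", {
  a <- random_rgb(8, 8, seed = 3)
  expect_identical(ssim_rgb(a, a), 1)
  # constant offset: contrast/structure = 1; luminance has a closed form
  cdat <- array(100, c(6, 6, 3))
  # add spatial variation so sd > 0
  set.seed(5); cdat <- cdat + array(sample(0:20, 108, TRUE), c(6, 6, 3))
  off <- 30
  p <- ssim_params()
  got <- ssim_rgb(rgb_image(cdat), rgb_image(cdat + off))
  lum <- vapply(1:3, function(k) {
    mu <- mean(cdat[, , k])
    (2 * mu * (mu + off) + p$C1) / (mu^2 + (mu + off)^2 + p$C1)
  }, numeric(1))
  expect_equal(got, mean(lum), tolerance = 1e-12)
  # from-scratch recomputation on a random pair
  b <- random_rgb(5, 5, seed = 6)
  a5 <- random_rgb(5, 5, seed = 7)
  ora <- mean(vapply(1:3, function(k) {
    x <- a5$data[, , k]; y <- b$data[, , k]
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    (2 * mx * my + p$C1) * (2 * cxy + p$C2) /
      ((mx^2 + my^2 + p$C1) * (vx + vy + p$C2))
  }, numeric(1)))
  expect_equal(ssim_rgb(a5, b), ora, tolerance = 1e-12)
  # symmetry and permutation invariance (global statistics)
  expect_equal(ssim_rgb(a5, b), ssim_rgb(b, a5), tolerance = 1e-14)
  set.seed(8); perm <- sample(25)
  pa <- a5$data; pb <- b$data
  for (k in 1:3) {
    pa[, , k] <- matrix(a5$data[, , k][perm], 5, 5)
    pb[, , k] <- matrix(b$data[, , k][perm], 5, 5)
  }
  expect_equal(ssim_rgb(rgb_image(pa), rgb_image(pb)), ssim_rgb(a5, b),
               tolerance = 1e-12)
})

test_that("SSIM constants derive from the dynamic range as printed", {
  p <- ssim_params(L = 255)
  expect_equal(p$C1, (0.01 * 255)^2)
  expect_equal(p$C2, (0.03 * 255)^2)
  expect_equal(p$C3, p$C2 / 2)
})

test_that("fibrous HSV mask applies the two stain color ranges", {
  # build single-pixel images with prescribed HSV (OpenCV scale) via inverse
  hsv_px <- function(h, s, v) {
    rgb <- grDevices::hsv(h / 180, s / 255, v / 255)
    m <- grDevices::col2rgb(rgb)
    rgb_image(array(as.numeric(m), c(1, 1, 3)))
  }
  expect_true(fibrous_mask(hsv_px(130, 200, 200))[1, 1])   # blue-to-pink
  expect_true(fibrous_mask(hsv_px(130, 10, 70))[1, 1])     # black variant
  expect_false(fibrous_mask(hsv_px(0, 0, 255))[1, 1])      # pure white
  expect_false(fibrous_mask(hsv_px(30, 200, 200))[1, 1])   # orange
  # union of ranges equals union of masks
  img <- random_rgb(12, 12, seed = 9)
  r <- default_fibrous_ranges()
  m_union <- fibrous_mask(img, r)
  expect_equal(m_union, fibrous_mask(img, r[1]) | fibrous_mask(img, r[2]))
  expect_error(hsv_range(c(120, 50, 50), c(110, 255, 255)), "lower")
})

test_that("fibrous RMSE restricts the error to masked pixels", {
  gt <- rgb_image(array(c(10, 20, 30, 40,   50, 60, 70, 80,
                          90, 100, 110, 120), c(2, 2, 3)))
  out <- rgb_image(gt$data + 6)
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  r <- fibrous_rmse(gt, out, mask)
  expect_equal(r$n_pixels, 2L)
  expect_equal(r$rmse, 6)  # constant difference
  # hand-built asymmetric case
  out2 <- gt$data
  out2[1, 1, ] <- out2[1, 1, ] + c(3, 0, 0)   # masked
  out2[2, 1, ] <- out2[2, 1, ] + 100          # unmasked, must not count
  r2 <- fibrous_rmse(gt, rgb_image(out2), mask)
  expect_equal(r2$rmse, sqrt(9 / 6), tolerance = 1e-12)
  # full mask reduces to whole-image RMSE
  full <- matrix(TRUE, 2, 2)
  expect_equal(fibrous_rmse(gt, out, full)$rmse, mse_rmse(gt, out)$rmse)
  expect_error(fibrous_rmse(gt, out, matrix(FALSE, 2, 2)), "empty")
})

test_that("pair and dataset evaluation assemble the metric columns", {
  ph <- generate_phantom(phantom_config(seed = 12))
  gt <- ph$evg_rgb
  rec <- evaluate_pair(gt, gt)
  expect_equal(rec$ssim, 1)
  expect_equal(rec$psnr, Inf)
  expect_equal(rec$rmse_whole, 0)
  expect_equal(rec$rmse_fibrous, 0)
  expect_gt(rec$n_fibrous_pixels, 0)
  # fields match individually computed metrics for a perturbed pair
  set.seed(13)
  out <- rgb_image(pmin(pmax(gt$data +
                               array(sample(-20:20, length(gt$data), TRUE),
                                     dim(gt$data)), 0), 255))
  rec2 <- evaluate_pair(gt, out)
  expect_equal(rec2$ssim, ssim_rgb(gt, out))
  expect_equal(rec2$rmse_whole, mse_rmse(gt, out)$rmse)
  expect_equal(rec2$rmse_fibrous,
               fibrous_rmse(gt, out, fibrous_mask(gt))$rmse)
  # dataset report over identical pairs equals the single-pair record
  rep <- evaluate_dataset(list(gt, gt), list(out, out))
  expect_equal(nrow(rep), 3)
  expect_equal(rep$rmse_whole[3], rec2$rmse_whole)
  expect_equal(rep$ssim[3], rec2$ssim)
})
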