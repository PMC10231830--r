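test_that("Beer-Lambert inversion maps absorbance to transmittance", {
  g <- tiny_grid(3)
  sp <- dye_spectrum(c(0, 1, 2), g, "x")
  expect_equal(transmittance_from_absorbance(sp), c(1, 0.1, 0.01))
  expect_error(dye_spectrum(c(-0.1, 0, 0), g), "nonnegative")
})

test_that("channel-selection basis is one-hot band slicing", {
  g <- default_grid()
  bs <- basis_channel_select(g)
  expect_equal(g$values[c(10, 11, 12)], c(465, 470, 475))
  expect_equal(rowSums(bs$matrix), c(1, 1, 1), ignore_attr = TRUE)
  cube <- random_cube(3, 3, 61, seed = 2)
  proj <- project_cube(cube, bs)
  expect_equal(proj, cube$data[, , c(10, 11, 12)])
  expect_error(basis_channel_select(g, c(10, 11, 62)), "out of range")
})

test_that("cube projection equals the per-pixel dot-product oracle", {
  set.seed(4)
  b <- 61
  cube <- random_cube(2, 2, b, seed = 4)
  m <- matrix(rnorm(3 * b), 3, b)
  bs <- basis_set(m, c("a", "b", "c"), default_grid())
  proj <- project_cube(cube, bs)
  for (h in 1:2) for (w in 1:2) for (k in 1:3) {
    acc <- 0
    for (bb in seq_len(b)) acc <- acc + m[k, bb] * cube$data[h, w, bb]
    expect_equal(proj[h, w, k], acc)
  }
  # linearity
  cube2 <- random_cube(2, 2, b, seed = 5)
  lin <- project_cube(hsi_cube(2 * cube$data + 3 * cube2$data,
                               cube$grid), bs)
  expect_equal(lin, 2 * proj + 3 * project_cube(cube2, bs))
})

test_that("PCA basis agrees with a dense eigendecomposition oracle", {
  set.seed(9)
  b <- 8
  # 50 pixels on an arbitrary full-rank toy spectrum set
  px <- matrix(runif(50 * b), 50, b)
  cubes <- list(hsi_cube(array(px[1:25, ], c(5, 5, b)), tiny_grid(b)),
                hsi_cube(array(px[26:50, ], c(5, 5, b)), tiny_grid(b)))
  pooled <- rbind(matrix(cubes[[1]]$data, 25, b),
                  matrix(cubes[[2]]$data, 25, b))
  bs <- basis_ldf_pca(rep(1, b), cubes)
  eig <- eigen(stats::cov(pooled))
  for (k in 1:2) {
    v <- eig$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(as.numeric(bs$matrix[k, ]), v, tolerance = 1e-8)
  }
  # rows orthonormal, explained variance nonincreasing and summing to <= 1
  expect_equal(sum(bs$matrix[1, ]^2), 1)
  expect_equal(sum(bs$matrix[1, ] * bs$matrix[2, ]), 0, tolerance = 1e-12)
  ev <- attr(bs, "explained_variance")
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-12)
})

test_that("rank-2 pixel data gives two components explaining all variance", {
  set.seed(11)
  b <- 10
  base1 <- runif(b); base2 <- runif(b)
  w <- matrix(runif(32, 0.2, 1), 16, 2)
  px <- w %*% rbind(base1, base2)
  cube <- hsi_cube(array(px, c(4, 4, b)), tiny_grid(b))
  bs <- basis_ldf_pca(rep(1, b), list(cube))
  ev <- attr(bs, "explained_variance")
  expect_gte(sum(ev[1:2]), 1 - 1e-9)
  # constant (rank-deficient after centering) data is rejected
  flat <- hsi_cube(array(rep(base1, each = 16), c(4, 4, b)), tiny_grid(b))
  expect_error(basis_ldf_pca(rep(1, b), list(flat)), "rank-deficient")
})

test_that("LDF + dye basis has the documented rows and shape", {
  g <- default_grid()
  dyes <- default_dye_spectra(g)
  ldf <- rep(0.5, 61)
  bs <- basis_ldf_dyes(ldf, dyes$hematoxylin, dyes$eosin)
  expect_equal(dim(bs$matrix), c(3L, 61L))
  expect_equal(bs$row_names, c("LDF", "eosin_T", "hematoxylin_T"))
  expect_equal(as.numeric(bs$matrix[2, ]),
               transmittance_from_absorbance(dyes$eosin))
  # zero-absorbance eosin row is all ones
  zero_e <- dye_spectrum(rep(0, 61), g, "eosin")
  bs0 <- basis_ldf_dyes(ldf, dyes$hematoxylin, zero_e)
  expect_true(all(bs0$matrix[2, ] == 1))
  # grid mismatch rejected
  other <- default_dye_spectra(wavelength_grid(420, 715, 5))
  expect_error(basis_ldf_dyes(ldf, dyes$hematoxylin, other$eosin),
               "different wavelength grids")
})

test_that("sRGB rendering matches a direct quadrature oracle", {
  g <- default_grid()
  cs <- colorimetric_system(g)
  # perfect transmitter -> white; opaque -> black
  ones <- hsi_cube(array(1, c(2, 2, 61)), g)
  expect_true(all(cube_to_srgb(ones, cs)$data == 255))
  zeros <- hsi_cube(array(0, c(2, 2, 61)), g)
  expect_true(all(cube_to_srgb(zeros, cs)$data == 0))
  # single-pixel oracle: independent summation with the same CMF table
  set.seed(3)
  tr <- runif(61, 0, 1)
  one_px <- hsi_cube(array(tr, c(1, 1, 61)), g)
  got <- cube_to_srgb(one_px, cs)$data[1, 1, ]
  w <- cs$illuminant * g$step_nm
  xyz <- as.numeric(cs$cmf %*% (tr * w))
  xyz_w <- as.numeric(cs$cmf %*% w)
  m <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  lin <- pmin(pmax(as.numeric(m %*% xyz) / as.numeric(m %*% xyz_w), 0), 1)
  gam <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  expect_true(all(abs(got - gam * 255) <= 1))
  # monotone in overall brightness
  darker <- cube_to_srgb(hsi_cube(array(tr * 0.5, c(1, 1, 61)), g), cs)
  expect_true(all(darker$data[1, 1, ] <= got))
})

test_that("basis and dye-spectrum CSV serialization round-trips", {
  tmp <- withr::local_tempdir()
  g <- default_grid()
  bs <- basis_ldf_dyes(runif(61), default_dye_spectra(g)$hematoxylin,
                       default_dye_spectra(g)$eosin)
  p <- file.path(tmp, "basis.csv")
  write_basis(bs, p)
  back <- read_basis(p)
  expect_equal(back$matrix, bs$matrix, tolerance = 1e-12)
  expect_equal(back$row_names, bs$row_names)
  sp <- default_dye_spectra(g)
  ps <- file.path(tmp, "dyes.csv")
  write_dye_spectra(sp, ps)
  back_sp <- read_dye_spectra(ps)
  expect_equal(back_sp$eosin$absorbance, sp$eosin$absorbance,
               tolerance = 1e-12)
  # the shipped synthetic defaults file is readable
  shipped <- read_dye_spectra(system.file("extdata",
                                          "dye_absorbance_synthetic.csv",
                                          package = "hyperstain"))
  expect_setequal(names(shipped), c("hematoxylin", "eosin"))
  expect_length(shipped$eosin$absorbance, 61)
})
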