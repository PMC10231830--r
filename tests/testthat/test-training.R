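test_that("loss operators match the printed arithmetic", {
  # discriminator LSGAN: perfect discrimination -> 0; scalar 0.5/0.5 -> 0.5
  expect_equal(adversarial_loss(array(1, c(2, 2, 1)), array(0, c(2, 2, 1))),
               0)
  expect_equal(adversarial_loss(0.5, 0.5), 0.25 + 0.25)
  expect_equal(adversarial_loss(NULL, array(1, c(3, 3, 1)), "generator"), 0)
  expect_error(adversarial_loss(numeric(0), numeric(0)), "empty")
  # cycle MAE: zero on identity, offset on constants, loop oracle
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_equal(cycle_loss(x, x), 0)
  expect_equal(cycle_loss(x, x + 0.2), 0.2)
  y <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  acc <- 0
  for (i in seq_along(x)) acc <- acc + abs(x[i] - y[i])
  expect_equal(cycle_loss(x, y), acc / length(x), tolerance = 1e-12)
  expect_error(cycle_loss(x, array(0, c(4, 4, 2))), "shape")
  # total loss: Eq with defaults lambda = 5, gamma = 0.5
  expect_equal(total_loss(1, 2, 4), 13)
  expect_equal(total_loss(0, 0, 0), 0)
  w0 <- loss_weights(5, 0)
  expect_equal(total_loss(1, 2, 4, w0), 11)   # no-identity ablation
  # linearity in each component
  expect_equal(total_loss(2, 3, 5) - total_loss(1, 3, 5), 1)
  expect_equal(total_loss(1, 4, 5) - total_loss(1, 3, 5), 5)
  expect_equal(total_loss(1, 3, 6) - total_loss(1, 3, 5), 0.5)
})

test_that("identity inputs satisfy the channel-adaptation contract", {
  ph <- generate_phantom(phantom_config(size = c(32, 32), seed = 21))
  basis <- basis_channel_select(default_grid())
  ii <- identity_inputs(ph$he_cube, ph$evg_rgb, basis)
  expect_equal(dim(ii$HE_red), c(32L, 32L, 3L))
  expect_equal(dim(ii$EVG_inc), c(32L, 32L, 61L))
  expect_true(all(ii$EVG_inc[, , 4:61] == 0))
  expect_equal(ii$EVG_inc[, , 1:3], ii$EVG_org)
  expect_true(max(abs(ii$HE_red)) <= 1)
  # identity loss equals a from-scratch recomputation with toy generators
  set.seed(22)
  bundle <- build_model_bundle(preset = "toy")
  got <- identity_loss(bundle, ii)
  ora <- mean(abs(bundle$G_EVG_to_HE$fwd(ii$HE_red) - ii$HE_org)) +
         mean(abs(bundle$G_HE_to_EVG$fwd(ii$EVG_inc) - ii$EVG_org))
  expect_equal(got, ora, tolerance = 1e-12)
  expect_gte(got, 0)
})

test_that("training configs enforce phase defaults and bounds", {
  c1 <- training_config(phase = 1L)
  expect_equal(c1$learning_rate, 2e-4)
  c2 <- training_config(phase = 2L)
  expect_equal(c2$learning_rate, 3e-5)
  expect_equal(loss_weights()$lambda_cycle, 5.0)
  expect_equal(loss_weights()$gamma_identity, 0.5)
  expect_error(training_config(phase = 3L))
  expect_error(training_config(batch_size = 9))
  expect_error(loss_weights(-1, 0))
})

test_that("phase-1 training descends and is seed-reproducible", {
  pools <- toy_pools(77, n_unpaired = 4, n_paired = 2, n_test = 1)
  basis <- basis_channel_select(default_grid())
  cfg <- training_config(phase = 1L, epochs = 6L, seed = 7,
                         tile_size = 32L, preset = "toy")
  r <- train_phase1(pools$unpaired, cfg, basis)
  expect_lt(tail(r$history$g_total, 1), r$history$g_total[1])
  expect_equal(nrow(r$history), 6)
  # same seed twice -> identical loss histories
  r2 <- train_phase1(pools$unpaired, cfg, basis)
  expect_identical(r$history, r2$history)
  # 0 epochs leaves the initialisation untouched
  cfg0 <- training_config(phase = 1L, epochs = 0L, seed = 7,
                          tile_size = 32L, preset = "toy")
  set.seed(7); b0 <- build_model_bundle(preset = "toy")
  set.seed(7); b1 <- build_model_bundle(preset = "toy")
  rb <- train_phase1(pools$unpaired, cfg0, basis, bundle = b1)
  x <- array(rnorm(32 * 32 * 61), c(32, 32, 61))
  expect_identical(rb$bundle$G_HE_to_EVG$fwd(x), b0$G_HE_to_EVG$fwd(x))
  expect_error(train_phase1(list(he_cubes = list(), evg_rgbs = list()),
                            cfg, basis), "empty")
})

test_that("validation-SSIM model selection returns the best epoch weights", {
  pools <- toy_pools(78, n_unpaired = 4, n_paired = 2, n_test = 1)
  basis <- basis_channel_select(default_grid())
  cfg <- training_config(phase = 1L, epochs = 5L, seed = 8,
                         tile_size = 32L, preset = "toy")
  r <- train_phase1(pools$unpaired, cfg, basis, val_pairs = pools$paired)
  expect_true("val_ssim" %in% names(r$history))
  expect_equal(r$best_epoch, which.max(r$history$val_ssim))
  val <- mean(mapply(function(cb, im) {
    ssim_rgb(im, convert_cube(r$bundle$G_HE_to_EVG, cb))
  }, pools$paired$he_cubes, pools$paired$evg_rgbs))
  expect_equal(val, max(r$history$val_ssim), tolerance = 1e-12)
})

test_that("phase-2 refinement reduces the supervised MSE", {
  pools <- toy_pools(79, n_unpaired = 2, n_paired = 4, n_test = 1)
  cfg2 <- training_config(phase = 2L, epochs = 8L, seed = 9,
                          tile_size = 32L, preset = "toy")
  r <- train_phase2_refine(pools$paired, cfg2, from_scratch = TRUE)
  expect_lt(tail(r$history$mse, 1), r$history$mse[1])
  expect_equal(r$init_mode, "random")
  # init from a bundle is tagged and does not modify the bundle
  set.seed(10); bundle <- build_model_bundle(preset = "toy")
  x <- hyperstain:::norm_cube_tile(pools$paired$he_cubes[[1]]$data)
  before <- bundle$G_HE_to_EVG$fwd(x)
  rp <- train_phase2_refine(pools$paired, cfg2, init = bundle)
  expect_equal(rp$init_mode, "pretrained")
  expect_identical(bundle$G_HE_to_EVG$fwd(x), before)
  expect_gt(max(abs(rp$generator$fwd(x) - before)), 0)
  # missing checkpoint without the ablation flag errors
  expect_error(train_phase2_refine(pools$paired, cfg2), "checkpoint")
})

test_that("a generator that already matches its targets is a fixed point", {
  pools <- toy_pools(80, n_unpaired = 2, n_paired = 2, n_test = 1)
  set.seed(11); bundle <- build_model_bundle(preset = "toy")
  # make the targets equal to the current generator output
  targets <- lapply(pools$paired$he_cubes, function(cb) {
    convert_cube(bundle$G_HE_to_EVG, cb)
  })
  paired <- list(he_cubes = pools$paired$he_cubes, evg_rgbs = targets)
  cfg2 <- training_config(phase = 2L, epochs = 2L, seed = 12,
                          tile_size = 32L, preset = "toy")
  r <- train_phase2_refine(paired, cfg2, init = bundle)
  # loss is only the 8-bit quantisation floor and weights barely move
  expect_lt(r$history$mse[1], 1e-4)
  x <- hyperstain:::norm_cube_tile(pools$paired$he_cubes[[1]]$data)
  expect_lt(max(abs(r$generator$fwd(x) - bundle$G_HE_to_EVG$fwd(x))), 0.05)
})
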