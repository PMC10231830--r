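# Two-phase training: Phase 1 is an unsupervised CycleGAN with adversarial
# (least-squares), cycle-consistency (MAE) and basis-function identity (MAE)
# losses; Phase 2 re-trains the HE->EVG generator in a supervised way on
# paired tiles with an MSE objective, initialised from the Phase-1 weights.

# Fixed normalization conventions: hyperspectral transmittance is mapped
# from [0, 1.2] to [-1, 1]; 8-bit RGB from [0, 255] to [-1, 1].
norm_cube_tile <- function(x) x / 0.6 - 1
denorm_cube_tile <- function(x) pmin(pmax((x + 1) * 0.6, 0), 1.2)
norm_rgb_tile <- function(x) x / 127.5 - 1
denorm_rgb_tile <- function(x) pmin(pmax((x + 1) * 127.5, 0), 255)

#' Loss weights for the total CycleGAN objective
#'
#' `L_total = L_adversarial + lambda * L_cycle + gamma * L_identity`,
#' with defaults `lambda = 5.0` and `gamma = 0.5`.
#'
#' @param lambda_cycle Cycle-consistency weight (`>= 0`).
#' @param gamma_identity Identity-loss weight (`>= 0`); 0 disables the
#'   identity term (the no-identity ablation).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_cycle = 5.0, gamma_identity = 0.5) {
  stopifnot(lambda_cycle >= 0, gamma_identity >= 0)
  structure(list(lambda_cycle = lambda_cycle,
                 gamma_identity = gamma_identity),
            class = "loss_weights")
}

#' Training configuration
#'
#' @param phase 1 (unsupervised CycleGAN) or 2 (supervised refinement).
#' @param learning_rate Adam learning rate; defaults 2e-4 for phase 1 and
#'   3e-5 for phase 2.
#' @param epochs Number of epochs.
#' @param seed Integer seed controlling weight init and data order.
#' @param basis_mode Identity-projection basis: `"channels"`, `"ldf_pca"` or
#'   `"ldf_dyes"`.
#' @param tile_size Square tile side (must be divisible by `2^depth`).
#' @param batch_size Tiles per optimizer step (1--6).
#' @param weights A [loss_weights()] bundle.
#' @param preset Network preset, `"toy"` or `"full"`.
#' @return An object of class `training_config`.
#' @export
training_config <- function(phase = 1L, learning_rate = NULL, epochs = 10L,
                            seed = 1L,
                            basis_mode = c("ldf_dyes", "channels", "ldf_pca"),
                            tile_size = 128L, batch_size = 1L,
                            weights = loss_weights(),
                            preset = c("toy", "full")) {
  stopifnot(phase %in% c(1L, 2L), epochs >= 0, batch_size >= 1,
            batch_size <= 6)
  if (is.null(learning_rate)) {
    learning_rate <- if (phase == 1L) 2e-4 else 3e-5
  }
  structure(list(phase = as.integer(phase), learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 basis_mode = match.arg(basis_mode),
                 tile_size = as.integer(tile_size),
                 batch_size = as.integer(batch_size),
                 weights = weights, preset = match.arg(preset)),
            class = "training_config")
}

#' Least-squares adversarial loss
#'
#' Discriminator side: `mean((D(real) - 1)^2) + mean(D(fake)^2)`.
#' Generator side: `mean((D(fake) - 1)^2)` (`scores_real` is ignored and may
#' be `NULL`).
#'
#' @param scores_real,scores_fake Patch-score maps (numeric arrays).
#' @param side `"discriminator"` or `"generator"`.
#' @return Scalar loss.
#' @export
adversarial_loss <- function(scores_real, scores_fake,
                             side = c("discriminator", "generator")) {
  side <- match.arg(side)
  if (length(scores_fake) == 0) stop("empty score map")
  if (side == "generator") return(mean((scores_fake - 1)^2))
  if (is.null(scores_real) || length(scores_real) == 0) {
    stop("empty score map")
  }
  mean((scores_real - 1)^2) + mean(scores_fake^2)
}

#' Cycle-consistency loss (mean absolute error)
#'
#' @param x Original tile.
#' @param reconstructed_x Round-trip reconstruction of the same shape.
#' @return Mean absolute difference over all elements.
#' @export
cycle_loss <- function(x, reconstructed_x) {
  if (!identical(dim(x), dim(reconstructed_x))) {
    stop("cycle_loss: shape mismatch")
  }
  mean(abs(x - reconstructed_x))
}

# MAE gradient wrt the first argument, scaled by `w`.
mae_grad <- function(pred, target, w = 1) {
  w * sign(pred - target) / length(pred)
}

#' Construct the identity-loss inputs for one unpaired pair of tiles
#'
#' `HE_red` is the 3-channel basis projection of the H&E cube tile, rescaled
#' per channel to `[-1, 1]` by tile min-max (the projection scale depends on
#' the basis, while the 3-channel generator expects tanh-scaled inputs);
#' `EVG_inc` is the normalised EVG tile zero-padded to the cube channel
#' count (channels 4..B are exactly zero). `HE_org` and `EVG_org` are the
#' normalised originals.
#'
#' @param he_cube An [hsi_cube()] tile.
#' @param evg_rgb An [rgb_image()] tile.
#' @param basis A [basis_set()] on the cube's grid.
#' @return An object of class `identity_inputs` with fields `HE_org`,
#'   `HE_red`, `EVG_org`, `EVG_inc`.
#' @export
identity_inputs <- function(he_cube, evg_rgb, basis) {
  red <- project_cube(he_cube, basis)
  for (k in 1:3) {
    ch <- red[, , k]; lo <- min(ch); hi <- max(ch)
    red[, , k] <- if (hi - lo < 1e-12) 0 else (ch - lo) / (hi - lo) * 2 - 1
  }
  evg_n <- norm_rgb_tile(evg_rgb$data)
  b <- dim(he_cube$data)[3]
  structure(list(HE_org = norm_cube_tile(he_cube$data),
                 HE_red = red,
                 EVG_org = evg_n,
                 EVG_inc = pad_with_zero_channels(evg_n, b)),
            class = "identity_inputs")
}

#' Basis-function identity loss
#'
#' `MAE(G_EVG_to_HE(HE_red), HE_org) + MAE(G_HE_to_EVG(EVG_inc), EVG_org)`:
#' each generator, fed a channel-adapted image already in its *target*
#' domain, should return it unchanged.
#'
#' @param bundle A `model_bundle`.
#' @param inputs An [identity_inputs()] object.
#' @return Scalar loss.
#' @export
identity_loss <- function(bundle, inputs) {
  stopifnot(inherits(bundle, "model_bundle"),
            inherits(inputs, "identity_inputs"))
  i_he <- bundle$G_EVG_to_HE$fwd(inputs$HE_red)
  i_evg <- bundle$G_HE_to_EVG$fwd(inputs$EVG_inc)
  cycle_loss(inputs$HE_org, i_he) + cycle_loss(inputs$EVG_org, i_evg)
}

#' Total CycleGAN loss
#'
#' `adv + lambda * cyc + gamma * idt`.
#'
#' @param adv,cyc,idt Loss components.
#' @param w A [loss_weights()] bundle.
#' @return Scalar total loss.
#' @export
total_loss <- function(adv, cyc, idt, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"),
            is.finite(adv), is.finite(cyc), is.finite(idt))
  adv + w$lambda_cycle * cyc + w$gamma_identity * idt
}

check_tile_sizes <- function(tiles, depth) {
  for (t in tiles) {
    d <- if (inherits(t, "hsi_cube")) dim(t$data)
         else if (inherits(t, "rgb_image")) dim(t$data) else dim(t)
    if (any(d[1:2] %% 2^depth != 0)) {
      stop(sprintf("tile size %dx%d not divisible by 2^depth = %d",
                   d[1], d[2], 2^depth))
    }
  }
}

#' Phase-1 unsupervised CycleGAN training
#'
#' Alternating generator/discriminator least-squares updates with Adam
#' (default learning rate 2e-4), cycle weight `lambda = 5`, identity weight
#' `gamma = 0.5`. Reproducible bit-for-bit under a fixed seed and data
#' order.
#'
#' @param data List with `he_cubes` (list of [hsi_cube()]s) and `evg_rgbs`
#'   (list of [rgb_image()]s); the pools may have different lengths
#'   (unpaired).
#' @param config A [training_config()] with `phase = 1`.
#' @param basis A [basis_set()] for the identity projection (may be `NULL`
#'   when `gamma_identity = 0`).
#' @param bundle Optional pre-built `model_bundle` (default: fresh bundle at
#'   the config preset, initialised from the config seed).
#' @param val_pairs Optional held-out registered pairs (list with `he_cubes`
#'   and `evg_rgbs`). When given, the HE-to-EVG generator is evaluated after
#'   every epoch by mean validation SSIM of its EVG predictions, and the
#'   returned bundle carries the best-epoch weights (model selection);
#'   otherwise the last epoch is returned.
#' @param verbose Print per-epoch losses.
#' @return List with `bundle` (trained `model_bundle`), `history` (per-epoch
#'   data frame of loss components, plus `val_ssim` when `val_pairs` is
#'   given) and `best_epoch`.
#' @export
train_phase1 <- function(data, config, basis = NULL, bundle = NULL,
                         val_pairs = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  if (config$phase != 1L) stop("config$phase must be 1")
  n_he <- length(data$he_cubes); n_evg <- length(data$evg_rgbs)
  if (n_he == 0 || n_evg == 0) stop("empty training pool")
  w <- config$weights
  if (w$gamma_identity > 0 && is.null(basis)) {
    stop("identity loss enabled but no basis supplied")
  }
  set.seed(config$seed)
  if (is.null(bundle)) {
    b_ch <- dim(data$he_cubes[[1]]$data)[3]
    bundle <- build_model_bundle(cube_channels = b_ch,
                                 preset = config$preset)
  }
  depth <- bundle$G_HE_to_EVG$spec$depth
  check_tile_sizes(data$he_cubes, depth)
  check_tile_sizes(data$evg_rgbs, depth)
  G1 <- bundle$G_HE_to_EVG; G2 <- bundle$G_EVG_to_HE
  D_HE <- bundle$D_HE; D_EVG <- bundle$D_EVG
  opt_g1 <- adam_init(G1); opt_g2 <- adam_init(G2)
  opt_d1 <- adam_init(D_HE); opt_d2 <- adam_init(D_EVG)
  lr <- config$learning_rate
  n_steps <- max(n_he, n_evg)
  hist <- NULL
  # precompute normalised tiles and identity inputs
  he_n <- lapply(data$he_cubes, function(cb) norm_cube_tile(cb$data))
  evg_n <- lapply(data$evg_rgbs, function(im) norm_rgb_tile(im$data))
  idt_in <- NULL
  if (w$gamma_identity > 0) {
    idt_in <- lapply(seq_len(n_steps), function(i) {
      identity_inputs(data$he_cubes[[(i - 1) %% n_he + 1]],
                      data$evg_rgbs[[(i - 1) %% n_evg + 1]], basis)
    })
  }
  mse_grad <- function(s, target) 2 * (s - target) / length(s)
  best_ssim <- -Inf; best_epoch <- NA_integer_; best_w <- NULL

  for (ep in seq_len(config$epochs)) {
    acc <- c(g_adv = 0, g_cycle = 0, g_identity = 0, g_total = 0,
             d_he = 0, d_evg = 0)
    for (i in seq_len(n_steps)) {
      he <- he_n[[(i - 1) %% n_he + 1]]
      evg <- evg_n[[(i - 1) %% n_evg + 1]]

      ## ---- generator update -------------------------------------------
      zero_grads(G1); zero_grads(G2); zero_grads(D_HE); zero_grads(D_EVG)
      # direction HE -> EVG -> HE
      f_evg <- G1$fwd(he)
      r_he <- G2$fwd(f_evg)
      s2 <- D_EVG$fwd(f_evg)
      adv <- adversarial_loss(NULL, s2, "generator")
      cyc <- cycle_loss(he, r_he)
      g_fevg <- D_EVG$bwd(array(mse_grad(s2, 1), dim = dim(s2))) +
                G2$bwd(mae_grad(r_he, he, w$lambda_cycle))
      G1$bwd(g_fevg)
      # direction EVG -> HE -> EVG
      f_he <- G2$fwd(evg)
      r_evg <- G1$fwd(f_he)
      s1 <- D_HE$fwd(f_he)
      adv <- adv + adversarial_loss(NULL, s1, "generator")
      cyc <- cyc + cycle_loss(evg, r_evg)
      g_fhe <- D_HE$bwd(array(mse_grad(s1, 1), dim = dim(s1))) +
               G1$bwd(mae_grad(r_evg, evg, w$lambda_cycle))
      G2$bwd(g_fhe)
      # identity terms
      idt <- 0
      if (w$gamma_identity > 0) {
        ii <- idt_in[[i]]
        i_he <- G2$fwd(ii$HE_red)
        idt <- cycle_loss(ii$HE_org, i_he)
        G2$bwd(mae_grad(i_he, ii$HE_org, w$gamma_identity))
        i_evg <- G1$fwd(ii$EVG_inc)
        idt <- idt + cycle_loss(ii$EVG_org, i_evg)
        G1$bwd(mae_grad(i_evg, ii$EVG_org, w$gamma_identity))
      }
      # discriminator grads picked up during G backward are discarded
      zero_grads(D_HE); zero_grads(D_EVG)
      adam_step(G1, opt_g1, lr); adam_step(G2, opt_g2, lr)

      ## ---- discriminator updates --------------------------------------
      zero_grads(D_EVG)
      sr <- D_EVG$fwd(evg)
      d_evg_loss <- mean((sr - 1)^2)
      D_EVG$bwd(array(mse_grad(sr, 1), dim = dim(sr)))
      sf <- D_EVG$fwd(f_evg)
      d_evg_loss <- d_evg_loss + mean(sf^2)
      D_EVG$bwd(array(mse_grad(sf, 0), dim = dim(sf)))
      adam_step(D_EVG, opt_d2, lr)

      zero_grads(D_HE)
      sr <- D_HE$fwd(he)
      d_he_loss <- mean((sr - 1)^2)
      D_HE$bwd(array(mse_grad(sr, 1), dim = dim(sr)))
      sf <- D_HE$fwd(f_he)
      d_he_loss <- d_he_loss + mean(sf^2)
      D_HE$bwd(array(mse_grad(sf, 0), dim = dim(sf)))
      adam_step(D_HE, opt_d1, lr)

      acc <- acc + c(adv, cyc, idt, total_loss(adv, cyc, idt, w),
                     d_he_loss, d_evg_loss)
    }
    acc <- acc / n_steps
    row <- data.frame(epoch = ep, g_adv = acc[1], g_cycle = acc[2],
                      g_identity = acc[3], g_total = acc[4], d_he = acc[5],
                      d_evg = acc[6], row.names = NULL)
    if (!is.null(val_pairs)) {
      val <- mean(mapply(function(cb, im) {
        ssim_rgb(im, convert_cube(G1, cb))
      }, val_pairs$he_cubes, val_pairs$evg_rgbs))
      row$val_ssim <- val
      if (val > best_ssim) {
        best_ssim <- val; best_epoch <- ep
        best_w <- lapply(bundle, net_weights)
      }
    }
    hist <- rbind(hist, row)
    if (verbose) {
      message(sprintf("epoch %d: G total %.4f (adv %.4f cyc %.4f idt %.4f)",
                      ep, acc[4], acc[1], acc[2], acc[3]))
    }
  }
  if (!is.null(best_w)) {
    for (nm in names(bundle)) set_net_weights(bundle[[nm]], best_w[[nm]], nm)
  }
  list(bundle = bundle, history = hist,
       best_epoch = if (is.na(best_epoch)) config$epochs else best_epoch)
}

#' Phase-2 supervised refinement of the HE-to-EVG generator
#'
#' Re-trains `G_HE_to_EVG` alone on registered pairs with an MSE objective
#' and a reduced Adam learning rate (default 3e-5), starting from the
#' Phase-1 weights. The Phase-1 discriminators play no role in the
#' supervised objective and are discarded. An ablation flag allows starting
#' from random weights instead.
#'
#' @param paired_data List with `he_cubes` and `evg_rgbs` of equal length
#'   (registered pairs).
#' @param config A [training_config()] with `phase = 2`.
#' @param init A `model_bundle`, a checkpoint path (from [save_weights()]),
#'   or `NULL` with `from_scratch = TRUE`.
#' @param from_scratch If `TRUE`, initialise the generator randomly (the
#'   no-pretraining ablation); otherwise `init` is required.
#' @param verbose Print per-epoch MSE.
#' @return List with `generator` (refined network), `history` (per-epoch
#'   MSE data frame) and `init_mode` (`"pretrained"` or `"random"`).
#' @export
train_phase2_refine <- function(paired_data, config, init = NULL,
                                from_scratch = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  if (config$phase != 2L) stop("config$phase must be 2")
  n <- length(paired_data$he_cubes)
  stopifnot(n >= 1, length(paired_data$evg_rgbs) == n)
  set.seed(config$seed)
  b_ch <- dim(paired_data$he_cubes[[1]]$data)[3]
  if (from_scratch) {
    gen <- build_generator(
      if (config$preset == "toy") toy_generator_spec(b_ch, 3L)
      else generator_spec(b_ch, 3L))
  } else {
    if (is.null(init)) {
      stop("phase 2 requires a phase-1 checkpoint (or from_scratch = TRUE)")
    }
    bundle <- if (is.character(init)) load_weights(init) else init
    stopifnot(inherits(bundle, "model_bundle"))
    gen <- clone_network(bundle$G_HE_to_EVG)  # leave the phase-1 bundle intact
  }
  check_tile_sizes(paired_data$he_cubes, gen$spec$depth)
  he_n <- lapply(paired_data$he_cubes, function(cb) norm_cube_tile(cb$data))
  evg_n <- lapply(paired_data$evg_rgbs, function(im) norm_rgb_tile(im$data))
  opt <- adam_init(gen)
  hist <- NULL
  for (ep in seq_len(config$epochs)) {
    mse_acc <- 0
    for (i in seq_len(n)) {
      zero_grads(gen)
      out <- gen$fwd(he_n[[i]])
      diff <- out - evg_n[[i]]
      mse_acc <- mse_acc + mean(diff^2)
      gen$bwd(2 * diff / length(diff))
      adam_step(gen, opt, config$learning_rate)
    }
    hist <- rbind(hist, data.frame(epoch = ep, mse = mse_acc / n))
    if (verbose) message(sprintf("epoch %d: MSE %.5f", ep, mse_acc / n))
  }
  list(generator = gen, history = hist,
       init_mode = if (from_scratch) "random" else "pretrained")
}

#' Apply a trained HE-to-EVG generator to a cube
#'
#' Normalises the cube, runs the generator, and denormalises the output to
#' an 8-bit RGB EVG prediction.
#'
#' @param gen A generator (61 to 3 channels) or a `model_bundle` (its
#'   `G_HE_to_EVG` is used).
#' @param cube An [hsi_cube()].
#' @return An [rgb_image()].
#' @export
convert_cube <- function(gen, cube) {
  if (inherits(gen, "model_bundle")) gen <- gen$G_HE_to_EVG
  stopifnot(inherits(cube, "hsi_cube"))
  out <- gen$fwd(norm_cube_tile(cube$data))
  rgb_image(denorm_rgb_tile(out))
}

#' Resolve a basis set from a training-config basis mode
#'
#' @param basis_mode `"channels"`, `"ldf_pca"` or `"ldf_dyes"`.
#' @param ldf Length-B LDF vector (required for the LDF modes).
#' @param training_cubes Cubes for PCA (required for `"ldf_pca"`).
#' @param grid Wavelength grid.
#' @param dyes Dye spectra list (for `"ldf_dyes"`).
#' @return A [basis_set()].
#' @export
resolve_basis <- function(basis_mode, ldf = NULL, training_cubes = NULL,
                          grid = default_grid(),
                          dyes = default_dye_spectra(grid)) {
  switch(basis_mode,
         channels = basis_channel_select(grid),
         ldf_pca = {
           if (is.null(ldf) || is.null(training_cubes)) {
             stop("ldf_pca basis needs `ldf` and `training_cubes`")
           }
           basis_ldf_pca(ldf, training_cubes)
         },
         ldf_dyes = {
           if (is.null(ldf)) stop("ldf_dyes basis needs `ldf`")
           basis_ldf_dyes(ldf, dyes$hematoxylin, dyes$eosin)
         },
         stop(sprintf("unknown basis mode '%s'", basis_mode)))
}
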