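# Heterogeneous-modality CycleGAN building blocks: two U-Net generators with
# different input/output channel counts (61->3 and 3->61) and two PatchGAN
# discriminators (61- and 3-channel inputs).

#' Generator architecture specification
#'
#' @param in_channels,out_channels Input/output channel counts (61 and 3, or
#'   3 and 61, for the two stain-conversion generators).
#' @param depth Number of stride-2 encoder levels; input spatial dims must be
#'   divisible by `2^depth`.
#' @param base_filters Filter count of the first encoder level (doubled per
#'   level).
#' @param output_activation `"tanh"` (images scaled to `(-1, 1)`) or
#'   `"linear"`.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(in_channels, out_channels, depth = 4L,
                           base_filters = 64L,
                           output_activation = c("tanh", "linear")) {
  stopifnot(in_channels >= 1, out_channels >= 1, depth >= 1,
            base_filters >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 output_activation = match.arg(output_activation)),
            class = "generator_spec")
}

#' Toy-scale presets for CPU experimentation
#'
#' Depth-2, 8-filter architectures suitable for 32 x 32 tiles on one CPU.
#'
#' @param in_channels,out_channels Channel counts.
#' @return A [generator_spec()] (`toy_generator_spec`) or
#'   [discriminator_spec()] (`toy_discriminator_spec`).
#' @export
toy_generator_spec <- function(in_channels, out_channels) {
  generator_spec(in_channels, out_channels, depth = 2L, base_filters = 8L)
}

#' @rdname toy_generator_spec
#' @export
toy_discriminator_spec <- function(in_channels) {
  discriminator_spec(in_channels, levels = 2L, base_filters = 8L)
}

#' Discriminator architecture specification
#'
#' @param in_channels Input channel count (61 for the H&E discriminator, 3
#'   for the EVG discriminator).
#' @param levels Number of stride-2 downsampling levels.
#' @param base_filters First-level filter count.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(in_channels, levels = 3L, base_filters = 64L) {
  stopifnot(in_channels >= 1, levels >= 1, base_filters >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 levels = as.integer(levels),
                 base_filters = as.integer(base_filters)),
            class = "discriminator_spec")
}

#' Build a U-Net generator
#'
#' Encoder: `depth` stride-2 4x4 convolutions (instance-normalised from the
#' second level, LeakyReLU); bottleneck 3x3 convolution; decoder: nearest
#' upsampling + 3x3 convolutions with skip concatenation of the matching
#' encoder feature maps (ReLU); final 3x3 convolution with the configured
#' output activation. Spatial output shape equals spatial input shape.
#'
#' @param spec A [generator_spec()].
#' @return A generator environment with `$fwd(x)` (`H x W x in -> H x W x
#'   out`), `$bwd(g)`, `$layers` and `$spec`.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  d <- spec$depth; base <- spec$base_filters
  ch <- base * 2^(seq_len(d) - 1)          # encoder output channels
  net <- new.env(parent = emptyenv())
  net$spec <- spec
  L <- list()
  prev <- spec$in_channels
  for (i in seq_len(d)) {
    L[[paste0("enc", i, "_conv")]] <- nn_conv(prev, ch[i], 4L, 2L, 1L)
    if (i >= 2) L[[paste0("enc", i, "_in")]] <- nn_instance_norm()
    L[[paste0("enc", i, "_act")]] <- nn_act("lrelu")
    prev <- ch[i]
  }
  L[["bott_conv"]] <- nn_conv(ch[d], ch[d], 3L, 1L, 1L)
  L[["bott_in"]] <- nn_instance_norm()
  L[["bott_act"]] <- nn_act("relu")
  for (i in rev(seq_len(d))) {
    L[[paste0("dec", i, "_up")]] <- nn_upsample2()
    in_c <- if (i >= 2) ch[i] + ch[i - 1] else ch[1]
    out_c <- if (i >= 2) ch[i - 1] else base
    L[[paste0("dec", i, "_conv")]] <- nn_conv(in_c, out_c, 3L, 1L, 1L)
    L[[paste0("dec", i, "_in")]] <- nn_instance_norm()
    L[[paste0("dec", i, "_act")]] <- nn_act("relu")
  }
  L[["out_conv"]] <- nn_conv(base, spec$out_channels, 3L, 1L, 1L)
  L[["out_act"]] <- nn_act(if (spec$output_activation == "tanh") "tanh"
                           else "linear")
  net$layers <- L

  net$fwd <- function(x) {
    dm <- dim(x)
    if (dm[3] != spec$in_channels) {
      stop(sprintf("generator expects %d input channels, got %d",
                   spec$in_channels, dm[3]))
    }
    if (any(dm[1:2] %% 2^d != 0)) {
      stop(sprintf("spatial dims (%d x %d) must be divisible by 2^depth = %d",
                   dm[1], dm[2], 2^d))
    }
    e <- vector("list", d)
    h <- x
    for (i in seq_len(d)) {
      h <- L[[paste0("enc", i, "_conv")]]$fwd(h)
      if (i >= 2) h <- L[[paste0("enc", i, "_in")]]$fwd(h)
      h <- L[[paste0("enc", i, "_act")]]$fwd(h)
      e[[i]] <- h
    }
    h <- L[["bott_act"]]$fwd(L[["bott_in"]]$fwd(L[["bott_conv"]]$fwd(h)))
    for (i in rev(seq_len(d))) {
      h <- L[[paste0("dec", i, "_up")]]$fwd(h)
      if (i >= 2) h <- concat_ch(h, e[[i - 1]])
      h <- L[[paste0("dec", i, "_conv")]]$fwd(h)
      h <- L[[paste0("dec", i, "_in")]]$fwd(h)
      h <- L[[paste0("dec", i, "_act")]]$fwd(h)
    }
    net$skip_ch <- ch
    L[["out_act"]]$fwd(L[["out_conv"]]$fwd(h))
  }

  net$bwd <- function(g) {
    g <- L[["out_conv"]]$bwd(L[["out_act"]]$bwd(g))
    skip_g <- vector("list", d)   # gradients flowing into encoder outputs
    for (i in seq_len(d)) {       # decoder blocks, outermost first
      g <- L[[paste0("dec", i, "_act")]]$bwd(g)
      g <- L[[paste0("dec", i, "_in")]]$bwd(g)
      g <- L[[paste0("dec", i, "_conv")]]$bwd(g)
      if (i >= 2) {
        sp <- split_ch(g, dim(g)[3] - net$skip_ch[i - 1])
        g <- sp[[1]]
        skip_g[[i - 1]] <- sp[[2]]
      }
      g <- L[[paste0("dec", i, "_up")]]$bwd(g)
    }
    g <- L[["bott_conv"]]$bwd(L[["bott_in"]]$bwd(L[["bott_act"]]$bwd(g)))
    for (i in rev(seq_len(d))) {
      if (!is.null(skip_g[[i]])) g <- g + skip_g[[i]]
      g <- L[[paste0("enc", i, "_act")]]$bwd(g)
      if (i >= 2) g <- L[[paste0("enc", i, "_in")]]$bwd(g)
      g <- L[[paste0("enc", i, "_conv")]]$bwd(g)
    }
    g
  }
  net
}

#' Build a PatchGAN discriminator
#'
#' `levels` stride-2 4x4 convolutions (instance-normalised from the second,
#' LeakyReLU) followed by a stride-1 4x4 convolution to a 1-channel spatial
#' patch-score map (no sigmoid; the adversarial loss is least-squares).
#'
#' @param spec A [discriminator_spec()].
#' @return A discriminator environment with `$fwd(x)` (`H x W x in -> h' x
#'   w' x 1`, `h' < H`), `$bwd(g)`, `$layers`, `$spec`.
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  net <- new.env(parent = emptyenv())
  net$spec <- spec
  L <- list()
  prev <- spec$in_channels
  for (i in seq_len(spec$levels)) {
    out_c <- spec$base_filters * 2^(i - 1)
    L[[paste0("d", i, "_conv")]] <- nn_conv(prev, out_c, 4L, 2L, 1L)
    if (i >= 2) L[[paste0("d", i, "_in")]] <- nn_instance_norm()
    L[[paste0("d", i, "_act")]] <- nn_act("lrelu")
    prev <- out_c
  }
  L[["score_conv"]] <- nn_conv(prev, 1L, 4L, 1L, 1L)
  net$layers <- L
  net$fwd <- function(x) {
    if (dim(x)[3] != spec$in_channels) {
      stop(sprintf("discriminator expects %d input channels, got %d",
                   spec$in_channels, dim(x)[3]))
    }
    if (any(dim(x)[1:2] < 2^spec$levels * 2)) {
      stop("input smaller than the discriminator receptive field")
    }
    h <- x
    for (i in seq_len(spec$levels)) {
      h <- L[[paste0("d", i, "_conv")]]$fwd(h)
      if (i >= 2) h <- L[[paste0("d", i, "_in")]]$fwd(h)
      h <- L[[paste0("d", i, "_act")]]$fwd(h)
    }
    L[["score_conv"]]$fwd(h)
  }
  net$bwd <- function(g) {
    g <- L[["score_conv"]]$bwd(g)
    for (i in rev(seq_len(spec$levels))) {
      g <- L[[paste0("d", i, "_act")]]$bwd(g)
      if (i >= 2) g <- L[[paste0("d", i, "_in")]]$bwd(g)
      g <- L[[paste0("d", i, "_conv")]]$bwd(g)
    }
    g
  }
  net
}

#' Count trainable parameters of a network
#' @param net Network from [build_generator()]/[build_discriminator()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net_layers_flat(net),
             function(ly) sum(vapply(ly$params, length, integer(1))),
             numeric(1)))
}

#' Assemble the four-network CycleGAN bundle
#'
#' `G_HE_to_EVG` (61 to 3 channels), `G_EVG_to_HE` (3 to 61), `D_HE`
#' (61-channel input) and `D_EVG` (3-channel input).
#'
#' @param cube_channels Hyperspectral channel count (default 61).
#' @param rgb_channels RGB channel count (default 3).
#' @param preset `"toy"` (depth 2, 8 filters; CPU-sized) or `"full"`
#'   (depth 4, 64 filters).
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `model_bundle`.
#' @export
build_model_bundle <- function(cube_channels = 61L, rgb_channels = 3L,
                               preset = c("toy", "full"), seed = NULL) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(seed)
  gs <- if (preset == "toy") {
    list(toy_generator_spec(cube_channels, rgb_channels),
         toy_generator_spec(rgb_channels, cube_channels))
  } else {
    list(generator_spec(cube_channels, rgb_channels),
         generator_spec(rgb_channels, cube_channels))
  }
  ds <- if (preset == "toy") {
    list(toy_discriminator_spec(cube_channels),
         toy_discriminator_spec(rgb_channels))
  } else {
    list(discriminator_spec(cube_channels),
         discriminator_spec(rgb_channels))
  }
  structure(list(G_HE_to_EVG = build_generator(gs[[1]]),
                 G_EVG_to_HE = build_generator(gs[[2]]),
                 D_HE = build_discriminator(ds[[1]]),
                 D_EVG = build_discriminator(ds[[2]])),
            class = "model_bundle")
}

#' Deep-copy a generator or discriminator
#'
#' Networks are mutable environments; training updates them in place. Use
#' this to keep an untouched copy (e.g. before supervised refinement).
#'
#' @param net Network built by [build_generator()] / [build_discriminator()].
#' @return An independent copy with identical weights.
#' @export
clone_network <- function(net) {
  fresh <- if (inherits(net$spec, "generator_spec")) build_generator(net$spec)
           else build_discriminator(net$spec)
  set_net_weights(fresh, net_weights(net))
  fresh
}

# ---- weight (de)serialization ---------------------------------------------

net_weights <- function(net) lapply(net_layers_flat(net), function(ly) ly$params)

set_net_weights <- function(net, w, net_name = "net") {
  lys <- net_layers_flat(net)
  if (length(lys) != length(w)) {
    stop(sprintf("%s: checkpoint has %d parameterised layers, model has %d",
                 net_name, length(w), length(lys)))
  }
  bad <- character(0)
  for (i in seq_along(lys)) {
    for (nm in names(lys[[i]]$params)) {
      cur <- lys[[i]]$params[[nm]]; new <- w[[i]][[nm]]
      same <- if (is.matrix(cur)) is.matrix(new) && all(dim(cur) == dim(new))
              else length(cur) == length(new)
      if (!same) bad <- c(bad, sprintf("%s layer %d (%s)", net_name, i, nm))
    }
  }
  if (length(bad)) {
    stop("weight shape mismatch in: ", paste(bad, collapse = "; "))
  }
  for (i in seq_along(lys)) lys[[i]]$params <- w[[i]]
  invisible(net)
}

bundle_arch <- function(bundle) {
  lapply(bundle, function(net) unclass(net$spec))
}

#' Save / load a model bundle
#'
#' Weights go to a single RDS file; the architecture specification is echoed
#' into a JSON sidecar (`<path>.json`) and validated at load time, so loading
#' weights into a mismatching architecture fails with the differing layers
#' named.
#'
#' @param bundle A `model_bundle`.
#' @param path Checkpoint path.
#' @return `save_weights` returns `path` invisibly; `load_weights` a
#'   `model_bundle`.
#' @export
save_weights <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(list(arch = bundle_arch(bundle),
               weights = lapply(bundle, net_weights)), path)
  jsonlite::write_json(bundle_arch(bundle), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_weights
#' @param into Optional existing `model_bundle` to load the weights into;
#'   its architecture must match the checkpoint.
#' @export
load_weights <- function(path, into = NULL) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' does not exist", path))
  ck <- readRDS(path)
  if (is.null(into)) {
    specs <- ck$arch
    into <- structure(
      list(G_HE_to_EVG = build_generator(do.call(generator_spec,
                                                 specs$G_HE_to_EVG)),
           G_EVG_to_HE = build_generator(do.call(generator_spec,
                                                 specs$G_EVG_to_HE)),
           D_HE = build_discriminator(do.call(discriminator_spec,
                                              specs$D_HE)),
           D_EVG = build_discriminator(do.call(discriminator_spec,
                                               specs$D_EVG))),
      class = "model_bundle")
  }
  for (nm in names(into)) set_net_weights(into[[nm]], ck$weights[[nm]], nm)
  into
}
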