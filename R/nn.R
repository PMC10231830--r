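# Minimal reverse-mode neural-network layers (single-image tensors, H x W x C
# arrays) backing the U-Net generators and PatchGAN discriminators: 2-D
# convolution (compiled kernels), non-affine instance normalization,
# LeakyReLU/ReLU/tanh activations, nearest-neighbour upsampling, and Adam.
# Each layer is an environment caching its forward inputs; bwd() must follow
# the matching fwd() and accumulates parameter gradients into $grads.

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = NULL,
                    init_sd = 0.02) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$k <- as.integer(k); ly$stride <- as.integer(stride)
  ly$pad <- as.integer(pad)
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$params <- list(w = matrix(rnorm(out_ch * k * k * in_ch, 0, init_sd),
                               out_ch, k * k * in_ch),
                    b = rep(0, out_ch))
  ly$grads <- list(w = ly$params$w * 0, b = ly$params$b * 0)
  ly$fwd <- function(x) {
    ly$x <- x
    cpp_conv2d_fwd(x, ly$params$w, ly$params$b, ly$k, ly$stride, ly$pad)
  }
  ly$bwd <- function(g) {
    r <- cpp_conv2d_bwd(ly$x, ly$params$w, g, ly$k, ly$stride, ly$pad)
    ly$grads$w <- ly$grads$w + r$gw
    ly$grads$b <- ly$grads$b + as.numeric(r$gb)
    r$gx
  }
  ly
}

nn_instance_norm <- function(eps = 1e-5) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "inorm"; ly$params <- list(); ly$grads <- list()
  ly$fwd <- function(x) {
    d <- dim(x); n <- d[1] * d[2]
    mu <- apply(x, 3, mean)
    xc <- sweep(x, 3, mu)
    v <- apply(xc^2, 3, mean)
    s <- sqrt(v + eps)
    ly$y <- sweep(xc, 3, s, "/")
    ly$s <- s; ly$n <- n
    ly$y
  }
  ly$bwd <- function(g) {
    gm <- apply(g, 3, mean)
    gym <- apply(g * ly$y, 3, mean)
    t1 <- sweep(g, 3, gm)
    t2 <- sweep(ly$y, 3, gym, "*")
    sweep(t1 - t2, 3, ly$s, "/")
  }
  ly
}

nn_act <- function(kind = c("lrelu", "relu", "tanh", "linear"),
                   slope = 0.2) {
  kind <- match.arg(kind)
  ly <- new.env(parent = emptyenv())
  ly$type <- kind; ly$params <- list(); ly$grads <- list()
  ly$fwd <- function(x) {
    ly$x <- x
    switch(kind,
           lrelu = ifelse(x > 0, x, slope * x),
           relu = pmax(x, 0),
           tanh = { ly$y <- tanh(x); ly$y },
           linear = x)
  }
  ly$bwd <- function(g) {
    switch(kind,
           lrelu = g * ifelse(ly$x > 0, 1, slope),
           relu = g * (ly$x > 0),
           tanh = g * (1 - ly$y^2),
           linear = g)
  }
  ly
}

nn_upsample2 <- function() {
  ly <- new.env(parent = emptyenv())
  ly$type <- "up2"; ly$params <- list(); ly$grads <- list()
  ly$fwd <- function(x) {
    d <- dim(x)
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
      drop = FALSE]
  }
  ly$bwd <- function(g) {
    d <- dim(g)
    h <- d[1] %/% 2L; w <- d[2] %/% 2L
    g[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
      g[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
      g[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
      g[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  }
  ly
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:2] == db[1:2]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

split_ch <- function(g, n_first) {
  list(g[, , seq_len(n_first), drop = FALSE],
       g[, , -seq_len(n_first), drop = FALSE])
}

net_layers_flat <- function(net) {
  Filter(function(ly) length(ly$params) > 0, net$layers)
}

zero_grads <- function(net) {
  for (ly in net_layers_flat(net)) {
    for (nm in names(ly$grads)) ly$grads[[nm]] <- ly$grads[[nm]] * 0
  }
  invisible(net)
}

#' Initialise an Adam optimizer state for a network
#'
#' @param net A generator or discriminator built by [build_generator()] /
#'   [build_discriminator()].
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser (defaults
#'   0.5 / 0.999 / 1e-8, the usual GAN settings).
#' @return Optimizer state environment.
#' @keywords internal
adam_init <- function(net, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$t <- 0L
  st$m <- list(); st$v <- list()
  lys <- net_layers_flat(net)
  for (i in seq_along(lys)) {
    st$m[[i]] <- lapply(lys[[i]]$params, function(p) p * 0)
    st$v[[i]] <- lapply(lys[[i]]$params, function(p) p * 0)
  }
  st
}

adam_step <- function(net, st, lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t; bc2 <- 1 - st$beta2^st$t
  lys <- net_layers_flat(net)
  for (i in seq_along(lys)) {
    ly <- lys[[i]]
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      st$m[[i]][[nm]] <- st$beta1 * st$m[[i]][[nm]] + (1 - st$beta1) * g
      st$v[[i]][[nm]] <- st$beta2 * st$v[[i]][[nm]] + (1 - st$beta2) * g^2
      ly$params[[nm]] <- ly$params[[nm]] -
        lr * (st$m[[i]][[nm]] / bc1) / (sqrt(st$v[[i]][[nm]] / bc2) + st$eps)
    }
  }
  invisible(net)
}
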