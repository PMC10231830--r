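# Synthetic paired phantoms: two-dye Beer-Lambert H&E transmittance cubes and
# matching EVG RGB renderings. Elastic and collagen fibers are drawn with
# identical eosin-dominant staining (so they are near-indistinguishable in
# H&E color); elastic fibers additionally carry a small smooth spectral
# perturbation that only a many-band observer can exploit, standing in for
# the real elastic-fiber signature. The paired EVG rendering shows them in
# deep blue vs. orchid.

#' Phantom generator configuration
#'
#' @param size `(H, W)` tile size; should be divisible by `2^depth` of the
#'   network the tiles will feed.
#' @param n_elastic_fibers,n_collagen_fibers,n_nuclei Structure counts.
#' @param fiber_width_px Stroke width in pixels.
#' @param eosin_range,hematoxylin_fiber_range Uniform concentration ranges
#'   for eosin on fibers (both classes, identical distribution) and the faint
#'   hematoxylin background staining of fibers.
#' @param hematoxylin_nucleus_range Hematoxylin concentration range on nuclei.
#' @param elastic_bump_amp Amplitude of the elastic-specific multiplicative
#'   transmittance bump centered near 560 nm (fraction, `<= 0.05` is
#'   realistic for a subtle signature).
#' @param noise_sd Relative (multiplicative) Gaussian transmittance noise.
#' @param seed Integer seed; the same seed reproduces the sample bit-exactly.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(size = c(64L, 64L),
                           n_elastic_fibers = 2L, n_collagen_fibers = 3L,
                           n_nuclei = 4L, fiber_width_px = 3,
                           eosin_range = c(0.45, 0.9),
                           hematoxylin_fiber_range = c(0.03, 0.1),
                           hematoxylin_nucleus_range = c(0.6, 1.0),
                           elastic_bump_amp = 0.04,
                           noise_sd = 0.01, seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 8), noise_sd >= 0,
            elastic_bump_amp >= 0)
  structure(list(size = as.integer(size),
                 n_elastic_fibers = n_elastic_fibers,
                 n_collagen_fibers = n_collagen_fibers,
                 n_nuclei = n_nuclei, fiber_width_px = fiber_width_px,
                 eosin_range = eosin_range,
                 hematoxylin_fiber_range = hematoxylin_fiber_range,
                 hematoxylin_nucleus_range = hematoxylin_nucleus_range,
                 elastic_bump_amp = elastic_bump_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# Rasterize one random curvilinear stroke onto an H x W canvas.
draw_fiber_stroke <- function(h, w, width_px) {
  len <- round(0.9 * max(h, w))
  x <- runif(1, 0.1 * w, 0.9 * w)
  y <- runif(1, 0.1 * h, 0.9 * h)
  theta <- runif(1, 0, 2 * pi)
  mask <- matrix(FALSE, h, w)
  r <- max(width_px / 2, 0.5)
  ri <- ceiling(r)
  offs <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2 + 0.25, ]
  for (s in seq_len(len)) {
    theta <- theta + rnorm(1, 0, 0.15)
    x <- x + cos(theta); y <- y + sin(theta)
    if (x < 1 || x > w || y < 1 || y > h) break
    py <- round(y) + offs$dy; px <- round(x) + offs$dx
    ok <- py >= 1 & py <= h & px >= 1 & px <= w
    mask[cbind(py[ok], px[ok])] <- TRUE
  }
  mask
}

draw_nucleus <- function(h, w) {
  cy <- runif(1, 3, h - 2); cx <- runif(1, 3, w - 2)
  a <- runif(1, 1.5, 3.5); b <- runif(1, 1.5, 3.5)
  phi <- runif(1, 0, pi)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  u <- (xx - cx) * cos(phi) + (yy - cy) * sin(phi)
  v <- -(xx - cx) * sin(phi) + (yy - cy) * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one paired phantom sample
#'
#' Draws random curvilinear elastic and collagen fiber strokes (disjoint) and
#' elliptical nuclei. The H&E cube is built by Beer-Lambert mixing
#' `T(lambda) = 10^-(c_h A_h(lambda) + c_e A_e(lambda))` with eosin-dominant
#' concentrations drawn from the *same* distribution for both fiber classes,
#' hematoxylin-dominant nuclei, and `T ~ 1` background; elastic pixels get a
#' small smooth multiplicative transmittance bump near 560 nm; multiplicative
#' Gaussian noise is applied last. The EVG RGB image renders the same
#' geometry with deep-blue elastic (~RGB 40,40,120), orchid collagen
#' (~RGB 218,112,214), near-black nuclei and a pale background.
#'
#' @param config A [phantom_config()].
#' @param dyes Dye spectra list as from [default_dye_spectra()].
#' @param grid Wavelength grid; default the 61-band 420--720 nm grid.
#' @return An object of class `phantom_sample`: list with `he_cube`
#'   ([hsi_cube()]), `evg_rgb` ([rgb_image()]), logical `elastic_mask`,
#'   `collagen_mask`, `nuclei_mask`, and the `config`.
#' @export
generate_phantom <- function(config = phantom_config(),
                             grid = default_grid(),
                             dyes = default_dye_spectra(grid)) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  h <- config$size[1]; w <- config$size[2]
  elastic <- matrix(FALSE, h, w); collagen <- matrix(FALSE, h, w)
  for (i in seq_len(config$n_elastic_fibers)) {
    elastic <- elastic | draw_fiber_stroke(h, w, config$fiber_width_px)
  }
  for (i in seq_len(config$n_collagen_fibers)) {
    placed <- FALSE
    for (try in 1:25) {
      cand <- draw_fiber_stroke(h, w, config$fiber_width_px)
      if (!any(cand & elastic)) { collagen <- collagen | cand; placed <- TRUE; break }
    }
    if (!placed) stop("could not place a collagen fiber disjoint from elastic fibers")
  }
  nuclei <- matrix(FALSE, h, w)
  for (i in seq_len(config$n_nuclei)) nuclei <- nuclei | draw_nucleus(h, w)
  nuclei <- nuclei & !elastic & !collagen

  c_e <- matrix(0, h, w); c_h <- matrix(0, h, w)
  fibers <- elastic | collagen
  c_e[fibers] <- runif(sum(fibers), config$eosin_range[1],
                       config$eosin_range[2])
  c_h[fibers] <- runif(sum(fibers), config$hematoxylin_fiber_range[1],
                       config$hematoxylin_fiber_range[2])
  c_h[nuclei] <- runif(sum(nuclei), config$hematoxylin_nucleus_range[1],
                       config$hematoxylin_nucleus_range[2])

  wl <- grid$values; b <- length(wl)
  a_h <- dyes$hematoxylin$absorbance; a_e <- dyes$eosin$absorbance
  absorb <- outer(as.vector(c_h), a_h) + outer(as.vector(c_e), a_e)
  tr <- 10^(-absorb)                                  # pixels x bands
  bump <- config$elastic_bump_amp * exp(-0.5 * ((wl - 560) / 20)^2)
  el_idx <- which(as.vector(elastic))
  if (length(el_idx)) {
    tr[el_idx, ] <- tr[el_idx, ] * rep(1 + bump, each = length(el_idx))
  }
  if (config$noise_sd > 0) {
    tr <- tr * (1 + rnorm(length(tr), 0, config$noise_sd))
  }
  tr[tr < 0] <- 0
  cube <- hsi_cube(array(tr, dim = c(h, w, b)), grid)

  evg <- array(0, dim = c(h, w, 3))
  base_cols <- list(background = c(243, 238, 232),
                    collagen = c(218, 112, 214),
                    elastic = c(40, 40, 120),
                    nuclei = c(30, 26, 34))
  for (k in 1:3) {
    ch <- matrix(base_cols$background[k], h, w)
    ch[collagen] <- base_cols$collagen[k]
    ch[elastic] <- base_cols$elastic[k]
    ch[nuclei] <- base_cols$nuclei[k]
    evg[, , k] <- ch
  }
  evg <- evg + array(rnorm(length(evg), 0, 3), dim = dim(evg))
  evg[evg < 0] <- 0; evg[evg > 255] <- 255

  structure(list(he_cube = cube, evg_rgb = rgb_image(evg),
                 elastic_mask = elastic, collagen_mask = collagen,
                 nuclei_mask = nuclei, config = config),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, %d elastic / %d collagen px, seed %d\n",
              x$config$size[1], x$config$size[2], sum(x$elastic_mask),
              sum(x$collagen_mask), x$config$seed))
  invisible(x)
}

derive_seed <- function(base, stream, i) {
  # double arithmetic (exact below 2^53), reduced to a valid 32-bit seed
  as.integer((as.numeric(base) * 100003 + as.numeric(stream) * 7919 +
                as.numeric(i)) %% 2147483629)
}

#' Generate a phantom dataset on disk
#'
#' Writes an unpaired pool (H&E cubes and EVG tiles drawn from disjoint seed
#' sets, so they are truly unpaired) and a paired pool. With
#' `misalign = TRUE` each paired EVG tile is perturbed by a random known
#' affine transform (saved as ground truth) for registration testing.
#'
#' Directory layout:
#' `unpaired/he/he_###.tiff(+.json)`, `unpaired/evg/evg_###.png`,
#' `paired/he/`, `paired/evg/`, `paired/masks/`, `paired/transforms/`,
#' `manifest.csv`.
#'
#' @param config A [phantom_config()]; its `seed` is the dataset base seed.
#' @param dir Output directory (created).
#' @param n_unpaired,n_paired Pool sizes (each `>= 1`).
#' @param misalign Perturb paired EVG tiles by a random saved affine.
#' @return Invisibly, the manifest data frame.
#' @export
generate_dataset <- function(config, dir, n_unpaired = 8L, n_paired = 4L,
                             misalign = FALSE) {
  stopifnot(n_unpaired >= 1, n_paired >= 1)
  for (d in c("unpaired/he", "unpaired/evg", "paired/he", "paired/evg",
              "paired/masks", "paired/transforms")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- list()
  cfg_with_seed <- function(s) { cfg <- config; cfg$seed <- s; cfg }
  for (i in seq_len(n_unpaired)) {
    s <- derive_seed(config$seed, 1L, i)
    ph <- generate_phantom(cfg_with_seed(s))
    f <- sprintf("unpaired/he/he_%03d.tiff", i)
    write_cube(ph$he_cube, file.path(dir, f))
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = f, role = "unpaired_he", seed = s)
    s2 <- derive_seed(config$seed, 2L, i)
    ph2 <- generate_phantom(cfg_with_seed(s2))
    f2 <- sprintf("unpaired/evg/evg_%03d.png", i)
    write_rgb(ph2$evg_rgb, file.path(dir, f2))
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = f2, role = "unpaired_evg", seed = s2)
  }
  for (i in seq_len(n_paired)) {
    s <- derive_seed(config$seed, 3L, i)
    ph <- generate_phantom(cfg_with_seed(s))
    fhe <- sprintf("paired/he/he_%03d.tiff", i)
    fevg <- sprintf("paired/evg/evg_%03d.png", i)
    write_cube(ph$he_cube, file.path(dir, fhe))
    evg <- ph$evg_rgb
    if (misalign) {
      set.seed(derive_seed(config$seed, 4L, i))
      ang <- runif(1, -5, 5) * pi / 180
      sc <- runif(1, 0.97, 1.03)
      tx <- runif(1, -3, 3); ty <- runif(1, -3, 3)
      m <- matrix(c(sc * cos(ang), -sc * sin(ang), tx,
                    sc * sin(ang),  sc * cos(ang), ty), 2, 3, byrow = TRUE)
      tr <- affine_transform(m)
      evg <- warp_affine(evg, tr, dim(evg$data)[1:2])
      jsonlite::write_json(list(matrix = m),
                           file.path(dir, sprintf("paired/transforms/t_%03d.json", i)),
                           auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    }
    write_rgb(evg, file.path(dir, fevg))
    masks <- array(0, dim = c(dim(ph$elastic_mask), 3L))
    masks[, , 1] <- ph$elastic_mask * 255
    masks[, , 2] <- ph$collagen_mask * 255
    masks[, , 3] <- ph$nuclei_mask * 255
    write_rgb(rgb_image(masks),
              file.path(dir, sprintf("paired/masks/mask_%03d.png", i)))
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = fhe, role = "paired_he", seed = s)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = fevg, role = "paired_evg", seed = s)
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Sample labelled elastic/collagen pixel spectra
#'
#' Draws per-class pixel transmittance spectra from phantom fiber regions,
#' for deriving the fallback LDF by linear discriminant analysis
#' ([derive_ldf()]).
#'
#' @param config A [phantom_config()].
#' @param n_per_class Spectra per class (`>= 2`).
#' @return List with `elastic` and `collagen` (`n x B` matrices).
#' @export
labeled_spectra <- function(config = phantom_config(), n_per_class = 100L) {
  stopifnot(n_per_class >= 2)
  el <- NULL; co <- NULL
  seed <- config$seed
  for (round in 1:20) {
    cfg <- config; cfg$seed <- derive_seed(seed, 5L, round)
    ph <- generate_phantom(cfg)
    d <- dim(ph$he_cube$data)
    px <- matrix(ph$he_cube$data, nrow = d[1] * d[2], ncol = d[3])
    el <- rbind(el, px[as.vector(ph$elastic_mask), , drop = FALSE])
    co <- rbind(co, px[as.vector(ph$collagen_mask), , drop = FALSE])
    if (nrow(el) >= n_per_class && nrow(co) >= n_per_class) break
  }
  if (nrow(el) < n_per_class || nrow(co) < n_per_class) {
    stop("could not sample enough fiber pixels; increase fiber counts/size")
  }
  list(elastic = el[seq_len(n_per_class), , drop = FALSE],
       collagen = co[seq_len(n_per_class), , drop = FALSE])
}

#' Default LDF for the phantom world
#'
#' Convenience wrapper: samples labelled spectra with [labeled_spectra()] and
#' fits the discriminant with [derive_ldf()].
#'
#' @param config A [phantom_config()].
#' @param n_per_class Spectra per class.
#' @return Length-B LDF vector.
#' @export
phantom_ldf <- function(config = phantom_config(), n_per_class = 200L) {
  sp <- labeled_spectra(config, n_per_class)
  derive_ldf(sp$elastic, sp$collagen)
}
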