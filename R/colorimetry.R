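# Colorimetry: CIE 1931 2-degree observer sampled on an arbitrary wavelength
# grid, and hyperspectral-transmittance -> sRGB rendering.

# Multi-lobe Gaussian analytic fit to the CIE 1931 2-deg color-matching
# functions (piecewise-sigma Gaussians); accurate to ~1% of peak, adequate for
# rendering stained-tissue transmittance.
cie_lobe <- function(wl, mu, s1, s2) {
  s <- ifelse(wl < mu, s1, s2)
  exp(-0.5 * ((wl - mu) / s)^2)
}

#' CIE 1931 2-degree color-matching functions on a grid
#'
#' @param grid A [wavelength_grid()].
#' @return `3 x B` matrix with rows `xbar`, `ybar`, `zbar`.
#' @export
cie1931_cmf <- function(grid) {
  wl <- grid$values
  xbar <- 1.056 * cie_lobe(wl, 599.8, 37.9, 31.0) +
          0.362 * cie_lobe(wl, 442.0, 16.0, 26.7) -
          0.065 * cie_lobe(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * cie_lobe(wl, 568.8, 46.9, 40.5) +
          0.286 * cie_lobe(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * cie_lobe(wl, 437.0, 11.8, 36.0) +
          0.681 * cie_lobe(wl, 459.0, 26.0, 13.8)
  m <- rbind(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0))
  colnames(m) <- wl
  m
}

#' Build a colorimetric system
#'
#' @param grid A [wavelength_grid()].
#' @param illuminant Length-B relative spectral power of the light source;
#'   default equal-energy (all ones). The microscope LED spectrum, if known,
#'   can be supplied here.
#' @param cmf Optional `3 x B` color-matching-function matrix; default CIE
#'   1931 2-degree observer.
#' @return An object of class `colorimetric_system`.
#' @export
colorimetric_system <- function(grid, illuminant = NULL, cmf = NULL) {
  stopifnot(inherits(grid, "wavelength_grid"))
  b <- length(grid$values)
  if (is.null(illuminant)) illuminant <- rep(1, b)
  if (is.null(cmf)) cmf <- cie1931_cmf(grid)
  if (length(illuminant) != b) stop("illuminant length must match grid")
  if (!all(dim(cmf) == c(3L, b))) stop("cmf must be 3 x B")
  if (any(illuminant < 0)) stop("illuminant must be nonnegative")
  if (any(cmf[2, ] < 0)) stop("ybar row must be nonnegative")
  structure(list(cmf = cmf, illuminant = illuminant, grid = grid),
            class = "colorimetric_system")
}

# XYZ (D65-referred) -> linear sRGB
XYZ_TO_SRGB <- matrix(c( 3.2406, -1.5372, -0.4986,
                        -0.9689,  1.8758,  0.0415,
                         0.0557, -0.2040,  1.0570),
                      nrow = 3, byrow = TRUE)

srgb_gamma <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Render a transmittance cube to an 8-bit sRGB image
#'
#' Integrates `illuminant * T * cmf` over wavelength to tristimulus XYZ,
#' converts to linear sRGB, and white-balances so that a perfect transmitter
#' (`T == 1` everywhere) renders as pure white (255, 255, 255). Linear values
#' are clipped to `[0, 1]` before gamma encoding.
#'
#' @param cube An [hsi_cube()].
#' @param cs A [colorimetric_system()] on the same grid; default built from
#'   the cube's grid.
#' @return An [rgb_image()].
#' @export
cube_to_srgb <- function(cube, cs = NULL) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (is.null(cs)) cs <- colorimetric_system(cube$grid)
  if (!grids_identical(cube$grid, cs$grid)) {
    stop("cube and colorimetric system are on different wavelength grids")
  }
  d <- dim(cube$data)
  px <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])  # pixels x bands
  w <- cs$illuminant * cs$grid$step_nm
  xyz <- px %*% t(cs$cmf * rep(w, each = 3))                # pixels x 3
  xyz_white <- as.numeric(cs$cmf %*% w)
  lin <- xyz %*% t(XYZ_TO_SRGB)
  lin_white <- as.numeric(XYZ_TO_SRGB %*% xyz_white)
  lin <- sweep(lin, 2, lin_white, "/")
  lin[lin < 0] <- 0; lin[lin > 1] <- 1
  out <- srgb_gamma(lin) * 255
  rgb_image(array(out, dim = c(d[1], d[2], 3L)))
}

#' Convert an 8-bit RGB image to OpenCV-convention HSV
#'
#' Hue on the integer 0--179 scale (degrees / 2), saturation and value on
#' 0--255, matching the convention the fibrous-mask thresholds are stated in.
#'
#' @param img An [rgb_image()] or `H x W x 3` array in `[0, 255]`.
#' @return `H x W x 3` array of H (0--180), S (0--255), V (0--255).
#' @export
rgb_to_hsv_cv <- function(img) {
  if (inherits(img, "rgb_image")) img <- img$data
  img <- as_array3d(img)
  d <- dim(img)
  m <- t(matrix(img, nrow = d[1] * d[2], ncol = 3L))  # 3 x pixels, 0..255
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)   # h,s,v in [0,1]
  out <- array(0, dim = c(d[1], d[2], 3L))
  out[, , 1] <- hsv[1, ] * 180
  out[, , 2] <- hsv[2, ] * 255
  out[, , 3] <- hsv[3, ] * 255
  out
}
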