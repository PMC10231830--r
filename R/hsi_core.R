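#' Construct a wavelength grid
#'
#' A wavelength grid is an evenly spaced, strictly increasing set of sampling
#' wavelengths in nanometres. The acquisition system this package targets
#' samples 151 bands from 350 to 1100 nm at 5 nm; the analysis range is the
#' 61-band 420--720 nm window.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must be `>= start_nm`.
#' @param step_nm Spacing (nm); must divide `stop_nm - start_nm` exactly.
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and `values` (inclusive of both endpoints).
#' @examples
#' length(wavelength_grid(350, 1100, 5)$values)  # 151
#' length(wavelength_grid(420, 720, 5)$values)   # 61
#' @export
wavelength_grid <- function(start_nm, stop_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be positive")
  if (stop_nm < start_nm) stop("stop_nm must be >= start_nm")
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop(sprintf("wavelength range %g..%g nm is not divisible by step %g nm",
                 start_nm, stop_nm, step_nm))
  }
  n <- as.integer(round(n_steps)) + 1L
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         values = start_nm + step_nm * (seq_len(n) - 1)),
    class = "wavelength_grid"
  )
}

#' @export
length.wavelength_grid <- function(x) length(x$values)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g..%g nm, step %g nm, %d bands\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$values)))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$values, b$values)) && a$step_nm == b$step_nm
}

#' The 61-band analysis grid (420--720 nm at 5 nm)
#' @return A `wavelength_grid` with 61 bands.
#' @export
default_grid <- function() wavelength_grid(420, 720, 5)

#' Construct a hyperspectral cube
#'
#' Wraps an `H x W x B` transmittance array together with its wavelength grid.
#' Transmittance is dimensionless; after calibration values are nominally in
#' `[0, ~1.2]` (slightly above 1 is possible where the specimen is brighter
#' than the white reference).
#'
#' @param data Numeric `H x W x B` array.
#' @param grid A [wavelength_grid()] whose band count equals `dim(data)[3]`.
#' @return An object of class `hsi_cube` with fields `data` and `grid`.
#' @export
hsi_cube <- function(data, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  data <- as_array3d(data)
  if (dim(data)[3] != length(grid$values)) {
    stop(sprintf("cube has %d bands but grid declares %d",
                 dim(data)[3], length(grid$values)))
  }
  if (any(!is.finite(data))) stop("cube contains non-finite values")
  structure(list(data = data, grid = grid), class = "hsi_cube")
}

as_array3d <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("expected an H x W x B array")
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%g..%g nm)\n",
              d[1], d[2], d[3], x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}

#' Construct an 8-bit sRGB image
#'
#' @param data `H x W x 3` numeric array with values in `[0, 255]`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(data) {
  data <- as_array3d(data)
  if (dim(data)[3] != 3L) stop("rgb_image requires exactly 3 channels")
  if (any(data < 0 | data > 255)) stop("rgb_image values must be in [0, 255]")
  data <- round(data)
  structure(list(data = data), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<rgb_image> %d x %d, 8-bit sRGB\n", d[1], d[2]))
  invisible(x)
}

#' Bundle raw/dark/white calibration frames
#'
#' @param raw,dark,white `H x W x B` arrays of camera counts: the specimen
#'   exposure, the dark frame (illumination off) and the white reference
#'   (blank slide, illumination on).
#' @param exposure_raw,exposure_dark,exposure_white Positive exposure values
#'   of the three frames.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(raw, dark, white,
                            exposure_raw, exposure_dark, exposure_white) {
  raw <- as_array3d(raw); dark <- as_array3d(dark); white <- as_array3d(white)
  if (!identical(dim(raw), dim(dark)) || !identical(dim(raw), dim(white))) {
    stop("raw, dark and white frames must share the same dimensions")
  }
  for (e in c(exposure_raw, exposure_dark, exposure_white)) {
    if (!is.numeric(e) || length(e) != 1L || e <= 0) {
      stop("exposure values must be positive scalars")
    }
  }
  structure(list(raw = raw, dark = dark, white = white,
                 exposure_raw = exposure_raw, exposure_dark = exposure_dark,
                 exposure_white = exposure_white),
            class = "calibration_set")
}

#' Calibrate a raw hyperspectral acquisition to transmittance
#'
#' Per pixel and band,
#' `T = (raw/E_raw - dark/E_d) / (white/E_w - dark/E_d)`,
#' which removes dark current and the spectral shape of the illumination.
#' Negative transmittance (raw below dark, i.e. sensor noise) is clipped to 0;
#' values above 1 are retained, so noise structure around the white reference
#' is not destroyed.
#'
#' @param cal A [calibration_set()].
#' @param grid Wavelength grid of the acquisition; defaults to the band count
#'   of the frames laid on [default_grid()] when it matches, otherwise must be
#'   supplied.
#' @return An [hsi_cube()] of transmittance.
#' @export
calibrate_cube <- function(cal, grid = NULL) {
  stopifnot(inherits(cal, "calibration_set"))
  num <- cal$raw / cal$exposure_raw - cal$dark / cal$exposure_dark
  den <- cal$white / cal$exposure_white - cal$dark / cal$exposure_dark
  bad <- which(den == 0)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(den))
    stop(sprintf(paste0("white/E_w - dark/E_d is zero at pixel (%d, %d), ",
                        "band %d (and %d location(s) in total)"),
                 idx[1], idx[2], idx[3], length(bad)))
  }
  tr <- num / den
  tr[tr < 0] <- 0
  if (is.null(grid)) {
    b <- dim(cal$raw)[3]
    grid <- if (b == 61L) default_grid() else
      wavelength_grid(420, 420 + 5 * (b - 1), 5)
  }
  hsi_cube(tr, grid)
}

#' Restrict a cube to a wavelength window
#'
#' @param cube An [hsi_cube()].
#' @param lo_nm,hi_nm Window endpoints; both must lie exactly on the grid.
#' @return The sub-cube with its restricted grid.
#' @examples
#' \dontrun{crop_band_range(cube151, 420, 720)  # -> 61 bands}
#' @export
crop_band_range <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "hsi_cube"))
  wl <- cube$grid$values
  i_lo <- match_wavelength(wl, lo_nm)
  i_hi <- match_wavelength(wl, hi_nm)
  if (i_hi < i_lo) stop("hi_nm must be >= lo_nm")
  hsi_cube(cube$data[, , i_lo:i_hi, drop = FALSE],
           wavelength_grid(wl[i_lo], wl[i_hi], cube$grid$step_nm))
}

match_wavelength <- function(wl, x) {
  i <- which(abs(wl - x) < 1e-9)
  if (length(i) != 1L) {
    stop(sprintf("wavelength %g nm is not on the grid (%g..%g step %g)",
                 x, wl[1], wl[length(wl)], wl[2] - wl[1]))
  }
  i
}

#' Zero-pad an image along the channel axis
#'
#' Used to feed a 3-channel EVG image into the 61-channel generator for the
#' identity loss: the 3 original channels come first, followed by
#' `target_channels - 3` all-zero channels (58 for the standard grids).
#'
#' @param img `H x W x C` numeric array (an [rgb_image()] is accepted and
#'   converted to float).
#' @param target_channels Total channel count after padding; `>= C`.
#' @return `H x W x target_channels` array.
#' @export
pad_with_zero_channels <- function(img, target_channels) {
  if (inherits(img, "rgb_image")) img <- img$data
  img <- as_array3d(img)
  d <- dim(img)
  if (target_channels < d[3]) {
    stop(sprintf("target_channels (%d) is smaller than current channels (%d)",
                 target_channels, d[3]))
  }
  if (target_channels == d[3]) return(img)
  out <- array(0, dim = c(d[1], d[2], target_channels))
  out[, , seq_len(d[3])] <- img
  out
}

# ---- I/O -------------------------------------------------------------------

#' Write / read hyperspectral cubes
#'
#' Cubes are stored as multi-page 32-bit float TIFF (one page per band) with a
#' JSON sidecar (`<path>.json`) recording the wavelength grid and a
#' power-of-two scale factor. Values are divided by the scale before writing
#' so they fit the TIFF [0, 1] range; because the scale is a power of two the
#' division is exact in binary floating point, and the round-trip is exact to
#' 32-bit float precision.
#'
#' @param cube An [hsi_cube()].
#' @param path Output TIFF path.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns an
#'   [hsi_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  mx <- max(cube$data, 1e-12)
  scale <- 2^ceiling(log2(max(mx, 1)))
  pages <- lapply(seq_len(dim(cube$data)[3]),
                  function(b) cube$data[, , b] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(start_nm = cube$grid$start_nm, stop_nm = cube$grid$stop_nm,
                  step_nm = cube$grid$step_nm,
                  n_bands = length(cube$grid$values), scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("missing wavelength sidecar '%s'", sidecar_path))
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("start_nm", "stop_nm", "step_nm", "n_bands", "scale")) {
    if (is.null(meta[[f]])) stop(sprintf("sidecar missing field '%s'", f))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  grid <- wavelength_grid(meta$start_nm, meta$stop_nm, meta$step_nm)
  if (length(pages) != meta$n_bands ||
      length(grid$values) != meta$n_bands) {
    stop(sprintf("file has %d pages but sidecar declares %d bands",
                 length(pages), meta$n_bands))
  }
  d <- dim(pages[[1]])
  data <- array(0, dim = c(d[1], d[2], length(pages)))
  for (b in seq_along(pages)) data[, , b] <- pages[[b]] * meta$scale
  hsi_cube(data, grid)
}

#' Write / read 8-bit RGB images (PNG)
#'
#' @param img An [rgb_image()].
#' @param path PNG path.
#' @return `write_rgb` returns `path` invisibly; `read_rgb` an [rgb_image()].
#' @export
write_rgb <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(img$data / 255, path)
  invisible(path)
}

#' @rdname write_rgb
#' @export
read_rgb <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  rgb_image(x * 255)
}
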