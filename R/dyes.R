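# Dye spectra: absorbance containers, Beer-Lambert conversion, the shipped
# synthetic hematoxylin/eosin stand-in spectra, and the fallback linear
# discriminant function (LDF) derived from labelled phantom spectra.

#' Construct a dye absorbance spectrum
#'
#' @param absorbance Length-B nonnegative absorbance values `A(lambda)`.
#' @param grid A [wavelength_grid()].
#' @param name Label, e.g. `"eosin"`.
#' @return An object of class `dye_spectrum`.
#' @export
dye_spectrum <- function(absorbance, grid, name = "dye") {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(absorbance) != length(grid$values)) {
    stop("absorbance length must match grid")
  }
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  if (any(absorbance < 0)) stop("absorbance must be nonnegative")
  structure(list(absorbance = as.numeric(absorbance), grid = grid,
                 name = name),
            class = "dye_spectrum")
}

#' Beer-Lambert conversion from absorbance to transmittance
#'
#' `T(lambda) = 10^(-A(lambda))`, the inverse of `A = -log10(T)`.
#'
#' @param spec A [dye_spectrum()].
#' @return Length-B transmittance vector, values in `(0, 1]`.
#' @examples
#' g <- wavelength_grid(420, 430, 5)
#' transmittance_from_absorbance(dye_spectrum(c(0, 1, 2), g))  # 1, 0.1, 0.01
#' @export
transmittance_from_absorbance <- function(spec) {
  stopifnot(inherits(spec, "dye_spectrum"))
  10^(-spec$absorbance)
}

#' Synthetic hematoxylin and eosin absorbance spectra
#'
#' Smooth Gaussian-shaped stand-ins for the published H&E absorbance curves
#' (which are not distributed in tabulated form): eosin absorbs around
#' 520--540 nm so eosin-rich tissue renders pink, hematoxylin absorbs broadly
#' around 560--650 nm so nuclei render blue-violet. These are synthetic
#' conventions, editable via the CSV at
#' `system.file("extdata", "dye_absorbance_synthetic.csv", package =
#' "hyperstain")` or by passing your own [dye_spectrum()] objects.
#'
#' @param grid A [wavelength_grid()]; default [default_grid()].
#' @param peak Peak absorbance of each dye (default 1).
#' @return Named list with `hematoxylin` and `eosin` [dye_spectrum()]s.
#' @export
default_dye_spectra <- function(grid = default_grid(), peak = 1.0) {
  wl <- grid$values
  a_e <- peak * exp(-0.5 * ((wl - 527) / 28)^2)
  a_h <- peak * (0.92 * exp(-0.5 * ((wl - 605) / 52)^2) +
                 0.15 * exp(-0.5 * ((wl - 450) / 40)^2))
  list(hematoxylin = dye_spectrum(a_h, grid, "hematoxylin"),
       eosin = dye_spectrum(a_e, grid, "eosin"))
}

#' Read / write dye spectra as CSV
#'
#' CSV layout: a `wavelength_nm` column followed by one named column per
#' spectrum.
#'
#' @param spectra Named list of [dye_spectrum()]s on a common grid.
#' @param path CSV path.
#' @return `write_dye_spectra` returns `path` invisibly; `read_dye_spectra`
#'   a named list of [dye_spectrum()]s.
#' @export
write_dye_spectra <- function(spectra, path) {
  grid <- spectra[[1]]$grid
  df <- data.frame(wavelength_nm = grid$values)
  for (nm in names(spectra)) {
    stopifnot(grids_identical(spectra[[nm]]$grid, grid))
    df[[nm]] <- spectra[[nm]]$absorbance
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dye_spectra
#' @export
read_dye_spectra <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl <- df$wavelength_nm
  grid <- wavelength_grid(wl[1], wl[length(wl)], wl[2] - wl[1])
  cols <- setdiff(names(df), "wavelength_nm")
  setNames(lapply(cols, function(nm) dye_spectrum(df[[nm]], grid, nm)), cols)
}

#' Derive a linear discriminant function from labelled fiber spectra
#'
#' The elastic/collagen LDF used as a basis row is, in the original workflow,
#' supplied externally. When no measured LDF is available this fallback fits
#' a two-class linear discriminant analysis to labelled elastic and collagen
#' pixel spectra (e.g. from [labeled_spectra()]) and returns the discriminant
#' weight vector, max-normalised to unit infinity norm.
#'
#' @param elastic,collagen Matrices (`n x B`) of pixel transmittance spectra.
#' @return Length-B numeric LDF weight vector.
#' @export
derive_ldf <- function(elastic, collagen) {
  stopifnot(is.matrix(elastic), is.matrix(collagen),
            ncol(elastic) == ncol(collagen))
  if (nrow(elastic) < 2 || nrow(collagen) < 2) {
    stop("need at least 2 spectra per class")
  }
  x <- rbind(elastic, collagen)
  y <- factor(rep(c("elastic", "collagen"),
                  c(nrow(elastic), nrow(collagen))))
  fit <- MASS::lda(x, grouping = y, tol = 1e-10)
  w <- as.numeric(fit$scaling[, 1])
  w / max(abs(w))
}
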