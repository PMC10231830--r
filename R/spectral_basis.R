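# Spectral basis sets: the three candidate 3 x B projection matrices used to
# reduce a 61-band H&E cube to 3 channels for the identity loss, and the
# projection operator itself.

#' Construct a basis set
#'
#' A basis set is a `3 x B` real matrix whose rows are spectral weight
#' vectors; multiplying a cube's pixel spectra by it yields a 3-channel image.
#'
#' @param matrix `3 x B` numeric matrix.
#' @param row_names Character vector of 3 row labels.
#' @param grid A [wavelength_grid()] with B bands.
#' @param normalize If `TRUE`, each row is divided by its maximum absolute
#'   entry (optional conditioning; rows are used unnormalised by default).
#' @return An object of class `basis_set`.
#' @export
basis_set <- function(matrix, row_names, grid, normalize = FALSE) {
  stopifnot(inherits(grid, "wavelength_grid"))
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 3L) stop("basis set must have exactly 3 rows")
  if (ncol(matrix) != length(grid$values)) {
    stop("basis column count must equal grid band count")
  }
  if (length(row_names) != 3L) stop("need 3 row names")
  if (any(apply(matrix, 1, function(r) all(r == 0)))) {
    stop("basis set contains an all-zero row")
  }
  if (normalize) matrix <- matrix / apply(abs(matrix), 1, max)
  rownames(matrix) <- row_names
  structure(list(matrix = matrix, row_names = row_names, grid = grid),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> rows: %s; %d bands (%g..%g nm)\n",
              paste(x$row_names, collapse = ", "),
              length(x$grid$values), x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}

#' Channel-selection basis
#'
#' Each row is a one-hot selector for one band, so projection equals slicing
#' those bands. The default channels 10, 11 and 12 correspond to 465, 470 and
#' 475 nm on the 61-band 420--720 nm grid (1-based band indexing:
#' `wavelength = 420 + (n - 1) * 5`).
#'
#' @param grid A [wavelength_grid()].
#' @param channels Integer vector of 3 one-based band indices.
#' @return A [basis_set()].
#' @export
basis_channel_select <- function(grid, channels = c(10L, 11L, 12L)) {
  stopifnot(inherits(grid, "wavelength_grid"))
  b <- length(grid$values)
  channels <- as.integer(channels)
  if (length(channels) != 3L) stop("exactly 3 channels required")
  if (any(channels < 1L | channels > b)) {
    stop(sprintf("channel out of range: grid has %d bands", b))
  }
  m <- matrix(0, nrow = 3, ncol = b)
  for (k in 1:3) m[k, channels[k]] <- 1
  basis_set(m, sprintf("channel_%d_%gnm", channels, grid$values[channels]),
            grid)
}

#' PCA + LDF basis
#'
#' Rows are the first two principal-component eigenvectors of the pooled,
#' mean-centered pixel spectra of the training cubes (covariance PCA), plus
#' the supplied LDF. Eigenvector signs are fixed so the largest-magnitude
#' coefficient is positive.
#'
#' @param ldf Length-B LDF weight vector.
#' @param training_cubes List of [hsi_cube()]s on a common grid.
#' @return A [basis_set()] with attribute `explained_variance` (the full
#'   eigenvalue-fraction vector).
#' @export
basis_ldf_pca <- function(ldf, training_cubes) {
  stopifnot(length(training_cubes) >= 1)
  grid <- training_cubes[[1]]$grid
  if (length(ldf) != length(grid$values)) stop("ldf length must match grid")
  px <- pool_pixel_spectra(training_cubes)
  if (nrow(px) < 2) stop("need at least 2 pixels for PCA")
  pc <- prcomp(px, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev > max(ev) * 1e-12) < 2) {
    stop("pixel matrix is rank-deficient: fewer than 2 nonzero eigenvalues")
  }
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (k in 1:2) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  bs <- basis_set(rbind(t(rot), as.numeric(ldf)),
                  c("PC1", "PC2", "LDF"), grid)
  attr(bs, "explained_variance") <- ev / sum(ev)
  bs
}

pool_pixel_spectra <- function(cubes) {
  grid <- cubes[[1]]$grid
  do.call(rbind, lapply(cubes, function(cb) {
    stopifnot(inherits(cb, "hsi_cube"))
    if (!grids_identical(cb$grid, grid)) stop("cubes on different grids")
    d <- dim(cb$data)
    matrix(cb$data, nrow = d[1] * d[2], ncol = d[3])
  }))
}

#' LDF + dye-transmittance basis
#'
#' Rows are the LDF, the eosin transmittance spectrum, and the hematoxylin
#' transmittance spectrum (Beer-Lambert inversion of their absorbances).
#'
#' @param ldf Length-B LDF weight vector.
#' @param hematoxylin,eosin [dye_spectrum()]s on a common grid.
#' @return A [basis_set()] with rows `LDF`, `eosin_T`, `hematoxylin_T`.
#' @export
basis_ldf_dyes <- function(ldf, hematoxylin, eosin) {
  stopifnot(inherits(hematoxylin, "dye_spectrum"),
            inherits(eosin, "dye_spectrum"))
  if (!grids_identical(hematoxylin$grid, eosin$grid)) {
    stop("dye spectra are on different wavelength grids")
  }
  grid <- hematoxylin$grid
  if (length(ldf) != length(grid$values)) stop("ldf length must match grid")
  basis_set(rbind(as.numeric(ldf),
                  transmittance_from_absorbance(eosin),
                  transmittance_from_absorbance(hematoxylin)),
            c("LDF", "eosin_T", "hematoxylin_T"), grid)
}

#' Project a cube onto a basis set
#'
#' `out[h, w, k] = sum_b basis[k, b] * cube[h, w, b]` - plain matrix
#' multiplication of each pixel spectrum by the basis.
#'
#' @param cube An [hsi_cube()].
#' @param basis A [basis_set()] on the same grid.
#' @return `H x W x 3` float array.
#' @export
project_cube <- function(cube, basis) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(basis, "basis_set"))
  if (!grids_identical(cube$grid, basis$grid)) {
    stop("cube and basis are on different wavelength grids")
  }
  d <- dim(cube$data)
  px <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  out <- px %*% t(basis$matrix)
  array(out, dim = c(d[1], d[2], 3L))
}

#' Serialize / load a basis set as CSV
#'
#' CSV layout: `wavelength_nm` column plus one column per basis row.
#'
#' @param basis A [basis_set()].
#' @param path CSV path.
#' @return `write_basis` returns `path` invisibly; `read_basis` a
#'   [basis_set()].
#' @export
write_basis <- function(basis, path) {
  df <- data.frame(wavelength_nm = basis$grid$values)
  for (k in 1:3) df[[basis$row_names[k]]] <- basis$matrix[k, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl <- df$wavelength_nm
  grid <- wavelength_grid(wl[1], wl[length(wl)], wl[2] - wl[1])
  cols <- setdiff(names(df), "wavelength_nm")
  if (length(cols) != 3L) stop("basis CSV must have 3 value columns")
  basis_set(t(as.matrix(df[cols])), cols, grid)
}
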