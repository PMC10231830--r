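# Image-quality metrics for generated vs. ground-truth EVG images:
# MSE/RMSE/PSNR, per-channel-averaged global SSIM, and fibrous-region RMSE
# restricted to an HSV color mask.

as_image_array <- function(x) {
  if (inherits(x, "rgb_image")) x$data else as_array3d(x)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("image shapes differ: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  }
}

#' Mean squared error and RMSE between two images
#'
#' MSE averages squared pixel differences over all `H * W * C` elements;
#' RMSE is its square root.
#'
#' @param gt,out Images ([rgb_image()] or arrays) of identical shape.
#' @return Named list with `mse` and `rmse`.
#' @export
mse_rmse <- function(gt, out) {
  gt <- as_image_array(gt); out <- as_image_array(out)
  check_same_shape(gt, out)
  mse <- mean((gt - out)^2)
  list(mse = mse, rmse = sqrt(mse))
}

#' Peak signal-to-noise ratio in dB
#'
#' `PSNR = 10 * log10(max^2 / MSE)` with `max = 255`. Identical images have
#' zero MSE; that case is reported as the `Inf` sentinel rather than an error.
#'
#' @inheritParams mse_rmse
#' @param max_value Peak signal value; default 255.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(gt, out, max_value = 255) {
  m <- mse_rmse(gt, out)$mse
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' SSIM parameter bundle
#'
#' Exponents for the luminance/contrast/structure terms (all default 1) and
#' the stabilising constants derived from the dynamic range `L`:
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2`.
#'
#' @param alpha,beta,gamma_exp Positive exponents.
#' @param L Dynamic range (255 for 8-bit images).
#' @return List of SSIM parameters.
#' @export
ssim_params <- function(alpha = 1, beta = 1, gamma_exp = 1, L = 255) {
  stopifnot(alpha > 0, beta > 0, gamma_exp > 0, L > 0)
  list(alpha = alpha, beta = beta, gamma_exp = gamma_exp, L = L,
       C1 = (0.01 * L)^2, C2 = (0.03 * L)^2, C3 = (0.03 * L)^2 / 2)
}

ssim_channel <- function(a, b, p) {
  mu_a <- mean(a); mu_b <- mean(b)
  # population (1/n) moments: the global-statistics SSIM uses plain means
  n <- length(a)
  va <- sum((a - mu_a)^2) / n
  vb <- sum((b - mu_b)^2) / n
  vab <- sum((a - mu_a) * (b - mu_b)) / n
  sa <- sqrt(va); sb <- sqrt(vb)
  l <- (2 * mu_a * mu_b + p$C1) / (mu_a^2 + mu_b^2 + p$C1)
  cc <- (2 * sa * sb + p$C2) / (va + vb + p$C2)
  s <- (vab + p$C3) / (sa * sb + p$C3)
  l^p$alpha * cc^p$beta * s^p$gamma_exp
}

#' Per-channel-averaged structural similarity (SSIM)
#'
#' SSIM is computed per channel from the *global* image statistics (mean,
#' standard deviation and cross-covariance of all pixels of that channel),
#' then averaged over the three channels. With unit exponents this reduces to
#' `(2 mu_a mu_b + C1)(2 cov + C2) / ((mu_a^2 + mu_b^2 + C1)(var_a + var_b +
#' C2))`. A sliding-window variant (`window > 0`) is also provided; note the
#' windowed form is a different estimator from the global one used for
#' reported values.
#'
#' @inheritParams mse_rmse
#' @param params An [ssim_params()] bundle.
#' @param window If `> 0`, side length of a square sliding window; 0 (the
#'   default) uses global statistics.
#' @return SSIM in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim_rgb <- function(gt, out, params = ssim_params(), window = 0L) {
  gt <- as_image_array(gt); out <- as_image_array(out)
  check_same_shape(gt, out)
  if (dim(gt)[3] != 3L) stop("ssim_rgb expects 3-channel images")
  vals <- vapply(1:3, function(k) {
    a <- gt[, , k]; b <- out[, , k]
    if (window <= 0) return(ssim_channel(a, b, params))
    d <- dim(a); w <- as.integer(window)
    if (any(d < w)) stop("window larger than image")
    acc <- 0; nwin <- 0
    for (i in seq_len(d[1] - w + 1)) {
      for (j in seq_len(d[2] - w + 1)) {
        acc <- acc + ssim_channel(a[i:(i + w - 1), j:(j + w - 1)],
                                  b[i:(i + w - 1), j:(j + w - 1)], params)
        nwin <- nwin + 1
      }
    }
    acc / nwin
  }, numeric(1))
  mean(vals)
}

#' HSV color range
#'
#' Bounds in the OpenCV convention: hue 0--179 (degrees / 2), saturation and
#' value 0--255.
#'
#' @param lower,upper Length-3 `(H, S, V)` triples with `lower <= upper`
#'   componentwise.
#' @return An object of class `hsv_range`.
#' @export
hsv_range <- function(lower, upper) {
  stopifnot(length(lower) == 3L, length(upper) == 3L)
  if (any(lower > upper)) stop("lower must be <= upper componentwise")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "hsv_range")
}

#' Default fibrous-region HSV ranges
#'
#' EVG-stained elastic and collagen fibers occupy colors from deep blue to
#' pink; two ranges cover them: blue-to-pink hues (`[110,50,50]` to
#' `[170,255,255]`) and dark near-black variants (`[120,0,55]` to
#' `[150,30,90]`).
#'
#' @return List of two [hsv_range()]s.
#' @export
default_fibrous_ranges <- function() {
  list(hsv_range(c(110, 50, 50), c(170, 255, 255)),
       hsv_range(c(120, 0, 55), c(150, 30, 90)))
}

#' Binary mask of fibrous regions by HSV thresholding
#'
#' Converts the EVG image to HSV and marks a pixel when it falls inside ANY
#' of the supplied ranges (componentwise inclusive bounds).
#'
#' @param evg An [rgb_image()].
#' @param ranges List of [hsv_range()]s; default [default_fibrous_ranges()].
#' @return `H x W` logical matrix.
#' @export
fibrous_mask <- function(evg, ranges = default_fibrous_ranges()) {
  hsv <- rgb_to_hsv_cv(evg)
  d <- dim(hsv)
  mask <- matrix(FALSE, d[1], d[2])
  for (r in ranges) {
    if (!inherits(r, "hsv_range")) stop("ranges must be hsv_range objects")
    hit <- hsv[, , 1] >= r$lower[1] & hsv[, , 1] <= r$upper[1] &
           hsv[, , 2] >= r$lower[2] & hsv[, , 2] <= r$upper[2] &
           hsv[, , 3] >= r$lower[3] & hsv[, , 3] <= r$upper[3]
    mask <- mask | hit
  }
  mask
}

#' RMSE restricted to masked pixels
#'
#' RMSE over the masked pixels of all three channels. The mask is normally
#' derived from the ground-truth EVG image (it defines where fibers truly
#' are).
#'
#' @inheritParams mse_rmse
#' @param mask `H x W` logical matrix with at least one `TRUE` pixel.
#' @return Named list with `rmse` and `n_pixels` (masked pixel count).
#' @export
fibrous_rmse <- function(gt, out, mask) {
  gt <- as_image_array(gt); out <- as_image_array(out)
  check_same_shape(gt, out)
  if (!identical(dim(mask), dim(gt)[1:2])) stop("mask shape mismatch")
  n <- sum(mask)
  if (n == 0) stop("fibrous mask is empty (0 pixels)")
  se <- 0
  for (k in 1:3) se <- se + sum((gt[, , k][mask] - out[, , k][mask])^2)
  list(rmse = sqrt(se / (3 * n)), n_pixels = as.integer(n))
}

#' Assemble the full metrics record for one registered pair
#'
#' @inheritParams mse_rmse
#' @param ranges Fibrous HSV ranges; default [default_fibrous_ranges()].
#' @param mask_from `"gt"` (default: mask from the ground-truth image) or
#'   `"union"` (union of ground-truth and output masks).
#' @return Data frame row with `ssim`, `psnr`, `rmse_whole`, `rmse_fibrous`,
#'   `n_fibrous_pixels`.
#' @export
evaluate_pair <- function(gt, out, ranges = default_fibrous_ranges(),
                          mask_from = c("gt", "union")) {
  mask_from <- match.arg(mask_from)
  mask <- fibrous_mask(gt, ranges)
  if (mask_from == "union") mask <- mask | fibrous_mask(out, ranges)
  fr <- if (any(mask)) fibrous_rmse(gt, out, mask) else
    list(rmse = NA_real_, n_pixels = 0L)
  data.frame(ssim = ssim_rgb(gt, out),
             psnr = psnr(gt, out),
             rmse_whole = mse_rmse(gt, out)$rmse,
             rmse_fibrous = fr$rmse,
             n_fibrous_pixels = fr$n_pixels)
}

#' Dataset-level metrics report
#'
#' One row per image pair plus a `mean` row (per-image averaging, matching
#' the reporting convention for test sets).
#'
#' @param gt_list,out_list Lists of images of equal length.
#' @param ... Passed to [evaluate_pair()].
#' @return Data frame with an `image` column; final row is the mean.
#' @export
evaluate_dataset <- function(gt_list, out_list, ...) {
  stopifnot(length(gt_list) == length(out_list), length(gt_list) >= 1)
  rows <- do.call(rbind, Map(function(g, o) evaluate_pair(g, o, ...),
                             gt_list, out_list))
  rows$image <- seq_len(nrow(rows))
  mean_row <- data.frame(lapply(rows[setdiff(names(rows), "image")],
                                mean),
                         image = NA_integer_)
  out <- rbind(rows, mean_row)
  out$image <- c(as.character(seq_len(nrow(rows))), "mean")
  out[, c("image", "ssim", "psnr", "rmse_whole", "rmse_fibrous",
          "n_fibrous_pixels")]
}
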