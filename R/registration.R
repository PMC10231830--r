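# Feature-based affine registration of the EVG tile (moving) onto the H&E
# tile (fixed): scale/rotation-invariant keypoints + descriptors, ratio-test
# matching, M-estimator SAmple Consensus (MSAC) outlier rejection, affine
# warp, and a green/magenta overlay for visual checking.

to_gray <- function(img) {
  if (inherits(img, "rgb_image")) img <- img$data
  img <- as_array3d(img)
  if (dim(img)[3] == 1L) return(img[, , 1])
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Separable convolution with replicate padding.
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  mp <- m[pad_idx(h), ]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + h - 1L), , drop = FALSE]
  mp <- out[, pad_idx(w)]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * mp[, i:(i + w - 1L), drop = FALSE]
  out
}

grad_xy <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- (m[, pmin(seq_len(w) + 1L, w)] - m[, pmax(seq_len(w) - 1L, 1L)]) / 2
  gy <- (m[pmin(seq_len(h) + 1L, h), ] - m[pmax(seq_len(h) - 1L, 1L), ]) / 2
  list(gx = gx, gy = gy)
}

# Vectorized bilinear sampling at 0-based (x, y); out-of-bounds -> 0.
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  gather <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xi))
    v[ok] <- m[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    v
  }
  val <- gather(x0, y0) * (1 - fx) * (1 - fy) +
         gather(x0 + 1, y0) * fx * (1 - fy) +
         gather(x0, y0 + 1) * (1 - fx) * fy +
         gather(x0 + 1, y0 + 1) * fx * fy
  val
}

bilinear_resize <- function(m, scale) {
  h2 <- max(8L, round(nrow(m) * scale)); w2 <- max(8L, round(ncol(m) * scale))
  xs <- (seq_len(w2) - 1) * (ncol(m) - 1) / max(w2 - 1, 1)
  ys <- (seq_len(h2) - 1) * (nrow(m) - 1) / max(h2 - 1, 1)
  matrix(bilinear_sample(m, rep(xs, each = h2), rep(ys, w2)), h2, w2)
}

harris_response <- function(gray, sigma = 1.5, k = 0.04) {
  g <- grad_xy(conv_sep(gray, gaussian_kernel1d(1)))
  kk <- gaussian_kernel1d(sigma)
  sxx <- conv_sep(g$gx * g$gx, kk)
  syy <- conv_sep(g$gy * g$gy, kk)
  sxy <- conv_sep(g$gx * g$gy, kk)
  (sxx * syy - sxy^2) - k * (sxx + syy)^2
}

quad_peak <- function(lo, mid, hi) {
  den <- lo - 2 * mid + hi
  if (abs(den) < 1e-12) return(0)
  d <- 0.5 * (lo - hi) / den
  max(min(d, 0.5), -0.5)
}

local_maxima <- function(r, border = 8L, thresh_frac = 0.005) {
  h <- nrow(r); w <- ncol(r)
  keep <- r >= thresh_frac * max(r)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- r[pmin(pmax(seq_len(h) + dy, 1L), h), pmin(pmax(seq_len(w) + dx, 1L), w)]
    keep <- keep & (r >= sh)
  }
  keep[seq_len(border), ] <- FALSE; keep[(h - border + 1):h, ] <- FALSE
  keep[, seq_len(border)] <- FALSE; keep[, (w - border + 1):w] <- FALSE
  which(keep, arr.ind = TRUE)
}

# Orientation-normalized 8x8 patch descriptor sampled at the detection scale.
patch_descriptor <- function(gray, x, y, angle, spacing) {
  grid <- (-3.5):3.5
  gx <- rep(grid, each = 8); gy <- rep(grid, 8)
  ca <- cos(angle); sa <- sin(angle)
  xs <- x + spacing * (ca * gx - sa * gy)
  ys <- y + spacing * (sa * gx + ca * gy)
  v <- bilinear_sample(gray, xs, ys)
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n < 1e-8) return(NULL)
  v / n
}

#' Built-in multiscale keypoint detector and descriptor
#'
#' Harris corners detected on a small image pyramid, each keypoint assigned a
#' dominant gradient orientation and described by an orientation-normalized,
#' contrast-normalized 8x8 intensity patch sampled at its detection scale.
#' This satisfies the scale- and rotation-invariant detector contract of
#' [detect_and_match()]; any function with the same signature
#' (`function(gray)` returning `list(points, descriptors)`) can be plugged in
#' instead.
#'
#' @param gray Numeric matrix (grayscale image, 0--255).
#' @param max_keypoints Cap on keypoints per scale.
#' @param scales Pyramid scale factors.
#' @return List with `points` (n x 2 matrix of 0-based `(x, y)`) and
#'   `descriptors` (n x 64 matrix).
#' @export
detect_keypoints <- function(gray, max_keypoints = 200L,
                             scales = c(1, 0.7, 0.5)) {
  pts <- NULL; desc <- NULL
  for (s in scales) {
    g <- if (s == 1) gray else bilinear_resize(gray, s)
    if (min(dim(g)) < 24) next
    r <- harris_response(g)
    loc <- local_maxima(r)
    if (nrow(loc) == 0) next
    ord <- order(r[loc], decreasing = TRUE)
    loc <- loc[head(ord, max_keypoints), , drop = FALSE]
    gs <- conv_sep(g, gaussian_kernel1d(2))
    gr <- grad_xy(gs)
    for (i in seq_len(nrow(loc))) {
      yy <- loc[i, 1]; xx <- loc[i, 2]
      # sub-pixel localisation: 1-D quadratic fit of the response peak
      dx <- quad_peak(r[yy, xx - 1], r[yy, xx], r[yy, xx + 1])
      dy <- quad_peak(r[yy - 1, xx], r[yy, xx], r[yy + 1, xx])
      ang <- atan2(gr$gy[yy, xx], gr$gx[yy, xx])
      d <- patch_descriptor(g, xx - 1 + dx, yy - 1 + dy, ang, spacing = 2.5)
      if (is.null(d)) next
      pts <- rbind(pts, c((xx - 1 + dx) / s, (yy - 1 + dy) / s))
      desc <- rbind(desc, d)
    }
  }
  if (is.null(pts)) list(points = matrix(0, 0, 2), descriptors = matrix(0, 0, 64))
  else list(points = pts, descriptors = desc)
}

#' Construct a feature match set
#'
#' @param fixed_points,moving_points `n x 2` matrices of 0-based `(x, y)`
#'   coordinates.
#' @param scores Per-match descriptor distances.
#' @return An object of class `feature_match_set`.
#' @export
feature_match_set <- function(fixed_points, moving_points, scores) {
  stopifnot(nrow(fixed_points) == nrow(moving_points),
            nrow(fixed_points) == length(scores))
  structure(list(fixed_points = fixed_points, moving_points = moving_points,
                 scores = scores),
            class = "feature_match_set")
}

#' Detect and match keypoints between two images
#'
#' Detects scale/rotation-invariant keypoints in both images, matches
#' descriptors by nearest Euclidean distance and filters ambiguous matches by
#' Lowe's ratio test.
#'
#' @param fixed,moving [rgb_image()]s (or grayscale matrices).
#' @param detector `"harris"` (the built-in [detect_keypoints()]) or a
#'   function `function(gray) -> list(points, descriptors)`.
#' @param ratio Ratio-test threshold (default 0.75).
#' @param max_keypoints Per-scale keypoint cap.
#' @return A [feature_match_set()].
#' @export
detect_and_match <- function(fixed, moving, detector = "harris",
                             ratio = 0.75, max_keypoints = 200L) {
  det <- if (is.function(detector)) detector
         else if (identical(detector, "harris"))
           function(g) detect_keypoints(g, max_keypoints)
         else stop(sprintf("unknown detector '%s' (pass a function for custom detectors)",
                           detector))
  kf <- det(to_gray(fixed)); km <- det(to_gray(moving))
  if (nrow(kf$points) < 3 || nrow(km$points) < 3) {
    stop("fewer than 3 keypoints detected; images may be featureless")
  }
  # squared Euclidean distances between descriptor sets
  d2 <- outer(rowSums(kf$descriptors^2), rowSums(km$descriptors^2), "+") -
    2 * kf$descriptors %*% t(km$descriptors)
  d2[d2 < 0] <- 0
  fi <- integer(0); mi <- integer(0); sc <- numeric(0)
  for (i in seq_len(nrow(d2))) {
    o <- order(d2[i, ])[1:2]
    best <- sqrt(d2[i, o[1]]); second <- sqrt(max(d2[i, o[2]], 1e-12))
    if (best <= ratio * second) {
      fi <- c(fi, i); mi <- c(mi, o[1]); sc <- c(sc, best)
    }
  }
  if (length(fi) < 3) stop("fewer than 3 matches survive the ratio test; affine is underdetermined")
  feature_match_set(kf$points[fi, , drop = FALSE],
                    km$points[mi, , drop = FALSE], sc)
}

#' Construct an affine transform
#'
#' @param matrix `2 x 3` matrix mapping moving-image `(x, y, 1)` coordinates
#'   onto fixed-image coordinates (0-based pixel centers).
#' @param inlier_count Supporting inlier count (bookkeeping).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, inlier_count = 0L) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(2L, 3L)))
  dimnames(matrix) <- NULL
  if (abs(det(matrix[, 1:2])) < 1e-12) {
    stop("linear part of the affine transform is singular")
  }
  structure(list(matrix = matrix, inlier_count = as.integer(inlier_count)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n"); print(x$matrix)
  cat(sprintf("inliers: %d\n", x$inlier_count)); invisible(x)
}

apply_affine <- function(m, pts) {
  cbind(m[1, 1] * pts[, 1] + m[1, 2] * pts[, 2] + m[1, 3],
        m[2, 1] * pts[, 1] + m[2, 2] * pts[, 2] + m[2, 3])
}

fit_affine_ls <- function(moving, fixed) {
  x <- cbind(moving, 1)
  a <- tryCatch(solve(crossprod(x), crossprod(x, fixed)),
                error = function(e) NULL)
  if (is.null(a)) return(NULL)
  t(a)  # 2 x 3
}

#' Robust affine estimation by M-estimator SAmple Consensus
#'
#' MSAC loop: repeatedly sample 3 matches, fit an exact affine, score the
#' hypothesis by the truncated squared transfer residual
#' (`min(r^2, tol^2)` summed over matches), keep the best, then refit by
#' least squares on its inliers. Deterministic under a fixed seed.
#'
#' @param matches A [feature_match_set()] with at least 3 matches.
#' @param inlier_tol_px Inlier tolerance in pixels (default 3).
#' @param max_iter Sampling iterations (default 2000).
#' @param seed Optional integer seed for reproducibility.
#' @return An [affine_transform()] with `inlier_count` set.
#' @export
estimate_affine_msac <- function(matches, inlier_tol_px = 3,
                                 max_iter = 2000L, seed = NULL) {
  stopifnot(inherits(matches, "feature_match_set"))
  mov <- matches$moving_points; fix <- matches$fixed_points
  n <- nrow(mov)
  if (n < 3) stop("need at least 3 matches")
  if (!is.null(seed)) set.seed(seed)
  tol2 <- inlier_tol_px^2
  best_score <- Inf; best_m <- NULL
  for (it in seq_len(max_iter)) {
    s <- sample.int(n, 3L)
    m <- fit_affine_ls(mov[s, , drop = FALSE], fix[s, , drop = FALSE])
    if (is.null(m)) next
    r2 <- rowSums((apply_affine(m, mov) - fix)^2)
    score <- sum(pmin(r2, tol2))
    if (score < best_score) { best_score <- score; best_m <- m }
  }
  if (is.null(best_m)) stop("MSAC failed to fit any affine hypothesis")
  for (pass in 1:2) {
    r2 <- rowSums((apply_affine(best_m, mov) - fix)^2)
    inl <- which(r2 < tol2)
    if (length(inl) < 3) stop("no affine model with >= 3 inliers")
    m <- fit_affine_ls(mov[inl, , drop = FALSE], fix[inl, , drop = FALSE])
    if (!is.null(m)) best_m <- m
  }
  r2 <- rowSums((apply_affine(best_m, mov) - fix)^2)
  affine_transform(best_m, inlier_count = sum(r2 < tol2))
}

#' Mean transfer residual of a transform on its inliers
#'
#' @param t An [affine_transform()].
#' @param matches A [feature_match_set()].
#' @param inlier_tol_px Tolerance defining inliers.
#' @return Mean Euclidean residual (pixels) over inlier matches.
#' @export
registration_residual <- function(t, matches, inlier_tol_px = 3) {
  r <- sqrt(rowSums((apply_affine(t$matrix, matches$moving_points) -
                       matches$fixed_points)^2))
  mean(r[r < inlier_tol_px])
}

#' Warp an image by an affine transform
#'
#' Resamples the moving image onto the fixed-image grid (inverse mapping with
#' bilinear interpolation); pixels mapping outside the moving image are
#' filled with 0. Output is aligned with the fixed image.
#'
#' @param moving An [rgb_image()] or numeric array/matrix.
#' @param t An [affine_transform()] mapping moving onto fixed coordinates.
#' @param out_shape `(H, W)` of the output (fixed-image grid).
#' @return Same type as `moving`.
#' @export
warp_affine <- function(moving, t, out_shape) {
  stopifnot(inherits(t, "affine_transform"))
  was_rgb <- inherits(moving, "rgb_image")
  arr <- if (was_rgb) moving$data else as_array3d(moving)
  h <- out_shape[1]; w <- out_shape[2]
  lin <- t$matrix[, 1:2]; off <- t$matrix[, 3]
  inv <- solve(lin)
  xs <- rep(seq_len(w) - 1, each = h); ys <- rep(seq_len(h) - 1, w)
  src <- cbind(inv[1, 1] * (xs - off[1]) + inv[1, 2] * (ys - off[2]),
               inv[2, 1] * (xs - off[1]) + inv[2, 2] * (ys - off[2]))
  out <- array(0, dim = c(h, w, dim(arr)[3]))
  for (k in seq_len(dim(arr)[3])) {
    out[, , k] <- matrix(bilinear_sample(arr[, , k], src[, 1], src[, 2]), h, w)
  }
  if (was_rgb) rgb_image(pmin(pmax(out, 0), 255)) else out
}

#' Green/magenta registration overlay
#'
#' Green channel from the registered (moving) image's luminance, magenta
#' (red + blue) from the fixed image's luminance: aligned structures look
#' gray, misalignments show green/magenta fringes.
#'
#' @param fixed,registered [rgb_image()]s of equal shape.
#' @return An [rgb_image()].
#' @export
overlay_check <- function(fixed, registered) {
  lf <- to_gray(fixed); lr <- to_gray(registered)
  if (!identical(dim(lf), dim(lr))) stop("overlay inputs must share shape")
  out <- array(0, dim = c(dim(lf), 3L))
  out[, , 1] <- lf; out[, , 2] <- lr; out[, , 3] <- lf
  rgb_image(pmin(pmax(out, 0), 255))
}

#' Register a moving EVG tile onto a fixed H&E tile
#'
#' Full pipeline: detect/match features, estimate the affine by MSAC, warp
#' the moving image onto the fixed grid.
#'
#' @inheritParams detect_and_match
#' @inheritParams estimate_affine_msac
#' @return List with `registered` ([rgb_image()]), `transform`
#'   ([affine_transform()]) and `matches`.
#' @export
register_pair <- function(fixed, moving, detector = "harris",
                          inlier_tol_px = 3, max_iter = 2000L, seed = NULL,
                          ratio = 0.75) {
  matches <- detect_and_match(fixed, moving, detector, ratio = ratio)
  tr <- estimate_affine_msac(matches, inlier_tol_px, max_iter, seed)
  fx <- if (inherits(fixed, "rgb_image")) dim(fixed$data) else dim(fixed)
  list(registered = warp_affine(moving, tr, fx[1:2]),
       transform = tr, matches = matches)
}

#' Save / load an affine transform as JSON
#' @param t An [affine_transform()].
#' @param path JSON path.
#' @return `write_transform` returns `path` invisibly; `read_transform` an
#'   [affine_transform()].
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(matrix = t$matrix,
                            inlier_count = t$inlier_count),
                       path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- x$matrix
  if (!is.matrix(m)) m <- matrix(unlist(m), 2, 3, byrow = TRUE)
  affine_transform(m, inlier_count = x$inlier_count %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
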