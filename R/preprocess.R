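#' @title Image-conditioning operators
#' @description Shared 2-D operators used throughout the workflow: per-plane
#'   min-max normalization, max/min projection of z-stacks, contrast-limited
#'   adaptive histogram equalization (CLAHE), Sobel edge magnitude, Gaussian
#'   smoothing and Otsu thresholding. All operators are deterministic and
#'   shape-preserving; Sobel and Gaussian use reflect (symmetric) padding.
#' @name preprocess
NULL

# reflect-pad a matrix by (ry, rx); edge row/col included in the reflection
pad_reflect <- function(m, ry, rx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(ry, nr))), seq_len(nr), nr + 1 - seq_len(min(ry, nr)))
  ci <- c(rev(seq_len(min(rx, nc))), seq_len(nc), nc + 1 - seq_len(min(rx, nc)))
  m[ri, ci, drop = FALSE]
}

# dense 2-D convolution (correlation) of padded image with a small kernel,
# implemented as a sum of shifted submatrices; m must already be padded
conv_valid <- function(mp, k) {
  kr <- nrow(k); kc <- ncol(k)
  nr <- nrow(mp) - kr + 1L; nc <- ncol(mp) - kc + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    if (k[i, j] != 0)
      out <- out + k[i, j] * mp[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
  }
  out
}

#' Min-max normalize a single image plane to [0, 1]
#'
#' Linear rescale mapping the plane minimum to 0 and maximum to 1. A constant
#' plane maps to all zeros. Used on every z-slice before projection so that
#' strongly z-varying out-of-focus background does not dominate the projection.
#'
#' With `probs` given (e.g. `c(0.001, 0.999)`), the rescale anchors are those
#' intensity quantiles instead of the extremes, and the result is clamped to
#' \[0, 1\]. A plane's absolute maximum is often a single unusually bright
#' object (a nascent-transcription focus, a hot pixel), which would compress
#' every other spot in that plane; quantile anchors make the per-plane scaling
#' consistent across the stack.
#'
#' @param plane numeric matrix.
#' @param probs optional length-2 quantile anchors for a robust rescale.
#' @return numeric matrix in \[0, 1\], same shape.
#' @export
normalize_plane <- function(plane, probs = NULL) {
  stopifnot(is.matrix(plane), length(plane) > 0)
  if (is.null(probs)) {
    lo <- min(plane); hi <- max(plane)
  } else {
    q <- stats::quantile(plane, probs = probs, names = FALSE)
    lo <- q[[1L]]; hi <- q[[2L]]
  }
  if (hi == lo) return(matrix(0, nrow(plane), ncol(plane)))
  pmin(pmax((plane - lo) / (hi - lo), 0), 1)
}

#' Project a z-stack to a single plane
#'
#' Pixelwise maximum (or minimum) intensity projection, optionally preceded by
#' per-plane min-max normalization. Max projection of normalized planes is the
#' substrate for spot detection; min projection of the probe channel retains
#' the cellular autofluorescence used as the watershed surface.
#'
#' When `normalize_per_plane = FALSE` the stack is rescaled globally (one
#' min-max over all planes) so the projection still satisfies the \[0, 1\]
#' range contract while preserving inter-plane intensity relations.
#'
#' @param stack an [image_stack].
#' @param kind `"max"` or `"min"`.
#' @param normalize_per_plane normalize each plane independently first?
#' @param probs optional quantile anchors passed to [normalize_plane()].
#' @return a `projection`: list with `pixels` (matrix in \[0, 1\]), `kind`,
#'   `source_channel`.
#' @export
project <- function(stack, kind = c("max", "min"), normalize_per_plane = TRUE,
                    probs = NULL) {
  kind <- match.arg(kind)
  stack <- as_image_stack(stack)
  planes <- stack$planes
  if (normalize_per_plane) {
    planes <- lapply(planes, normalize_plane, probs = probs)
  } else {
    lo <- min(vapply(planes, min, 0)); hi <- max(vapply(planes, max, 0))
    planes <- if (hi == lo) {
      lapply(planes, function(p) matrix(0, nrow(p), ncol(p)))
    } else {
      lapply(planes, function(p) (p - lo) / (hi - lo))
    }
  }
  acc <- planes[[1L]]
  f <- if (kind == "max") pmax else pmin
  for (p in planes[-1L]) acc <- f(acc, p)
  structure(list(pixels = acc, kind = kind,
                 source_channel = stack$channel %||% ""),
            class = "projection")
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-based histogram equalization with a clip limit (Zuiderveld). The image
#' is divided into a `tile_grid` of contextual regions; each region's 256-bin
#' histogram is clipped at `clip_limit * tile_pixels`, the excess redistributed
#' uniformly, and its CDF used as an intensity mapping. Per-pixel output is the
#' bilinear interpolation of the four nearest tile mappings, which removes
#' tile-boundary seams. With a 1x1 grid this reduces exactly to global
#' clipped histogram equalization.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param clip_limit histogram clip limit as a fraction of tile pixel count
#'   (default 0.01).
#' @param tile_grid integer 2-vector `(rows, cols)` of tiles (default 8x8).
#' @param bins number of histogram bins (default 256).
#' @return numeric matrix in \[0, 1\], same shape.
#' @export
clahe <- function(img, clip_limit = 0.01, tile_grid = c(8L, 8L), bins = 256L) {
  stopifnot(is.matrix(img))
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    fs_stop("config", "clahe expects an image in [0, 1]")
  img <- pmin(pmax(img, 0), 1)
  nty <- as.integer(tile_grid[[1L]]); ntx <- as.integer(tile_grid[[2L]])
  if (nty < 1L || ntx < 1L) fs_stop("config", "tile_grid must be >= 1")
  H <- nrow(img); W <- ncol(img)
  if (nty > H || ntx > W)
    fs_stop("config", "tile grid %dx%d larger than image %dx%d", nty, ntx, H, W)

  bin <- pmin(floor(img * bins) + 1L, bins)     # 1..bins
  # tile index per row / per column (approximately equal tiles)
  ty_of <- pmin(floor((seq_len(H) - 1L) * nty / H) + 1L, nty)
  tx_of <- pmin(floor((seq_len(W) - 1L) * ntx / W) + 1L, ntx)

  # per-tile clipped-CDF mappings: array [nty, ntx, bins]
  maps <- array(0, dim = c(nty, ntx, bins))
  for (a in seq_len(nty)) for (b in seq_len(ntx)) {
    sub <- bin[ty_of == a, tx_of == b, drop = FALSE]
    n <- length(sub)
    h <- tabulate(sub, nbins = bins)
    clip <- max(clip_limit * n, 1)
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip) + excess / bins
    maps[a, b, ] <- cumsum(h) / n
  }

  # tile centers (in pixel coordinates) for interpolation
  cy <- vapply(seq_len(nty), function(a) mean(which(ty_of == a)), 0)
  cx <- vapply(seq_len(ntx), function(b) mean(which(tx_of == b)), 0)

  # per-row lower tile + weight, clamped at the borders
  lw <- function(pos, centers) {
    k <- length(centers)
    lo <- findInterval(pos, centers)          # 0..k
    lo <- pmin(pmax(lo, 1L), max(k - 1L, 1L))
    hi <- pmin(lo + 1L, k)
    span <- centers[hi] - centers[lo]
    w <- ifelse(span > 0, (pos - centers[lo]) / span, 0)
    w <- pmin(pmax(w, 0), 1)
    list(lo = lo, hi = hi, w = w)
  }
  ry <- lw(seq_len(H), cy); rx <- lw(seq_len(W), cx)

  YLO <- matrix(ry$lo, H, W); YHI <- matrix(ry$hi, H, W)
  XLO <- matrix(rx$lo, H, W, byrow = TRUE); XHI <- matrix(rx$hi, H, W, byrow = TRUE)
  WY <- matrix(ry$w, H, W); WX <- matrix(rx$w, H, W, byrow = TRUE)

  g <- function(ti, tj) matrix(maps[cbind(as.vector(ti), as.vector(tj),
                                          as.vector(bin))], H, W)
  out <- (1 - WY) * (1 - WX) * g(YLO, XLO) +
         (1 - WY) * WX       * g(YLO, XHI) +
         WY       * (1 - WX) * g(YHI, XLO) +
         WY       * WX       * g(YHI, XHI)
  pmin(pmax(out, 0), 1)
}

#' Sobel gradient magnitude
#'
#' Convolves with the standard 3x3 Sobel pair and returns
#' `sqrt(gx^2 + gy^2)`. Reflect padding; zero on constant images. Edge
#' filtering converts diffraction-limited spots into small rings, the pattern
#' the annular correlation template is matched against.
#'
#' @param img numeric matrix.
#' @return non-negative numeric matrix, same shape.
#' @export
sobel_magnitude <- function(img) {
  stopifnot(is.matrix(img))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  mp <- pad_reflect(img, 1L, 1L)
  gx <- conv_valid(mp, kx)
  gy <- conv_valid(mp, ky)
  sqrt(gx^2 + gy^2)
}

#' Otsu threshold
#'
#' Exhaustive search over the bin edges of a 256-bin histogram for the
#' threshold maximizing between-class variance.
#'
#' @param img numeric matrix with at least two distinct values.
#' @param bins number of histogram bins (default 256).
#' @return scalar threshold (a value strictly inside the image range); pixels
#'   `> threshold` form the upper class.
#' @export
otsu_threshold <- function(img, bins = 256L) {
  stopifnot(is.matrix(img) || is.numeric(img))
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi == lo) fs_stop("validation", "otsu_threshold: image is constant")
  edges <- seq(lo, hi, length.out = bins + 1L)
  b <- pmin(floor((v - lo) / (hi - lo) * bins) + 1L, bins)
  h <- as.numeric(tabulate(b, nbins = bins))
  n <- length(v)
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(h)[-bins]
  w1 <- n - w0
  mu0 <- cumsum(h * centers)[-bins] / pmax(w0, 1)
  mu1 <- (sum(h * centers) - cumsum(h * centers)[-bins]) / pmax(w1, 1)
  sb <- ifelse(w0 > 0 & w1 > 0, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(sb)
  edges[k + 1L]
}

#' Gaussian smoothing
#'
#' Separable convolution with a normalized Gaussian kernel of standard
#' deviation `sigma` pixels (radius `ceiling(3 sigma)`), reflect padding.
#' `sigma = 0` is the identity.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels, >= 0.
#' @return numeric matrix, same shape.
#' @export
gaussian_smooth <- function(img, sigma) {
  stopifnot(is.matrix(img))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    fs_stop("config", "sigma must be a single non-negative number")
  if (sigma == 0) return(img)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  mp <- pad_reflect(img, r, 0L)
  tmp <- conv_valid(mp, matrix(k, ncol = 1L))
  mp2 <- pad_reflect(tmp, 0L, r)
  conv_valid(mp2, matrix(k, nrow = 1L))
}
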