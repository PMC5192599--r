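test_that("normalize_plane is a linear min-max rescale", {
  expect_equal(normalize_plane(matrix(c(0, 10, 5, 10), 2, 2)),
               matrix(c(0, 1, 0.5, 1), 2, 2))
  expect_equal(normalize_plane(matrix(7, 3, 4)), matrix(0, 3, 4))

  set.seed(11)
  m <- matrix(runif(64, 10, 50), 8, 8)
  n1 <- normalize_plane(m)
  # idempotent, and invariant under positive affine input transforms
  expect_equal(normalize_plane(n1), n1)
  expect_equal(normalize_plane(3.7 * m + 12), n1, tolerance = 1e-12)
  # quantile anchors clamp into [0, 1]
  nq <- normalize_plane(m, probs = c(0.05, 0.95))
  expect_true(all(nq >= 0 & nq <= 1))
})

test_that("projection equals the per-pixel brute-force oracle", {
  s <- image_stack(list(matrix(c(0, 1), 1, 2), matrix(c(1, 0), 1, 2)))
  expect_equal(project(s, "max", normalize_per_plane = FALSE)$pixels,
               matrix(c(1, 1), 1, 2))
  expect_equal(project(s, "min", normalize_per_plane = FALSE)$pixels,
               matrix(c(0, 0), 1, 2))

  # single plane: projection is the normalized plane itself
  set.seed(21)
  p1 <- matrix(runif(36, 5, 9), 6, 6)
  expect_equal(project(image_stack(p1), "max")$pixels, normalize_plane(p1))

  # random 5-plane stack vs naive loop over pixels
  planes <- lapply(1:5, function(i) matrix(runif(48, 0, 10), 6, 8))
  st <- image_stack(planes)
  normed <- lapply(planes, normalize_plane)
  oracle_max <- matrix(0, 6, 8); oracle_min <- matrix(0, 6, 8)
  for (i in 1:6) for (j in 1:8) {
    v <- vapply(normed, function(p) p[i, j], 0)
    oracle_max[i, j] <- max(v); oracle_min[i, j] <- min(v)
  }
  expect_equal(project(st, "max")$pixels, oracle_max)
  expect_equal(project(st, "min")$pixels, oracle_min)
  # pixelwise ordering of the two projections
  expect_true(all(oracle_max >= oracle_min))
})

test_that("single-tile CLAHE equals global clipped histogram equalization", {
  set.seed(31)
  img <- matrix(runif(400), 20, 20)
  out <- clahe(img, clip_limit = 0.01, tile_grid = c(1L, 1L))

  bins <- 256L
  b <- pmin(floor(img * bins) + 1L, bins)
  h <- tabulate(b, nbins = bins)
  clip <- max(0.01 * length(img), 1)
  h2 <- pmin(h, clip) + sum(pmax(h - clip, 0)) / bins
  cdf <- cumsum(h2) / length(img)
  expect_equal(out, matrix(cdf[b], 20, 20))

  # monotone mapping preserves (non-strict) rank order
  expect_true(all(diff(out[order(img)]) >= -1e-12))
})

test_that("CLAHE respects its range and degenerate-input contracts", {
  expect_equal(max(clahe(matrix(0.5, 32, 32))) -
                 min(clahe(matrix(0.5, 32, 32))), 0)
  set.seed(32)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- clahe(img, clip_limit = 0.02, tile_grid = c(4L, 4L))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(dim(out), dim(img))
  expect_error(clahe(matrix(runif(16), 4, 4), tile_grid = c(8L, 8L)),
               class = "fishspot_config_error")
})

test_that("Sobel magnitude equals direct convolution with the 3x3 pair", {
  expect_equal(sobel_magnitude(matrix(2, 5, 7)), matrix(0, 5, 7))

  # vertical step edge: response maximal along the step columns
  step <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  sm <- sobel_magnitude(step)
  expect_true(all(sm[, c(3, 4)] >= sm[, c(1, 6)]))

  set.seed(41)
  img <- matrix(runif(64), 8, 8)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      v <- reflect_px(img, i + a, j + b)
      gx <- gx + kx[a + 2, b + 2] * v
      gy <- gy + ky[a + 2, b + 2] * v
    }
    oracle[i, j] <- sqrt(gx^2 + gy^2)
  }
  expect_equal(sobel_magnitude(img), oracle, tolerance = 1e-12)
})

test_that("Otsu threshold maximizes between-class variance over 256 bins", {
  bi <- matrix(c(rep(0.1, 1000), rep(0.9, 1000)), 40, 50)
  th <- otsu_threshold(bi)
  expect_gt(th, 0.1); expect_lt(th, 0.9)

  # naive exhaustive-search oracle over all bin cut points
  otsu_oracle <- function(v, bins = 256L) {
    lo <- min(v); hi <- max(v)
    edges <- seq(lo, hi, length.out = bins + 1L)
    b <- pmin(floor((v - lo) / (hi - lo) * bins) + 1L, bins)
    centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
    best <- -Inf; arg <- NA
    for (k in 1:(bins - 1L)) {
      in0 <- b <= k
      n0 <- sum(in0); n1 <- length(v) - n0
      if (n0 == 0 || n1 == 0) next
      mu0 <- mean(centers[b[in0]]); mu1 <- mean(centers[b[!in0]])
      sb <- n0 * n1 * (mu0 - mu1)^2
      if (sb > best) { best <- sb; arg <- edges[k + 1L] }
    }
    arg
  }
  set.seed(51)
  for (i in 1:8) {
    v <- c(rnorm(150, 0.3, 0.05), rnorm(80, 0.7, 0.08))
    img <- matrix(v, 23, 10)
    expect_equal(otsu_threshold(img), otsu_oracle(as.numeric(img)),
                 tolerance = 1e-12)
  }

  # translation equivariance and degenerate input
  set.seed(52)
  img <- matrix(runif(256), 16, 16)
  expect_equal(otsu_threshold(img + 5), otsu_threshold(img) + 5,
               tolerance = 1e-9)
  expect_error(otsu_threshold(matrix(1, 4, 4)),
               class = "fishspot_validation_error")

  # independent cross-check against EBImage's implementation (bin-width slack
  # for its slightly different edge convention)
  binw <- (max(img) - min(img)) / 256
  eb <- EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256)
  expect_lt(abs(otsu_threshold(img) - eb), 2 * binw)
})

test_that("Gaussian smoothing equals dense separable convolution", {
  set.seed(61)
  img <- matrix(runif(64), 8, 8)
  expect_identical(gaussian_smooth(img, 0), img)
  expect_error(gaussian_smooth(img, -1), class = "fishspot_config_error")

  sigma <- 1.3
  r <- ceiling(3 * sigma)
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    acc <- 0
    for (a in -r:r) for (b in -r:r)
      acc <- acc + k2[a + r + 1, b + r + 1] * reflect_px(img, i + a, j + b)
    oracle[i, j] <- acc
  }
  expect_equal(gaussian_smooth(img, sigma), oracle, tolerance = 1e-12)

  # impulse response in the interior is the kernel itself
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- gaussian_smooth(imp, sigma)
  expect_equal(out[(8 - r):(8 + r), (8 - r):(8 + r)], k2, tolerance = 1e-12)
  # mean preserved away from boundary effects (symmetric padding, unit kernel)
  expect_equal(sum(out), 1, tolerance = 1e-9)
})
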