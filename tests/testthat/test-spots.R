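test_that("diffraction radius follows the Rayleigh criterion", {
  opt <- test_optics()
  expect_equal(diffraction_radius_px(opt, "exon"),
               0.61 * 600 / 1.46 / 160, tolerance = 1e-12)
  opt2 <- optics_config(160, 1.46, c(exon = 1200))
  expect_equal(diffraction_radius_px(opt2, "exon"),
               2 * diffraction_radius_px(opt, "exon"))
  opt3 <- optics_config(160, 0.73, c(exon = 600))
  expect_equal(diffraction_radius_px(opt3, "exon"),
               2 * diffraction_radius_px(opt, "exon"))
})

test_that("annular templates have the stated geometry", {
  tpl <- make_annular_template(2, 1)
  expect_identical(dim(tpl$pixels), c(7L, 7L))
  expect_identical(tpl$pixels[4, 4], 0)           # annulus excludes center
  expect_equal(tpl$pixels, t(tpl$pixels))
  rot90 <- tpl$pixels[nrow(tpl$pixels):1, ]
  expect_equal(tpl$pixels, t(rot90))              # 90-degree rotation symmetry

  # ring pixel count equals brute-force lattice enumeration
  cnt <- 0L
  for (dy in -3:3) for (dx in -3:3) {
    d <- sqrt(dy^2 + dx^2)
    if (d >= 1.5 && d <= 2.5) cnt <- cnt + 1L
  }
  expect_identical(sum(tpl$pixels), as.numeric(cnt))
  expect_error(make_annular_template(0), class = "fishspot_config_error")
})

test_that("ncc_match equals the naive per-placement Pearson oracle", {
  set.seed(101)
  img <- matrix(runif(16 * 16), 16, 16)
  tpl <- matrix(runif(25), 5, 5)
  cm <- ncc_match(img, tpl)
  oracle <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12)
    oracle[i, j] <- cor(as.vector(img[i:(i + 4), j:(j + 4)]), as.vector(tpl))
  expect_equal(cm$values, oracle, tolerance = 1e-10)

  # perfect match and perfect anti-correlation
  img2 <- matrix(0.5, 20, 20)
  img2[4:8, 6:10] <- tpl
  img2[12:16, 3:7] <- -tpl + 1.2
  cm2 <- ncc_match(img2, tpl)
  expect_equal(cm2$values[4, 6], 1, tolerance = 1e-9)
  expect_equal(cm2$values[12, 3], -1, tolerance = 1e-9)

  # zero-variance windows correlate as 0, not NaN
  expect_true(all(is.finite(cm2$values)))
  expect_identical(cm2$values[1, 1], 0)

  expect_error(ncc_match(matrix(0, 4, 4), tpl),
               class = "fishspot_structural_error")
})

test_that("correlation maps are bounded on random inputs", {
  set.seed(102)
  for (i in 1:25) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    ts <- sample(c(3, 5, 7), 1)
    cm <- ncc_match(matrix(runif(h * w), h, w),
                    matrix(runif(ts * ts), ts, ts))
    expect_lte(max(abs(cm$values)), 1 + 1e-6)
  }
})

# a controlled projection: flat background, pixel-integrated Gaussian spots,
# optional Poisson+read noise. Note the correlation detector is contrast
# invariant, so with ANY white noise a few ring-shaped noise patterns score
# like spots regardless of the noise amplitude; exact-count checks therefore
# use the noise-free construction.
planted_projection <- function(pos, amp = 120, bg = 100, sigma = 0.73,
                               H = 128, W = 128, seed = 1, noise = TRUE) {
  set.seed(seed)
  img <- matrix(bg, H, W)
  for (k in seq_len(nrow(pos)))
    img <- fishspot:::add_gaussian(img, pos[k, 1], pos[k, 2], sigma,
                                   amp / (2 * pnorm(0.5 / sigma) - 1)^2)
  if (noise)
    img <- matrix(rpois(H * W, as.vector(img)), H, W) +
      matrix(rnorm(H * W, 0, 3), H, W)
  normalize_plane(pmax(img, 0))
}

test_that("two-pass detection recovers planted well-separated spots", {
  set.seed(103)
  pos <- as.matrix(expand.grid(y = seq(20, 110, by = 22),
                               x = seq(18, 112, by = 24)))[1:20, ] +
    matrix(runif(40, -1.5, 1.5), 20, 2)
  proj <- planted_projection(pos, amp = 170, noise = FALSE)
  edges <- sobel_magnitude(proj)
  ss <- two_pass_detect(edges, test_optics(), "exon")
  expect_identical(nrow(ss$spots), 20L)
  for (k in 1:20)
    expect_lte(min(sqrt((ss$spots$y - pos[k, 1])^2 +
                          (ss$spots$x - pos[k, 2])^2)), 1)
})

test_that("a blank image yields an empty, valid spot set", {
  edges <- sobel_magnitude(matrix(0.3, 64, 64))
  ss <- two_pass_detect(edges, test_optics(), "exon")
  expect_identical(nrow(ss$spots), 0L)
})

test_that("detection is invariant to positive affine intensity rescaling", {
  sc <- generate_scene(small_scene_params(), seed = 7)
  st <- sc$fov$probe_channels$exon
  st2 <- image_stack(lapply(st$planes, function(p) 3 * p + 40), "exon")
  s1 <- detect_channel(st, sc$fov$optics, "exon")
  s2 <- detect_channel(st2, sc$fov$optics, "exon")
  expect_identical(s1$spots$y, s2$spots$y)
  expect_identical(s1$spots$x, s2$spots$x)
  expect_equal(s1$spots$score, s2$spots$score, tolerance = 1e-9)
})

test_that("spot count is non-increasing in the correlation threshold", {
  sc <- generate_scene(small_scene_params(), seed = 8)
  st <- sc$fov$probe_channels$exon
  counts <- sapply(seq(0.3, 0.9, by = 0.1), function(t)
    nrow(detect_channel(st, sc$fov$optics, "exon", threshold = t)$spots))
  expect_true(all(diff(counts) <= 0))
  # spot sets respect their own invariants
  ss <- detect_channel(st, sc$fov$optics, "exon", threshold = 0.6)
  if (nrow(ss$spots) >= 2) {
    d <- as.matrix(dist(ss$spots[, c("y", "x")]))
    diag(d) <- Inf
    expect_gte(min(d), ss$min_separation)
  }
  expect_true(all(ss$spots$score >= 0.6))
})

test_that("single-plane channel detection reduces to the 2-D caller", {
  set.seed(104)
  pos <- cbind(runif(6, 20, 100), runif(6, 20, 100))
  proj <- planted_projection(pos, H = 120, W = 120, seed = 9)
  st <- image_stack(proj, "exon")
  s1 <- detect_channel(st, test_optics(), "exon")
  s2 <- two_pass_detect(sobel_magnitude(normalize_plane(proj)),
                        test_optics(), "exon")
  expect_equal(s1$spots, s2$spots)
})

test_that("spots closer than min_separation are suppressed to one", {
  pos <- rbind(c(60, 60), c(60, 61.4))
  proj <- planted_projection(pos, amp = 150, seed = 10)
  edges <- sobel_magnitude(proj)
  ss <- two_pass_detect(edges, test_optics(), "exon", min_separation = 3)
  near <- sum(sqrt((ss$spots$y - 60)^2 + (ss$spots$x - 60.7)^2) <= 3)
  expect_identical(near, 1L)
})
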