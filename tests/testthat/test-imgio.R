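test_that("image_stack enforces its shape and sign invariants", {
  expect_error(image_stack(list()), class = "fishspot_structural_error")
  expect_error(image_stack(list(matrix(0, 2, 2), matrix(0, 2, 3))),
               class = "fishspot_structural_error")
  expect_error(image_stack(matrix(-1, 2, 2)),
               class = "fishspot_validation_error")
  s <- image_stack(matrix(1, 4, 4))   # 1-plane stack is valid
  expect_length(s$planes, 1L)
})

test_that("TIFF stack I/O round-trips integer data exactly", {
  set.seed(71)
  planes <- lapply(1:4, function(i) matrix(sample(0:65535, 60), 6, 10))
  st <- image_stack(planes, channel = "exon")
  f <- tempfile(fileext = ".tif")
  write_stack_tiff(st, f, bits = 16L)
  back <- read_stack_tiff(f, channel = "exon")
  expect_length(back$planes, 4L)
  for (i in 1:4) expect_equal(back$planes[[i]], planes[[i]],
                              ignore_attr = TRUE)
})

test_that("multi-channel fields round-trip through one interleaved TIFF", {
  set.seed(72)
  mk <- function() lapply(1:3, function(i) matrix(sample(0:4095, 64), 8, 8))
  fov <- field_of_view(image_stack(mk(), "dapi"),
                       list(exon = image_stack(mk(), "exon"),
                            intron = image_stack(mk(), "intron")),
                       test_optics())
  f <- tempfile(fileext = ".tif")
  write_field(fov, f)
  back <- read_field(f, channel_map = list(dapi = 1L, exon = 2L, intron = 3L),
                     optics = test_optics())
  expect_identical(stack_dim <- sapply(back$probe_channels, function(s)
    length(s$planes)), c(exon = 3L, intron = 3L))
  for (z in 1:3) {
    expect_equal(back$dapi$planes[[z]], fov$dapi$planes[[z]],
                 ignore_attr = TRUE)
    expect_equal(back$probe_channels$exon$planes[[z]],
                 fov$probe_channels$exon$planes[[z]], ignore_attr = TRUE)
  }
})

test_that("field assembly rejects inconsistent channels", {
  d <- image_stack(matrix(1, 4, 4), "dapi")
  p_ok <- image_stack(matrix(1, 4, 4), "exon")
  p_bad <- image_stack(matrix(1, 4, 5), "exon")
  expect_error(field_of_view(d, list(exon = p_bad), test_optics()),
               class = "fishspot_structural_error")
  expect_silent(field_of_view(d, list(exon = p_ok), test_optics()))

  # two single-channel files of differing width
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  write_stack_tiff(image_stack(matrix(1:12, 3, 4)), f1)
  write_stack_tiff(image_stack(matrix(1:15, 3, 5)), f2)
  expect_error(read_field(c(f1, f2), list(dapi = 1L, exon = 2L),
                          test_optics()),
               class = "fishspot_structural_error")
  # missing DAPI role
  expect_error(read_field(c(f1, f2), list(exon = 1L, intron = 2L),
                          test_optics()),
               class = "fishspot_config_error")
})

test_that("optics configuration is validated", {
  expect_error(optics_config(160, 2.1, c(exon = 600)),
               class = "fishspot_config_error")
  expect_error(optics_config(-1, 1.4, c(exon = 600)),
               class = "fishspot_config_error")
})

test_that("cell tables conserve spot assignments", {
  rec0 <- data.frame(cell_id = integer(0), area_px = integer(0),
                     count_exon = integer(0))
  f <- tempfile(fileext = ".csv")
  write_cell_table(rec0, f)
  expect_length(readLines(f), 1L)   # header only

  seg <- matrix(0L, 10, 10); seg[2:5, 2:5] <- 1L; seg[7:9, 6:9] <- 2L
  sp <- data.frame(y = c(3, 4, 5, 8, 8, 7, 8, 9), x = c(3, 2, 4, 7, 8, 6, 9, 7),
                   score = runif(8))
  ss <- fishspot:::new_spot_set(sp, "exon", 0.5, 2)
  asg <- assign_spots(seg, ss)
  rec <- make_cell_records(seg, list(exon = asg))
  write_cell_table(rec, f)
  back <- read.csv(f)
  expect_equal(sum(back$count_exon), 8L)
  expect_equal(back$count_exon, c(3L, 5L))
})

test_that("overlay marks exactly the label-transition pixels", {
  seg <- matrix(1L, 12, 12); seg[, 7:12] <- 2L
  base <- matrix(0.5, 12, 12)
  f <- tempfile(fileext = ".png")
  rgb <- write_annotated_overlay(base, seg, list(), f)
  expect_true(file.exists(f))
  # 4-neighbor label-difference oracle
  oracle <- matrix(FALSE, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= 12 && jj >= 1 && jj <= 12 &&
          seg[ii, jj] != seg[i, j]) oracle[i, j] <- TRUE
    }
  }
  marked <- rgb[, , 1] == 1 & rgb[, , 2] == 1 & rgb[, , 3] == 0
  expect_identical(marked, oracle)
  # base image untouched by rendering
  expect_equal(base, matrix(0.5, 12, 12))
  # shape mismatch is a structural error
  expect_error(write_annotated_overlay(base, matrix(1L, 5, 5), list(), f),
               class = "fishspot_structural_error")
})

test_that("overlay renders spot markers and count labels deterministically", {
  seg <- matrix(1L, 40, 40)
  base <- matrix(0, 40, 40)
  sp <- fishspot:::new_spot_set(
    data.frame(y = c(10, 30), x = c(10, 30), score = c(0.9, 0.8)), "exon",
    0.6, 2)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  r1 <- write_annotated_overlay(base, seg, list(exon = sp), f1,
                                counts = c("1" = 4L))
  r2 <- write_annotated_overlay(base, seg, list(exon = sp), f2,
                                counts = c("1" = 4L))
  expect_identical(r1, r2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(any(r1[, , 1] == 1 & r1[, , 2] < 1))   # red spot marker pixels
  expect_true(any(r1[, , 1] == 1 & r1[, , 2] == 1 & r1[, , 3] == 1)) # digits
})
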