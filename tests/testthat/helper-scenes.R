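# shared fixtures: small, fast synthetic scenes and file paths

exon_table <- system.file("extdata", "pp2a_exon_probes.txt", package = "fishspot")
intron_table <- system.file("extdata", "pp2a_intron_probes.txt", package = "fishspot")

# a compact field that keeps per-test runtime low while exercising the same
# geometry (space-filling cells, disk nuclei, z-varying background)
small_scene_params <- function(...) {
  base <- list(width = 192L, height = 192L, n_planes = 6L, n_cells = 4L,
               nucleus_radius_px = 12L, min_center_dist_px = 60,
               border_margin_px = 18L, mrna_mean = 20)
  over <- list(...)
  base[names(over)] <- over
  do.call(scene_params, base)
}

test_optics <- function() {
  optics_config(pixel_size_nm = 160, numerical_aperture = 1.46,
                emission_wavelength_nm = c(exon = 600, intron = 680))
}

# reflect-padded pixel lookup used by the direct-convolution oracles
reflect_px <- function(m, i, j) {
  n <- nrow(m); p <- ncol(m)
  if (i < 1L) i <- 1L - i
  if (i > n) i <- 2L * n + 1L - i
  if (j < 1L) j <- 1L - j
  if (j > p) j <- 2L * p + 1L - j
  m[i, j]
}
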