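#' Parameters for the synthetic scene generator
#'
#' Defaults emulate the acquisition this workflow targets: a 512x512 EM-CCD
#' field at 160 nm/px through a 1.46 NA 100x objective, 10 optical sections
#' 0.2 um apart, ~20 space-filling root-meristem cells per field, and
#' diffraction-limited (~275 nm FWHM) single-molecule spots on a background
#' whose out-of-focus component varies strongly from plane to plane. Per-cell
#' mRNA counts follow a negative binomial with mean 74 and dispersion such
#' that roughly 30% of cells exceed 90 molecules; 84% of cells carry 1-2
#' nuclear nascent-transcription foci. Plant cell walls autofluoresce, so the
#' probe-channel background is ridged along cell boundaries - the structure
#' the watershed surface relies on.
#'
#' @param width,height field size in pixels.
#' @param n_planes number of z-sections.
#' @param n_cells number of cells.
#' @param pixel_size_nm,numerical_aperture,z_step_um optics.
#' @param emission_wavelength_nm named emission wavelengths (nm) per channel.
#' @param nucleus_radius_px nuclear disk radius.
#' @param min_center_dist_px minimum distance between nucleus centers.
#' @param border_margin_px keep nuclei and spots this far from the border.
#' @param mrna_mean,mrna_dispersion negative-binomial mean and size for
#'   per-cell mRNA counts.
#' @param mrna_fixed if non-`NULL`, every cell gets exactly this many mRNA
#'   spots instead of a negative-binomial draw (useful for controlled tests).
#' @param spot_fwhm_nm in-focus spot full width at half maximum.
#' @param defocus_rate fractional growth of the spot sigma per plane of
#'   defocus.
#' @param snr_mean,snr_sd,snr_min spot signal-to-noise ratios are drawn from
#'   a normal distribution (mean 20, sd 5 by default - the ~25%
#'   coefficient of variation of probe-binding stochasticity across the ~48
#'   oligos labelling each molecule) truncated below at `snr_min` (default
#'   5). SNR is defined on the image the detector analyzes - the
#'   per-plane-normalized maximum-intensity projection: a spot of SNR s
#'   stands s local noise standard deviations above the projected background
#'   at its position. Because the projection takes the pixelwise maximum
#'   over all planes, the rendered amplitude first clears the expected
#'   maximum of the per-plane noise.
#' @param nascent_snr_range SNR range for nascent foci (brighter: several
#'   transcripts at one locus).
#' @param p_active probability a cell is transcriptionally active.
#' @param p_two_sites probability an active cell shows two sites (two
#'   alleles) rather than one.
#' @param background_counts mean camera counts of the probe-channel
#'   background at unit plane factor.
#' @param plane_factor_range background multiplier from first to last plane
#'   (out-of-focus light).
#' @param field_modulation relative amplitude of the smooth low-frequency
#'   background field.
#' @param wall_counts peak added counts of the cell-wall autofluorescence
#'   ridge.
#' @param dapi_counts nuclear DAPI amplitude; `dapi_background` its
#'   background.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param deconvolve_sigma 0 (default) emulates raw camera planes with
#'   pixel-white noise. A positive value (px) emulates deconvolved stacks,
#'   whose residual noise is spatially smooth at the point-spread-function
#'   scale: each noisy plane is convolved with a Gaussian of this sigma,
#'   spots are rendered sharper so their observed size stays `spot_fwhm_nm`,
#'   and SNR stays defined on the final data. Note that PSF-scale-correlated
#'   noise is shape-identical to dim spots, which the (contrast-invariant)
#'   correlation detector cannot distinguish; see the methods vignette.
#' @return a `scene_params` list.
#' @export
scene_params <- function(width = 512L, height = 512L, n_planes = 10L,
                         n_cells = 20L,
                         pixel_size_nm = 160, numerical_aperture = 1.46,
                         z_step_um = 0.2,
                         emission_wavelength_nm = c(exon = 600, intron = 680,
                                                    dapi = 450),
                         nucleus_radius_px = 16L,
                         min_center_dist_px = 80,
                         border_margin_px = 24L,
                         mrna_mean = 74, mrna_dispersion = 8,
                         mrna_fixed = NULL,
                         spot_fwhm_nm = 275,
                         defocus_rate = 0.9,
                         snr_mean = 20, snr_sd = 5, snr_min = 5,
                         nascent_snr_range = c(12, 18),
                         p_active = 0.84, p_two_sites = 0.4,
                         background_counts = 200,
                         plane_factor_range = c(0.7, 1.4),
                         field_modulation = 0.3,
                         wall_counts = 150,
                         dapi_counts = 500, dapi_background = 50,
                         read_noise_sd = 5, deconvolve_sigma = 0) {
  p <- as.list(environment())
  class(p) <- "scene_params"
  p
}

# bilinear upscale of a coarse grid to H x W (smooth low-frequency field)
upscale_bilinear <- function(coarse, H, W) {
  ch <- nrow(coarse); cw <- ncol(coarse)
  ys <- seq(1, ch, length.out = H)
  xs <- seq(1, cw, length.out = W)
  y0 <- pmin(floor(ys), ch - 1L); x0 <- pmin(floor(xs), cw - 1L)
  wy <- ys - y0; wx <- xs - x0
  a <- coarse[y0, x0, drop = FALSE]; b <- coarse[y0, x0 + 1L, drop = FALSE]
  c_ <- coarse[y0 + 1L, x0, drop = FALSE]; d <- coarse[y0 + 1L, x0 + 1L, drop = FALSE]
  WY <- matrix(wy, H, W); WX <- matrix(wx, H, W, byrow = TRUE)
  (1 - WY) * (1 - WX) * a + (1 - WY) * WX * b + WY * (1 - WX) * c_ + WY * WX * d
}

# add a 2-D Gaussian of total flux `flux`, sd `sigma`, centered at (cy, cx);
# pixel values are the Gaussian integrated over each pixel (the camera
# collects photons over the pixel area - point sampling would alias spots
# whose sigma is below the pixel pitch)
add_gaussian <- function(m, cy, cx, sigma, flux) {
  r <- ceiling(4 * sigma + 2)
  ys <- max(1L, floor(cy - r)):min(nrow(m), ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(ncol(m), ceiling(cx + r))
  if (length(ys) == 0L || length(xs) == 0L) return(m)
  py <- stats::pnorm((ys + 0.5 - cy) / sigma) - stats::pnorm((ys - 0.5 - cy) / sigma)
  px <- stats::pnorm((xs + 0.5 - cx) / sigma) - stats::pnorm((xs - 0.5 - cx) / sigma)
  m[ys, xs] <- m[ys, xs] + flux * outer(py, px)
  m
}

#' Generate a synthetic field of view with ground truth
#'
#' Builds a three-channel z-stack (DAPI + exon + intron probe channels) with
#' known cells, nuclei, cytoplasmic mRNA spots and nuclear nascent foci:
#' cells are the Voronoi regions of the nucleus centers; each mRNA is a 2-D
#' Gaussian placed in one z-plane with defocus spreading into neighbors;
#' the background is a smooth low-frequency field whose amplitude varies
#' strongly across planes, plus cell-wall autofluorescence ridges; camera
#' noise is Poisson shot noise plus Gaussian read noise. Nascent foci are
#' rendered in both the intron channel and (co-localized, since nascent
#' transcripts carry exon sequence) the exon channel.
#'
#' Regenerating with the same seed and parameters reproduces the scene
#' bit-exactly.
#'
#' @param params a [scene_params()] list.
#' @param seed integer RNG seed.
#' @return a `synthetic_scene`: list with `fov` ([field_of_view]),
#'   `truth_cells` (label matrix), `truth_nuclei` (logical matrix),
#'   `truth_spots` (per-channel data.frames `y`, `x`, `z`, `amplitude`),
#'   `truth_counts` (per-cell exon-channel spot counts), `truth_nascent`
#'   (per-cell site counts), `centers`, `params`, `seed`.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  p <- params
  stopifnot(inherits(p, "scene_params"))
  if (p$n_cells < 1L) fs_stop("config", "n_cells must be >= 1")
  H <- p$height; W <- p$width; nz <- p$n_planes
  m <- p$border_margin_px
  if (2 * m >= min(H, W))
    fs_stop("validation", "image too small for the requested border margin")
  set.seed(as.integer(seed))

  # --- nucleus centers with minimum spacing (rejection sampling) ----------
  cy <- numeric(0); cx <- numeric(0)
  tries <- 0L
  while (length(cy) < p$n_cells) {
    if (tries > 5000L)
      fs_stop("validation",
              "cannot place %d nucleus centers at spacing %.0f px in %dx%d",
              p$n_cells, p$min_center_dist_px, H, W)
    yy <- runif(1, m, H - m); xx <- runif(1, m, W - m)
    if (length(cy) == 0L ||
        min((cy - yy)^2 + (cx - xx)^2) >= p$min_center_dist_px^2) {
      cy <- c(cy, yy); cx <- c(cx, xx)
    }
    tries <- tries + 1L
  }
  centers <- data.frame(id = seq_len(p$n_cells), y = cy, x = cx)

  # --- geometry: Voronoi cells, disk nuclei -------------------------------
  truth_cells <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  yg <- matrix(seq_len(H), H, W); xg <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(p$n_cells)) {
    d <- (yg - cy[[i]])^2 + (xg - cx[[i]])^2
    sel <- d < bestd
    truth_cells[sel] <- i
    bestd[sel] <- d[sel]
  }
  truth_nuclei <- matrix(FALSE, H, W)
  for (i in seq_len(p$n_cells)) {
    d <- (yg - cy[[i]])^2 + (xg - cx[[i]])^2
    truth_nuclei <- truth_nuclei | (d <= p$nucleus_radius_px^2)
  }

  # --- shared background structure ----------------------------------------
  field <- upscale_bilinear(matrix(rnorm(64), 8L, 8L), H, W)
  field <- 1 + p$field_modulation * field / max(abs(field))
  wall <- boundary_pixels(truth_cells) * 1
  wall <- gaussian_smooth(wall, 1.2)
  if (max(wall) > 0) wall <- wall / max(wall)
  zmid <- (nz + 1) / 2
  plane_factor <- seq(p$plane_factor_range[[1L]], p$plane_factor_range[[2L]],
                      length.out = max(nz, 2L))[seq_len(nz)]

  sigma0 <- p$spot_fwhm_nm / 2.355 / p$pixel_size_nm
  sd_dec <- p$deconvolve_sigma
  if (sd_dec >= sigma0)
    fs_stop("config", "deconvolve_sigma must be below the spot sigma (%.2f px)",
            sigma0)
  # spots are rendered at sigma_render so that after the deconvolved-noise
  # smoothing their observed sigma is sigma0; flux-conserving rendering makes
  # the in-focus observed peak of a flux-F spot equal F * peak_per_flux
  sigma_render <- sqrt(sigma0^2 - sd_dec^2)
  peak_per_flux <- (2 * stats::pnorm(0.5 / sigma0) - 1)^2
  # white-noise sd reduction of the plane smoothing (discrete kernel energy)
  noise_factor <- if (sd_dec > 0) {
    r <- ceiling(3 * sd_dec)
    k1 <- exp(-(seq(-r, r))^2 / (2 * sd_dec^2)); k1 <- k1 / sum(k1)
    sum(k1^2)
  } else 1
  noise_sd <- function(bg) noise_factor * sqrt(bg + p$read_noise_sd^2)
  # E[max of nz standard normals]: the amount the max projection lifts the
  # background, which a spot must clear before its SNR counts
  emax <- if (nz > 1L) {
    nz * stats::integrate(function(x) x * stats::dnorm(x) *
                            stats::pnorm(x)^(nz - 1L),
                          -Inf, Inf)$value
  } else 0

  blank_planes <- function() lapply(seq_len(nz), function(z) matrix(0, H, W))
  bg_exon <- lapply(seq_len(nz), function(z)
    p$background_counts * plane_factor[[z]] * field + p$wall_counts * wall)
  bg_intron <- lapply(seq_len(nz), function(z)
    0.75 * p$background_counts * plane_factor[[z]] * field +
      p$wall_counts * wall)
  sig_exon <- blank_planes(); sig_intron <- blank_planes()

  render_spot <- function(planes, bg, yy, xx, zz, snr) {
    yr <- round(yy); xr <- round(xx)
    bgmax <- max(vapply(bg, function(pl) pl[yr, xr], 0))
    sp <- noise_sd(bgmax)
    # observed prominence snr * sd above the projected background: the max
    # projection lifts the background by ~E[max] plane-noise sd, which the
    # spot must clear before its snr counts; rendered brighter to undo the
    # plane-smoothing peak loss. Cross-plane background differences are
    # handled by the per-plane normalization the detector applies.
    amp <- (emax + snr) * sp
    flux <- amp / peak_per_flux
    for (dz in -2:2) {
      z2 <- zz + dz
      if (z2 < 1L || z2 > nz) next
      sg <- sigma_render * (1 + p$defocus_rate * abs(dz))
      # constant flux: defocus spreads the same photons over a wider foot,
      # so the peak declines on its own
      planes[[z2]] <- add_gaussian(planes[[z2]], yy, xx, sg, flux)
    }
    list(planes = planes, amplitude = amp)
  }

  # --- cytoplasmic mRNA spots (exon channel) ------------------------------
  interior <- matrix(FALSE, H, W)
  interior[(m + 1L):(H - m), (m + 1L):(W - m)] <- TRUE
  n_mrna <- if (!is.null(p$mrna_fixed)) {
    rep(as.integer(p$mrna_fixed), p$n_cells)
  } else {
    rnbinom(p$n_cells, size = p$mrna_dispersion, mu = p$mrna_mean)
  }
  exon_spots <- vector("list", p$n_cells)
  for (i in seq_len(p$n_cells)) {
    allowed <- which(truth_cells == i & !truth_nuclei & interior)
    if (length(allowed) == 0L)
      fs_stop("validation", "cell %d has no cytoplasmic pixels for spots", i)
    k <- n_mrna[[i]]
    if (k == 0L) { exon_spots[[i]] <- NULL; next }
    pick <- allowed[sample.int(length(allowed), k, replace = TRUE)]
    yy <- ((pick - 1L) %% H) + 1L + runif(k, -0.45, 0.45)
    xx <- ((pick - 1L) %/% H) + 1L + runif(k, -0.45, 0.45)
    zz <- sample.int(nz, k, replace = TRUE)
    snr <- pmax(rnorm(k, p$snr_mean, p$snr_sd), p$snr_min)
    amps <- numeric(k)
    for (j in seq_len(k)) {
      res <- render_spot(sig_exon, bg_exon, yy[[j]], xx[[j]], zz[[j]], snr[[j]])
      sig_exon <- res$planes
      amps[[j]] <- res$amplitude
    }
    exon_spots[[i]] <- data.frame(cell_id = i, y = yy, x = xx, z = zz,
                                  amplitude = amps)
  }

  # --- nuclear nascent foci (intron channel + co-localized exon signal) ---
  active <- runif(p$n_cells) < p$p_active
  n_sites <- ifelse(active, 1L + (runif(p$n_cells) < p$p_two_sites), 0L)
  intron_spots <- vector("list", p$n_cells)
  for (i in seq_len(p$n_cells)) {
    k <- n_sites[[i]]
    if (k == 0L) next
    nucpix <- which(truth_cells == i & truth_nuclei & interior)
    if (length(nucpix) == 0L)
      fs_stop("validation", "cell %d has no nuclear pixels for nascent foci", i)
    pick <- nucpix[sample.int(length(nucpix), k, replace = FALSE)]
    yy <- ((pick - 1L) %% H) + 1L + runif(k, -0.45, 0.45)
    xx <- ((pick - 1L) %/% H) + 1L + runif(k, -0.45, 0.45)
    zz <- sample.int(nz, k, replace = TRUE)
    snr <- runif(k, p$nascent_snr_range[[1L]], p$nascent_snr_range[[2L]])
    amps <- numeric(k)
    for (j in seq_len(k)) {
      res <- render_spot(sig_intron, bg_intron, yy[[j]], xx[[j]], zz[[j]],
                         snr[[j]])
      sig_intron <- res$planes
      amps[[j]] <- res$amplitude
      # nascent transcripts also carry exon sequence
      res2 <- render_spot(sig_exon, bg_exon, yy[[j]], xx[[j]], zz[[j]],
                          0.75 * snr[[j]])
      sig_exon <- res2$planes
    }
    intron_spots[[i]] <- data.frame(cell_id = i, y = yy, x = xx, z = zz,
                                    amplitude = amps)
  }
  exon_truth <- do.call(rbind, c(exon_spots, intron_spots))
  if (is.null(exon_truth))
    exon_truth <- data.frame(cell_id = integer(0), y = numeric(0),
                             x = numeric(0), z = integer(0),
                             amplitude = numeric(0))
  intron_truth <- do.call(rbind, intron_spots)
  if (is.null(intron_truth))
    intron_truth <- data.frame(cell_id = integer(0), y = numeric(0),
                               x = numeric(0), z = integer(0),
                               amplitude = numeric(0))

  # --- DAPI channel -------------------------------------------------------
  focus <- exp(-((seq_len(nz) - zmid) / (nz / 3))^2)
  nuc_soft <- gaussian_smooth(truth_nuclei * 1, 1)
  dapi_planes <- lapply(seq_len(nz), function(z)
    p$dapi_background * plane_factor[[z]] * field +
      p$dapi_counts * focus[[z]] * nuc_soft)

  # --- camera noise -------------------------------------------------------
  expose <- function(signal) {
    lapply(signal, function(pl) {
      v <- rpois(length(pl), lambda = as.vector(pl)) +
        rnorm(length(pl), sd = p$read_noise_sd)
      out <- matrix(v, H, W)
      if (sd_dec > 0) out <- gaussian_smooth(out, sd_dec)
      matrix(pmin(pmax(round(out), 0), 65535), H, W)
    })
  }
  exon_planes <- expose(mapply(`+`, bg_exon, sig_exon, SIMPLIFY = FALSE))
  intron_planes <- expose(mapply(`+`, bg_intron, sig_intron, SIMPLIFY = FALSE))
  dapi_planes <- expose(dapi_planes)

  optics <- optics_config(p$pixel_size_nm, p$numerical_aperture,
                          p$emission_wavelength_nm)
  fov <- field_of_view(
    image_stack(dapi_planes, "dapi", p$z_step_um),
    list(exon = image_stack(exon_planes, "exon", p$z_step_um),
         intron = image_stack(intron_planes, "intron", p$z_step_um)),
    optics
  )

  truth_counts <- stats::setNames(
    vapply(seq_len(p$n_cells), function(i)
      sum(exon_truth$cell_id == i), 0L), seq_len(p$n_cells))

  structure(list(
    fov = fov,
    truth_cells = truth_cells,
    truth_nuclei = truth_nuclei,
    truth_spots = list(exon = exon_truth, intron = intron_truth),
    truth_counts = truth_counts,
    truth_nascent = stats::setNames(n_sites, seq_len(p$n_cells)),
    centers = centers,
    params = p,
    seed = as.integer(seed)
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> seed %d: %d cells, %d exon spots, %d nascent foci\n",
              x$seed, x$params$n_cells, nrow(x$truth_spots$exon),
              nrow(x$truth_spots$intron)))
  invisible(x)
}

#' Score detected spots against ground truth
#'
#' Greedy nearest-neighbor matching: detections are visited in decreasing
#' score order and matched to the nearest unmatched truth spot within
#' `match_radius_px`; each truth spot is matched at most once.
#'
#' @param truth a `synthetic_scene`, or a data.frame of truth spots with
#'   columns `y`, `x`.
#' @param spots a `spot_set`.
#' @param match_radius_px matching radius in pixels (default 2).
#' @param channel which truth channel when `truth` is a scene (default the
#'   spot set's channel).
#' @return list with `precision` (NA when nothing was detected), `recall`,
#'   `f1`, `rmse` (localization RMSE of matches), `tp`, `fp`, `fn`.
#' @export
score_detection <- function(truth, spots, match_radius_px = 2,
                            channel = NULL) {
  stopifnot(match_radius_px > 0, inherits(spots, "spot_set"))
  tdf <- if (inherits(truth, "synthetic_scene")) {
    truth$truth_spots[[channel %||% spots$channel]]
  } else truth
  det <- spots$spots
  nt <- nrow(tdf); nd <- nrow(det)
  if (nd == 0L)
    return(list(precision = NA_real_, recall = if (nt > 0L) 0 else NA_real_,
                f1 = NA_real_, rmse = NA_real_, tp = 0L, fp = 0L, fn = nt))
  det <- det[order(-det$score, det$y, det$x), , drop = FALSE]
  matched <- logical(nt)
  tp <- 0L
  sqerr <- numeric(0)
  for (i in seq_len(nd)) {
    if (nt == 0L) break
    d2 <- (tdf$y - det$y[[i]])^2 + (tdf$x - det$x[[i]])^2
    d2[matched] <- Inf
    j <- which.min(d2)
    if (is.finite(d2[[j]]) && d2[[j]] <= match_radius_px^2) {
      matched[[j]] <- TRUE
      tp <- tp + 1L
      sqerr <- c(sqerr, d2[[j]])
    }
  }
  fp <- nd - tp; fn <- nt - tp
  precision <- tp / nd
  recall <- if (nt > 0L) tp / nt else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       rmse = if (length(sqerr)) sqrt(mean(sqerr)) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
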