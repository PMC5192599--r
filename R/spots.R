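#' Diffraction radius in pixels
#'
#' Rayleigh criterion `r = 0.61 * lambda_em / NA`, converted to pixels. This
#' sets the scale of a diffraction-limited single-molecule spot and hence of
#' the correlation template.
#'
#' @param optics an [optics_config].
#' @param channel probe channel name (selects the emission wavelength).
#' @return radius in pixels (> 0).
#' @export
diffraction_radius_px <- function(optics, channel) {
  stopifnot(inherits(optics, "optics_config"))
  lam <- optics$emission_wavelength_nm
  lam <- if (!is.null(names(lam)) && channel %in% names(lam)) lam[[channel]]
         else lam[[1L]]
  0.61 * lam / optics$numerical_aperture / optics$pixel_size_nm
}

#' Build an annular correlation template
#'
#' A ring of ones at distance `radius_px +/- ring_width_px / 2` from the
#' center of an odd-sided square, zero elsewhere. On a Sobel edge image a
#' diffraction-limited spot appears as just such a ring, so this template
#' picks out candidate single-molecule locations without any absolute
#' intensity threshold.
#'
#' @param radius_px ring radius in pixels (> 0).
#' @param ring_width_px radial width of the ring (default 2).
#' @return a `spot_template`: list with `pixels` (odd-sided matrix), `origin`
#'   (center, (y, x)), `provenance`.
#' @export
make_annular_template <- function(radius_px, ring_width_px = 2) {
  if (radius_px <= 0) fs_stop("config", "radius must be > 0")
  side <- 2L * as.integer(ceiling(radius_px + ring_width_px)) + 1L
  c0 <- (side + 1L) %/% 2L
  d <- sqrt(outer((seq_len(side) - c0)^2, (seq_len(side) - c0)^2, "+"))
  px <- (d >= radius_px - ring_width_px / 2 &
         d <= radius_px + ring_width_px / 2) * 1
  structure(list(pixels = px, origin = c(c0, c0), provenance = "annular"),
            class = "spot_template")
}

as_template <- function(x) {
  if (inherits(x, "spot_template")) return(x)
  stopifnot(is.matrix(x))
  if (nrow(x) %% 2L == 0L || ncol(x) %% 2L == 0L)
    fs_stop("config", "template sides must be odd")
  structure(list(pixels = x, origin = (dim(x) + 1L) %/% 2L,
                 provenance = "image_patch"),
            class = "spot_template")
}

#' Normalized cross-correlation template matching
#'
#' Pearson correlation between the template and every same-sized window of
#' the image (valid-mode extent): values in \[-1, 1\], +1 a perfect match, -1
#' perfect anti-correlation, invariant to positive affine intensity changes
#' of either input. Near-constant windows correlate as 0.
#'
#' @param img 2-D matrix.
#' @param tpl a `spot_template` (or odd-sided matrix).
#' @return a `correlation_map`: list with `values`
#'   (`(H - th + 1) x (W - tw + 1)` matrix), `template`, and `offset` (the
#'   (y, x) shift from map position to full-image template-center position).
#' @export
ncc_match <- function(img, tpl) {
  stopifnot(is.matrix(img))
  tpl <- as_template(tpl)
  th <- nrow(tpl$pixels); tw <- ncol(tpl$pixels)
  if (th >= nrow(img) || tw >= ncol(img))
    fs_stop("structural", "template (%dx%d) must be smaller than image (%dx%d)",
            th, tw, nrow(img), ncol(img))
  vals <- ncc_match_cpp(img, tpl$pixels)
  structure(list(values = vals, template = tpl,
                 offset = c((th - 1L) %/% 2L, (tw - 1L) %/% 2L)),
            class = "correlation_map")
}

# local maxima (8-neighborhood, >= comparison) of a matrix, as data.frame
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (H < 3L || W < 3L) return(data.frame(y = integer(0), x = integer(0),
                                          score = numeric(0)))
  ok <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ys <- max(1L, 1L + dy):min(H, H + dy)
    xs <- max(1L, 1L + dx):min(W, W + dx)
    ok[ys - dy, xs - dx] <- ok[ys - dy, xs - dx] & (m[ys - dy, xs - dx] >= m[ys, xs])
  }
  idx <- which(ok, arr.ind = TRUE)
  data.frame(y = idx[, 1L], x = idx[, 2L], score = m[idx])
}

# greedy non-maximum suppression: keep candidates in descending score order,
# dropping any within min_sep of an already-kept candidate. Suppression by a
# higher-scoring neighbor is threshold-independent, so filtering the kept set
# at any threshold afterwards equals thresholding first. An occupancy grid
# keeps the neighbor search local (O(n * min_sep^2) instead of O(n^2)).
nms <- function(cand, min_sep) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(-cand$score, cand$y, cand$x), , drop = FALSE]
  H <- max(cand$y); W <- max(cand$x)
  occ <- matrix(FALSE, H, W)
  r <- ceiling(min_sep)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    y <- cand$y[[i]]; x <- cand$x[[i]]
    ys <- max(1L, y - r):min(H, y + r)
    xs <- max(1L, x - r):min(W, x + r)
    near <- which(occ[ys, xs, drop = FALSE], arr.ind = TRUE)
    clash <- FALSE
    if (nrow(near) > 0L) {
      dy <- ys[near[, 1L]] - y; dx <- xs[near[, 2L]] - x
      clash <- any(dy * dy + dx * dx < min_sep^2)
    }
    if (!clash) {
      keep[[i]] <- TRUE
      occ[y, x] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

new_spot_set <- function(df, channel, threshold, min_separation) {
  rownames(df) <- NULL
  structure(list(spots = df, channel = channel, threshold = threshold,
                 min_separation = min_separation),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> '%s': %d spot(s), threshold %.2f\n",
              x$channel, nrow(x$spots), x$threshold))
  invisible(x)
}

# candidate spots from the two-pass correlation, before thresholding
two_pass_candidates <- function(edge_img, radius_px, ring_width_px = 2,
                                min_separation = NULL) {
  tpl <- make_annular_template(radius_px, ring_width_px)
  if (is.null(min_separation)) min_separation <- ceiling(radius_px)
  cm1 <- ncc_match(edge_img, tpl)

  # second pass: the single best annular match, cut from the edge image,
  # becomes the refined template. The raw argmax can sit a pixel or two off
  # the ring's true center (sub-pixel spot phase); an off-center template
  # would displace every second-pass detection by the same amount, so the
  # patch is re-centered on the edge-magnitude centroid of the ring first.
  best <- which(cm1$values == max(cm1$values), arr.ind = TRUE)[1L, , drop = TRUE]
  th <- nrow(tpl$pixels); tw <- ncol(tpl$pixels)
  rh <- (th - 1L) %/% 2L; rw <- (tw - 1L) %/% 2L
  cy <- best[[1L]] + rh; cx <- best[[2L]] + rw
  win <- edge_img[(cy - rh):(cy + rh), (cx - rw):(cx + rw), drop = FALSE]
  wgt <- win - min(win)
  if (sum(wgt) > 0) {
    cy <- cy + round(sum((row(win) - (rh + 1L)) * wgt) / sum(wgt))
    cx <- cx + round(sum((col(win) - (rw + 1L)) * wgt) / sum(wgt))
  }
  cy <- min(max(cy, rh + 1L), nrow(edge_img) - rh)
  cx <- min(max(cx, rw + 1L), ncol(edge_img) - rw)
  patch <- edge_img[(cy - rh):(cy + rh), (cx - rw):(cx + rw), drop = FALSE]
  cm2 <- ncc_match(edge_img, patch)

  cand <- local_maxima(cm2$values)
  cand <- nms(cand, min_separation)
  cand$y <- cand$y + cm2$offset[[1L]]
  cand$x <- cand$x + cm2$offset[[2L]]
  list(candidates = cand, min_separation = min_separation,
       map1 = cm1, map2 = cm2)
}

#' Two-pass template-matching spot detection
#'
#' The core spot caller: (1) normalized cross-correlation of the edge image
#' with an annular template sized to the diffraction radius; (2) the single
#' best match is cut from the edge image and used as a refined template for a
#' second correlation pass; (3) local maxima of the second map with
#' correlation at or above `threshold` and pairwise separation at least
#' `min_separation` become spots, reported in full-image coordinates.
#'
#' @param edge_img Sobel edge magnitude of the normalized max projection.
#' @param optics an [optics_config].
#' @param channel channel name (selects emission wavelength; recorded in the
#'   result).
#' @param threshold correlation threshold in \[-1, 1\] (default 0.6; see
#'   [calibrate_threshold()]).
#' @param min_separation minimum pairwise spot distance in pixels (default:
#'   diffraction radius rounded up).
#' @param ring_width_px annulus width (default 2).
#' @return a `spot_set`: data.frame `spots` with `y`, `x`, `score`.
#' @export
two_pass_detect <- function(edge_img, optics, channel = "probe",
                            threshold = 0.6, min_separation = NULL,
                            ring_width_px = 2) {
  r <- diffraction_radius_px(optics, channel)
  res <- two_pass_candidates(edge_img, r, ring_width_px, min_separation)
  sel <- res$candidates[res$candidates$score >= threshold, , drop = FALSE]
  new_spot_set(sel, channel, threshold, res$min_separation)
}

#' Detect spots in one probe channel
#'
#' The full per-channel caller: each z-slice is min-max normalized, the stack
#' max-projected, the projection Sobel-filtered, and the two-pass correlation
#' detector applied to the edge magnitude.
#'
#' @param probe probe-channel [image_stack].
#' @param norm_probs optional quantile anchors for the per-plane
#'   normalization (e.g. `c(0.001, 0.999)`; default `NULL` = exact min-max).
#'   Robust anchors keep one very bright object (e.g. a nascent focus) from
#'   compressing all other spots in its plane.
#' @inheritParams two_pass_detect
#' @return a `spot_set`.
#' @export
detect_channel <- function(probe, optics, channel = NULL, threshold = 0.6,
                           min_separation = NULL, ring_width_px = 2,
                           norm_probs = NULL) {
  probe <- as_image_stack(probe)
  if (is.null(channel)) channel <- if (nzchar(probe$channel)) probe$channel else "probe"
  proj <- project(probe, "max", normalize_per_plane = TRUE,
                  probs = norm_probs)$pixels
  edges <- sobel_magnitude(proj)
  two_pass_detect(edges, optics, channel, threshold, min_separation,
                  ring_width_px)
}
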