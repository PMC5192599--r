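#' Derive watershed seeds from the DAPI channel
#'
#' Implements the nuclear seed-finding pipeline: each DAPI plane is min-max
#' normalized, the stack max-projected, the projection locally equalized with
#' CLAHE, Sobel-filtered to find nuclear edges, and Otsu-thresholded; enclosed
#' regions are filled, components smaller than `min_nucleus_area` discarded,
#' and each surviving nucleus reduced to its centroid.
#'
#' `seed_strategy = "edge"` (default) applies Otsu to the Sobel edge
#' magnitude and fills the enclosed outlines; `"intensity"` applies Otsu
#' directly to the equalized projection.
#'
#' @param dapi DAPI [image_stack].
#' @param min_nucleus_area discard components below this area (px^2, default 50).
#' @param clip_limit,tile_grid CLAHE parameters (see [clahe()]).
#' @param sigma_seed Gaussian denoising sigma (px) applied to the equalized
#'   projection before edge detection (default 1; 0 disables). CLAHE
#'   equalizes background tiles too, so without this mild denoise the Sobel
#'   response of camera noise fragments the nuclear outlines and hole-filling
#'   cannot recover solid nuclei.
#' @param seed_strategy `"edge"` or `"intensity"`.
#' @return a `seed_set`: list with `seeds` (data.frame `id`, `y`, `x`) and
#'   `nucleus_mask` (logical matrix, filled nuclei) for QC. Zero detected
#'   nuclei yield an empty seed set with a warning.
#' @export
find_nuclear_seeds <- function(dapi, min_nucleus_area = 50,
                               clip_limit = 0.01, tile_grid = c(8L, 8L),
                               sigma_seed = 1,
                               seed_strategy = c("edge", "intensity")) {
  seed_strategy <- match.arg(seed_strategy)
  dapi <- as_image_stack(dapi, "dapi")
  proj <- project(dapi, "max", normalize_per_plane = TRUE)$pixels
  eq <- clahe(proj, clip_limit = clip_limit, tile_grid = tile_grid)
  if (sigma_seed > 0) eq <- gaussian_smooth(eq, sigma_seed)

  mask <- if (seed_strategy == "edge") {
    edges <- sobel_magnitude(eq)
    if (max(edges) == min(edges)) {
      matrix(FALSE, nrow(proj), ncol(proj))
    } else {
      edges > otsu_threshold(edges)
    }
  } else {
    if (max(eq) == min(eq)) matrix(FALSE, nrow(proj), ncol(proj))
    else eq > otsu_threshold(eq)
  }

  filled <- matrix(as.logical(EBImage::fillHull(EBImage::Image(mask * 1)) > 0),
                   nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(filled * 1))),
                nrow(filled), ncol(filled))

  seeds <- data.frame(id = integer(0), y = integer(0), x = integer(0))
  keep_mask <- matrix(FALSE, nrow(filled), ncol(filled))
  if (max(lab) > 0L) {
    next_id <- 1L
    for (k in seq_len(max(lab))) {
      px <- which(lab == k, arr.ind = TRUE)
      if (nrow(px) < min_nucleus_area) next
      seeds <- rbind(seeds, data.frame(id = next_id,
                                       y = as.integer(round(mean(px[, 1L]))),
                                       x = as.integer(round(mean(px[, 2L])))))
      keep_mask[px] <- TRUE
      next_id <- next_id + 1L
    }
  }
  if (nrow(seeds) == 0L)
    fs_warn("no nuclei detected; downstream segmentation will be skipped")
  structure(list(seeds = seeds, nucleus_mask = keep_mask), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d nuclear seed(s)\n", nrow(x$seeds)))
  invisible(x)
}

#' Build the watershed flooding surface from probe-channel autofluorescence
#'
#' Minimum-intensity projection of the probe channel (which retains each
#' cell's background autofluorescence while suppressing the transient bright
#' spots), equalized with CLAHE and Gaussian-smoothed. In plant tissue the
#' cell walls autofluoresce strongly, so this surface is ridged along cell
#' boundaries - exactly what seeded flooding needs.
#'
#' @param probe probe-channel [image_stack].
#' @param sigma_grad Gaussian sigma in pixels (default 2).
#' @param clip_limit,tile_grid CLAHE parameters.
#' @return 2-D matrix in \[0, 1\].
#' @export
build_gradient_surface <- function(probe, sigma_grad = 2,
                                   clip_limit = 0.01, tile_grid = c(8L, 8L)) {
  probe <- as_image_stack(probe)
  proj <- project(probe, "min", normalize_per_plane = TRUE)$pixels
  if (max(proj) == min(proj)) return(proj)
  eq <- clahe(proj, clip_limit = clip_limit, tile_grid = tile_grid)
  sm <- gaussian_smooth(eq, sigma_grad)
  pmin(pmax(sm, 0), 1)
}

#' Seeded watershed segmentation into cells
#'
#' Priority-flood watershed of the surface from the given seeds: pixels are
#' claimed in order of increasing surface value (ties in breadth-first
#' order), 4-connected, so region boundaries form along surface ridges. Every
#' in-mask pixel is assigned to exactly one seed's label.
#'
#' @param gradient 2-D surface matrix.
#' @param seeds a `seed_set` from [find_nuclear_seeds()], or a data.frame with
#'   columns `id`, `y`, `x`.
#' @param mask optional logical foreground matrix; outside pixels stay 0.
#' @return integer label matrix (0 = unassigned, k = cell with seed id k).
#' @export
watershed_cells <- function(gradient, seeds, mask = NULL) {
  stopifnot(is.matrix(gradient))
  sdf <- if (inherits(seeds, "seed_set")) seeds$seeds else as.data.frame(seeds)
  if (nrow(sdf) == 0L) fs_stop("config", "watershed requires at least one seed")
  if (anyDuplicated(sdf[, c("y", "x")]))
    fs_stop("config", "two seeds share identical coordinates")
  if (anyDuplicated(sdf$id)) fs_stop("config", "seed ids must be unique")
  if (any(sdf$y < 1L | sdf$y > nrow(gradient) |
          sdf$x < 1L | sdf$x > ncol(gradient)))
    fs_stop("structural", "seed coordinates outside image bounds")
  if (!is.null(mask)) {
    stopifnot(is.logical(mask))
    if (!identical(dim(mask), dim(gradient)))
      fs_stop("structural", "mask shape does not match gradient")
  }
  sm <- cbind(as.integer(sdf$id), as.integer(sdf$y), as.integer(sdf$x))
  watershed_cpp(gradient, sm, mask)
}

#' Jaccard overlap of a segmentation against truth labels
#'
#' For each truth region, the best-overlapping predicted region's
#' intersection-over-union. A segmentation-quality QC metric for synthetic
#' scenes.
#'
#' @param seg,truth integer label matrices of identical shape.
#' @return named numeric vector of per-truth-region Jaccard indices.
#' @export
segmentation_jaccard <- function(seg, truth) {
  stopifnot(identical(dim(seg), dim(truth)))
  ids <- setdiff(sort(unique(as.vector(truth))), 0L)
  out <- numeric(length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    tm <- truth == ids[[i]]
    cand <- table(seg[tm])
    cand <- cand[names(cand) != "0"]
    if (length(cand) == 0L) { out[[i]] <- 0; next }
    best <- as.integer(names(cand)[which.max(cand)])
    pm <- seg == best
    out[[i]] <- sum(tm & pm) / sum(tm | pm)
  }
  out
}
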