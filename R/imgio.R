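#' Construct an image stack
#'
#' One channel's z-stack of 2-D planes (z ascending). Planes are stored as
#' numeric matrices indexed \[y, x\]; intensities must be non-negative.
#'
#' @param planes list of matrices, or a 3-D array with dimensions (y, x, z).
#' @param channel channel name (e.g. `"dapi"`, `"exon"`).
#' @param z_step_um optional z-step in micrometers (metadata only).
#' @return an `image_stack`.
#' @export
image_stack <- function(planes, channel = "", z_step_um = NULL) {
  if (is.array(planes) && length(dim(planes)) == 3L)
    planes <- lapply(seq_len(dim(planes)[3L]), function(k) planes[, , k])
  if (is.matrix(planes)) planes <- list(planes)
  if (!is.list(planes) || length(planes) == 0L)
    fs_stop("structural", "image_stack needs at least one plane")
  dims <- vapply(planes, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    fs_stop("structural", "all planes must share identical height x width")
  if (any(vapply(planes, function(p) min(p) < 0, TRUE)))
    fs_stop("validation", "intensities must be non-negative")
  structure(list(planes = planes, channel = channel, z_step_um = z_step_um),
            class = "image_stack")
}

as_image_stack <- function(x, channel = "") {
  if (inherits(x, "image_stack")) x else image_stack(x, channel)
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> '%s': %d plane(s) of %d x %d\n",
              x$channel, length(x$planes), nrow(x$planes[[1]]), ncol(x$planes[[1]])))
  invisible(x)
}

stack_dim <- function(s) c(dim(s$planes[[1L]]), length(s$planes))

#' Optical parameters of the acquisition
#'
#' @param pixel_size_nm size of one camera pixel at the sample, nanometers.
#' @param numerical_aperture objective NA (<= 1.7; e.g. 1.46 for a 100x
#'   oil-immersion objective).
#' @param emission_wavelength_nm named numeric vector of emission wavelengths
#'   per probe channel, nanometers.
#' @return an `optics_config`.
#' @export
optics_config <- function(pixel_size_nm, numerical_aperture,
                          emission_wavelength_nm) {
  if (any(c(pixel_size_nm, numerical_aperture, emission_wavelength_nm) <= 0))
    fs_stop("config", "optics values must be strictly positive")
  if (numerical_aperture > 1.7)
    fs_stop("config", "numerical aperture %.2f exceeds 1.7", numerical_aperture)
  structure(list(pixel_size_nm = pixel_size_nm,
                 numerical_aperture = numerical_aperture,
                 emission_wavelength_nm = emission_wavelength_nm),
            class = "optics_config")
}

#' Assemble a multi-channel field of view
#'
#' @param dapi DAPI (nuclear stain) [image_stack].
#' @param probe_channels named list of 1-2 probe-channel [image_stack]s.
#' @param optics an [optics_config].
#' @return a `field_of_view`.
#' @export
field_of_view <- function(dapi, probe_channels, optics) {
  dapi <- as_image_stack(dapi, "dapi")
  if (!is.list(probe_channels) || length(probe_channels) < 1L ||
      is.null(names(probe_channels)) || any(!nzchar(names(probe_channels))))
    fs_stop("config", "probe_channels must be a named list of 1-2 stacks")
  probe_channels <- mapply(as_image_stack, probe_channels,
                           names(probe_channels), SIMPLIFY = FALSE)
  d0 <- stack_dim(dapi)
  for (nm in names(probe_channels)) {
    if (!identical(stack_dim(probe_channels[[nm]]), d0))
      fs_stop("structural",
              "channel '%s' dimensions (%s) differ from DAPI (%s)",
              nm, paste(stack_dim(probe_channels[[nm]]), collapse = "x"),
              paste(d0, collapse = "x"))
  }
  stopifnot(inherits(optics, "optics_config"))
  structure(list(dapi = dapi, probe_channels = probe_channels, optics = optics),
            class = "field_of_view")
}

#' @export
print.field_of_view <- function(x, ...) {
  d <- stack_dim(x$dapi)
  cat(sprintf("<field_of_view> %d x %d x %d z-planes; probe channels: %s\n",
              d[1], d[2], d[3], paste(names(x$probe_channels), collapse = ", ")))
  invisible(x)
}

# ---- TIFF I/O ---------------------------------------------------------------

#' Read a single-channel z-stack from a multi-page TIFF
#'
#' Accepts 8/16-bit integer or 32-bit float TIFFs. Integer data are returned
#' as integer-valued matrices (lossless); float data as stored.
#'
#' @param path TIFF path.
#' @param channel channel name to record.
#' @return an [image_stack].
#' @export
read_stack_tiff <- function(path, channel = "") {
  if (!file.exists(path)) fs_stop("parse", "file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse grayscale-as-RGB
    storage.mode(p) <- "double"
    p
  })
  image_stack(planes, channel = channel)
}

#' Write a z-stack as a multi-page TIFF
#'
#' Integer-valued stacks are written losslessly as 16-bit (or 8-bit) pages;
#' float stacks as 32-bit float.
#'
#' @param stack an [image_stack].
#' @param path output path.
#' @param bits 8, 16 (integer) or 32 (float).
#' @export
write_stack_tiff <- function(stack, path, bits = 16L) {
  stack <- as_image_stack(stack)
  if (bits == 32L) {
    tiff::writeTIFF(stack$planes, path, bits.per.sample = 32L,
                    compression = "none")
    return(invisible(path))
  }
  maxval <- 2^bits - 1
  if (max(vapply(stack$planes, max, 0)) > maxval)
    fs_stop("config", "intensities exceed %d-bit range", bits)
  scaled <- lapply(stack$planes, function(p) p / maxval)
  tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Read a multi-channel field of view from TIFF files
#'
#' Either per-channel multi-page TIFFs (`paths` = named or unnamed character
#' vector, `channel_map` mapping channel name to element index), or a single
#' interleaved multi-page TIFF (`channel_map` mapping name to channel index;
#' pages are assumed channel-fastest, i.e. c1z1, c2z1, ..., as written by
#' [write_field()]). `channel_map` must cover `"dapi"` plus at least one probe
#' channel.
#'
#' @param paths one or more TIFF paths.
#' @param channel_map named list/vector of integer indices, e.g.
#'   `list(dapi = 1, exon = 2)`.
#' @param optics an [optics_config].
#' @return a [field_of_view].
#' @export
read_field <- function(paths, channel_map, optics) {
  cm <- unlist(channel_map)
  if (!("dapi" %in% names(cm)))
    fs_stop("config", "channel_map must include a 'dapi' channel")
  if (length(cm) < 2L)
    fs_stop("config", "channel_map must include at least one probe channel")
  if (length(paths) == 1L) {
    pages <- tiff::readTIFF(paths, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    ncha <- length(cm)
    if (length(pages) %% ncha != 0L)
      fs_stop("structural", "page count %d is not a multiple of %d channels",
              length(pages), ncha)
    stacks <- lapply(cm, function(ci) {
      image_stack(lapply(pages[seq(ci, length(pages), by = ncha)], function(p) {
        storage.mode(p) <- "double"; p
      }))
    })
  } else {
    stacks <- lapply(cm, function(ci) read_stack_tiff(paths[[ci]]))
  }
  names(stacks) <- names(cm)
  for (nm in names(stacks)) stacks[[nm]]$channel <- nm
  field_of_view(stacks[["dapi"]], stacks[setdiff(names(stacks), "dapi")], optics)
}

#' Write a field of view as one interleaved multi-page TIFF
#'
#' Pages are ordered channel-fastest (c1z1, c2z1, ..., c1z2, ...), DAPI first;
#' [read_field()] with the matching `channel_map` reads it back losslessly for
#' integer data.
#'
#' @param fov a [field_of_view].
#' @param path output path.
#' @param bits bits per sample (16 default).
#' @return the channel order written, invisibly.
#' @export
write_field <- function(fov, path, bits = 16L) {
  stopifnot(inherits(fov, "field_of_view"))
  stacks <- c(list(dapi = fov$dapi), fov$probe_channels)
  nz <- stack_dim(fov$dapi)[3L]
  maxval <- 2^bits - 1
  pages <- list()
  for (z in seq_len(nz))
    for (nm in names(stacks))
      pages[[length(pages) + 1L]] <- stacks[[nm]]$planes[[z]] / maxval
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(names(stacks))
}

# ---- tabular and overlay outputs -------------------------------------------

#' Write the per-cell results table
#'
#' One CSV row per cell: id, area, centroid, mRNA count per probe channel,
#' nascent site count, active and border flags.
#'
#' @param records data.frame of cell records (see [make_cell_records()]).
#' @param path output CSV path.
#' @export
write_cell_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# pixels where the label differs from a 4-neighbor (the outer side of each
# boundary is marked in both adjacent regions)
boundary_pixels <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  b <- matrix(FALSE, H, W)
  b[-H, ] <- b[-H, ] | (labels[-H, ] != labels[-1L, ])
  b[-1L, ] <- b[-1L, ] | (labels[-1L, ] != labels[-H, ])
  b[, -W] <- b[, -W] | (labels[, -W] != labels[, -1L])
  b[, -1L] <- b[, -1L] | (labels[, -1L] != labels[, -W])
  b
}

# 3x5 bitmap digits for deterministic device-free count labels
.digit_font <- local({
  rows <- c(
    "111101101101111", "010110010010111", "111001111100111", "111001111001111",
    "101101111001001", "111100111001111", "111100111101111", "111001001001001",
    "111101111101111", "111101111001111"
  )
  lapply(rows, function(r) matrix(as.integer(strsplit(r, "")[[1L]]) == 1L,
                                  nrow = 5L, byrow = TRUE))
})

draw_text <- function(canvas, y, x, text, value = 1) {
  glyphs <- strsplit(text, "")[[1L]]
  H <- nrow(canvas); W <- ncol(canvas)
  for (g in glyphs) {
    if (g %in% as.character(0:9)) {
      bm <- .digit_font[[as.integer(g) + 1L]]
      for (i in 1:5) for (j in 1:3) {
        yy <- y + i - 1L; xx <- x + j - 1L
        if (bm[i, j] && yy >= 1L && yy <= H && xx >= 1L && xx <= W)
          canvas[yy, xx] <- value
      }
    }
    x <- x + 4L
  }
  canvas
}

#' Write an annotated overlay image
#'
#' Renders, over the (min-projected) probe autofluorescence, the watershed
#' cell boundaries, detected spot markers per channel, and each cell's mRNA
#' count, then writes an RGB PNG. Rendering is device-free and deterministic
#' for fixed inputs; the input arrays are never modified.
#'
#' @param fov a [field_of_view] (the first probe channel provides the
#'   background), or a 2-D matrix in \[0, 1\] used directly as background.
#' @param seg integer label matrix from [watershed_cells()].
#' @param spots named list of `spot_set`s per channel (may be empty).
#' @param path output PNG path.
#' @param counts optional named integer vector of per-cell counts to print at
#'   cell centroids (names = cell ids).
#' @return the RGB array written, invisibly.
#' @export
write_annotated_overlay <- function(fov, seg, spots = list(), path,
                                    counts = NULL) {
  base <- if (is.matrix(fov)) {
    fov
  } else {
    project(fov$probe_channels[[1L]], "min", normalize_per_plane = TRUE)$pixels
  }
  if (!identical(dim(base), dim(seg)))
    fs_stop("structural", "segmentation shape (%s) does not match image (%s)",
            paste(dim(seg), collapse = "x"), paste(dim(base), collapse = "x"))
  H <- nrow(base); W <- ncol(base)
  R <- G <- B <- pmin(pmax(base, 0), 1)

  bd <- boundary_pixels(seg)
  R[bd] <- 1; G[bd] <- 1; B[bd] <- 0          # yellow boundaries

  cols <- list(c(1, 0.2, 0.2), c(0.2, 1, 0.2), c(0.4, 0.6, 1))
  ci <- 1L
  for (ch in names(spots)) {
    ss <- spots[[ch]]
    co <- cols[[(ci - 1L) %% length(cols) + 1L]]; ci <- ci + 1L
    if (!is.null(ss) && nrow(ss$spots) > 0L) {
      for (k in seq_len(nrow(ss$spots))) {
        y <- round(ss$spots$y[[k]]); x <- round(ss$spots$x[[k]])
        for (d in -1:1) {
          yy <- y + d; xx <- x + d
          if (yy >= 1 && yy <= H && x >= 1 && x <= W) {
            R[yy, x] <- co[1]; G[yy, x] <- co[2]; B[yy, x] <- co[3]
          }
          if (y >= 1 && y <= H && xx >= 1 && xx <= W) {
            R[y, xx] <- co[1]; G[y, xx] <- co[2]; B[y, xx] <- co[3]
          }
        }
      }
    }
  }

  if (!is.null(counts) && length(counts) > 0L) {
    ids <- as.integer(names(counts))
    for (k in seq_along(counts)) {
      px <- which(seg == ids[[k]], arr.ind = TRUE)
      if (nrow(px) == 0L) next
      cy <- round(mean(px[, 1L])); cx <- round(mean(px[, 2L]))
      txt <- as.character(counts[[k]])
      x0 <- cx - (4L * nchar(txt) - 1L) %/% 2L
      R <- draw_text(R, cy - 2L, x0, txt, 1)
      G <- draw_text(G, cy - 2L, x0, txt, 1)
      B <- draw_text(B, cy - 2L, x0, txt, 1)
    }
  }

  rgb <- array(c(R, G, B), dim = c(H, W, 3L))
  png::writePNG(rgb, path)
  invisible(rgb)
}
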