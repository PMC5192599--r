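#' Assign detected spots to segmented cells
#'
#' Each spot is assigned to the segmentation label at its (rounded) pixel
#' coordinate; label 0 collects unassigned (inter-cell) spots. Conservation
#' holds by construction: assigned + unassigned = detected.
#'
#' @param seg integer label matrix.
#' @param spots a `spot_set`.
#' @return list with `counts` (named integer vector per cell id, including
#'   zero-count cells), `by_cell` (list of spot data.frames), `unassigned`
#'   (data.frame).
#' @export
assign_spots <- function(seg, spots) {
  stopifnot(is.matrix(seg), inherits(spots, "spot_set"))
  df <- spots$spots
  ids <- setdiff(sort(unique(as.vector(seg))), 0L)
  counts <- stats::setNames(integer(length(ids)), ids)
  by_cell <- stats::setNames(vector("list", length(ids)), ids)
  if (nrow(df) == 0L)
    return(list(counts = counts, by_cell = by_cell,
                unassigned = df))
  y <- as.integer(round(df$y)); x <- as.integer(round(df$x))
  if (any(y < 1L | y > nrow(seg) | x < 1L | x > ncol(seg)))
    fs_stop("structural", "spot coordinates outside segmentation bounds")
  lab <- seg[cbind(y, x)]
  for (id in ids) {
    sel <- lab == id
    counts[[as.character(id)]] <- sum(sel)
    by_cell[[as.character(id)]] <- df[sel, , drop = FALSE]
  }
  list(counts = counts, by_cell = by_cell,
       unassigned = df[lab == 0L, , drop = FALSE])
}

#' Call nascent transcription sites per cell
#'
#' Nascent (intron-probe) foci mark sites of active transcription and are
#' biologically restricted to the nucleus; spots falling outside the nucleus
#' mask are therefore discarded as artifacts (the discard count is recorded
#' for QC rather than silently dropped). Remaining spots are counted per cell.
#' If exon-channel spots are supplied, each site is annotated with whether an
#' exon spot lies within `colocal_radius_px` (nascent transcripts carry exon
#' sequence, so true sites co-localize with mRNA foci).
#'
#' @param seg integer label matrix.
#' @param nucleus_mask logical matrix aligned with `seg`.
#' @param nascent_spots `spot_set` from the intron channel.
#' @param exon_spots optional `spot_set` from the exon channel.
#' @param colocal_radius_px co-localization distance (default: pass the
#'   diffraction radius).
#' @return list with `site_count` (named integer per cell), `discarded`
#'   (number of extra-nuclear nascent spots), `sites` (data.frame with
#'   `cell_id`, `y`, `x`, `score`, `colocalized`).
#' @export
call_nascent_sites <- function(seg, nucleus_mask, nascent_spots,
                               exon_spots = NULL, colocal_radius_px = 2) {
  stopifnot(is.matrix(seg), is.logical(nucleus_mask),
            identical(dim(seg), dim(nucleus_mask)),
            inherits(nascent_spots, "spot_set"))
  ids <- setdiff(sort(unique(as.vector(seg))), 0L)
  site_count <- stats::setNames(integer(length(ids)), ids)
  df <- nascent_spots$spots
  discarded <- 0L
  sites <- data.frame(cell_id = integer(0), y = numeric(0), x = numeric(0),
                      score = numeric(0), colocalized = logical(0))
  if (nrow(df) > 0L) {
    y <- as.integer(round(df$y)); x <- as.integer(round(df$x))
    if (any(y < 1L | y > nrow(seg) | x < 1L | x > ncol(seg)))
      fs_stop("structural", "nascent spot coordinates outside bounds")
    innuc <- nucleus_mask[cbind(y, x)]
    discarded <- sum(!innuc)
    if (discarded > 0L)
      fs_warn("%d nascent spot(s) outside the nucleus mask discarded", discarded)
    keep <- df[innuc, , drop = FALSE]
    if (nrow(keep) > 0L) {
      lab <- seg[cbind(as.integer(round(keep$y)), as.integer(round(keep$x)))]
      colo <- rep(NA, nrow(keep))
      if (!is.null(exon_spots) && nrow(exon_spots$spots) > 0L) {
        ex <- exon_spots$spots
        colo <- vapply(seq_len(nrow(keep)), function(i) {
          min((ex$y - keep$y[[i]])^2 + (ex$x - keep$x[[i]])^2) <=
            colocal_radius_px^2
        }, TRUE)
      }
      sites <- data.frame(cell_id = lab, y = keep$y, x = keep$x,
                          score = keep$score, colocalized = colo)
      incell <- sites[sites$cell_id > 0L, , drop = FALSE]
      tab <- table(incell$cell_id)
      site_count[names(tab)] <- as.integer(tab)
    }
  }
  list(site_count = site_count, discarded = discarded, sites = sites)
}

#' Build per-cell records
#'
#' Combines segmentation geometry, per-channel spot assignments, and nascent
#' site calls into one row per cell. A cell is transcriptionally active iff it
#' has at least one nascent site; cells touching the image border are flagged
#' (clipped cells undercount mRNA).
#'
#' @param seg integer label matrix.
#' @param assignments named list (per probe channel) of [assign_spots()]
#'   results.
#' @param nascent optional [call_nascent_sites()] result.
#' @return data.frame with columns `cell_id`, `area_px`, `centroid_y`,
#'   `centroid_x`, `count_<channel>`..., `nascent_site_count`, `active`,
#'   `border_cell`.
#' @export
make_cell_records <- function(seg, assignments, nascent = NULL) {
  ids <- setdiff(sort(unique(as.vector(seg))), 0L)
  H <- nrow(seg); W <- ncol(seg)
  rec <- data.frame(cell_id = ids)
  rec$area_px <- NA_integer_; rec$centroid_y <- NA_real_; rec$centroid_x <- NA_real_
  rec$border_cell <- FALSE
  for (i in seq_along(ids)) {
    px <- which(seg == ids[[i]], arr.ind = TRUE)
    rec$area_px[[i]] <- nrow(px)
    rec$centroid_y[[i]] <- mean(px[, 1L])
    rec$centroid_x[[i]] <- mean(px[, 2L])
    rec$border_cell[[i]] <- any(px[, 1L] %in% c(1L, H) | px[, 2L] %in% c(1L, W))
  }
  for (ch in names(assignments)) {
    cnt <- assignments[[ch]]$counts
    rec[[paste0("count_", ch)]] <- as.integer(cnt[as.character(ids)])
  }
  if (!is.null(nascent)) {
    rec$nascent_site_count <- as.integer(nascent$site_count[as.character(ids)])
    rec$active <- rec$nascent_site_count >= 1L
  } else {
    rec$nascent_site_count <- NA_integer_
    rec$active <- NA
  }
  rec
}

#' Population summary of per-cell transcript counts
#'
#' Mean and standard error of mRNA per cell, a binned frequency distribution
#' (default bin width 15 molecules), the fraction of transcriptionally active
#' cells, and the histogram of nascent sites per cell.
#'
#' @param records data.frame from [make_cell_records()].
#' @param channel which count column to summarize (default: first
#'   `count_*` column).
#' @param bin_width histogram bin width in molecules (default 15).
#' @return a `population_summary` list: `n_cells`, `mean_mrna_per_cell`,
#'   `sem`, `histogram` (data.frame `bin_lo`, `bin_hi`, `cell_count`),
#'   `fraction_active` (NA if no nascent channel), `nascent_site_histogram`.
#' @export
summarize_cells <- function(records, channel = NULL, bin_width = 15L) {
  if (is.null(records) || nrow(records) == 0L)
    fs_stop("validation", "cannot summarize an empty cell list")
  count_cols <- grep("^count_", names(records), value = TRUE)
  col <- if (is.null(channel)) count_cols[[1L]] else paste0("count_", channel)
  if (!col %in% names(records))
    fs_stop("config", "no column '%s' in records", col)
  counts <- records[[col]]
  n <- nrow(records)
  nbin <- max(floor(max(counts) / bin_width) + 1L, 1L)
  lo <- (seq_len(nbin) - 1L) * bin_width
  hist <- data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                     cell_count = vapply(lo, function(b)
                       sum(counts >= b & counts < b + bin_width), 0L))
  frac_active <- if (all(is.na(records$active))) NA_real_
                 else mean(records$active, na.rm = TRUE)
  nsh <- if (all(is.na(records$nascent_site_count))) NULL else {
    m <- max(records$nascent_site_count, na.rm = TRUE)
    stats::setNames(vapply(0:m, function(k)
      sum(records$nascent_site_count == k, na.rm = TRUE), 0L), 0:m)
  }
  structure(list(
    n_cells = n,
    mean_mrna_per_cell = mean(counts),
    sem = stats::sd(counts) / sqrt(n),
    histogram = hist,
    fraction_active = frac_active,
    nascent_site_histogram = nsh,
    channel = sub("^count_", "", col),
    bin_width = as.integer(bin_width)
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %d cells; mean %.1f mRNA/cell (SEM %.1f)",
              x$n_cells, x$mean_mrna_per_cell, x$sem))
  if (!is.na(x$fraction_active))
    cat(sprintf("; %.0f%% transcriptionally active", 100 * x$fraction_active))
  cat("\n")
  invisible(x)
}
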