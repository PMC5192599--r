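#' Default pipeline configuration
#'
#' All stage parameters with their defaults, as a nested list that
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param ... named overrides of top-level entries (partial lists are merged).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    optics = list(pixel_size_nm = 160, numerical_aperture = 1.46,
                  emission_wavelength_nm = list(exon = 600, intron = 680,
                                                dapi = 450)),
    channels = list(dapi = "dapi", exon = "exon", intron = "intron"),
    normalize = list(method = "minmax", probs = c(0.001, 0.999)),
    clahe = list(clip_limit = 0.01, tile_grid = c(8L, 8L)),
    segmentation = list(min_nucleus_area = 50, sigma_grad = 2,
                        sigma_seed = 1, seed_strategy = "edge",
                        use_foreground_mask = FALSE),
    detection = list(threshold = 0.6, min_separation = NULL,
                     ring_width_px = 2),
    nascent = list(colocal_radius_px = NULL),
    summary = list(bin_width = 15L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- run_config()
  over <- yaml::read_yaml(path)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

cfg_optics <- function(cfg) {
  optics_config(cfg$optics$pixel_size_nm, cfg$optics$numerical_aperture,
                unlist(cfg$optics$emission_wavelength_nm))
}

#' Run the full quantification workflow
#'
#' Executes the end-to-end analysis on a field of view: nuclear seed finding
#' from DAPI, watershed segmentation on the probe-autofluorescence surface,
#' two-pass correlation spot detection per probe channel, spot-to-cell
#' assignment, nascent-site calling on the intron channel, population
#' summary, and (optionally) all file outputs: seed list and per-channel spot
#' CSVs, cell table CSV, `summary.json`, nucleus-mask and false-color label
#' PNGs, the annotated overlay PNG, and `run.log`.
#'
#' @param fov a [field_of_view], or TIFF path(s) accepted by [read_field()].
#' @param config a [run_config()].
#' @param output_dir directory for outputs; `NULL` computes in memory only.
#' @param stage run up to this stage only: `"segmentation"`, `"detection"`,
#'   or `"all"` (default).
#' @param channel_map passed to [read_field()] when `fov` is a path.
#' @return a `pipeline_result` list: `seeds`, `labels`, `spots` (per
#'   channel), `records`, `summary`, `config`.
#' @export
run_pipeline <- function(fov, config = run_config(), output_dir = NULL,
                         stage = c("all", "segmentation", "detection"),
                         channel_map = NULL) {
  stage <- match.arg(stage)
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  optics <- cfg_optics(config)
  if (is.character(fov))
    fov <- read_field(fov, channel_map %||%
                        list(dapi = 1L, exon = 2L, intron = 3L), optics)
  stopifnot(inherits(fov, "field_of_view"))
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  out <- function(f) if (is.null(output_dir)) NULL else file.path(output_dir, f)

  ch <- config$channels
  exon_name <- ch$exon
  intron_name <- if (!is.null(ch$intron) && ch$intron %in%
                       names(fov$probe_channels)) ch$intron else NULL

  # --- segmentation -------------------------------------------------------
  say("stage segmentation: seeds (strategy=%s, min_area=%s)",
      config$segmentation$seed_strategy, config$segmentation$min_nucleus_area)
  seeds <- find_nuclear_seeds(
    fov$dapi,
    min_nucleus_area = config$segmentation$min_nucleus_area,
    clip_limit = config$clahe$clip_limit,
    tile_grid = config$clahe$tile_grid,
    sigma_seed = config$segmentation$sigma_seed,
    seed_strategy = config$segmentation$seed_strategy
  )
  say("stage segmentation: %d seed(s) found", nrow(seeds$seeds))
  labels <- NULL
  if (nrow(seeds$seeds) > 0L) {
    surface <- build_gradient_surface(
      fov$probe_channels[[exon_name]],
      sigma_grad = config$segmentation$sigma_grad,
      clip_limit = config$clahe$clip_limit,
      tile_grid = config$clahe$tile_grid
    )
    mask <- NULL
    if (isTRUE(config$segmentation$use_foreground_mask))
      mask <- surface > otsu_threshold(surface)
    labels <- watershed_cells(surface, seeds, mask)
    say("stage segmentation: watershed produced %d region(s)",
        length(setdiff(unique(as.vector(labels)), 0L)))
  }
  if (!is.null(output_dir)) {
    write.csv(seeds$seeds, out("seeds.csv"), row.names = FALSE, quote = FALSE)
    png::writePNG(seeds$nucleus_mask * 1, out("nucleus_mask.png"))
    if (!is.null(labels)) {
      # fixed false-color palette, deterministic without touching the RNG
      ids <- 0:max(labels)
      pal <- cbind((sin(ids * 12.9898) * 43758.5453) %% 1,
                   (sin(ids * 78.2330) * 26951.3721) %% 1,
                   (sin(ids * 37.7190) * 15731.7439) %% 1)
      pal[1L, ] <- 0
      rgb <- array(pal[labels + 1L, ], dim = c(dim(labels), 3L))
      png::writePNG(rgb, out("labels.png"))
    }
  }
  result <- list(seeds = seeds, labels = labels, config = config)
  class(result) <- "pipeline_result"
  if (stage == "segmentation" || is.null(labels)) {
    if (!is.null(output_dir)) writeLines(log_lines, out("run.log"))
    return(result)
  }

  # --- spot detection per probe channel ----------------------------------
  spots <- list()
  for (nm in names(fov$probe_channels)) {
    say("stage detection: channel '%s' (threshold=%.2f)", nm,
        config$detection$threshold)
    spots[[nm]] <- detect_channel(
      fov$probe_channels[[nm]], optics, channel = nm,
      threshold = config$detection$threshold,
      min_separation = config$detection$min_separation,
      ring_width_px = config$detection$ring_width_px,
      norm_probs = if (identical(config$normalize$method, "percentile"))
        unlist(config$normalize$probs) else NULL
    )
    say("stage detection: channel '%s' -> %d spot(s)", nm,
        nrow(spots[[nm]]$spots))
    if (!is.null(output_dir)) {
      sdf <- spots[[nm]]$spots
      write.csv(data.frame(x = sdf$x, y = sdf$y, score = round(sdf$score, 6),
                           channel = nm),
                out(sprintf("spots_%s.csv", nm)), row.names = FALSE,
                quote = FALSE)
    }
  }
  result$spots <- spots
  if (stage == "detection") {
    if (!is.null(output_dir)) writeLines(log_lines, out("run.log"))
    return(result)
  }

  # --- quantification -----------------------------------------------------
  say("stage quantify: assigning spots to cells")
  assignments <- lapply(spots, function(s) assign_spots(labels, s))
  nascent <- NULL
  if (!is.null(intron_name)) {
    r <- diffraction_radius_px(optics, intron_name)
    nascent <- call_nascent_sites(
      labels, seeds$nucleus_mask, spots[[intron_name]],
      exon_spots = spots[[exon_name]],
      colocal_radius_px = config$nascent$colocal_radius_px %||% r
    )
    say("stage quantify: %d extra-nuclear nascent spot(s) discarded",
        nascent$discarded)
  }
  records <- make_cell_records(labels, assignments, nascent)
  summary <- summarize_cells(records, channel = exon_name,
                             bin_width = config$summary$bin_width)
  say("stage quantify: %d cells, mean %.1f mRNA/cell", summary$n_cells,
      summary$mean_mrna_per_cell)

  if (!is.null(output_dir)) {
    write_cell_table(records, out("cells.csv"))
    js <- list(
      n_cells = summary$n_cells,
      mean_mrna_per_cell = summary$mean_mrna_per_cell,
      sem = summary$sem,
      fraction_active = summary$fraction_active,
      histogram = summary$histogram,
      nascent_site_histogram = as.list(summary$nascent_site_histogram),
      config = unclass(config)
    )
    jsonlite::write_json(js, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    counts <- stats::setNames(records[[paste0("count_", exon_name)]],
                              records$cell_id)
    write_annotated_overlay(fov, labels, spots, out("overlay.png"),
                            counts = counts)
    writeLines(log_lines, out("run.log"))
  }
  result$records <- records
  result$summary <- summary
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d seed(s)", nrow(x$seeds$seeds)))
  if (!is.null(x$spots))
    cat(sprintf("; spots: %s",
                paste(sprintf("%s=%d", names(x$spots),
                              vapply(x$spots, function(s) nrow(s$spots), 0L)),
                      collapse = ", ")))
  if (!is.null(x$summary))
    cat(sprintf("; mean %.1f mRNA/cell", x$summary$mean_mrna_per_cell))
  cat("\n")
  invisible(x)
}

#' Calibrate the correlation threshold against ground truth
#'
#' The correlation threshold trades false negatives against false positives;
#' it is chosen by comparison with known spots in test data. This sweeps a
#' threshold grid over truth-bearing synthetic scenes, scores precision,
#' recall and F1 at each value, and reports the F1-optimal threshold (ties
#' broken toward the higher threshold). The per-scene correlation maps are
#' computed once; thresholding commutes with non-maximum suppression, so the
#' sweep is exact and the detected count is non-increasing in the threshold.
#'
#' @param scenes list of `synthetic_scene`s (or a single scene).
#' @param grid numeric vector of thresholds to evaluate.
#' @param channel probe channel to calibrate on (default `"exon"`).
#' @param match_radius_px truth-matching radius (default 2).
#' @return list with `table` (data.frame `threshold`, `precision`, `recall`,
#'   `f1`, `n_spots`) and `best` (the F1-argmax threshold).
#' @export
calibrate_threshold <- function(scenes, grid = seq(0.3, 0.9, by = 0.05),
                                channel = "exon", match_radius_px = 2) {
  if (length(grid) == 0L) fs_stop("config", "threshold grid is empty")
  if (inherits(scenes, "synthetic_scene")) scenes <- list(scenes)
  grid <- sort(grid)

  per_scene <- lapply(scenes, function(sc) {
    optics <- sc$fov$optics
    stack <- sc$fov$probe_channels[[channel]]
    proj <- project(stack, "max", normalize_per_plane = TRUE)$pixels
    edges <- sobel_magnitude(proj)
    r <- diffraction_radius_px(optics, channel)
    res <- two_pass_candidates(edges, r)
    list(cand = res$candidates, min_sep = res$min_separation,
         truth = sc$truth_spots[[channel]])
  })

  rows <- lapply(grid, function(th) {
    tp <- 0L; nd <- 0L; nt <- 0L
    for (ps in per_scene) {
      sel <- ps$cand[ps$cand$score >= th, , drop = FALSE]
      ss <- new_spot_set(sel, channel, th, ps$min_sep)
      sc <- score_detection(ps$truth, ss, match_radius_px)
      tp <- tp + sc$tp; nd <- nd + nrow(sel); nt <- nt + nrow(ps$truth)
    }
    data.frame(threshold = th,
               precision = if (nd > 0L) tp / nd else NA_real_,
               recall = if (nt > 0L) tp / nt else NA_real_,
               f1 = if (nd > 0L && nt > 0L && tp > 0L)
                 2 * tp / (nd + nt) else NA_real_,
               n_spots = nd)
  })
  tab <- do.call(rbind, rows)
  f1 <- ifelse(is.na(tab$f1), -Inf, tab$f1)
  best <- tab$threshold[[max(which(f1 == max(f1)))]]
  list(table = tab, best = best)
}
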