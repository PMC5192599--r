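#' Parse an smFISH probe table
#'
#' Reads a plain-text table of singly labeled oligonucleotide probes, one probe
#' per line as `<index><sep><sequence>`, and returns a validated [probe_set].
#' Commercial smFISH probe sets (e.g. Stellaris designs) tile a transcript with
#' ~48 short oligos; the packaged fixtures are the published exon- and
#' intron-targeting sets against the Arabidopsis *PP2A* housekeeping gene.
#'
#' The separator (tab, comma, or whitespace) is detected per file. An optional
#' header line is skipped. Sequences are normalized to lower case.
#'
#' Published tables occasionally contain a truncated entry; by default a
#' non-uniform probe length therefore raises a warning rather than an error,
#' so the set remains usable while the anomaly is surfaced
#' (`length_check = "error"` enforces strict uniformity).
#'
#' @param path path to the probe table.
#' @param name free-text name for the set.
#' @param target_kind `"exonic"` (mRNA) or `"intronic"` (nascent transcripts).
#' @param length_check `"warn"` (default) or `"error"` for non-uniform lengths.
#' @return A `probe_set` object: list with `name`, `target_kind`, and `probes`
#'   (data.frame of `index`, `sequence`).
#' @examples
#' f <- system.file("extdata", "pp2a_exon_probes.txt", package = "fishspot")
#' ps <- parse_probe_table(f, "PP2A exon", "exonic")
#' probe_summary(ps)$count
#' @export
parse_probe_table <- function(path, name, target_kind = c("exonic", "intronic"),
                              length_check = c("warn", "error")) {
  target_kind <- match.arg(target_kind)
  length_check <- match.arg(length_check)
  if (!file.exists(path)) fs_stop("parse", "probe table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) fs_stop("parse", "probe table is empty: %s", path)

  # header = first line whose second field is not a DNA sequence
  first <- strsplit(trimws(lines[[1L]]), "[\t, ]+")[[1L]]
  has_header <- length(first) >= 2L &&
    (is.na(suppressWarnings(as.integer(first[[1L]]))) ||
       !grepl("^[acgtACGT]+$", first[[2L]]))
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) fs_stop("parse", "probe table has no data rows: %s", path)

  idx <- integer(length(body))
  seqs <- character(length(body))
  for (i in seq_along(body)) {
    lineno <- i + if (has_header) 1L else 0L
    fields <- strsplit(trimws(body[[i]]), "[\t, ]+")[[1L]]
    if (length(fields) != 2L)
      fs_stop("parse", "line %d: expected '<index><sep><sequence>', got %d field(s)",
              lineno, length(fields))
    n <- suppressWarnings(as.integer(fields[[1L]]))
    if (is.na(n) || n < 1L)
      fs_stop("parse", "line %d: probe index '%s' is not a positive integer",
              lineno, fields[[1L]])
    s <- tolower(fields[[2L]])
    if (!grepl("^[acgt]+$", s))
      fs_stop("validation", "line %d: sequence contains non-ACGT characters: '%s'",
              lineno, fields[[2L]])
    idx[[i]] <- n
    seqs[[i]] <- s
  }

  if (anyDuplicated(seqs))
    fs_stop("validation", "duplicate probe sequence: '%s'",
            seqs[duplicated(seqs)][[1L]])
  if (!identical(sort(idx), seq_along(idx)))
    fs_stop("validation", "probe indices are not 1..%d consecutive", length(idx))
  ord <- order(idx)
  idx <- idx[ord]; seqs <- seqs[ord]

  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    msg <- sprintf("probe lengths are not uniform (%s nt); offending probe(s): %s",
                   paste(sort(unique(lens)), collapse = "/"),
                   paste(idx[lens != as.integer(names(sort(table(lens),
                                                           decreasing = TRUE))[1L])],
                         collapse = ", "))
    if (length_check == "error") fs_stop("validation", "%s", msg) else fs_warn("%s", msg)
  }

  structure(
    list(name = name, target_kind = target_kind,
         probes = data.frame(index = idx, sequence = seqs,
                             stringsAsFactors = FALSE)),
    class = "probe_set"
  )
}

#' Construct a probe set from sequences
#'
#' @param sequences character vector of DNA sequences (indices are implied 1..N).
#' @inheritParams parse_probe_table
#' @return A `probe_set`.
#' @export
probe_set <- function(sequences, name = "probe set",
                      target_kind = c("exonic", "intronic")) {
  target_kind <- match.arg(target_kind)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(paste(seq_along(sequences), sequences, sep = "\t"), f)
  ps <- parse_probe_table(f, name, target_kind)
  ps
}

#' Write a probe set back to a plain-text table
#'
#' Tab-separated `<index>\t<sequence>` lines, no header; round-trips with
#' [parse_probe_table()] byte-identically up to case normalization.
#'
#' @param ps a `probe_set`.
#' @param path output path.
#' @export
write_probe_table <- function(ps, path) {
  stopifnot(inherits(ps, "probe_set"))
  writeLines(paste(ps$probes$index, ps$probes$sequence, sep = "\t"), path)
  invisible(path)
}

#' Summarize a probe set
#'
#' @param ps a `probe_set`.
#' @return list with `count`, `length` (modal probe length in nt), `lengths`
#'   (per probe), and `gc_fraction_per_probe`.
#' @export
probe_summary <- function(ps) {
  stopifnot(inherits(ps, "probe_set"))
  s <- ps$probes$sequence
  lens <- nchar(s)
  gc <- vapply(strsplit(s, ""), function(ch) mean(ch %in% c("g", "c")), 0)
  list(
    count = nrow(ps$probes),
    length = as.integer(names(sort(table(lens), decreasing = TRUE))[1L]),
    lengths = lens,
    gc_fraction_per_probe = gc
  )
}

#' @export
print.probe_set <- function(x, ...) {
  sm <- probe_summary(x)
  cat(sprintf("<probe_set> %s (%s): %d probes, %d nt\n",
              x$name, x$target_kind, sm$count, sm$length))
  invisible(x)
}
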