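#' Read intervals from a BED file
#'
#' BED coordinates are already 0-based half-open and are used as-is. Strand
#' `"."` (or a missing strand column) is treated as unstranded.
#'
#' @param path Path to a BED file (gz transparent).
#' @param kind One of `"bed3"` (chrom/start/end) or `"bed6"` (adds
#'   name/score/strand).
#' @param extra_cols Optional named character vector of additional columns
#'   appended after the `kind` columns; names become column names, values are
#'   readr single-letter type codes (e.g. `c(state = "i")`).
#' @param layout Optional genome layout for validation.
#' @return A tibble of intervals.
#' @export
read_bed <- function(path, kind = c("bed6", "bed3"), extra_cols = NULL,
                     layout = NULL) {
  kind <- match.arg(kind)
  base_names <- switch(kind,
    bed3 = c("chrom", "start", "end"),
    bed6 = c("chrom", "start", "end", "name", "score", "strand")
  )
  base_types <- switch(kind, bed3 = "cdd", bed6 = "cddcdc")
  x <- readr::read_tsv(path,
    col_names = c(base_names, names(extra_cols)),
    col_types = paste0(base_types, paste(extra_cols, collapse = "")),
    comment = "#", progress = FALSE
  )
  validate_intervals(x, layout, what = paste0("BED file ", path))
  if ("strand" %in% names(x)) {
    bad <- !x$strand %in% c("+", "-", ".")
    if (any(bad)) abort(sprintf("invalid strand value(s) in %s", path))
  }
  x
}

#' Write intervals to a BED file
#'
#' Emits `chrom`, `start`, `end` plus `name`, `score`, `strand` when present,
#' followed by any columns named in `extra_cols`.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @param extra_cols Character vector of additional column names to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = NULL) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  out <- x[, c(cols, extra_cols)]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a chromatin-state segmentation
#'
#' BED4-style file whose fourth column is the integer state label (1-15 for
#' the wheat hidden-Markov segmentation). Segments on one chromosome must not
#' overlap.
#'
#' @param path Path to the state BED.
#' @param layout Optional genome layout for validation.
#' @return A tibble with `chrom`, `start`, `end`, `state`.
#' @export
read_states <- function(path, layout = NULL) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "state"),
                       col_types = "cddi", comment = "#", progress = FALSE)
  validate_intervals(x, layout, what = "chromatin states")
  if (any(x$state < 1 | x$state > 15)) {
    abort("chromatin state labels must be in 1..15")
  }
  validate_states(x)
  x
}

validate_states <- function(states) {
  ok <- states |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    summarise(ok = all(.data$start[-1] >= .data$end[-n()]) || n() < 2) |>
    pull(.data$ok)
  if (!all(ok)) abort("chromatin-state segments overlap within a chromosome")
  invisible(states)
}

#' Read Hi-C contacts from BEDPE
#'
#' Standard ten-column BEDPE with the read-pair count in column 11.
#'
#' @param path Path to the BEDPE file.
#' @param layout Optional genome layout for validation.
#' @return A tibble with both anchors and `read_pairs`.
#' @export
read_hic_bedpe <- function(path, layout = NULL) {
  x <- readr::read_tsv(path,
    col_names = c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "name", "score", "strand1", "strand2", "read_pairs"),
    col_types = "cddcddcdcci", comment = "#", progress = FALSE
  )
  x <- select(x, -"name", -"score", -"strand1", -"strand2")
  validate_intervals(rename(x, chrom = "chrom1", start = "start1", end = "end1"),
                     layout, what = "Hi-C anchor 1")
  validate_intervals(
    select(x, chrom = "chrom2", start = "start2", end = "end2"),
    layout, what = "Hi-C anchor 2"
  )
  if (any(x$read_pairs < 1)) abort("Hi-C read_pairs must be >= 1")
  x
}

#' Write Hi-C contacts to BEDPE
#'
#' @param contacts Tibble as returned by [read_hic_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hic_bedpe <- function(contacts, path) {
  out <- contacts |>
    transmute(.data$chrom1, .data$start1, .data$end1,
              .data$chrom2, .data$start2, .data$end2,
              name = ".", score = 0, strand1 = ".", strand2 = ".",
              .data$read_pairs)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a histone/DNase peak panel
#'
#' A peak panel couples peak intervals (BED4: chrom, start, end, peak id) with
#' a signal matrix TSV (`peak_id`, `mark`, then one numeric column per panel
#' sample). All peaks must share the same ordered sample set; signals must be
#' non-negative.
#'
#' @param bed_path Path to the peak BED4.
#' @param signal_path Path to the signal-matrix TSV (with header).
#' @param layout Optional genome layout for validation.
#' @return A tibble with `peak_id`, `chrom`, `start`, `end`, `mark`, and a
#'   `signal` list-column of named numeric vectors (one value per sample).
#' @export
read_peak_panel <- function(bed_path, signal_path, layout = NULL) {
  peaks <- readr::read_tsv(bed_path,
    col_names = c("chrom", "start", "end", "peak_id"),
    col_types = "cddc", comment = "#", progress = FALSE
  )
  validate_intervals(peaks, layout, what = "peak panel")
  sig <- readr::read_tsv(signal_path, col_types = readr::cols(
    peak_id = readr::col_character(), mark = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  samples <- setdiff(names(sig), c("peak_id", "mark"))
  if (length(samples) < 1) abort("peak panel signal matrix has no sample columns")
  m <- as.matrix(sig[, samples])
  if (any(m < 0)) abort("peak panel signals must be >= 0")
  sig$signal <- lapply(seq_len(nrow(m)), function(i) setNames(m[i, ], samples))
  panel <- inner_join(select(sig, "peak_id", "mark", "signal"), peaks,
                      by = "peak_id") |>
    select("peak_id", "chrom", "start", "end", "mark", "signal")
  panel
}

#' Write a peak panel
#'
#' @param panel Panel tibble as returned by [read_peak_panel()].
#' @param bed_path Output BED4 path.
#' @param signal_path Output signal-matrix TSV path.
#' @return `bed_path`, invisibly.
#' @export
write_peak_panel <- function(panel, bed_path, signal_path) {
  peaks <- distinct(panel, .data$chrom, .data$start, .data$end, .data$peak_id)
  readr::write_tsv(peaks[, c("chrom", "start", "end", "peak_id")], bed_path,
                   col_names = FALSE, progress = FALSE)
  sig <- bind_cols(
    panel[, c("peak_id", "mark")],
    as_tibble(do.call(rbind, panel$signal))
  )
  readr::write_tsv(sig, signal_path, progress = FALSE)
  invisible(bed_path)
}

#' Read dual-luciferase reporter measurements
#'
#' TSV with header `construct_id  fluc  rluc  role`; `role` marks the
#' `blank` and `negative` control constructs (anything else is a candidate).
#'
#' @param path Path to the TSV.
#' @return A tibble of measurements.
#' @export
read_reporter <- function(path) {
  readr::read_tsv(path, col_types = "cddc", progress = FALSE)
}
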