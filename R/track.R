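#' Build a strand-specific 5'-end track
#'
#' Accumulates single-base polymerase 5'-end events (one BED6 record per
#' sequenced molecule; the 5' coordinate of the read marks the engaged
#' polymerase) into a sparse per-position, per-strand count track. This is the
#' primitive every downstream quantification reads from.
#'
#' @param events A BED6 path or a tibble with `chrom`, `start`, `end`,
#'   `strand` (each record exactly 1 bp wide, strand `+` or `-`).
#' @param layout Genome layout tibble ([read_chrom_sizes()]).
#' @return A `nascent_track` object: sparse counts plus `total_events` and the
#'   layout. The events-per-million normalization factor is
#'   `1e6 / total_events`.
#' @export
build_track <- function(events, layout) {
  if (is.character(events)) events <- read_bed(events, "bed6")
  validate_layout(layout)
  if (nrow(events) > 0) {
    if (any(events$end - events$start != 1)) {
      abort(paste0("5'-end event records must span exactly 1 bp; ",
                   "pre-extract read 5' ends before building a track"))
    }
    if (!all(events$strand %in% c("+", "-"))) {
      abort("5'-end events must be stranded (+ or -)")
    }
    validate_intervals(events, layout, what = "5'-end events")
  }
  counts <- events |>
    count(.data$chrom, .data$strand, pos = .data$start, name = "count") |>
    arrange(.data$chrom, .data$strand, .data$pos)
  new_track(counts, layout)
}

new_track <- function(counts, layout) {
  structure(
    list(counts = counts, total_events = sum(counts$count), layout = layout),
    class = "nascent_track"
  )
}

#' @export
print.nascent_track <- function(x, ...) {
  cat(sprintf(
    "<nascent_track> %s events at %s positions on %d chromosome(s)\n",
    format(x$total_events, big.mark = ","),
    format(nrow(x$counts), big.mark = ","), nrow(x$layout)
  ))
  invisible(x)
}

#' Events-per-million normalization factor of a track
#'
#' @param track A `nascent_track`.
#' @return `1e6 / total_events`.
#' @export
norm_factor <- function(track) {
  if (track$total_events == 0) {
    abort("cannot normalize a track with zero events")
  }
  1e6 / track$total_events
}

#' Normalized per-position densities of a track
#'
#' Each occupied position gets `count * 1e6 / total_events` (events per
#' million). Zero positions stay implicit; relative ratios between positions
#' are preserved exactly, and the densities sum to 1e6 over the genome.
#'
#' @param track A `nascent_track`.
#' @return A tibble `chrom`, `strand`, `pos`, `count`, `density`.
#' @export
track_density <- function(track) {
  mutate(track$counts, density = .data$count * norm_factor(track))
}

#' Merge replicate tracks
#'
#' Position-wise count sum; total events add up. All tracks must share one
#' genome layout.
#'
#' @param tracks A list of `nascent_track` objects (or several passed as
#'   `...`).
#' @param ... Additional tracks.
#' @return A merged `nascent_track`.
#' @export
merge_tracks <- function(tracks, ...) {
  if (inherits(tracks, "nascent_track")) tracks <- list(tracks, ...)
  if (length(tracks) < 1) abort("need at least one track to merge")
  ref <- tracks[[1]]$layout
  for (t in tracks[-1]) {
    if (!identical(ref[, c("chrom", "length")], t$layout[, c("chrom", "length")])) {
      abort("cannot merge tracks with mismatched genome layouts")
    }
  }
  counts <- purrr::map(tracks, "counts") |>
    bind_rows() |>
    count(.data$chrom, .data$strand, .data$pos, wt = .data$count,
          name = "count") |>
    arrange(.data$chrom, .data$strand, .data$pos)
  new_track(counts, ref)
}

#' Genome-wide binned density of a track
#'
#' Fixed tiling from position 0; the final partial bin is included. Densities
#' are events-per-million sums per bin, strand-summed unless `stranded`.
#'
#' @param track A `nascent_track`.
#' @param bin Bin width in bp (default 500, the replicate-correlation bin).
#' @param stranded Keep strands separate?
#' @return A tibble `chrom`, `bin_start` (plus `strand` if stranded) with a
#'   `density` column; every bin of the genome is present (zeros included).
#' @export
binned_density <- function(track, bin = 500, stranded = FALSE) {
  grid <- track$layout |>
    mutate(n_bins = ceiling(.data$length / bin)) |>
    reframe(bin_start = seq(0, by = bin, length.out = .data$n_bins),
            .by = "chrom")
  dens <- track_density(track) |>
    mutate(bin_start = (.data$pos %/% bin) * bin)
  if (stranded) {
    grid <- tidyr::crossing(grid, strand = c("+", "-"))
    dens <- count(dens, .data$chrom, .data$strand, .data$bin_start,
                  wt = .data$density, name = "density")
    out <- left_join(grid, dens, by = c("chrom", "strand", "bin_start"))
  } else {
    dens <- count(dens, .data$chrom, .data$bin_start,
                  wt = .data$density, name = "density")
    out <- left_join(grid, dens, by = c("chrom", "bin_start"))
  }
  mutate(out, density = tidyr::replace_na(.data$density, 0))
}

#' Replicate correlation of two tracks
#'
#' Pearson correlation of depth-normalized densities over all genome-wide
#' bins (500 bp by default, strand-summed by default). Because both tracks are
#' normalized to events per million first, the correlation is invariant to
#' sequencing depth.
#'
#' @param a,b `nascent_track` objects on the same layout.
#' @param bin Bin width in bp.
#' @param stranded Correlate per-strand densities instead of strand-summed?
#' @return Pearson r, or `NA` (with a warning) if either binned vector has
#'   zero variance.
#' @export
replicate_correlation <- function(a, b, bin = 500, stranded = FALSE) {
  if (!identical(a$layout[, c("chrom", "length")],
                 b$layout[, c("chrom", "length")])) {
    abort("tracks are on different genome layouts")
  }
  da <- binned_density(a, bin, stranded)$density
  db <- binned_density(b, bin, stranded)$density
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    warn("zero variance in binned densities; correlation undefined")
    return(NA_real_)
  }
  cor(da, db)
}

#' Windowed signal around anchor positions
#'
#' Sums normalized density in `[pos - flank, pos + flank]` around each anchor
#' (the +/-250 bp quantification window by default). Windows are clipped at
#' chromosome edges.
#'
#' @param track A `nascent_track`.
#' @param anchors A tibble with `chrom`, `pos` (0-based) and, for stranded
#'   modes, `strand`.
#' @param flank Half-window in bp.
#' @param strand_mode `"anchor"` restricts to the anchor's strand, `"opposite"`
#'   to the other strand, `"both"` sums both strands.
#' @return Numeric vector of densities, one per anchor row.
#' @export
window_signal <- function(track, anchors, flank = 250,
                          strand_mode = c("anchor", "opposite", "both")) {
  strand_mode <- match.arg(strand_mode)
  dens <- track_density(track)
  n <- nrow(anchors)
  out <- numeric(n)
  if (n == 0 || nrow(dens) == 0) return(out)
  qstrand <- switch(strand_mode,
    anchor = anchors$strand,
    opposite = chartr("+-", "-+", anchors$strand),
    both = rep(".", n)
  )
  key <- if (strand_mode == "both") dens$chrom else
    paste(dens$chrom, dens$strand)
  akey <- if (strand_mode == "both") anchors$chrom else
    paste(anchors$chrom, qstrand)
  for (k in unique(akey)) {
    sel <- which(key == k)
    rows <- which(akey == k)
    if (!length(sel)) next
    # strand groups can interleave positions; re-sort and cumulate
    pos <- dens$pos[sel]
    ord <- order(pos)
    pos <- pos[ord]
    cs <- cumsum(dens$density[sel][ord])
    hi <- findInterval(anchors$pos[rows] + flank, pos)
    lo <- findInterval(anchors$pos[rows] - flank - 1, pos)
    out[rows] <- ifelse(hi > 0, cs[pmax(hi, 1)], 0) -
      ifelse(lo > 0, cs[pmax(lo, 1)], 0)
  }
  out
}

#' Metaprofile matrix around anchors
#'
#' Bins normalized density in `[-flank, flank)` around each anchor, orienting
#' minus-strand anchors so that downstream of the anchor is always to the
#' right. Anchors lying off-chromosome yield rows of `NA`.
#'
#' @param track A `nascent_track`.
#' @param anchors Tibble with `chrom`, `pos`, `strand`.
#' @param flank Half-window (bp), default 3000.
#' @param bin Bin width (bp); `2 * flank / bin` columns.
#' @param strand_mode `"both"`, `"sense"` (events on the anchor strand) or
#'   `"antisense"`.
#' @return A numeric matrix, rows = anchors, columns = bins from upstream to
#'   downstream.
#' @export
metaprofile <- function(track, anchors, flank = 3000, bin = 100,
                        strand_mode = c("both", "sense", "antisense")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot((2 * flank) %% bin == 0)
  nbins <- as.integer(2 * flank / bin)
  m <- matrix(0, nrow = nrow(anchors), ncol = nbins)
  len <- track$layout$length[match(anchors$chrom, track$layout$chrom)]
  off <- is.na(len) | anchors$pos < 0 | anchors$pos >= len
  m[off, ] <- NA_real_
  dens <- track_density(track)
  if (nrow(dens) == 0 || all(off)) return(m)
  ev_gr <- points_gr(dens$chrom, dens$pos, dens$strand)
  ok <- which(!off)
  win <- tibble(
    chrom = anchors$chrom[ok],
    start = pmax(anchors$pos[ok] - flank, 0),
    end = pmin(anchors$pos[ok] + flank, len[ok])
  )
  hits <- GenomicRanges::findOverlaps(ev_gr, as_gr(win, use_strand = FALSE),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  row <- ok[si]
  sign <- ifelse(anchors$strand[row] == "-", -1, 1)
  offset <- sign * (dens$pos[qi] - anchors$pos[row])
  keep <- offset >= -flank & offset < flank
  if (strand_mode != "both") {
    same <- dens$strand[qi] == anchors$strand[row]
    keep <- keep & if (strand_mode == "sense") same else !same
  }
  if (any(keep)) {
    col <- (offset[keep] + flank) %/% bin + 1
    idx <- (row[keep] - 1) * nbins + col
    acc <- rowsum(dens$density[qi[keep]], idx)
    m[as.integer(rownames(acc))] <- acc[, 1]
  }
  m
}

#' Write track events back to BED6
#'
#' One record per occupied position with the count in the score column
#' (`expand = FALSE`), or one single-base record per event (`expand = TRUE`,
#' the same dialect [build_track()] consumes).
#'
#' @param events Event tibble (`chrom`, `start`, `end`, `strand`, optionally
#'   `name`/`score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  out <- transmute(events,
    .data$chrom, .data$start, .data$end,
    name = ".", score = 0, .data$strand
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
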