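#' Poisson background threshold for TSS detection
#'
#' Smallest raw count `k*` whose genome-wide Poisson upper tail
#' `P(X >= k | lambda)` is at most `alpha`, where `lambda` is the mean
#' per-base event rate of the strand. Counts at or above `k*` are unlikely
#' to arise from uniform background at level `alpha`.
#'
#' @param lambda Background rate (events per bp per strand).
#' @param alpha Upper-tail significance level, in (0, 1).
#' @return Integer threshold `k*`.
#' @export
tss_threshold <- function(lambda, alpha) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)")
  }
  # qpois gives the smallest m with P(X <= m) >= 1 - alpha,
  # i.e. P(X >= m + 1) <= alpha.
  qpois(1 - alpha, lambda) + 1L
}

#' Call transcription start sites from a track
#'
#' Per strand, a position is a TSS candidate when its raw count reaches both
#' the Poisson background threshold ([tss_threshold()], with the strand's
#' genome-wide mean rate as background) and `min_count`. Within any run of
#' candidates spaced closer than `collapse_dist` on one strand, only the
#' maximal-count position is kept (ties break to the leftmost), so one sharp
#' initiation site yields one call.
#'
#' @param track A `nascent_track` with at least one event.
#' @param alpha Poisson upper-tail level (default 1e-6).
#' @param min_count Minimum raw count per called position (default 5).
#' @param collapse_dist Candidates closer than this many bp collapse to the
#'   strongest (default 50).
#' @return A tibble of calls: `chrom`, `strand`, `pos`, `count`.
#' @export
call_tss <- function(track, alpha = 1e-6, min_count = 5, collapse_dist = 50) {
  if (track$total_events == 0) abort("cannot call TSSs on an empty track")
  genome_length <- sum(track$layout$length)
  calls <- track$counts |>
    mutate(
      lambda = sum(.data$count) / genome_length,
      .by = "strand"
    ) |>
    mutate(threshold = pmax(tss_threshold(.data$lambda[1], alpha), min_count),
           .by = "strand") |>
    filter(.data$count >= .data$threshold) |>
    select("chrom", "strand", "pos", "count")
  if (nrow(calls) == 0) return(calls)
  calls |>
    arrange(.data$chrom, .data$strand, .data$pos) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(run = cumsum(c(TRUE, diff(.data$pos) >= collapse_dist))) |>
    group_by(.data$chrom, .data$strand, .data$run) |>
    arrange(desc(.data$count), .data$pos, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("chrom", "strand", "pos", "count") |>
    arrange(.data$chrom, .data$strand, .data$pos)
}

#' Merge TSS calls into TSS clusters
#'
#' Single-linkage chaining per chromosome and strand: consecutive calls at
#' most `merge_dist` bp apart join one cluster, so one transcript dotted with
#' several called peaks becomes a single TSS cluster (TC). The cluster span
#' covers its member calls; the 5' end of the cluster w.r.t. its strand is
#' taken as the TSS.
#'
#' @param calls Call tibble from [call_tss()].
#' @param merge_dist Chaining distance in bp (default 3000).
#' @return A tibble of clusters: `tc_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `n_calls`, `count` (summed member counts).
#' @export
merge_tss_clusters <- function(calls, merge_dist = 3000) {
  if (nrow(calls) == 0) {
    return(tibble(tc_id = character(), chrom = character(), strand = character(),
                  start = double(), end = double(), tss = double(),
                  n_calls = integer(), count = double()))
  }
  calls |>
    arrange(.data$chrom, .data$strand, .data$pos) |>
    group_by(.data$chrom, .data$strand) |>
    mutate(run = cumsum(c(TRUE, diff(.data$pos) > merge_dist))) |>
    group_by(.data$chrom, .data$strand, .data$run) |>
    summarise(
      start = min(.data$pos), end = max(.data$pos) + 1,
      tss = if (.data$strand[1] == "-") max(.data$pos) else min(.data$pos),
      n_calls = n(), count = sum(.data$count), .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start, .data$strand) |>
    mutate(tc_id = sprintf("TC%06d", row_number())) |>
    select("tc_id", "chrom", "strand", "start", "end", "tss", "n_calls",
           "count")
}

#' Keep clusters supported by every replicate
#'
#' A merged-replicate cluster is retained only if every replicate contributes
#' at least one TSS call inside the cluster span on the same strand — the
#' all-replicates filter that removes technique noise.
#'
#' @param clusters Merged-track clusters from [merge_tss_clusters()].
#' @param replicate_calls A list of per-replicate call tibbles
#'   (from [call_tss()] on each replicate track).
#' @return The subset of `clusters` found in all replicates.
#' @export
replicate_consistent <- function(clusters, replicate_calls) {
  if (length(replicate_calls) == 0) {
    abort("need at least one replicate call set")
  }
  if (length(replicate_calls) == 1) {
    warn("single replicate: no cross-replicate filtering possible")
    return(clusters)
  }
  if (nrow(clusters) == 0) return(clusters)
  cl_gr <- GenomicRanges::GRanges(clusters$chrom,
    IRanges::IRanges(clusters$start + 1, clusters$end),
    strand = clusters$strand)
  keep <- rep(TRUE, nrow(clusters))
  for (calls in replicate_calls) {
    if (nrow(calls) == 0) return(clusters[FALSE, ])
    hit <- GenomicRanges::countOverlaps(
      cl_gr, points_gr(calls$chrom, calls$pos, calls$strand),
      ignore.strand = FALSE
    ) > 0
    keep <- keep & hit
  }
  clusters[keep, ]
}

#' Quantify TSS clusters
#'
#' Adds `signal_250`: normalized density in `tss +/- flank` restricted to the
#' cluster strand — the per-TC transcription level used for ranking and
#' decile grouping.
#'
#' @param tcs Cluster tibble.
#' @param track `nascent_track` to quantify on (usually the merged track).
#' @param flank Half-window in bp (default 250).
#' @return `tcs` with a `signal_250` column.
#' @export
quantify_tcs <- function(tcs, track, flank = 250) {
  anchors <- transmute(tcs, .data$chrom, pos = .data$tss, .data$strand)
  mutate(tcs, signal_250 = window_signal(track, anchors, flank, "anchor"))
}

#' Split TSS clusters into signal deciles
#'
#' Sorts by decreasing `signal_250` (ties broken by chromosome then TSS) and
#' assigns groups of size `floor(n/10)`, spreading the remainder over the top
#' groups; group 1 holds the strongest clusters. Group-mean signal is
#' non-increasing by construction.
#'
#' @param tcs Quantified cluster tibble (needs `signal_250`).
#' @param n_groups Number of groups (default 10).
#' @return `tcs`, sorted, with a `decile` column. With fewer clusters than
#'   groups, each cluster gets its own group (with a warning).
#' @export
decile_groups <- function(tcs, n_groups = 10) {
  n <- nrow(tcs)
  if (n < n_groups) {
    warn(sprintf("only %d clusters: returning %d singleton groups", n, n))
    n_groups <- max(n, 1L)
  }
  base <- n %/% n_groups
  rem <- n - base * n_groups
  sizes <- base + (seq_len(n_groups) <= rem)
  tcs |>
    arrange(desc(.data$signal_250), .data$chrom, .data$tss) |>
    mutate(decile = rep(seq_len(n_groups), times = sizes))
}
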