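#' Genome-coverage saturation curve under read subsampling
#'
#' Randomly subsamples the supplied read positions at each requested size,
#' bins the genome (10 kb by default), and calls a bin covered when at least
#' `cutoff` reads fall in it. With `nested = TRUE` (default) smaller
#' subsamples are subsets of larger ones drawn from a single seeded
#' permutation, so the covered fraction is non-decreasing in subsample size
#' and converges to the fraction of bins covered by the full data.
#'
#' @param events Read positions: a tibble with `chrom`, `pos` (or `start`)
#'   and optionally `count` (rows expanded accordingly), or a
#'   `nascent_track`.
#' @param layout Genome layout tibble (unless `events` is a track).
#' @param sizes Integer vector of subsample sizes; sizes above the available
#'   total are capped with a warning.
#' @param bin Bin width in bp (default 10000).
#' @param cutoff Reads per bin required for coverage (default 5).
#' @param seed Seed for the permutation.
#' @param nested Nested subsamples (default) or independent draws per size.
#' @return A tibble `size` (requested), `n_used`, `covered_bins`, `fraction`.
#' @export
coverage_saturation <- function(events, layout = NULL, sizes, bin = 10000,
                                cutoff = 5, seed = 1, nested = TRUE) {
  if (inherits(events, "nascent_track")) {
    layout <- events$layout
    events <- rename(events$counts, count = "count")
  }
  if (is.null(layout)) abort("a genome layout is required")
  if (!"pos" %in% names(events)) events <- rename(events, pos = "start")
  if ("count" %in% names(events)) {
    events <- tidyr::uncount(events, weights = .data$count)
  }
  total_bins <- sum(ceiling(layout$length / bin))
  n_avail <- nrow(events)
  sizes <- sort(unique(sizes))
  if (any(sizes > n_avail)) {
    warn(sprintf("subsample sizes capped at the %d available reads", n_avail))
  }
  bin_id <- paste(events$chrom, events$pos %/% bin)
  withr::with_seed(seed, {
    perm <- sample.int(n_avail)
    purrr::map(sizes, function(s) {
      k <- min(s, n_avail)
      idx <- if (nested) perm[seq_len(k)] else sample.int(n_avail, k)
      covered <- if (k == 0) 0L else sum(table(bin_id[idx]) >= cutoff)
      tibble(size = s, n_used = k, covered_bins = covered,
             fraction = covered / total_bins)
    }) |>
      bind_rows()
  })
}
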