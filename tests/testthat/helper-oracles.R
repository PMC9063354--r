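# Independent brute-force oracles, deliberately naive (O(n^2) scans and
# direct enumeration), used to cross-check the package's interval and
# statistical machinery.

brute_nearest_gene <- function(iv, genes) {
  vapply(seq_len(nrow(iv)), function(i) {
    g <- genes[genes$chrom == iv$chrom[i], ]
    if (nrow(g) == 0) return(Inf)
    min(pmax(0, pmax(g$start - iv$end[i], iv$start[i] - g$end)))
  }, numeric(1))
}

# Transitive-closure merge of calls within merge_dist, per chrom/strand.
brute_merge_clusters <- function(calls, merge_dist = 3000) {
  out <- list()
  for (key in unique(paste(calls$chrom, calls$strand))) {
    sub <- calls[paste(calls$chrom, calls$strand) == key, ]
    pos <- sort(sub$pos)
    comp <- rep(NA_integer_, length(pos))
    next_id <- 0L
    for (i in seq_along(pos)) {
      linked <- which(!is.na(comp) & abs(pos - pos[i]) <= merge_dist)
      if (length(linked)) {
        ids <- unique(comp[linked])
        comp[comp %in% ids] <- ids[1]
        comp[i] <- ids[1]
      } else {
        next_id <- next_id + 1L
        comp[i] <- next_id
      }
    }
    for (id in unique(comp)) {
      p <- pos[comp == id]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = sub$chrom[1], strand = sub$strand[1],
        start = min(p), end = max(p) + 1, n_calls = length(p)
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, strand, start)
}

brute_hic_support <- function(enh, prom, contacts) {
  total <- 0
  for (i in seq_len(nrow(contacts))) {
    c1 <- contacts[i, ]
    ov <- function(ch, s, e, r) ch == r$chrom && s < r$end && e > r$start
    o1e <- ov(c1$chrom1, c1$start1, c1$end1, enh)
    o1p <- ov(c1$chrom1, c1$start1, c1$end1, prom)
    o2e <- ov(c1$chrom2, c1$start2, c1$end2, enh)
    o2p <- ov(c1$chrom2, c1$start2, c1$end2, prom)
    if ((o1e && o2p) || (o2e && o1p)) total <- total + c1$read_pairs
  }
  total
}

brute_state_counts <- function(tcs, states) {
  vapply(seq_len(nrow(tcs)), function(i) {
    hit <- which(states$chrom == tcs$chrom[i] &
                   states$start <= tcs$tss[i] & tcs$tss[i] < states$end)
    if (length(hit)) as.character(states$state[hit[1]]) else "unassigned"
  }, character(1))
}

brute_window_signal <- function(track, anchors, flank, strand_mode = "anchor") {
  dens <- track_density(track)
  vapply(seq_len(nrow(anchors)), function(i) {
    sel <- dens$chrom == anchors$chrom[i] &
      dens$pos >= anchors$pos[i] - flank & dens$pos <= anchors$pos[i] + flank
    if (strand_mode == "anchor") {
      sel <- sel & dens$strand == anchors$strand[i]
    } else if (strand_mode == "opposite") {
      sel <- sel & dens$strand != anchors$strand[i]
    }
    sum(dens$density[sel])
  }, numeric(1))
}

# Smallest k with P(X >= k | lambda) <= alpha, by direct tail summation.
brute_poisson_threshold <- function(lambda, alpha, kmax = 1000) {
  tail_p <- 1 - cumsum(stats::dpois(0:kmax, lambda))  # P(X >= k+1)
  which(c(1, tail_p) <= alpha)[1] - 1L
}

# Mean pairwise haplotype difference per site, windowed; direct enumeration
# over all haplotype pairs.
brute_windowed_pi <- function(sites, gt, layout, window = 500) {
  hap <- function(g) switch(g, "0/0" = c(0, 0), "0/1" = c(0, 1),
                            "1/0" = c(1, 0), "1/1" = c(1, 1), NULL)
  pi_site <- vapply(seq_len(nrow(sites)), function(i) {
    h <- unlist(lapply(gt[i, ], hap))
    n <- length(h)
    if (n < 2) return(0)
    diffs <- 0
    pairs <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      diffs <- diffs + (h[a] != h[b])
      pairs <- pairs + 1
    }
    diffs / pairs
  }, numeric(1))
  grid <- dplyr::reframe(
    dplyr::mutate(layout, n_win = ceiling(length / window)),
    start = seq(0, by = window, length.out = n_win), .by = chrom
  )
  per <- dplyr::summarise(
    tibble::tibble(chrom = sites$chrom, start = (sites$pos %/% window) * window,
                   pi_site = pi_site),
    pi_sum = sum(pi_site), .by = c(chrom, start)
  )
  out <- dplyr::left_join(grid, per, by = c("chrom", "start"))
  out$pi <- ifelse(is.na(out$pi_sum), 0, out$pi_sum) / window
  out
}
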