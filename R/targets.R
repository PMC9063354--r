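#' Promoter windows of genes
#'
#' Strand-aware window around the annotated TSS: `up` bp upstream and `down`
#' bp downstream, clipped at chromosome edges. The promoter always overlaps
#' or abuts the gene body.
#'
#' @param genes Gene-model tibble.
#' @param up,down Extent upstream/downstream of the TSS in bp (defaults
#'   1000/500).
#' @param layout Optional genome layout for edge clipping.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
promoters_of <- function(genes, up = 1000, down = 500, layout = NULL) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  out <- genes |>
    transmute(
      .data$gene_id, .data$chrom,
      start = pmax(ifelse(.data$strand == "+", tss - up, tss - down), 0),
      end = ifelse(.data$strand == "+", tss + down, tss + up)
    )
  if (!is.null(layout)) {
    len <- layout$length[match(out$chrom, layout$chrom)]
    out <- mutate(out, end = pmin(.data$end, len))
  }
  out
}

# Strongest (max mean signal) panel peak overlapping each region, per mark.
# Returns tibble(id, mark, signal list-col).
strongest_peaks <- function(panel, regions) {
  if (nrow(panel) == 0 || nrow(regions) == 0) {
    return(tibble(id = character(), mark = character(), signal = list()))
  }
  hits <- GenomicRanges::findOverlaps(
    as_gr(regions, use_strand = FALSE),
    as_gr(panel, use_strand = FALSE),
    ignore.strand = TRUE
  )
  tibble(
    id = regions$id[S4Vectors::queryHits(hits)],
    mark = panel$mark[S4Vectors::subjectHits(hits)],
    signal = panel$signal[S4Vectors::subjectHits(hits)]
  ) |>
    mutate(mean_sig = vapply(.data$signal, mean, numeric(1))) |>
    group_by(.data$id, .data$mark) |>
    arrange(desc(.data$mean_sig), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("id", "mark", "signal")
}

#' Histone-signal correlation between an enhancer and a promoter
#'
#' Pearson correlation, across the panel samples, between the signal vector
#' of the strongest peak overlapping the enhancer and that of the strongest
#' peak overlapping the promoter, computed per mark. Pairs with no
#' overlapping peak on either side, or a zero-variance vector, get `NA`
#' (the pair fails the correlation criterion).
#'
#' @param enh One-row tibble (`chrom`, `start`, `end`) for the enhancer.
#' @param prom One-row tibble for the promoter window.
#' @param panel Peak panel ([read_peak_panel()]).
#' @return A tibble `mark`, `r`.
#' @export
pair_correlation <- function(enh, prom, panel) {
  pe <- strongest_peaks(panel, mutate(enh[1, ], id = "enh"))
  pp <- strongest_peaks(panel, mutate(prom[1, ], id = "prom"))
  marks <- unique(panel$mark)
  r <- vapply(marks, function(m) {
    a <- pe$signal[pe$mark == m]
    b <- pp$signal[pp$mark == m]
    if (length(a) == 0 || length(b) == 0) return(NA_real_)
    safe_cor(a[[1]], b[[1]])
  }, numeric(1))
  tibble(mark = marks, r = unname(r))
}

safe_cor <- function(a, b) {
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Hi-C read-pair support for an enhancer-promoter pair
#'
#' Sum of `read_pairs` over contacts with one anchor overlapping the enhancer
#' and the other overlapping the promoter, in either anchor orientation.
#'
#' @param enh,prom One-row interval tibbles.
#' @param contacts Hi-C contact tibble ([read_hic_bedpe()]).
#' @return Total supporting read pairs (0 if none).
#' @export
hic_support <- function(enh, prom, contacts) {
  sup <- hic_support_pairs(
    mutate(enh[1, ], id = "e"), mutate(prom[1, ], id = "p"), contacts
  )
  if (nrow(sup) == 0) 0L else sup$hic_pairs[1]
}

# Vectorized Hi-C support for all (enhancer, promoter) combinations present
# in the overlap structure; returns only pairs with support > 0.
hic_support_pairs <- function(enh, prom, contacts) {
  empty <- tibble(enh_id = character(), prom_id = character(),
                  hic_pairs = integer())
  if (nrow(contacts) == 0 || nrow(enh) == 0 || nrow(prom) == 0) return(empty)
  a1 <- as_gr(tibble(chrom = contacts$chrom1, start = contacts$start1,
                     end = contacts$end1), use_strand = FALSE)
  a2 <- as_gr(tibble(chrom = contacts$chrom2, start = contacts$start2,
                     end = contacts$end2), use_strand = FALSE)
  e_gr <- as_gr(enh, use_strand = FALSE)
  p_gr <- as_gr(prom, use_strand = FALSE)
  ov <- function(anchor, regions, ids) {
    h <- GenomicRanges::findOverlaps(anchor, regions, ignore.strand = TRUE)
    tibble(contact = S4Vectors::queryHits(h),
           id = ids[S4Vectors::subjectHits(h)])
  }
  orient1 <- inner_join(rename(ov(a1, e_gr, enh$id), enh_id = "id"),
                        rename(ov(a2, p_gr, prom$id), prom_id = "id"),
                        by = "contact", relationship = "many-to-many")
  orient2 <- inner_join(rename(ov(a2, e_gr, enh$id), enh_id = "id"),
                        rename(ov(a1, p_gr, prom$id), prom_id = "id"),
                        by = "contact", relationship = "many-to-many")
  bind_rows(orient1, orient2) |>
    distinct(.data$contact, .data$enh_id, .data$prom_id) |>
    mutate(read_pairs = contacts$read_pairs[.data$contact]) |>
    count(.data$enh_id, .data$prom_id, wt = .data$read_pairs,
          name = "hic_pairs")
}

#' Assign transcribed enhancers to target genes
#'
#' For every transcribed enhancer, candidate genes within `primary_dist`
#' (edge-to-edge, same chromosome) are tested against two criteria: the
#' histone-panel correlation between enhancer and promoter reaches
#' `corr_cutoff` for at least one mark, and at least one Hi-C read pair
#' connects them. Every passing candidate becomes a link. Only if no
#' candidate passes within `primary_dist` is the search expanded to
#' `expanded_dist` under the same criteria (links tagged
#' `expanded_2Mb`). Output ordering is deterministic, independent of the
#' input ordering of genes and contacts.
#'
#' @param enhancers Elements with `status` (only transcribed ones are
#'   searched).
#' @param genes Gene-model tibble.
#' @param panel Peak panel.
#' @param contacts Hi-C contact tibble.
#' @param corr_cutoff Minimum per-mark Pearson r (default 0.7).
#' @param primary_dist,expanded_dist Search radii in bp (500 kb / 2 Mb).
#' @param promoter_up,promoter_down Promoter window extents (bp).
#' @param layout Optional genome layout.
#' @return A link tibble: `enhancer_id`, `gene_id`, `chrom`, `distance`,
#'   `correlation`, `mark`, `hic_pairs`, `search_tier`.
#' @export
assign_targets <- function(enhancers, genes, panel, contacts,
                           corr_cutoff = 0.7, primary_dist = 5e5,
                           expanded_dist = 2e6, promoter_up = 1000,
                           promoter_down = 500, layout = NULL) {
  empty <- tibble(enhancer_id = character(), gene_id = character(),
                  chrom = character(), distance = double(),
                  correlation = double(), mark = character(),
                  hic_pairs = integer(), search_tier = character())
  enh <- if ("status" %in% names(enhancers)) {
    filter(enhancers, .data$status == "transcribed")
  } else {
    enhancers
  }
  if (nrow(enh) == 0 || nrow(genes) == 0) return(empty)

  proms <- promoters_of(genes, promoter_up, promoter_down, layout)
  # candidate pairs on shared chromosomes within the expanded radius
  cand <- inner_join(
    select(enh, enh_id = "enhancer_id", "chrom", e_start = "start",
           e_end = "end"),
    select(genes, "gene_id", "chrom", g_start = "start", g_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    mutate(distance = interval_gap(.data$e_start, .data$e_end,
                                   .data$g_start, .data$g_end)) |>
    filter(.data$distance <= expanded_dist)
  if (nrow(cand) == 0) return(empty)

  enh_peaks <- strongest_peaks(panel, transmute(enh, id = .data$enhancer_id,
                                                .data$chrom, .data$start,
                                                .data$end))
  prom_peaks <- strongest_peaks(panel, transmute(proms, id = .data$gene_id,
                                                 .data$chrom, .data$start,
                                                 .data$end))
  corr <- inner_join(rename(enh_peaks, enh_id = "id", enh_sig = "signal"),
                     rename(prom_peaks, gene_id = "id", prom_sig = "signal"),
                     by = "mark", relationship = "many-to-many") |>
    semi_join(cand, by = c("enh_id", "gene_id")) |>
    mutate(r = purrr::map2_dbl(.data$enh_sig, .data$prom_sig, safe_cor)) |>
    filter(!is.na(.data$r)) |>
    group_by(.data$enh_id, .data$gene_id) |>
    arrange(desc(.data$r), .data$mark, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("enh_id", "gene_id", correlation = "r", "mark")

  hic <- hic_support_pairs(
    transmute(enh, id = .data$enhancer_id, .data$chrom, .data$start, .data$end),
    transmute(proms, id = .data$gene_id, .data$chrom, .data$start, .data$end),
    contacts
  )

  scored <- cand |>
    left_join(corr, by = c("enh_id", "gene_id")) |>
    left_join(hic, by = c("enh_id" = "enh_id", "gene_id" = "prom_id")) |>
    mutate(hic_pairs = tidyr::replace_na(.data$hic_pairs, 0L),
           pass = !is.na(.data$correlation) &
             .data$correlation >= corr_cutoff & .data$hic_pairs >= 1)

  links <- scored |>
    filter(.data$pass) |>
    mutate(tier = ifelse(.data$distance <= primary_dist,
                         "primary_500kb", "expanded_2Mb")) |>
    group_by(.data$enh_id) |>
    filter(if (any(.data$tier == "primary_500kb")) {
      .data$tier == "primary_500kb"
    } else {
      TRUE
    }) |>
    ungroup()

  links |>
    transmute(
      enhancer_id = .data$enh_id, .data$gene_id, .data$chrom,
      .data$distance, .data$correlation, .data$mark, .data$hic_pairs,
      search_tier = .data$tier
    ) |>
    arrange(.data$enhancer_id, .data$gene_id)
}

#' Summarise target-gene expression by enhancer association
#'
#' Counts the transcribed enhancers linked to each gene and groups genes by
#' that count (0, 1, 2, 3+), for comparing expression with/without enhancer
#' association and across association multiplicity.
#'
#' @param links Link tibble ([assign_targets()]).
#' @param expression Expression tibble (`gene_id`, `level`).
#' @return A tibble `gene_id`, `level`, `n_enhancers`, `group`,
#'   `has_enhancer`. Linked genes absent from the expression table are
#'   dropped with a warning.
#' @export
target_expression_summary <- function(links, expression) {
  counts <- count(links, .data$gene_id, name = "n_enhancers")
  missing <- setdiff(counts$gene_id, expression$gene_id)
  if (length(missing)) {
    warn(sprintf("%d linked gene(s) missing from the expression table; excluded",
                 length(missing)))
  }
  expression |>
    left_join(counts, by = "gene_id") |>
    mutate(
      n_enhancers = tidyr::replace_na(.data$n_enhancers, 0L),
      group = factor(ifelse(.data$n_enhancers >= 3, "3+",
                            as.character(.data$n_enhancers)),
                     levels = c("0", "1", "2", "3+")),
      has_enhancer = .data$n_enhancers > 0
    )
}
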