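#' Classify TSS clusters as genic-proximal, masked, or intergenic
#'
#' A cluster whose span overlaps any annotated gene body (high or low
#' confidence) extended by `flank` bp on both sides — strand-agnostic — is
#' `genic_proximal`. Remaining clusters overlapping the coding-transcript
#' mask (assembled protein-coding transcripts not present in the annotation)
#' are `masked` and excluded from the intergenic set. Everything else is
#' `intergenic`.
#'
#' @param tcs Cluster tibble ([merge_tss_clusters()]).
#' @param genes Gene-model tibble.
#' @param coding_mask Optional tibble of mask intervals (`chrom`, `start`,
#'   `end`).
#' @param flank Gene flank in bp (default 1000).
#' @return `tcs` with a `genomic_class` column.
#' @export
classify_tcs <- function(tcs, genes, coding_mask = NULL, flank = 1000) {
  if (nrow(tcs) == 0) return(mutate(tcs, genomic_class = character()))
  tc_gr <- as_gr(tcs, use_strand = FALSE)
  flanked <- genes |>
    transmute(.data$chrom, start = pmax(.data$start - flank, 0),
              end = .data$end + flank)
  genic <- if (nrow(genes)) {
    GenomicRanges::countOverlaps(tc_gr, as_gr(flanked, use_strand = FALSE),
                                 ignore.strand = TRUE) > 0
  } else {
    rep(FALSE, nrow(tcs))
  }
  masked <- if (!is.null(coding_mask) && nrow(coding_mask)) {
    GenomicRanges::countOverlaps(tc_gr, as_gr(coding_mask, use_strand = FALSE),
                                 ignore.strand = TRUE) > 0
  } else {
    rep(FALSE, nrow(tcs))
  }
  mutate(tcs, genomic_class = case_when(
    genic ~ "genic_proximal",
    masked ~ "masked",
    TRUE ~ "intergenic"
  ))
}

#' Fractions of 5'-end events per genomic category
#'
#' Assigns every event to exactly one category by the priority
#' exon > intron > TSS1K > TES1K > intergenic, so genic signal is never
#' double-counted. TSS1K/TES1K are strand-aware: the 1 kb upstream of the
#' gene TSS and the 1 kb downstream of the transcription end site.
#'
#' @param track A `nascent_track`.
#' @param genes Gene-model tibble with `exons` list-column.
#' @param flank TSS1K/TES1K extent in bp (default 1000).
#' @return A tibble `category`, `n_events`, `fraction` (fractions sum to 1).
#' @export
read_category_fractions <- function(track, genes, flank = 1000) {
  cats <- c("exon", "intron", "TSS1K", "TES1K", "intergenic")
  dens <- track$counts
  if (nrow(dens) == 0) {
    return(tibble(category = factor(cats, cats), n_events = 0, fraction = NA_real_))
  }
  ev_gr <- points_gr(dens$chrom, dens$pos)
  assigned <- rep("intergenic", nrow(dens))
  overlaps_any <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, nrow(dens)))
    iv <- filter(iv, .data$end > .data$start)
    if (nrow(iv) == 0) return(rep(FALSE, nrow(dens)))
    GenomicRanges::countOverlaps(ev_gr, as_gr(iv, use_strand = FALSE),
                                 ignore.strand = TRUE) > 0
  }
  if (nrow(genes)) {
    exon_iv <- genes |>
      select("chrom", "exons") |>
      tidyr::unnest("exons")
    body_iv <- genes[, c("chrom", "start", "end")]
    plus <- genes$strand == "+"
    tss1k <- tibble(
      chrom = genes$chrom,
      start = pmax(ifelse(plus, genes$start - flank, genes$end), 0),
      end = ifelse(plus, genes$start, genes$end + flank)
    )
    tes1k <- tibble(
      chrom = genes$chrom,
      start = pmax(ifelse(plus, genes$end, genes$start - flank), 0),
      end = ifelse(plus, genes$end + flank, genes$start)
    )
    in_exon <- overlaps_any(exon_iv)
    in_body <- overlaps_any(body_iv)
    in_tss <- overlaps_any(tss1k)
    in_tes <- overlaps_any(tes1k)
    assigned[in_tes] <- "TES1K"
    assigned[in_tss] <- "TSS1K"
    assigned[in_body & !in_exon] <- "intron"
    assigned[in_exon] <- "exon"
  }
  tibble(category = factor(assigned, cats), n = dens$count) |>
    count(.data$category, wt = .data$n, name = "n_events", .drop = FALSE) |>
    mutate(fraction = .data$n_events / sum(.data$n_events))
}
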