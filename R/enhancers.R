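#' Define enhancer-like elements from a chromatin-state segmentation
#'
#' Keeps segments in the enhancer-associated states (5-7 in the 15-state
#' wheat segmentation: open chromatin, histone acetylation, CpG islands),
#' merges adjacent or overlapping kept segments into elements, and discards
#' any element closer than `min_gene_dist` bp (edge to edge) to an annotated
#' gene body, so elements are genuinely gene-distal.
#'
#' @param states State segmentation tibble ([read_states()]).
#' @param genes Gene-model tibble.
#' @param keep_states Integer states treated as enhancer-like (default 5:7).
#' @param min_gene_dist Minimum distance to the nearest gene, bp (default
#'   3000).
#' @return A tibble of elements: `enhancer_id`, `chrom`, `start`, `end`,
#'   `source_states` (comma-joined), `distance_to_gene`.
#' @export
define_enhancer_like <- function(states, genes, keep_states = 5:7,
                                 min_gene_dist = 3000) {
  kept <- filter(states, .data$state %in% keep_states)
  if (nrow(kept) == 0) {
    return(tibble(enhancer_id = character(), chrom = character(),
                  start = double(), end = double(),
                  source_states = character(), distance_to_gene = double()))
  }
  red <- GenomicRanges::reduce(as_gr(kept, use_strand = FALSE))
  elements <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = BiocGenerics::start(red) - 1,
    end = BiocGenerics::end(red)
  )
  hits <- GenomicRanges::findOverlaps(red, as_gr(kept, use_strand = FALSE))
  st <- tibble(i = S4Vectors::queryHits(hits),
               state = kept$state[S4Vectors::subjectHits(hits)]) |>
    summarise(source_states = paste(sort(unique(.data$state)), collapse = ","),
              .by = "i")
  elements$source_states <- st$source_states[match(seq_len(nrow(elements)), st$i)]
  elements |>
    nearest_gene_distance(genes) |>
    filter(.data$distance_to_gene >= min_gene_dist) |>
    arrange(.data$chrom, .data$start) |>
    mutate(enhancer_id = sprintf("ENH%05d", row_number())) |>
    select("enhancer_id", "chrom", "start", "end", "source_states",
           "distance_to_gene")
}

#' Mark elements as transcribed or untranscribed
#'
#' An element is `transcribed` when at least one intergenic TSS cluster
#' overlaps it on either strand (its eRNA evidence), `untranscribed`
#' otherwise.
#'
#' @param elements Element tibble ([define_enhancer_like()]).
#' @param tcs Classified cluster tibble; only rows with
#'   `genomic_class == "intergenic"` are used (a missing `genomic_class`
#'   column raises an error).
#' @return `elements` with `status`, `n_tcs_plus`, `n_tcs_minus` columns.
#' @export
assign_transcription <- function(elements, tcs) {
  if (!"genomic_class" %in% names(tcs)) {
    abort("TCs must be classified first (see classify_tcs())")
  }
  tcs <- filter(tcs, .data$genomic_class == "intergenic")
  map <- enhancer_tc_overlaps(elements, tcs)
  per <- map |>
    count(.data$enhancer_id, .data$strand) |>
    tidyr::pivot_wider(names_from = "strand", values_from = "n", values_fill = 0)
  if (!"+" %in% names(per)) per[["+"]] <- integer(nrow(per))
  if (!"-" %in% names(per)) per[["-"]] <- integer(nrow(per))
  elements |>
    left_join(per, by = "enhancer_id") |>
    mutate(
      n_tcs_plus = tidyr::replace_na(.data[["+"]], 0),
      n_tcs_minus = tidyr::replace_na(.data[["-"]], 0)
    ) |>
    select(-any_of(c("+", "-"))) |>
    mutate(status = ifelse(.data$n_tcs_plus + .data$n_tcs_minus > 0,
                           "transcribed", "untranscribed"))
}

#' Overlap map between elements and TSS clusters
#'
#' @param elements Element tibble.
#' @param tcs Cluster tibble.
#' @return A tibble `enhancer_id`, `tc_id`, `strand` with one row per
#'   overlapping element/cluster pair (any-strand, >= 1 shared base).
#' @export
enhancer_tc_overlaps <- function(elements, tcs) {
  if (nrow(elements) == 0 || nrow(tcs) == 0) {
    return(tibble(enhancer_id = character(), tc_id = character(),
                  strand = character()))
  }
  hits <- GenomicRanges::findOverlaps(
    as_gr(elements, use_strand = FALSE), as_gr(tcs, use_strand = FALSE),
    ignore.strand = TRUE
  )
  tibble(
    enhancer_id = elements$enhancer_id[S4Vectors::queryHits(hits)],
    tc_id = tcs$tc_id[S4Vectors::subjectHits(hits)],
    strand = tcs$strand[S4Vectors::subjectHits(hits)]
  )
}

#' Classify enhancer transcription directionality
#'
#' For each transcribed element, the per-strand signal is the normalized
#' density in a +/-250 bp window around the 5' end of the strongest
#' overlapping cluster on that strand. The more actively transcribed strand
#' is the primary strand (ties break to `+`). Elements with called clusters
#' on both strands are bidirectional (`BE`); with clusters on one strand,
#' unidirectional (`UE`) — for those the secondary signal is measured on the
#' opposite strand around the primary anchor. Untranscribed elements pass
#' through with `dir_class = "none"`; calling this on a table without any
#' transcribed element is an error.
#'
#' @param elements Elements with `status` ([assign_transcription()]).
#' @param track `nascent_track` used for signal quantification.
#' @param tcs Classified, quantified cluster tibble (needs `signal_250`; see
#'   [quantify_tcs()]).
#' @param flank Half-window for strand signals (default 250).
#' @return `elements` with `primary_strand`, `dir_class`, `signal_primary`,
#'   `signal_secondary`, `tss_primary` columns.
#' @export
classify_direction <- function(elements, track, tcs, flank = 250) {
  if (!"status" %in% names(elements)) {
    abort("elements must carry transcription status (see assign_transcription())")
  }
  if (!any(elements$status == "transcribed")) {
    abort("no transcribed elements to classify")
  }
  if (!"signal_250" %in% names(tcs)) tcs <- quantify_tcs(tcs, track, flank)
  map <- enhancer_tc_overlaps(elements, filter(tcs, .data$genomic_class == "intergenic"))
  best <- map |>
    inner_join(select(tcs, "tc_id", "tss", "signal_250"), by = "tc_id") |>
    group_by(.data$enhancer_id, .data$strand) |>
    arrange(desc(.data$signal_250), .data$tss, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  wide <- best |>
    select("enhancer_id", "strand", "tss", "signal_250") |>
    tidyr::pivot_wider(names_from = "strand",
                       values_from = c("tss", "signal_250"))
  for (col in c("tss_+", "tss_-", "signal_250_+", "signal_250_-")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- left_join(elements, wide, by = "enhancer_id")
  has_p <- !is.na(out[["tss_+"]])
  has_m <- !is.na(out[["tss_-"]])
  s_p <- out[["signal_250_+"]]
  s_m <- out[["signal_250_-"]]
  both <- has_p & has_m
  primary <- case_when(
    both & s_m > s_p ~ "-",
    both ~ "+",
    has_p ~ "+",
    has_m ~ "-",
    TRUE ~ NA_character_
  )
  tss_primary <- ifelse(primary == "+", out[["tss_+"]], out[["tss_-"]])
  sig_primary <- ifelse(primary == "+", s_p, s_m)
  # Secondary: the other strand's cluster signal when present, otherwise the
  # opposite-strand density around the primary anchor.
  sig_secondary <- ifelse(both, pmin(s_p, s_m, na.rm = TRUE), NA_real_)
  need <- which(!both & !is.na(primary))
  if (length(need)) {
    anchors <- tibble(chrom = out$chrom[need], pos = tss_primary[need],
                      strand = primary[need])
    sig_secondary[need] <- window_signal(track, anchors, flank, "opposite")
  }
  out |>
    mutate(
      primary_strand = ifelse(.data$status == "transcribed", primary, NA_character_),
      dir_class = case_when(
        .data$status != "transcribed" ~ "none",
        both ~ "BE",
        TRUE ~ "UE"
      ),
      signal_primary = ifelse(.data$status == "transcribed", sig_primary, NA_real_),
      signal_secondary = ifelse(.data$status == "transcribed", sig_secondary, NA_real_),
      tss_primary = ifelse(.data$status == "transcribed", tss_primary, NA_real_)
    ) |>
    select(-any_of(c("tss_+", "tss_-", "signal_250_+", "signal_250_-")))
}

#' Count TSS clusters per chromatin state
#'
#' Each cluster is assigned the state of the segment containing its TSS
#' (5' end); clusters whose TSS falls in no segment go to the `unassigned`
#' bucket. Counts over all buckets equal the number of clusters.
#'
#' @param tcs Cluster tibble.
#' @param states State segmentation tibble.
#' @return A tibble `state` (factor `1`..`15`, `unassigned`), `n_tcs`.
#' @export
state_tc_counts <- function(tcs, states) {
  levels <- c(as.character(1:15), "unassigned")
  assigned <- rep("unassigned", nrow(tcs))
  if (nrow(tcs) > 0 && nrow(states) > 0) {
    hits <- GenomicRanges::findOverlaps(
      points_gr(tcs$chrom, tcs$tss),
      as_gr(states, use_strand = FALSE),
      ignore.strand = TRUE, select = "first"
    )
    ok <- !is.na(hits)
    assigned[ok] <- as.character(states$state[hits[ok]])
  }
  tibble(state = factor(assigned, levels)) |>
    count(.data$state, name = "n_tcs", .drop = FALSE)
}
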