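#' Run the nascent-transcription analysis end to end
#'
#' Convenience wrapper chaining the full analysis: per-replicate tracks,
#' merged track, TSS calling with the all-replicates filter, TC
#' quantification and classification, enhancer-like element definition,
#' transcription status and directionality, and target assignment.
#'
#' @param reads List of per-replicate event tibbles (or BED6 paths).
#' @param layout Genome layout tibble.
#' @param genes Gene-model tibble.
#' @param states Chromatin-state segmentation tibble.
#' @param coding_mask Optional coding-transcript mask tibble.
#' @param panel Optional peak panel (enables target assignment).
#' @param contacts Optional Hi-C contacts (enables target assignment).
#' @param alpha,min_count [call_tss()] parameters.
#' @param corr_cutoff [assign_targets()] correlation cutoff.
#' @param min_gene_dist [define_enhancer_like()] distance filter.
#' @return A list: `track` (merged), `replicate_tracks`, `tcs` (classified,
#'   quantified, replicate-consistent), `enhancers` (with status and
#'   direction), `links` (NULL without panel/contacts).
#' @export
run_erna_analysis <- function(reads, layout, genes, states,
                              coding_mask = NULL, panel = NULL,
                              contacts = NULL, alpha = 1e-6, min_count = 5,
                              corr_cutoff = 0.7, min_gene_dist = 3000) {
  rep_tracks <- purrr::map(reads, build_track, layout = layout)
  track <- merge_tracks(rep_tracks)
  rep_calls <- purrr::map(rep_tracks, call_tss, alpha = alpha,
                          min_count = min_count)
  tcs <- call_tss(track, alpha = alpha, min_count = min_count) |>
    merge_tss_clusters() |>
    replicate_consistent(rep_calls) |>
    quantify_tcs(track) |>
    classify_tcs(genes, coding_mask)
  enhancers <- define_enhancer_like(states, genes,
                                    min_gene_dist = min_gene_dist) |>
    assign_transcription(tcs)
  if (any(enhancers$status == "transcribed")) {
    enhancers <- classify_direction(enhancers, track, tcs)
  }
  links <- NULL
  if (!is.null(panel) && !is.null(contacts)) {
    links <- assign_targets(enhancers, genes, panel, contacts,
                            corr_cutoff = corr_cutoff, layout = layout)
  }
  list(track = track, replicate_tracks = rep_tracks, tcs = tcs,
       enhancers = enhancers, links = links)
}
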