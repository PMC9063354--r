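# Shared fixtures, cached per test run so expensive simulations build once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_layout <- function(lengths = 1e5, chroms = "chr1A", subgenome = "A") {
  tibble::tibble(chrom = chroms, length = lengths,
                 subgenome = rep_len(subgenome, length(chroms)))
}

events_tbl <- function(chrom, pos, strand) {
  tibble::tibble(chrom = chrom, start = pos, end = pos + 1, strand = strand)
}

genes_tbl <- function(chrom, start, end, strand = "+",
                      gene_id = sprintf("g%03d", seq_along(start))) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = rep_len(strand, length(start)),
    start = start, end = end, confidence = "high",
    exons = purrr::map2(start, end, ~ tibble::tibble(start = .x, end = .y))
  )
}

# Mid-scale study for module tests (2 Mb chromosomes, 40 triads).
small_study <- function() {
  fixture("small_study", function() {
    simulate_erna_study(sim_config(seed = 42, chrom_length = 2e6,
                                   n_triads = 40, n_enhancers = 60))
  })
}

small_analysis <- function() {
  fixture("small_analysis", function() {
    s <- small_study()
    run_erna_analysis(s$reads, s$genome$layout, s$genome$genes,
                      s$landscape$states, s$landscape$coding_mask,
                      s$landscape$panel, s$landscape$contacts)
  })
}

# Default-scale "easy" study used by the recovery acceptance tests.
easy_study <- function() {
  fixture("easy_study", function() simulate_erna_study(sim_config(seed = 101)))
}

easy_analysis <- function() {
  fixture("easy_analysis", function() {
    s <- easy_study()
    run_erna_analysis(s$reads, s$genome$layout, s$genome$genes,
                      s$landscape$states, s$landscape$coding_mask,
                      s$landscape$panel, s$landscape$contacts)
  })
}

# 1:1 match between recovered elements and planted enhancers (by overlap).
match_truth <- function(enhancers, truth) {
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(enhancers$chrom,
                           IRanges::IRanges(enhancers$start + 1, enhancers$end)),
    GenomicRanges::GRanges(truth$chrom,
                           IRanges::IRanges(truth$start + 1, truth$end))
  )
  tibble::tibble(ei = S4Vectors::queryHits(hits),
                 ti = S4Vectors::subjectHits(hits))
}
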