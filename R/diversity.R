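#' Windowed nucleotide diversity from a VCF
#'
#' Per biallelic SNP, the per-site diversity is
#' `pi_site = 2 j (n - j) / (n (n - 1))` with `n` the called haplotypes
#' (2 per non-missing diploid genotype) and `j` the alternate-allele
#' haplotypes — the mean pairwise difference over all haplotype pairs at the
#' site. Window diversity is the sum of `pi_site` over the window divided by
#' the window length (the vcftools `--window-pi` convention), tiled from
#' position 0. Multiallelic and indel records are skipped with a message;
#' windows without variants get `pi = 0`.
#'
#' @param vcf Path to a VCF (plain or gzipped) or a `vcfR` object.
#' @param layout Genome layout tibble (defines the window grid).
#' @param window Window size in bp (default 500).
#' @return A tibble `chrom`, `start`, `end`, `subgenome`, `n_variants`, `pi`.
#' @export
windowed_pi <- function(vcf, layout, window = 500) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as_tibble(fix)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  skipped <- sum(!biallelic)
  if (skipped > 0) {
    inform(sprintf("skipped %d non-biallelic-SNP record(s)", skipped))
  }
  grid <- layout |>
    mutate(n_win = ceiling(.data$length / window)) |>
    reframe(start = seq(0, by = window, length.out = .data$n_win),
            .by = c("chrom", "subgenome")) |>
    mutate(end = .data$start + window)

  if (any(biallelic)) {
    gt <- gt[biallelic, , drop = FALSE]
    pos <- as.numeric(fix$POS[biallelic]) - 1  # VCF is 1-based
    chrom <- fix$CHROM[biallelic]
    called <- !is.na(gt) & !grepl("\\.", gt)
    alt <- matrix(stringr::str_count(gt, "1"), nrow = nrow(gt))
    alt[!called] <- 0
    n_hap <- 2 * rowSums(called)
    j <- rowSums(alt)
    pi_site <- ifelse(n_hap > 1, 2 * j * (n_hap - j) / (n_hap * (n_hap - 1)), 0)
    seg <- j > 0 & j < n_hap
    per_win <- tibble(
      chrom = chrom, start = (pos %/% window) * window,
      pi_site = pi_site, seg = seg
    ) |>
      summarise(pi_sum = sum(.data$pi_site), n_variants = sum(.data$seg),
                .by = c("chrom", "start"))
    grid <- left_join(grid, per_win, by = c("chrom", "start"))
  } else {
    grid$pi_sum <- NA_real_
    grid$n_variants <- NA_integer_
  }
  grid |>
    mutate(
      n_variants = tidyr::replace_na(.data$n_variants, 0L),
      pi = tidyr::replace_na(.data$pi_sum, 0) / window
    ) |>
    select("chrom", "start", "end", "subgenome", "n_variants", "pi")
}

#' Compare diversity of eRNA regions against random intergenic regions
#'
#' Computes the mean window diversity of each supplied region (transcribed
#' enhancers with eRNA) and of a length-matched set of random intergenic
#' regions sampled uniformly from the gene-free space of the same genome
#' (seeded). The output carries a per-subgenome breakdown.
#'
#' @param windows Windowed diversity tibble ([windowed_pi()]).
#' @param regions Regions of interest (`chrom`, `start`, `end`), e.g.
#'   transcribed enhancer elements.
#' @param genes Gene-model tibble (defines intergenic space as the complement
#'   of gene bodies).
#' @param layout Genome layout tibble.
#' @param n_random Number of random regions (default: one per observed
#'   region, length-matched).
#' @param seed Seed for the random sampling.
#' @return A tibble `class` (`"eRNA"`/`"random_intergenic"`), `chrom`,
#'   `start`, `end`, `subgenome`, `mean_pi`.
#' @export
region_diversity_compare <- function(windows, regions, genes, layout,
                                     n_random = nrow(regions), seed = 1) {
  random <- sample_intergenic_regions(
    lengths = sample_region_lengths(regions, n_random, seed),
    genes = genes, layout = layout, seed = seed
  )
  obs <- mutate(regions[, c("chrom", "start", "end")], class = "eRNA")
  rnd <- mutate(random, class = "random_intergenic")
  bind_rows(obs, rnd) |>
    region_mean_pi(windows) |>
    left_join(select(layout, "chrom", "subgenome"), by = "chrom") |>
    select("class", "chrom", "start", "end", "subgenome", "mean_pi")
}

# Mean pi over windows overlapping each region.
region_mean_pi <- function(regions, windows) {
  hits <- GenomicRanges::findOverlaps(
    as_gr(regions, use_strand = FALSE),
    as_gr(windows, use_strand = FALSE),
    ignore.strand = TRUE
  )
  mp <- tibble(i = S4Vectors::queryHits(hits),
               pi = windows$pi[S4Vectors::subjectHits(hits)]) |>
    summarise(mean_pi = mean(.data$pi), .by = "i")
  regions$mean_pi <- mp$mean_pi[match(seq_len(nrow(regions)), mp$i)]
  regions
}

sample_region_lengths <- function(regions, n_random, seed) {
  lens <- regions$end - regions$start
  withr::with_seed(seed, {
    if (n_random == length(lens)) lens else sample(lens, n_random, replace = TRUE)
  })
}

#' Sample random intergenic regions
#'
#' Draws regions of the requested lengths uniformly from the gene-free space
#' of the genome: a gap is chosen with probability proportional to the number
#' of valid start positions it offers for the region's length, then the start
#' is uniform within the gap. Every sampled region is fully intergenic and
#' on-genome.
#'
#' @param lengths Integer vector of region lengths (bp).
#' @param genes Gene-model tibble.
#' @param layout Genome layout tibble.
#' @param seed Seed.
#' @return A tibble `chrom`, `start`, `end`.
#' @export
sample_intergenic_regions <- function(lengths, genes, layout, seed = 1) {
  space <- if (nrow(genes)) {
    interval_complement(genes[, c("chrom", "start", "end")], layout)
  } else {
    transmute(layout, .data$chrom, start = 0, end = .data$length)
  }
  withr::with_seed(seed, {
    purrr::map(lengths, function(len) {
      slots <- pmax(space$end - space$start - len + 1, 0)
      if (sum(slots) == 0) {
        abort(sprintf("no intergenic gap can host a %d bp region", len))
      }
      g <- sample.int(nrow(space), 1, prob = slots)
      s <- space$start[g] + sample.int(slots[g], 1) - 1
      tibble(chrom = space$chrom[g], start = s, end = s + len)
    }) |>
      bind_rows()
  })
}
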