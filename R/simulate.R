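#' Configuration for the synthetic hexaploid study
#'
#' Defines every parameter of the toy-genome simulation: three subgenomes
#' with 1:1:1 homoeolog triads, genic transcription with TSS-proximal pausing
#' and exon-biased bodies, planted transcribed/untranscribed enhancer-like
#' elements with strand-specific eRNA spikes, a histone peak panel correlated
#' at true enhancer-promoter pairs, Hi-C contacts concentrated at true pairs,
#' a planted association between enhancer transcription and homoeolog
#' dominance, and reduced nucleotide diversity inside eRNA regions.
#'
#' Defaults describe a 3 x 5 Mb genome with 100 triads and 200 enhancers:
#' large enough for stable recovery statistics, small enough to simulate in
#' well under a minute.
#'
#' @param seed Integer master seed; every stage derives its stream from it.
#' @param n_chroms_per_subgenome,chrom_length Genome shape.
#' @param n_triads Homoeolog triads (3 genes each).
#' @param n_enhancers Enhancer-like elements planted >= 3 kb from genes.
#' @param frac_transcribed Fraction of elements carrying eRNA.
#' @param frac_bidirectional Fraction of transcribed elements with divergent
#'   (two-strand) initiation.
#' @param secondary_depth_frac Secondary-strand depth relative to primary at
#'   bidirectional elements.
#' @param genic_read_depth Mean 5'-end reads per gene per replicate (scaled
#'   by relative expression).
#' @param erna_read_depth Mean reads per transcribed-enhancer strand per
#'   replicate (scaled by the element's eRNA strength).
#' @param pausing_peak_weight Fraction of genic reads in the TSS-proximal
#'   pausing spike.
#' @param exon_intron_ratio Per-bp density ratio of exonic to intronic body
#'   reads.
#' @param background_rate Uniform background events per bp per strand per
#'   replicate.
#' @param n_replicates Biological replicates emitted.
#' @param planted_or Population odds ratio between enhancer side and dominant
#'   side among discordant homoeolog pairs (used by
#'   [simulate_discordant_pairs()]).
#' @param balanced_rate Fraction of discordant pairs with balanced
#'   expression.
#' @param target_expression_boost Multiplicative expression boost of true
#'   target genes.
#' @param panel_size Samples per peak-panel mark.
#' @param panel_marks Mark names in the panel.
#' @param panel_noise_sd Latent-space noise added to promoter-side panel
#'   signals (0 = noise-free; true pairs then correlate perfectly).
#' @param hic_pairs_true Mean extra read pairs at true pairs (each true pair
#'   gets at least one).
#' @param hic_pairs_false Mean read pairs at decoy pairs (0 = no false
#'   support).
#' @param frac_expanded_tier Fraction of transcribed enhancers whose only
#'   true target lies beyond 500 kb (exercises the 2 Mb expansion).
#' @param n_vcf_samples Diploid samples in the variant simulation.
#' @param diversity_baseline Expected per-site nucleotide diversity outside
#'   eRNA regions.
#' @param erna_reduction Fractional diversity reduction inside eRNA regions.
#' @param enhancer_width Min/max element width (bp).
#' @param min_gene_dist Distance kept between planted elements and genes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms_per_subgenome = 1L,
                       chrom_length = 5e6,
                       n_triads = 100L,
                       n_enhancers = 200L,
                       frac_transcribed = 0.5,
                       frac_bidirectional = 0.35,
                       secondary_depth_frac = 0.7,
                       genic_read_depth = 50,
                       erna_read_depth = 30,
                       pausing_peak_weight = 0.4,
                       exon_intron_ratio = 3,
                       background_rate = 2e-4,
                       n_replicates = 4L,
                       planted_or = 1.5,
                       balanced_rate = 0.4,
                       target_expression_boost = 2,
                       panel_size = 8L,
                       panel_marks = c("H3K27ac", "H3K9ac"),
                       panel_noise_sd = 0,
                       hic_pairs_true = 3,
                       hic_pairs_false = 0,
                       frac_expanded_tier = 0.1,
                       n_vcf_samples = 20L,
                       diversity_baseline = 0.003,
                       erna_reduction = 0.5,
                       enhancer_width = c(800, 2000),
                       min_gene_dist = 3000) {
  cfg <- as.list(environment())
  fracs <- c(cfg$frac_transcribed, cfg$frac_bidirectional,
             cfg$secondary_depth_frac, cfg$balanced_rate,
             cfg$frac_expanded_tier, cfg$erna_reduction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  rates <- c(cfg$genic_read_depth, cfg$erna_read_depth, cfg$background_rate,
             cfg$hic_pairs_true, cfg$hic_pairs_false, cfg$diversity_baseline)
  if (any(rates < 0)) abort("rates must be >= 0")
  if (cfg$planted_or <= 0) abort("planted_or must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate the toy hexaploid genome
#'
#' Places one homoeolog per subgenome at jittered syntenic positions for each
#' triad; genes get 2-6 exons, a shared triad strand, a confidence class, and
#' log-normal base expression (triad-correlated with per-gene divergence).
#' Gene intervals never overlap within a chromosome.
#'
#' @param cfg A [sim_config()].
#' @return A list: `layout`, `genes` (with `subgenome`, `homoeolog_group`,
#'   `exons`), `homoeolog_map`, `expression` (base levels, before landscape
#'   effects).
#' @export
simulate_genome <- function(cfg) {
  withr::with_seed(cfg$seed + 101L, {
    subg <- c("A", "B", "D")
    layout <- tidyr::crossing(i = seq_len(cfg$n_chroms_per_subgenome),
                              subgenome = subg) |>
      transmute(chrom = paste0("chr", .data$i, .data$subgenome),
                length = cfg$chrom_length, subgenome = .data$subgenome) |>
      arrange(.data$chrom)

    triads <- tibble(
      triad = seq_len(cfg$n_triads),
      chrom_i = ((seq_len(cfg$n_triads) - 1) %% cfg$n_chroms_per_subgenome) + 1,
      strand = sample(c("+", "-"), cfg$n_triads, replace = TRUE),
      base_expr = rlnorm(cfg$n_triads, meanlog = 1, sdlog = 0.7)
    ) |>
      mutate(slot = row_number(), .by = "chrom_i")

    per_chrom <- max(table(triads$chrom_i))
    margin <- 0.03 * cfg$chrom_length
    spacing <- (cfg$chrom_length - 2 * margin) / per_chrom

    genes <- tidyr::crossing(triads, subgenome = subg) |>
      mutate(
        chrom = paste0("chr", .data$chrom_i, .data$subgenome),
        gene_len = round(runif(n(), 1500, 6000)),
        center = margin + (.data$slot - 0.5) * spacing +
          runif(n(), -0.08, 0.08) * spacing,
        start = round(.data$center - .data$gene_len / 2),
        end = .data$start + .data$gene_len,
        gene_id = sprintf("gene%04d%s", .data$triad, .data$subgenome),
        homoeolog_group = sprintf("TRIAD%04d", .data$triad),
        confidence = sample(c("high", "low"), n(), replace = TRUE,
                            prob = c(0.9, 0.1)),
        level = .data$base_expr * rlnorm(n(), 0, 0.15)
      )
    genes$exons <- purrr::map2(genes$start, genes$end, sim_exons)
    genes <- genes |>
      select("gene_id", "chrom", "strand", "start", "end", "confidence",
             "exons", "subgenome", "homoeolog_group", "level") |>
      arrange(.data$chrom, .data$start)

    overlap <- genes |>
      arrange(.data$chrom, .data$start) |>
      summarise(bad = any(.data$start[-1] < .data$end[-n()]) && n() > 1,
                .by = "chrom")
    if (any(overlap$bad)) {
      abort("could not place genes without overlap; lower n_triads")
    }

    hmap <- genes |>
      select("homoeolog_group", "subgenome", "gene_id") |>
      tidyr::pivot_wider(names_from = "subgenome", values_from = "gene_id",
                         names_prefix = "gene_") |>
      rename(group_id = "homoeolog_group")

    list(
      layout = layout,
      genes = select(genes, -"level"),
      homoeolog_map = hmap,
      expression = select(genes, "gene_id", "level")
    )
  })
}

# 2-6 non-overlapping exons spanning the gene, first and last at the ends.
sim_exons <- function(start, end) {
  n_ex <- sample(2:6, 1)
  n_seg <- 2 * n_ex - 1
  w <- runif(n_seg, 0.5, 1.5)
  w <- w / sum(w) * (end - start)
  bounds <- start + round(cumsum(c(0, w)))
  bounds[length(bounds)] <- end
  idx <- seq(1, n_seg, by = 2)
  tibble(start = bounds[idx], end = bounds[idx + 1])
}

#' Simulate the regulatory landscape
#'
#' Places enhancer-like elements in kept chromatin states (5-7) at least
#' 3 kb from any gene, decoy segments in other states (including kept-state
#' segments deliberately placed too close to genes, which the distance filter
#' must discard), masked intergenic coding units, planted eRNA status and
#' directionality, true enhancer-target pairs (a configurable fraction only
#' reachable through the 2 Mb expansion), a latent-factor peak panel whose
#' true pairs share signal vectors, Hi-C contacts guaranteed at true pairs,
#' and the final expression table with the target boost applied.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return A list with `states`, `coding_mask`, `enhancers` (truth),
#'   `links` (truth), `panel`, `contacts`, `expression`, `masked_units`, and
#'   the latent matrices used to rebuild the panel at any noise level
#'   ([rebuild_panel()]).
#' @export
simulate_regulatory_landscape <- function(cfg, genome) {
  withr::with_seed(cfg$seed + 202L, {
    layout <- genome$layout
    genes <- genome$genes

    slots <- intergenic_slots(genes, layout, clearance = cfg$min_gene_dist + 1200,
                              step = 9000)
    need <- cfg$n_enhancers + cfg$n_enhancers %/% 2 + 5L
    if (nrow(slots) < need) {
      abort("not enough intergenic space for the requested enhancer count")
    }
    slots <- slice_sample(slots, n = nrow(slots))  # shuffle
    enh_slots <- slots[seq_len(cfg$n_enhancers), ]
    decoy_slots <- slots[cfg$n_enhancers + seq_len(cfg$n_enhancers %/% 2), ]
    mask_slots <- slots[cfg$n_enhancers + cfg$n_enhancers %/% 2 + 1:5, ]

    width <- round(runif(cfg$n_enhancers, cfg$enhancer_width[1],
                         cfg$enhancer_width[2]))
    enh <- tibble(
      enhancer_id = sprintf("TRUE_ENH%04d", seq_len(cfg$n_enhancers)),
      chrom = enh_slots$chrom,
      start = round(enh_slots$center - width / 2),
      end = round(enh_slots$center + width / 2),
      transcribed = runif(cfg$n_enhancers) < cfg$frac_transcribed
    ) |>
      mutate(
        bidirectional = .data$transcribed &
          runif(n()) < cfg$frac_bidirectional,
        primary_strand = ifelse(.data$transcribed,
                                sample(c("+", "-"), n(), replace = TRUE),
                                NA_character_),
        tss_primary = ifelse(.data$transcribed,
                             .data$start +
                               round(runif(n(), 0.35, 0.65) * (.data$end - .data$start)),
                             NA_real_),
        tss_secondary = ifelse(.data$bidirectional,
                               .data$tss_primary -
                                 ifelse(.data$primary_strand == "+", 1, -1) *
                                 sample(80:150, n(), replace = TRUE),
                               NA_real_),
        erna_strength = ifelse(.data$transcribed, exp(runif(n(), 0, 0.8)), 0)
      ) |>
      arrange(.data$chrom, .data$start)

    # state segments: enhancers (some split into two kept states), near-gene
    # kept-state decoys, and far decoys in non-kept states
    enh_states <- purrr::pmap(enh[, c("chrom", "start", "end")],
      function(chrom, start, end) {
        if (runif(1) < 0.2) {
          cut <- round(runif(1, start + 100, end - 100))
          st <- sample(5:7, 2)
          tibble(chrom = chrom, start = c(start, cut), end = c(cut, end),
                 state = st)
        } else {
          tibble(chrom = chrom, start = start, end = end,
                 state = sample(5:7, 1))
        }
      }) |>
      bind_rows()
    near_genes <- slice_sample(genes, n = min(30, nrow(genes)))
    near_decoys <- tibble(
      chrom = near_genes$chrom,
      start = near_genes$end + round(runif(nrow(near_genes), 200, 1500)),
      state = sample(5:7, nrow(near_genes), replace = TRUE)
    ) |>
      mutate(end = .data$start + round(runif(n(), 400, 1200)))
    far_decoys <- tibble(
      chrom = decoy_slots$chrom,
      start = round(decoy_slots$center - 500),
      end = round(decoy_slots$center + 500),
      state = sample(c(1:4, 8:15), nrow(decoy_slots), replace = TRUE)
    )
    states <- bind_rows(enh_states, near_decoys, far_decoys) |>
      arrange(.data$chrom, .data$start)

    masked_units <- tibble(
      unit_id = sprintf("MASKED%02d", seq_len(nrow(mask_slots))),
      chrom = mask_slots$chrom,
      start = round(mask_slots$center - 500),
      end = round(mask_slots$center + 500)
    )
    coding_mask <- transmute(masked_units, .data$chrom,
                             start = .data$start - 200, end = .data$end + 200)

    links <- plant_targets(cfg, enh, genes)

    expression <- genome$expression |>
      mutate(level = .data$level *
               ifelse(.data$gene_id %in% links$gene_id,
                      cfg$target_expression_boost, 1))

    # latent factors for the peak panel; promoter noise stored so the panel
    # can be rebuilt deterministically at any noise level
    latents <- panel_latents(cfg, enh, genes, links)
    panel <- rebuild_panel(cfg, latents, noise_sd = cfg$panel_noise_sd)

    contacts <- plant_contacts(cfg, enh, genes, links)

    list(
      states = states, coding_mask = coding_mask, enhancers = enh,
      links = links, masked_units = masked_units, expression = expression,
      panel = panel, panel_latents = latents, contacts = contacts
    )
  })
}

# Candidate placement slots: centers of 9-kb steps through gene-free gaps,
# keeping `clearance` bp away from the flanking genes.
intergenic_slots <- function(genes, layout, clearance, step) {
  gaps <- interval_complement(genes[, c("chrom", "start", "end")], layout)
  gaps |>
    mutate(lo = .data$start + clearance, hi = .data$end - clearance) |>
    filter(.data$hi - .data$lo > step) |>
    purrr::pmap(function(chrom, lo, hi, ...) {
      tibble(chrom = chrom,
             center = seq(lo + step / 2, hi - step / 2, by = step))
    }) |>
    bind_rows()
}

plant_targets <- function(cfg, enh, genes) {
  available <- genes$gene_id
  out <- list(tibble(enhancer_id = character(), gene_id = character(),
                     distance = double(), tier = character()))
  transcribed <- filter(enh, .data$transcribed)
  expanded <- runif(nrow(transcribed)) < cfg$frac_expanded_tier
  for (i in seq_len(nrow(transcribed))) {
    e <- transcribed[i, ]
    cand <- genes |>
      filter(.data$chrom == e$chrom, .data$gene_id %in% available) |>
      mutate(gap = interval_gap(e$start, e$end, .data$start, .data$end))
    pool <- if (expanded[i]) {
      filter(cand, .data$gap > 6e5, .data$gap <= 1.9e6)
    } else {
      filter(cand, .data$gap > 0, .data$gap <= 4.8e5)
    }
    k <- min(if (expanded[i]) 1L else sample(1:2, 1), nrow(pool))
    if (k == 0) next
    chosen <- slice_sample(pool, n = k)
    available <- setdiff(available, chosen$gene_id)
    out[[length(out) + 1]] <- tibble(
      enhancer_id = e$enhancer_id, gene_id = chosen$gene_id,
      distance = chosen$gap,
      tier = ifelse(expanded[i], "expanded_2Mb", "primary_500kb")
    )
  }
  bind_rows(out)
}

panel_latents <- function(cfg, enh, genes, links) {
  n_e <- nrow(enh)
  n_g <- nrow(genes)
  marks <- cfg$panel_marks
  enh_lat <- lapply(marks, function(m) {
    matrix(rnorm(n_e * cfg$panel_size), nrow = n_e,
           dimnames = list(enh$enhancer_id, NULL))
  })
  gene_lat <- lapply(marks, function(m) {
    matrix(rnorm(n_g * cfg$panel_size), nrow = n_g,
           dimnames = list(genes$gene_id, NULL))
  })
  names(enh_lat) <- names(gene_lat) <- marks
  # true-target promoters share their enhancer's latent vector
  for (m in marks) {
    gi <- match(links$gene_id, genes$gene_id)
    ei <- match(links$enhancer_id, enh$enhancer_id)
    gene_lat[[m]][gi, ] <- enh_lat[[m]][ei, ]
  }
  gene_eps <- lapply(marks, function(m) {
    matrix(rnorm(n_g * cfg$panel_size), nrow = n_g,
           dimnames = list(genes$gene_id, NULL))
  })
  names(gene_eps) <- marks
  list(enh_lat = enh_lat, gene_lat = gene_lat, gene_eps = gene_eps,
       enh = enh[, c("enhancer_id", "chrom", "start", "end")],
       promoters = promoters_of(genes),
       samples = paste0("S", seq_len(cfg$panel_size)))
}

#' Rebuild the peak panel at a given promoter-side noise level
#'
#' The panel's enhancer peaks are fixed; promoter-side signal vectors are
#' `exp(latent + noise_sd * eps)` with `latent` and `eps` frozen in the
#' landscape, so sweeping `noise_sd` degrades true-pair correlations
#' deterministically (common random numbers).
#'
#' @param cfg A [sim_config()].
#' @param latents `panel_latents` element of a landscape.
#' @param noise_sd Latent-space noise standard deviation.
#' @return A peak-panel tibble ([read_peak_panel()] format).
#' @export
rebuild_panel <- function(cfg, latents, noise_sd = 0) {
  rows <- list()
  for (m in names(latents$enh_lat)) {
    e_sig <- exp(latents$enh_lat[[m]])
    p_sig <- exp(latents$gene_lat[[m]] + noise_sd * latents$gene_eps[[m]])
    rows[[length(rows) + 1]] <- latents$enh |>
      transmute(
        peak_id = paste0("pk_", .data$enhancer_id, "_", m),
        .data$chrom, .data$start, .data$end, mark = m,
        signal = lapply(seq_len(n()),
                        function(i) setNames(e_sig[i, ], latents$samples))
      )
    rows[[length(rows) + 1]] <- latents$promoters |>
      transmute(
        peak_id = paste0("pk_", .data$gene_id, "_", m),
        .data$chrom, start = pmax(.data$start, 0), .data$end, mark = m,
        signal = lapply(seq_len(n()),
                        function(i) setNames(p_sig[i, ], latents$samples))
      )
  }
  bind_rows(rows)
}

plant_contacts <- function(cfg, enh, genes, links) {
  proms <- promoters_of(genes)
  true_c <- links |>
    inner_join(select(enh, "enhancer_id", e_chrom = "chrom",
                      e_start = "start", e_end = "end"), by = "enhancer_id") |>
    inner_join(select(proms, "gene_id", p_chrom = "chrom",
                      p_start = "start", p_end = "end"), by = "gene_id") |>
    transmute(
      chrom1 = .data$e_chrom, start1 = .data$e_start, end1 = .data$e_end,
      chrom2 = .data$p_chrom, start2 = pmax(.data$p_start, 0),
      end2 = .data$p_end,
      read_pairs = 1L + rpois(n(), max(cfg$hic_pairs_true - 1, 0))
    )
  false_c <- NULL
  if (cfg$hic_pairs_false > 0) {
    n_false <- nrow(true_c)
    fe <- slice_sample(enh, n = n_false, replace = TRUE)
    fg <- slice_sample(proms, n = n_false, replace = TRUE)
    decoy <- tibble(
      chrom1 = fe$chrom, start1 = fe$start, end1 = fe$end,
      chrom2 = fg$chrom, start2 = pmax(fg$start, 0), end2 = fg$end,
      read_pairs = rpois(n_false, cfg$hic_pairs_false),
      pair_key = paste(fe$enhancer_id, fg$gene_id)
    )
    truth_key <- paste(links$enhancer_id, links$gene_id)
    false_c <- decoy |>
      filter(.data$read_pairs >= 1, !.data$pair_key %in% truth_key) |>
      select(-"pair_key")
  }
  bind_rows(true_c, false_c)
}

#' Simulate per-replicate nascent 5'-end reads
#'
#' Genic reads mix a TSS-proximal pausing spike with body reads whose per-bp
#' density favours exons over introns; transcribed enhancers get a sharp
#' primary-strand initiation spike (plus a divergent secondary spike when
#' bidirectional) with a short downstream tail; masked units are transcribed
#' like eRNAs; uniform Poisson background covers both strands. Replicates
#' are independent Poisson draws sharing all planted positions.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param landscape Output of [simulate_regulatory_landscape()].
#' @param n_replicates Number of replicates (default `cfg$n_replicates`).
#' @return A list of event tibbles (`chrom`, `start`, `end`, `strand`), one
#'   per replicate.
#' @export
simulate_nascent_reads <- function(cfg, genome, landscape,
                                   n_replicates = cfg$n_replicates) {
  genes <- genome$genes
  expr <- landscape$expression$level[match(genes$gene_id,
                                           landscape$expression$gene_id)]
  rel <- expr / mean(expr)
  layout <- genome$layout
  seg_tbl <- gene_segments(genes, cfg$exon_intron_ratio)
  purrr::map(seq_len(n_replicates), function(rep_i) {
    withr::with_seed(cfg$seed + 303L + rep_i, {
      genic <- sim_genic_reads(cfg, genes, rel, seg_tbl)
      erna <- sim_erna_reads(cfg, landscape)
      masked <- sim_spike_reads(
        chrom = landscape$masked_units$chrom,
        tss = landscape$masked_units$start,
        strand = rep("+", nrow(landscape$masked_units)),
        depth = rep(cfg$erna_read_depth, nrow(landscape$masked_units))
      )
      bg <- sim_background_reads(cfg, layout)
      reads <- bind_rows(genic, erna, masked, bg)
      len <- layout$length[match(reads$chrom, layout$chrom)]
      reads |>
        mutate(pos = pmin(pmax(.data$pos, 0), len - 1)) |>
        transmute(.data$chrom, start = .data$pos, end = .data$pos + 1,
                  .data$strand) |>
        arrange(.data$chrom, .data$start, .data$strand)
    })
  })
}

gene_segments <- function(genes, exon_intron_ratio) {
  ex <- genes |>
    select("gene_id", "chrom", "strand", "exons") |>
    tidyr::unnest("exons") |>
    mutate(kind = "exon")
  body <- genes[, c("gene_id", "chrom", "strand", "start", "end")]
  introns <- ex |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    mutate(next_start = lead(.data$start)) |>
    ungroup() |>
    filter(!is.na(.data$next_start), .data$next_start > .data$end) |>
    transmute(.data$gene_id, .data$chrom, .data$strand,
              start = .data$end, end = .data$next_start, kind = "intron")
  bind_rows(ex, introns) |>
    mutate(weight = (.data$end - .data$start) *
             ifelse(.data$kind == "exon", exon_intron_ratio, 1))
}

sim_genic_reads <- function(cfg, genes, rel, seg_tbl) {
  n_reads <- rpois(nrow(genes), cfg$genic_read_depth * rel)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  sgn <- ifelse(genes$strand == "+", 1, -1)
  out <- purrr::map(which(n_reads > 0), function(i) {
    n <- n_reads[i]
    n_pause <- rbinom(1, n, cfg$pausing_peak_weight)
    pause_pos <- tss[i] + sgn[i] * ifelse(runif(n_pause) < 0.5, 0,
                                          sample(1:150, n_pause, replace = TRUE))
    segs <- seg_tbl[seg_tbl$gene_id == genes$gene_id[i], ]
    si <- sample.int(nrow(segs), n - n_pause, replace = TRUE,
                     prob = segs$weight)
    body_pos <- segs$start[si] +
      floor(runif(n - n_pause) * (segs$end[si] - segs$start[si]))
    tibble(chrom = genes$chrom[i], pos = c(pause_pos, body_pos),
           strand = genes$strand[i])
  })
  bind_rows(out)
}

# Concentrated initiation spike: 80% at the exact TSS, 10% within +/-2 bp,
# 10% in a 200-bp downstream tail.
sim_spike_reads <- function(chrom, tss, strand, depth) {
  out <- purrr::map(seq_along(tss), function(i) {
    n <- rpois(1, depth[i])
    if (n == 0) return(NULL)
    u <- runif(n)
    sgn <- if (strand[i] == "+") 1 else -1
    pos <- ifelse(u < 0.8, tss[i],
                  ifelse(u < 0.9,
                         tss[i] + sample(c(-2, -1, 1, 2), n, replace = TRUE),
                         tss[i] + sgn * sample(10:200, n, replace = TRUE)))
    tibble(chrom = chrom[i], pos = pos, strand = strand[i])
  })
  bind_rows(out)
}

sim_erna_reads <- function(cfg, landscape) {
  enh <- filter(landscape$enhancers, .data$transcribed)
  primary <- sim_spike_reads(enh$chrom, enh$tss_primary, enh$primary_strand,
                             cfg$erna_read_depth * enh$erna_strength)
  be <- filter(enh, .data$bidirectional)
  secondary <- sim_spike_reads(
    be$chrom, be$tss_secondary, chartr("+-", "-+", be$primary_strand),
    cfg$erna_read_depth * cfg$secondary_depth_frac * be$erna_strength
  )
  bind_rows(primary, secondary)
}

sim_background_reads <- function(cfg, layout) {
  purrr::map(c("+", "-"), function(s) {
    n <- rpois(1, cfg$background_rate * sum(layout$length))
    ci <- sample.int(nrow(layout), n, replace = TRUE,
                     prob = layout$length)
    tibble(chrom = layout$chrom[ci],
           pos = floor(runif(n) * layout$length[ci]),
           strand = s)
  }) |>
    bind_rows()
}

#' Simulate a population VCF with reduced diversity in eRNA regions
#'
#' Biallelic SNPs are planted at a Poisson per-bp rate calibrated so the
#' expected per-site diversity equals `diversity_baseline` genome-wide; sites
#' inside transcribed-enhancer (eRNA) intervals are thinned by
#' `erna_reduction`. Alternate-allele counts are uniform over the folded
#' frequency spectrum; genotypes are assigned by random haplotype draws over
#' `n_vcf_samples` diploids.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param landscape Output of [simulate_regulatory_landscape()].
#' @return A list: `sites` tibble (`chrom`, `pos`, `j_alt`), `gt` character
#'   matrix (sites x samples), `samples`.
#' @export
simulate_variants <- function(cfg, genome, landscape) {
  withr::with_seed(cfg$seed + 404L, {
    n_hap <- 2L * cfg$n_vcf_samples
    js <- seq_len(n_hap %/% 2)
    mean_pi_site <- mean(2 * js * (n_hap - js) / (n_hap * (n_hap - 1)))
    rate <- cfg$diversity_baseline / mean_pi_site
    erna <- landscape$enhancers |>
      filter(.data$transcribed) |>
      select("chrom", "start", "end")
    sites <- purrr::pmap(genome$layout[, c("chrom", "length")],
      function(chrom, length) {
        n <- rpois(1, rate * length)
        tibble(chrom = chrom, pos = sort(sample.int(length, n)) - 1)
      }) |>
      bind_rows()
    if (nrow(erna) > 0 && cfg$erna_reduction > 0) {
      inside <- GenomicRanges::countOverlaps(
        points_gr(sites$chrom, sites$pos),
        as_gr(erna, use_strand = FALSE), ignore.strand = TRUE
      ) > 0
      keep <- !inside | runif(nrow(sites)) >= cfg$erna_reduction
      sites <- sites[keep, ]
    }
    sites$j_alt <- sample.int(n_hap %/% 2, nrow(sites), replace = TRUE)
    gt_codes <- c("0/0", "0/1", "1/1")
    gt <- vapply(sites$j_alt, function(j) {
      hap <- sample.int(n_hap, j)
      gt_codes[tabulate((hap + 1L) %/% 2L, cfg$n_vcf_samples) + 1L]
    }, character(cfg$n_vcf_samples))
    gt <- t(matrix(gt, nrow = cfg$n_vcf_samples))
    samples <- sprintf("CULTIVAR%02d", seq_len(cfg$n_vcf_samples))
    colnames(gt) <- samples
    list(sites = sites, gt = gt, samples = samples)
  })
}

#' Write simulated variants to a VCF file
#'
#' @param variants Output of [simulate_variants()].
#' @param path Output path (`.vcf`, plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", variants$samples), collapse = "\t")
  )
  if (nrow(variants$sites) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt_cols <- apply(variants$gt, 1, paste, collapse = "\t")
  body <- paste(variants$sites$chrom, variants$sites$pos + 1, ".", "A", "T",
                ".", "PASS", ".", "GT", gt_cols, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate reporter-assay measurements
#'
#' Dual-luciferase constructs for a sample of transcribed and untranscribed
#' enhancers, plus blank and negative controls: relative intensity grows
#' with the element's planted eRNA strength, the negative control sits at
#' 1.6 and the blank at 1.0 by construction.
#'
#' @param cfg A [sim_config()].
#' @param landscape Output of [simulate_regulatory_landscape()].
#' @param n_each Constructs per class (default 18).
#' @return A measurement tibble (`construct_id`, `fluc`, `rluc`, `role`,
#'   `enhancer_id`).
#' @export
simulate_reporter <- function(cfg, landscape, n_each = 18) {
  withr::with_seed(cfg$seed + 505L, {
    tr <- filter(landscape$enhancers, .data$transcribed) |>
      slice_sample(n = min(n_each, sum(landscape$enhancers$transcribed)))
    un <- filter(landscape$enhancers, !.data$transcribed) |>
      slice_sample(n = min(n_each, sum(!landscape$enhancers$transcribed)))
    cand <- bind_rows(
      mutate(tr, rel = pmax(0.1, 0.8 + 1.6 * .data$erna_strength +
                              rnorm(n(), 0, 0.3))),
      mutate(un, rel = pmax(0.1, 0.9 + rnorm(n(), 0, 0.3)))
    )
    blank_rel <- 2.0
    meas <- bind_rows(
      tibble(construct_id = "blank", rel = 1, role = "blank",
             enhancer_id = NA_character_),
      tibble(construct_id = "negative", rel = 1.6, role = "negative",
             enhancer_id = NA_character_),
      transmute(cand, construct_id = paste0("cons_", .data$enhancer_id),
                .data$rel, role = "candidate", enhancer_id = .data$enhancer_id)
    )
    meas |>
      mutate(
        rluc = runif(n(), 800, 1200),
        fluc = .data$rel * blank_rel * .data$rluc
      ) |>
      select("construct_id", "fluc", "rluc", "role", "enhancer_id")
  })
}

#' Solve dominance-outcome probabilities for a planted odds ratio
#'
#' Among discordant pairs, outcomes are: enhancer-bearing homoeolog dominant
#' (probability `p_enh`), enhancer-free homoeolog dominant (`p_free`), or
#' balanced (fixed `balanced_rate`). `p_enh` is solved so the population odds
#' ratio of the [pair_contingency()] table — odds of the enhancer side being
#' dominant versus the enhancer-free side — equals `or`.
#'
#' @param or Planted odds ratio (> 0).
#' @param balanced_rate Balanced-outcome probability.
#' @return Named vector `c(p_enh, p_free, p_balanced)`.
#' @export
dominance_probs <- function(or, balanced_rate = 0.4) {
  stopifnot(or > 0, balanced_rate >= 0, balanced_rate < 1)
  q <- 1 - balanced_rate
  f <- function(p_enh) {
    p_free <- q - p_enh
    (p_enh * (1 - p_free)) / (p_free * (1 - p_enh)) - or
  }
  p_enh <- uniroot(f, c(q * 1e-6, q * (1 - 1e-6)), tol = 1e-12)$root
  c(p_enh = p_enh, p_free = q - p_enh, p_balanced = balanced_rate)
}

#' Simulate discordant homoeolog pair records at a planted odds ratio
#'
#' Generates `n` discordant pairs (the enhancer equally likely on either
#' subgenome) whose expression values realize the dominance outcomes drawn
#' from [dominance_probs()], so that [bias_call()] + [pair_contingency()] +
#' [odds_ratio()] estimate an odds ratio whose population value is exactly
#' `or`. Used for estimator-level calibration.
#'
#' @param n Number of discordant pairs.
#' @param or Planted odds ratio.
#' @param balanced_rate Balanced-outcome probability.
#' @param fc_threshold,min_expr The [bias_call()] gates the records are built
#'   to respect.
#' @param seed Seed.
#' @return A pair tibble compatible with [bias_call()].
#' @export
simulate_discordant_pairs <- function(n, or, balanced_rate = 0.4,
                                      fc_threshold = 2, min_expr = 0.5,
                                      seed = 1) {
  probs <- dominance_probs(or, balanced_rate)
  withr::with_seed(seed, {
    enh_a <- runif(n) < 0.5
    outcome <- sample(c("enh", "free", "bal"), n, replace = TRUE, prob = probs)
    base <- pmax(rlnorm(n, 0, 1), 2 * min_expr)
    hi <- base * fc_threshold * (1 + rexp(n, 2))
    bal <- base * runif(n, 1 / fc_threshold + 0.06, fc_threshold - 0.12)
    dom_a <- (outcome == "enh" & enh_a) | (outcome == "free" & !enh_a)
    expr_a <- ifelse(outcome == "bal", base, ifelse(dom_a, hi, base))
    expr_b <- ifelse(outcome == "bal", bal, ifelse(dom_a, base, hi))
    tibble(
      group_id = sprintf("PAIR%05d", seq_len(n)),
      gene_a = paste0("gA", seq_len(n)), gene_b = paste0("gB", seq_len(n)),
      expr_a = expr_a, expr_b = expr_b,
      enh_a = enh_a, enh_b = !enh_a,
      pairing = "simulated"
    )
  })
}

#' Run the full synthetic study
#'
#' Chains genome, landscape, reads, variants, and reporter simulation under
#' one master seed and bundles the planted truth.
#'
#' @param cfg A [sim_config()].
#' @return A list: `cfg`, `genome`, `landscape`, `reads`, `variants`,
#'   `reporter`, `truth`.
#' @export
simulate_erna_study <- function(cfg) {
  genome <- simulate_genome(cfg)
  landscape <- simulate_regulatory_landscape(cfg, genome)
  reads <- simulate_nascent_reads(cfg, genome, landscape)
  variants <- simulate_variants(cfg, genome, landscape)
  reporter <- simulate_reporter(cfg, landscape)
  truth <- list(
    enhancers = landscape$enhancers,
    links = landscape$links,
    masked_units = landscape$masked_units,
    config_hash = rlang::hash(unclass(cfg))
  )
  list(cfg = cfg, genome = genome, landscape = landscape, reads = reads,
       variants = variants, reporter = reporter, truth = truth)
}

#' Write a simulated study to disk
#'
#' Emits every pipeline input in its standard on-disk format (chrom sizes,
#' GFF3 genes, state/mask BEDs, per-replicate 5'-end BED6, peak panel BED +
#' signal TSV, Hi-C BEDPE, VCF, expression/homoeolog/reporter TSVs), the
#' machine-readable ground truth as JSON, and a manifest listing files, seed,
#' and configuration hash. Rerunning with the same configuration reproduces
#' the manifest byte-for-byte.
#'
#' @param sim Output of [simulate_erna_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(sim$genome$layout, p("chrom.sizes"), col_names = FALSE,
                   progress = FALSE)
  write_gff3(sim$genome$genes, p("genes.gff3"))
  readr::write_tsv(sim$genome$homoeolog_map, p("homoeologs.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$landscape$expression, p("expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$landscape$states, p("states.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(sim$landscape$coding_mask, p("mask.bed"), col_names = FALSE,
                   progress = FALSE)
  read_files <- sprintf("reads.rep%d.bed", seq_along(sim$reads))
  purrr::walk2(sim$reads, read_files, function(r, f) write_events_bed(r, p(f)))
  write_peak_panel(sim$landscape$panel, p("panel.bed"), p("panel.tsv"))
  write_hic_bedpe(sim$landscape$contacts, p("contacts.bedpe"))
  write_vcf(sim$variants, p("variants.vcf"))
  readr::write_tsv(sim$reporter, p("reporter.tsv"), progress = FALSE)
  truth <- list(
    enhancers = sim$truth$enhancers,
    links = sim$truth$links,
    masked_units = sim$truth$masked_units,
    config_hash = sim$truth$config_hash
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  manifest <- list(
    seed = sim$cfg$seed,
    config_hash = sim$truth$config_hash,
    files = c("chrom.sizes", "genes.gff3", "homoeologs.tsv", "expression.tsv",
              "states.bed", "mask.bed", read_files, "panel.bed", "panel.tsv",
              "contacts.bedpe", "variants.vcf", "reporter.tsv", "truth.json")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
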