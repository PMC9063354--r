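mk_panel <- function(...) {
  # each ... is list(id, chrom, start, end, mark, signal)
  rows <- lapply(list(...), function(p) {
    tibble::tibble(peak_id = p[[1]], chrom = p[[2]], start = p[[3]],
                   end = p[[4]], mark = p[[5]],
                   signal = list(setNames(p[[6]], paste0("S", seq_along(p[[6]])))))
  })
  dplyr::bind_rows(rows)
}

test_that("promoter windows are strand-aware and abut the gene body", {
  genes <- dplyr::bind_rows(
    genes_tbl("chr1A", 10000, 20000, "+", "gP"),
    genes_tbl("chr1A", 30000, 40000, "-", "gM")
  )
  pr <- promoters_of(genes)
  expect_equal(pr$start[pr$gene_id == "gP"], 9000)
  expect_equal(pr$end[pr$gene_id == "gP"], 10500)
  # minus-strand TSS is the gene end (here 40000): [39500, 41000)
  expect_equal(pr$start[pr$gene_id == "gM"], 39500)
  expect_equal(pr$end[pr$gene_id == "gM"], 41000)
  # promoter overlaps or abuts the gene body
  expect_true(all(pr$start < genes$end & pr$end > genes$start))
  # clipped at chromosome start
  g0 <- genes_tbl("chr1A", 500, 3000, "+", "g0")
  expect_equal(promoters_of(g0)$start, 0)
})

test_that("pair correlation uses the strongest overlapping peak per mark", {
  enh <- tibble::tibble(chrom = "chr1A", start = 1000, end = 2000)
  prom <- tibble::tibble(chrom = "chr1A", start = 9000, end = 10500)
  v <- c(1, 5, 2, 8, 3, 9, 4, 7)
  panel <- mk_panel(
    list("e_weak", "chr1A", 1100, 1300, "H3K27ac", v / 10),
    list("e_strong", "chr1A", 1400, 1900, "H3K27ac", v),
    list("p1", "chr1A", 9100, 9900, "H3K27ac", v * 3)
  )
  r <- pair_correlation(enh, prom, panel)
  expect_equal(r$r, 1)  # strongest enhancer peak is proportional to promoter

  rev_panel <- mk_panel(
    list("e1", "chr1A", 1100, 1300, "m", c(1, 2, 3, 4)),
    list("p1", "chr1A", 9100, 9900, "m", c(4, 3, 2, 1))
  )
  expect_equal(pair_correlation(enh, prom, rev_panel)$r, -1)

  # no overlapping peak on one side -> NA sentinel
  off <- mk_panel(list("e1", "chr1A", 50000, 51000, "m", c(1, 2, 3, 4)))
  expect_true(is.na(pair_correlation(enh, prom, off)$r))
  # zero variance -> NA
  flat <- mk_panel(
    list("e1", "chr1A", 1100, 1300, "m", rep(2, 4)),
    list("p1", "chr1A", 9100, 9900, "m", c(1, 2, 3, 4))
  )
  expect_true(is.na(pair_correlation(enh, prom, flat)$r))
})

test_that("random signal vectors match the direct Pearson formula", {
  withr::with_seed(51, {
    for (i in 1:20) {
      a <- rnorm(8); b <- rnorm(8)
      # closed-form Pearson
      want <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      panel <- mk_panel(
        list("e", "chr1A", 100, 200, "m", a - min(a) + 0.1),
        list("p", "chr1A", 900, 1000, "m", b - min(b) + 0.1)
      )
      got <- pair_correlation(tibble::tibble(chrom = "chr1A", start = 100, end = 200),
                              tibble::tibble(chrom = "chr1A", start = 900, end = 1000),
                              panel)$r
      expect_equal(got, want)
    }
  })
})

test_that("Hi-C support counts both anchor orientations and sums read pairs", {
  enh <- tibble::tibble(chrom = "chr1A", start = 1000, end = 2000)
  prom <- tibble::tibble(chrom = "chr1A", start = 9000, end = 10000)
  contacts <- tibble::tibble(
    chrom1 = "chr1A", start1 = c(1100, 9100, 40000),
    end1 = c(1200, 9200, 41000),
    chrom2 = "chr1A", start2 = c(9100, 1500, 50000),
    end2 = c(9200, 1600, 51000),
    read_pairs = c(2L, 3L, 7L)
  )
  expect_equal(hic_support(enh, prom, contacts), 5)
  expect_equal(hic_support(enh, prom, contacts),
               brute_hic_support(enh, prom, contacts))
})

test_that("Hi-C support equals an exhaustive double loop on random sets", {
  withr::with_seed(52, {
    contacts <- tibble::tibble(
      chrom1 = sample(c("chr1A", "chr1B"), 60, TRUE),
      start1 = s1 <- sample.int(1e5, 60), end1 = s1 + sample.int(2000, 60),
      chrom2 = sample(c("chr1A", "chr1B"), 60, TRUE),
      start2 = s2 <- sample.int(1e5, 60), end2 = s2 + sample.int(2000, 60),
      read_pairs = sample.int(5, 60, TRUE)
    )
    for (i in 1:25) {
      enh <- tibble::tibble(chrom = sample(c("chr1A", "chr1B"), 1),
                            start = a <- sample.int(1e5, 1), end = a + 1500)
      prom <- tibble::tibble(chrom = sample(c("chr1A", "chr1B"), 1),
                             start = b <- sample.int(1e5, 1), end = b + 1500)
      expect_equal(hic_support(enh, prom, contacts),
                   brute_hic_support(enh, prom, contacts))
    }
  })
})

test_that("target assignment applies cutoff, Hi-C, and the expansion rule", {
  layout <- toy_layout(3e6)
  enh <- tibble::tibble(enhancer_id = c("E1", "E2"), chrom = "chr1A",
                        start = c(1e6, 2e6), end = c(1e6, 2e6) + 1000,
                        status = "transcribed")
  genes <- dplyr::bind_rows(
    genes_tbl("chr1A", 1101000, 1105000, "+", "g_near"),     # 100 kb from E1
    genes_tbl("chr1A", 1201000, 1205000, "+", "g_nocorr"),   # 200 kb from E1
    genes_tbl("chr1A", 801000, 805000, "+", "g_far")         # 1.2 Mb from E2
  )
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  panel <- mk_panel(
    list("pE1", "chr1A", 1e6, 1e6 + 1000, "m", v),
    list("pE2", "chr1A", 2e6, 2e6 + 1000, "m", v),
    list("p_near", "chr1A", 1100000, 1101500, "m", v * 2),   # r = 1
    list("p_nocorr", "chr1A", 1200000, 1201500, "m", rev(v)),# r < 0.7
    list("p_far", "chr1A", 800500, 801500, "m", v + 0.5)     # r = 1
  )
  contacts <- tibble::tibble(
    chrom1 = "chr1A", start1 = c(1e6, 1e6, 2e6), end1 = c(1e6, 1e6, 2e6) + 1000,
    chrom2 = "chr1A", start2 = c(1100100, 1200100, 800600),
    end2 = c(1101400, 1201400, 801400),
    read_pairs = c(2L, 5L, 1L)
  )
  links <- assign_targets(enh, genes, panel, contacts, layout = layout)
  expect_equal(nrow(links), 2)
  e1 <- links[links$enhancer_id == "E1", ]
  expect_equal(e1$gene_id, "g_near")        # g_nocorr fails despite 5 Hi-C pairs
  expect_equal(e1$search_tier, "primary_500kb")
  expect_equal(e1$hic_pairs, 2L)
  e2 <- links[links$enhancer_id == "E2", ]
  expect_equal(e2$gene_id, "g_far")
  expect_equal(e2$search_tier, "expanded_2Mb")

  # output invariant to input ordering of genes and contacts
  withr::with_seed(53, {
    links2 <- assign_targets(enh, genes[sample(3), ], panel,
                             contacts[sample(3), ], layout = layout)
  })
  expect_equal(as.data.frame(links), as.data.frame(links2))
})

test_that("no expansion link is emitted when a primary-tier link exists", {
  layout <- toy_layout(3e6)
  enh <- tibble::tibble(enhancer_id = "E1", chrom = "chr1A",
                        start = 1e6, end = 1e6 + 1000, status = "transcribed")
  genes <- dplyr::bind_rows(
    genes_tbl("chr1A", 1101000, 1105000, "+", "g_near"),
    genes_tbl("chr1A", 2501000, 2505000, "+", "g_far")  # 1.5 Mb
  )
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  panel <- mk_panel(
    list("pE1", "chr1A", 1e6, 1e6 + 1000, "m", v),
    list("p_near", "chr1A", 1100000, 1101500, "m", v),
    list("p_far", "chr1A", 2500000, 2501500, "m", v)
  )
  contacts <- tibble::tibble(
    chrom1 = "chr1A", start1 = rep(1e6, 2), end1 = rep(1e6 + 1000, 2),
    chrom2 = "chr1A", start2 = c(1100100, 2500100), end2 = c(1101400, 2501400),
    read_pairs = c(1L, 4L)
  )
  links <- assign_targets(enh, genes, panel, contacts, layout = layout)
  expect_equal(links$gene_id, "g_near")
  expect_true(all(links$search_tier == "primary_500kb"))
})

test_that("target expression summary groups genes by association count", {
  links <- tibble::tibble(
    enhancer_id = c("E1", "E2", "E3"), gene_id = c("g1", "g2", "g2"),
    chrom = "chr1A", distance = 1e4, correlation = 0.9, mark = "m",
    hic_pairs = 1L, search_tier = "primary_500kb"
  )
  expr <- tibble::tibble(gene_id = c("g1", "g2", "g3"), level = c(5, 8, 1))
  s <- target_expression_summary(links, expr)
  expect_equal(s$n_enhancers[match(c("g1", "g2", "g3"), s$gene_id)],
               c(1L, 2L, 0L))
  expect_equal(as.character(s$group[s$gene_id == "g3"]), "0")
  expect_true(s$has_enhancer[s$gene_id == "g2"])

  # empty link list: everything in group 0
  s0 <- target_expression_summary(links[0, ], expr)
  expect_true(all(s0$group == "0"))

  # linked gene missing from expression triggers a warning
  expect_warning(target_expression_summary(links, expr[1, ]), "missing")
})

test_that("planted targets receive higher expression than unlinked genes", {
  s <- small_study()
  res <- small_analysis()
  summ <- target_expression_summary(res$links, s$landscape$expression)
  expect_gt(mean(summ$level[summ$has_enhancer]),
            mean(summ$level[!summ$has_enhancer]))
})
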