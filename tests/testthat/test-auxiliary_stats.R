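write_test_vcf <- function(sites, gt, samples) {
  f <- tempfile(fileext = ".vcf")
  write_vcf(list(sites = sites, gt = gt, samples = samples), f)
  f
}

test_that("per-site pi follows the haplotype-pair formula", {
  layout <- toy_layout(1000)
  # 4 haplotypes, 2 alt: all 6 pairs, 4 differ -> pi_site = 2/3
  sites <- tibble::tibble(chrom = "chr1A", pos = 100)
  gt <- matrix(c("0/1", "0/1"), nrow = 1)
  f <- write_test_vcf(sites, gt, c("s1", "s2"))
  w <- windowed_pi(f, layout, window = 500)
  expect_equal(w$pi[w$start == 0], (2 / 3) / 500)
  expect_equal(w$pi[w$start == 500], 0)  # monomorphic window
  expect_equal(w$n_variants, c(1L, 0L))

  # missing genotypes reduce the called haplotype count
  gt2 <- matrix(c("0/1", "./."), nrow = 1)
  f2 <- write_test_vcf(sites, gt2, c("s1", "s2"))
  w2 <- windowed_pi(f2, layout, window = 500)
  expect_equal(w2$pi[1], (2 * 1 * 1 / (2 * 1)) / 500)  # n = 2, j = 1 -> pi = 1
})

test_that("windowed pi equals exhaustive pairwise enumeration on a toy VCF", {
  layout <- toy_layout(5000)
  withr::with_seed(81, {
    sites <- tibble::tibble(chrom = "chr1A", pos = sort(sample.int(5000, 20)) - 1)
    codes <- c("0/0", "0/1", "1/1", "./.")
    gt <- matrix(sample(codes, 20 * 5, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
                 nrow = 20)
  })
  f <- write_test_vcf(sites, gt, paste0("s", 1:5))
  got <- windowed_pi(f, layout, window = 500)
  want <- brute_windowed_pi(sites, gt, layout, window = 500)
  expect_equal(got$pi, want$pi, tolerance = 1e-12)
})

test_that("multiallelic records are skipped with a message", {
  layout <- toy_layout(1000)
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1A\t101\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2",
    "chr1A\t201\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/1"
  ), f)
  expect_message(w <- windowed_pi(f, layout), "skipped 1")
  expect_equal(sum(w$n_variants), 1)
})

test_that("random intergenic regions are intergenic, on-genome, length-matched", {
  s <- small_study()
  genes <- s$genome$genes
  layout <- s$genome$layout
  regions <- dplyr::filter(s$truth$enhancers, transcribed)[, c("chrom", "start", "end")]
  rnd <- sample_intergenic_regions(regions$end - regions$start, genes, layout,
                                   seed = 5)
  expect_equal(sort(rnd$end - rnd$start), sort(regions$end - regions$start))
  validate_intervals(rnd, layout)
  d <- nearest_gene_distance(rnd, genes)$distance_to_gene
  expect_true(all(d >= 0))
  ov <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(rnd$chrom, IRanges::IRanges(rnd$start + 1, rnd$end)),
    GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  )
  expect_true(all(ov == 0))
})

test_that("planted diversity reduction in eRNA regions is detected", {
  s <- small_study()
  f <- tempfile(fileext = ".vcf")
  write_vcf(s$variants, f)
  w <- windowed_pi(f, s$genome$layout)
  regions <- dplyr::filter(s$truth$enhancers, transcribed)[, c("chrom", "start", "end")]
  lower <- vapply(1:10, function(seed) {
    cmp <- region_diversity_compare(w, regions, s$genome$genes,
                                    s$genome$layout, seed = seed)
    mean(cmp$mean_pi[cmp$class == "eRNA"], na.rm = TRUE) <
      mean(cmp$mean_pi[cmp$class == "random_intergenic"], na.rm = TRUE)
  }, logical(1))
  expect_true(all(lower))
})

test_that("coverage saturation handles the toy example and degenerate sizes", {
  layout <- toy_layout(1e5)  # 10 bins of 10 kb
  # 3 bins with >= 5 reads, plus scattered reads below the cutoff
  ev <- tibble::tibble(
    chrom = "chr1A",
    pos = c(rep(5000, 6), rep(25000, 5), rep(95000, 7), 35000, 45000)
  )
  cs <- coverage_saturation(ev, layout, sizes = nrow(ev), seed = 1)
  expect_equal(cs$fraction, 0.3)
  cs0 <- coverage_saturation(ev, layout, sizes = 0, seed = 1)
  expect_equal(cs0$fraction, 0)
  expect_warning(
    coverage_saturation(ev, layout, sizes = 1e6, seed = 1),
    "capped"
  )
})

test_that("nested saturation curves are monotone and converge", {
  layout <- toy_layout(2e5)
  withr::with_seed(82, {
    ev <- tibble::tibble(chrom = "chr1A",
                         pos = sample.int(2e5, 5000, TRUE) - 1)
  })
  sizes <- c(0, 10, 100, 500, 1000, 2500, 5000)
  cs <- coverage_saturation(ev, layout, sizes = sizes, seed = 3)
  expect_true(all(diff(cs$fraction) >= 0))
  full <- coverage_saturation(ev, layout, sizes = 5000, seed = 99)
  expect_equal(cs$fraction[cs$size == 5000], full$fraction)
  expect_true(all(cs$fraction <= full$fraction))
})

test_that("reporter scoring normalizes to blank and applies the 2.0 cutoff", {
  meas <- tibble::tibble(
    construct_id = c("blank", "neg", "c1", "c2"),
    fluc = c(2000, 3200, 4000, 3900),
    rluc = c(1000, 1000, 1000, 1000),
    role = c("blank", "negative", "candidate", "candidate")
  )
  sc <- reporter_score(meas, "blank")
  expect_equal(sc$relative_intensity[sc$construct_id == "blank"], 1)
  expect_equal(sc$relative_intensity[sc$construct_id == "neg"], 1.6)
  expect_false(sc$is_positive[sc$construct_id == "neg"])
  # boundary: exactly 2.0 counts as positive
  expect_true(sc$is_positive[sc$construct_id == "c1"])
  expect_false(sc$is_positive[sc$construct_id == "c2"])

  # shared rescaling of all readings changes nothing
  sc2 <- reporter_score(dplyr::mutate(meas, fluc = fluc * 7, rluc = rluc * 7),
                        "blank")
  expect_equal(sc2$relative_intensity, sc$relative_intensity)

  expect_error(reporter_score(meas, "nope"), "not found")
  expect_error(reporter_score(dplyr::mutate(meas, rluc = c(0, rluc[-1])),
                              "blank"), "positive")
})

test_that("activity correlation is robust to a planted extreme outlier", {
  withr::with_seed(83, {
    n <- 20
    act <- seq(1, 3, length.out = n) + rnorm(n, 0, 0.05)
    dens <- act * 2 + rnorm(n, 0, 0.05)
  })
  base <- tibble::tibble(construct_id = paste0("c", 1:20), feature = "eRNA",
                         activity = act, density = dens)
  r0 <- activity_signal_correlation(base)
  expect_gt(r0$r, 0.95)

  # one extreme point flips the sign without removal; the MAD rule restores it
  spiked <- dplyr::bind_rows(
    base,
    tibble::tibble(construct_id = "out", feature = "eRNA",
                   activity = 60, density = -120)
  )
  raw <- cor(spiked$activity, spiked$density)
  expect_lt(raw, 0)
  rr <- activity_signal_correlation(spiked)
  expect_gt(rr$r, 0.9)
  expect_true("out" %in% rr$removed[[1]])
  expect_equal(rr$n_removed, 1L)
})

test_that("permuted activities give small correlations", {
  withr::with_seed(84, {
    dens <- runif(30, 1, 5)
    rs <- vapply(1:40, function(i) {
      d <- tibble::tibble(construct_id = paste0("c", 1:30), feature = "f",
                          activity = sample(dens), density = dens)
      activity_signal_correlation(d)$r
    }, numeric(1))
  })
  expect_gte(mean(abs(rs) < 0.4), 0.9)
})
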