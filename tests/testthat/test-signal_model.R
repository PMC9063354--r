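layout1 <- toy_layout(1e5)

test_that("build_track accumulates events per position and strand", {
  ev <- events_tbl("chr1A", c(100, 100, 100, 100, 200), c("+", "+", "+", "-", "+"))
  tr <- build_track(ev, layout1)
  expect_equal(tr$total_events, 5)
  cp <- tr$counts
  expect_equal(cp$count[cp$pos == 100 & cp$strand == "+"], 3)
  expect_equal(cp$count[cp$pos == 100 & cp$strand == "-"], 1)

  # degenerate empty input
  empty <- build_track(events_tbl(character(), double(), character()), layout1)
  expect_equal(empty$total_events, 0)

  # records wider than 1 bp are rejected with advice
  wide <- tibble::tibble(chrom = "chr1A", start = 10, end = 12, strand = "+")
  expect_error(build_track(wide, layout1), "pre-extract")
  bad <- tibble::tibble(chrom = "chr1A", start = 10, end = 11, strand = ".")
  expect_error(build_track(bad, layout1), "stranded")
})

test_that("normalization preserves ratios, sums to 1e6, and is depth-invariant", {
  ev <- events_tbl("chr1A", c(10, 10, 20, 30), c("+", "+", "+", "-"))
  tr <- build_track(ev, layout1)
  d <- track_density(tr)
  expect_equal(sum(d$density), 1e6)
  expect_equal(d$density[d$pos == 10] / d$density[d$pos == 20], 2)

  doubled <- build_track(dplyr::bind_rows(ev, ev), layout1)
  expect_equal(track_density(doubled)$density, d$density)

  expect_error(norm_factor(build_track(ev[0, ], layout1)), "zero events")
})

test_that("replicate correlation is 1 for identical or depth-scaled tracks", {
  withr::with_seed(11, {
    ev <- events_tbl("chr1A", sample.int(1e5, 2000, replace = TRUE) - 1,
                     sample(c("+", "-"), 2000, TRUE))
  })
  a <- build_track(ev, layout1)
  expect_equal(replicate_correlation(a, a), 1)
  b <- build_track(dplyr::bind_rows(ev, ev, ev), layout1)  # 3x depth
  expect_equal(replicate_correlation(a, b), 1)
  expect_equal(replicate_correlation(a, b), replicate_correlation(b, a))
})

test_that("independent Poisson tracks are uncorrelated over 1e4 bins", {
  big <- toy_layout(5e6)
  withr::with_seed(12, {
    mk <- function() {
      n <- 30000
      build_track(events_tbl("chr1A", sample.int(5e6, n, TRUE) - 1,
                             sample(c("+", "-"), n, TRUE)), big)
    }
    a <- mk(); b <- mk()
  })
  expect_lt(abs(replicate_correlation(a, b)), 0.05)
})

test_that("zero-variance binned density yields an NA correlation with warning", {
  small <- toy_layout(1000)  # two 500-bp bins
  a <- build_track(events_tbl("chr1A", c(10, 20, 600), rep("+", 3)), small)
  flat <- build_track(events_tbl("chr1A", c(100, 600), rep("+", 2)), small)
  expect_warning(r <- replicate_correlation(a, flat), "zero variance")
  expect_true(is.na(r))
})

test_that("merging tracks sums counts and totals; layouts must match", {
  ev1 <- events_tbl("chr1A", c(5, 5), c("+", "+"))
  ev2 <- events_tbl("chr1A", c(900, 5), c("-", "+"))
  t1 <- build_track(ev1, layout1)
  t2 <- build_track(ev2, layout1)
  m <- merge_tracks(list(t1, t2))
  expect_equal(m$total_events, t1$total_events + t2$total_events)
  expect_equal(m$counts$count[m$counts$pos == 5 & m$counts$strand == "+"], 3)
  expect_equal(m$counts$count[m$counts$pos == 900], 1)

  m2 <- merge_tracks(list(t1, t1))
  expect_equal(m2$counts$count, t1$counts$count * 2)

  other <- toy_layout(5e4)
  expect_error(merge_tracks(list(t1, build_track(ev1, other))), "mismatched")
})

test_that("window_signal equals per-base brute force on random tracks", {
  withr::with_seed(13, {
    ev <- events_tbl("chr1A", sample.int(1e4, 3000, TRUE) - 1,
                     sample(c("+", "-"), 3000, TRUE))
    tr <- build_track(ev, layout1)
    anchors <- tibble::tibble(chrom = "chr1A",
                              pos = sample.int(1e4, 50) - 1,
                              strand = sample(c("+", "-"), 50, TRUE))
  })
  for (mode in c("anchor", "opposite", "both")) {
    expect_equal(window_signal(tr, anchors, 250, mode),
                 brute_window_signal(tr, anchors, 250, mode))
  }
  # flank 0 reduces to the single-base density
  expect_equal(window_signal(tr, anchors, 0, "anchor"),
               brute_window_signal(tr, anchors, 0, "anchor"))
})

test_that("a track fully inside the window sums to its normalized total", {
  ev <- events_tbl("chr1A", c(100, 110, 120), rep("+", 3))
  tr <- build_track(ev, layout1)
  anchors <- tibble::tibble(chrom = "chr1A", pos = 110, strand = "+")
  expect_equal(window_signal(tr, anchors, 250), 1e6)
})

test_that("metaprofile centers deltas and flips minus-strand anchors", {
  tr <- build_track(events_tbl("chr1A", rep(5000, 4), rep("+", 4)), layout1)
  anchors <- tibble::tibble(chrom = "chr1A", pos = 5000, strand = "+")
  m <- metaprofile(tr, anchors, flank = 1000, bin = 100)
  expect_equal(ncol(m), 20)
  expect_equal(which(m[1, ] > 0), 11)  # first downstream bin

  # minus-strand anchor, signal 100 bp downstream (leftward in genome
  # coordinates) must appear right of center
  tr2 <- build_track(events_tbl("chr1A", 4900, "-"), layout1)
  anchors2 <- tibble::tibble(chrom = "chr1A", pos = 5000, strand = "-")
  m2 <- metaprofile(tr2, anchors2, flank = 1000, bin = 100)
  expect_equal(which(m2[1, ] > 0), 12)

  # anchor off the chromosome gives an NA row
  m3 <- metaprofile(tr, tibble::tibble(chrom = "chr1A", pos = -5, strand = "+"),
                    flank = 1000, bin = 100)
  expect_true(all(is.na(m3[1, ])))
})

test_that("symmetric signal yields a column-symmetric mean profile", {
  # offsets at +/-150 and +/-250 land in mirrored half-open bins
  pos <- c(4750, 5250, 4850, 5150)
  tr <- build_track(events_tbl("chr1A", pos, rep("+", 4)), layout1)
  anchors <- tibble::tibble(chrom = "chr1A", pos = 5000, strand = "+")
  m <- metaprofile(tr, anchors, flank = 500, bin = 100)
  prof <- colMeans(m)
  expect_equal(prof, rev(prof))
})
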