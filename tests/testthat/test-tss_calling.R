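test_that("Poisson detection threshold matches direct tail summation", {
  # lambda = 1: P(X >= 9) = 1.11e-6 > 1e-6, P(X >= 10) <= 1e-6, so k* = 10
  expect_equal(tss_threshold(1, 1e-6), 10)
  expect_gt(1 - ppois(8, 1), 1e-6)
  expect_lte(1 - ppois(9, 1), 1e-6)
  for (lambda in c(0.005, 0.05, 0.5, 1, 4)) {
    for (alpha in c(1e-4, 1e-6)) {
      expect_equal(tss_threshold(lambda, alpha),
                   brute_poisson_threshold(lambda, alpha),
                   info = sprintf("lambda=%g alpha=%g", lambda, alpha))
    }
  }
  expect_error(tss_threshold(1, 0), "alpha")
  expect_error(tss_threshold(1, 1.5), "alpha")
})

test_that("call_tss keeps spikes, drops uniform background, collapses runs", {
  layout <- toy_layout(1e5)
  # uniform counts of 1 never reach min_count
  uni <- build_track(events_tbl("chr1A", seq(0, 99999, by = 100), "+"), layout)
  expect_equal(nrow(call_tss(uni)), 0)

  # one strong position on empty background -> exactly one call
  spike <- build_track(events_tbl("chr1A", rep(5000, 1000), "+"), layout)
  calls <- call_tss(spike)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 5000)

  # candidates closer than 50 bp collapse to the maximal count (ties left)
  ev <- events_tbl("chr1A", c(rep(1000, 10), rep(1030, 7), rep(2000, 8),
                              rep(2030, 8)),
                   "+")
  tr <- build_track(ev, layout)
  calls2 <- call_tss(tr)
  expect_equal(calls2$pos, c(1000, 2000))
  expect_equal(calls2$count, c(10, 8))

  expect_error(call_tss(build_track(ev[0, ], layout)), "empty track")
})

test_that("cluster merging matches worked examples", {
  calls <- tibble::tibble(chrom = "chr1A", strand = "+",
                          pos = c(1000, 2500, 7000), count = c(5, 8, 5))
  cl <- merge_tss_clusters(calls)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$tss[1], 1000)
  expect_equal(cl$start[1], 1000)
  expect_equal(cl$end[1], 2501)
  expect_equal(cl$n_calls, c(2, 1))

  # on the minus strand the 5' end is the rightmost member
  neg <- tibble::tibble(chrom = "chr1A", strand = "-",
                        pos = c(1000, 2500), count = c(5, 5))
  expect_equal(merge_tss_clusters(neg)$tss, 2500)
})

test_that("cluster merging equals brute-force transitive closure", {
  withr::with_seed(21, {
    for (i in 1:60) {
      n <- sample(3:40, 1)
      calls <- tibble::tibble(
        chrom = sample(c("chr1A", "chr1B"), n, TRUE),
        strand = sample(c("+", "-"), n, TRUE),
        pos = sample.int(5e4, n), count = sample.int(20, n, TRUE)
      ) |>
        dplyr::distinct(chrom, strand, pos, .keep_all = TRUE)
      got <- merge_tss_clusters(calls, merge_dist = 3000) |>
        dplyr::select(chrom, strand, start, end, n_calls) |>
        dplyr::arrange(chrom, strand, start)
      want <- brute_merge_clusters(calls, merge_dist = 3000)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  })
})

test_that("cluster merging is idempotent and clusters are well-separated", {
  withr::with_seed(22, {
    calls <- tibble::tibble(chrom = "chr1A", strand = "+",
                            pos = sort(sample.int(2e5, 100)),
                            count = sample.int(30, 100, TRUE))
  })
  cl <- merge_tss_clusters(calls)
  # member conservation
  expect_equal(sum(cl$n_calls), nrow(calls))
  # re-merging the cluster TSS positions changes nothing structurally:
  # consecutive clusters on one strand are > merge_dist apart
  gaps <- cl$start[-1] - cl$end[-nrow(cl)]
  expect_true(all(gaps > 3000 - 1))
  cl2 <- merge_tss_clusters(
    tibble::tibble(chrom = cl$chrom, strand = cl$strand, pos = cl$tss,
                   count = cl$count)
  )
  expect_equal(nrow(cl2), nrow(cl))
})

test_that("the all-replicates filter keeps only fully supported clusters", {
  clusters <- tibble::tibble(
    tc_id = c("TC1", "TC2"), chrom = "chr1A", strand = "+",
    start = c(1000, 9000), end = c(1200, 9100), tss = c(1000, 9000),
    n_calls = 1L, count = 10
  )
  call_at <- function(pos) tibble::tibble(chrom = "chr1A", strand = "+",
                                          pos = pos, count = 10)
  reps <- list(call_at(c(1050, 9050)), call_at(c(1100, 9020)),
               call_at(1150), call_at(c(1000, 9099)))
  kept <- replicate_consistent(clusters, reps)
  expect_equal(kept$tc_id, "TC1")  # TC2 missing from replicate 3

  # same-strand requirement
  reps2 <- list(call_at(1050),
                tibble::tibble(chrom = "chr1A", strand = "-", pos = 1050,
                               count = 10))
  expect_equal(nrow(replicate_consistent(clusters[1, ], reps2)), 0)

  expect_warning(replicate_consistent(clusters, reps[1]), "single replicate")
  expect_error(replicate_consistent(clusters, list()), "at least one")
})

test_that("decile grouping sorts, spreads remainders, and breaks ties", {
  tcs <- tibble::tibble(
    tc_id = sprintf("TC%03d", 1:100), chrom = "chr1A", strand = "+",
    start = 1:100 * 10, end = 1:100 * 10 + 1, tss = 1:100 * 10,
    signal_250 = 101 - (1:100)
  )
  g <- decile_groups(tcs)
  expect_equal(as.integer(table(g$decile)), rep(10L, 10))
  expect_true(all(g$signal_250[g$decile == 1] >= max(g$signal_250[g$decile == 2])))
  means <- tapply(g$signal_250, g$decile, mean)
  expect_true(all(diff(means) <= 0))

  # remainder spread over the top groups
  g2 <- decile_groups(tcs[1:103, ] |>
                        dplyr::mutate(tss = c(tss[1:100], 2000, 2010, 2020)))
  expect_equal(as.integer(table(g2$decile)), c(11L, 11L, 11L, rep(10L, 7)))

  # all-equal signals: deterministic coordinate tie-break
  tied <- dplyr::mutate(tcs, signal_250 = 1)
  expect_equal(decile_groups(tied)$tc_id, decile_groups(tied)$tc_id)
  expect_equal(decile_groups(tied)$tss, sort(tied$tss))

  expect_warning(decile_groups(tcs[1:4, ]), "singleton")
})
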