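# The stringent coordinate-UMI filter, checked against a brute-force
# all-pairs + connected-components oracle and against simulation truth.

test_that("umi_distance sums per-end shifts and is infinite across chromosomes", {
  a <- list(umi_lchrom = "chr1", umi_left = 100, umi_rchrom = "chr1", umi_right = 350)
  expect_equal(umi_distance(a, a), 0)
  b <- list(umi_lchrom = "chr1", umi_left = 101, umi_rchrom = "chr1", umi_right = 351)
  expect_equal(umi_distance(a, b), 2)
  c <- list(umi_lchrom = "chr2", umi_left = 100, umi_rchrom = "chr2", umi_right = 350)
  expect_equal(umi_distance(a, c), Inf)
})

test_that("extract_umi takes the outer coordinates of first and last slice", {
  s <- tibble(read_id = "r1", slice_index = 1:2, chrom = "chr1",
              start = c(100, 300), end = c(150, 350))
  u <- extract_umi(s)
  expect_equal(c(u$umi_left, u$umi_right), c(100, 350))
  # single slice: that slice's two ends
  u1 <- extract_umi(tibble(read_id = "x", slice_index = 1, chrom = "chr2",
                           start = 40, end = 90))
  expect_equal(c(u1$umi_left, u1$umi_right), c(40, 90))
  # ends may live on different chromosomes
  s2 <- tibble(read_id = "r2", slice_index = 1:2, chrom = c("chr1", "chr2"),
               start = c(100, 7), end = c(150, 60))
  u2 <- extract_umi(s2)
  expect_equal(u2$umi_lchrom, "chr1")
  expect_equal(u2$umi_rchrom, "chr2")
  expect_equal(c(u2$umi_left, u2$umi_right), c(100, 60))
})

test_that("wobble clustering collapses chains and respects the threshold", {
  # identical UMIs: one retained
  r <- filter_duplicates(umi_reads(c(100, 100, 100), c(350, 350, 350)))
  expect_equal(r$report$n_retained, 1L)

  # distance 1: one cluster
  r <- filter_duplicates(umi_reads(c(100, 101), c(350, 350)))
  expect_equal(r$report$n_retained, 1L)

  # single-linkage chain at pairwise distance 2 merges extremes 4 apart
  r <- filter_duplicates(umi_reads(c(100, 102, 104), c(350, 350, 350)))
  expect_equal(r$report$n_retained, 1L)

  # distance 3 with max_wobble 2: two clusters
  r <- filter_duplicates(umi_reads(c(100, 103), c(350, 350)))
  expect_equal(r$report$n_retained, 2L)

  # same coordinates on another chromosome pair never merge
  r <- filter_duplicates(dplyr::bind_rows(umi_reads(100, 350, "chr1"),
                                          umi_reads(100, 350, "chr2")))
  expect_equal(r$report$n_retained, 2L)
})

test_that("retained counts equal the all-pairs union-find oracle", {
  withr::with_seed(51, {
    for (rep in 1:30) {
      n <- sample(10:400, 1)
      umis <- random_umi_set(n, n_chrom = sample(1:2, 1),
                             coord_range = sample(c(25, 60, 200), 1))
      for (w in c(0, 1, 2, 5)) {
        got <- filter_duplicates(umis, max_wobble = w)$report$n_retained
        expect_equal(got, oracle_cluster_count(umis, w),
                     info = sprintf("rep %d n %d w %d", rep, n, w))
      }
    }
  })
})

test_that("retained count is non-increasing in max_wobble", {
  withr::with_seed(52, {
    umis <- random_umi_set(300, coord_range = 40)
    counts <- vapply(c(0, 1, 2, 3, 5, 8),
                     function(w) filter_duplicates(umis, w)$report$n_retained,
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("max_wobble = 0 reduces to exact-key hash deduplication", {
  withr::with_seed(53, {
    umis <- random_umi_set(500, coord_range = 15)
    got <- filter_duplicates(umis, max_wobble = 0)$report$n_retained
    key <- paste(umis$umi_lchrom, umis$umi_left, umis$umi_rchrom, umis$umi_right)
    expect_equal(got, length(unique(key)))
  })
})

test_that("the representative has the most exact copies, ties broken lexically", {
  umis <- umi_reads(c(100, 100, 102, 102, 102), c(350, 350, 350, 350, 350))
  r <- filter_duplicates(umis, max_wobble = 2)
  expect_equal(r$report$n_retained, 1L)
  # (102, 350) occurs three times vs two: its first read id wins
  expect_equal(r$retained$read_id, "r003")
  # pure tie: smallest coordinate, then read id
  tie <- umi_reads(c(102, 100), c(350, 350))
  expect_equal(filter_duplicates(tie)$retained$read_id, "r002")
})

test_that("drop_wobble_clusters removes wobble-linked clusters entirely", {
  umis <- dplyr::bind_rows(
    umi_reads(c(100, 101), c(350, 350)),          # wobble pair -> dropped
    umi_reads(c(900, 900), c(950, 950)),          # exact duplicates -> 1 kept
    umi_reads(500, 600)                           # singleton -> kept
  )
  r <- filter_duplicates(umis, max_wobble = 2, drop_wobble_clusters = TRUE)
  expect_equal(r$report$n_retained, 2L)
  expect_true(all(r$retained$umi_left %in% c(900, 500)))
})

test_that("deduplication is performed within viewpoint groups", {
  umis <- dplyr::bind_rows(umi_reads(100, 350), umi_reads(100, 350))
  umis$viewpoint <- c("alpha", "beta")
  r <- filter_duplicates(umis)
  expect_equal(r$report$n_retained, 2L) # same key, different groups
})

test_that("simulation truth bounds the retained count", {
  fx <- sparse_fixture(n_molecules = 5000, wobble_prob = 0.2, dup_rate = 2, seed = 55)
  dd <- filter_duplicates(fx$informative)
  ts <- dedup_truth_summary(dd, fx$lib$truth)
  # never more than the molecules that entered; conservative when wobble merges
  expect_lte(ts$n_retained, ts$n_true_molecules)
  expect_lte(ts$n_retained, ts$n_distinct_true_umis)
  expect_gte(ts$n_retained, 0.9 * ts$n_true_molecules)

  # with eps = 0 every retained read is one distinct true UMI
  fx0 <- sparse_fixture(n_molecules = 3000, wobble_prob = 0, dup_rate = 2, seed = 56)
  dd0 <- filter_duplicates(fx0$informative)
  ts0 <- dedup_truth_summary(dd0, fx0$lib$truth)
  expect_equal(ts0$n_retained, ts0$n_distinct_true_umis)
})

test_that("tidy and glance expose the clustering", {
  umis <- umi_reads(c(100, 101, 200), c(350, 350, 400))
  r <- filter_duplicates(umis)
  td <- tidy(r)
  expect_equal(nrow(td), 3L)
  expect_equal(length(unique(td$cluster)), 2L)
  gl <- glance(r)
  expect_equal(gl$n_retained, 2L)
})
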