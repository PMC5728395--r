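# Probe design against fragment ends and count-table analysis.

test_that("probes take the top strand left and bottom strand right", {
  genome <- c(chr1 = "AAGATCAA")
  map <- digest_reference(genome) # [0,2) [2,8)
  pd <- design_probes(map, genome, targets = map$frag_id[2], probe_length = 4)
  expect_equal(pd$left_seq, "GATC")
  expect_equal(pd$right_seq, "TTGA") # revcomp of "TCAA"
  expect_equal(pd$left_strand, "+")
  expect_equal(pd$right_strand, "-")
  expect_equal(c(pd$left_start, pd$left_end), c(2, 6))
  expect_equal(c(pd$right_start, pd$right_end), c(4, 8))

  # L = fragment length: both probes cover the whole fragment
  pd6 <- design_probes(map, genome, targets = map$frag_id[2], probe_length = 6)
  expect_equal(pd6$left_seq, "GATCAA")
  expect_equal(pd6$right_seq, revcomp("GATCAA"))

  # fragments shorter than L are skipped and reported
  pd9 <- design_probes(map, genome, targets = map$frag_id, probe_length = 3)
  expect_equal(attr(pd9, "skipped"), map$frag_id[1]) # the 2 bp fragment
  expect_equal(pd9$frag_id, map$frag_id[2])

  expect_error(design_probes(map, genome, targets = 99L), "absent")
})

test_that("reverse-complementing the right probe restores the top strand", {
  withr::with_seed(81, {
    genome <- c(g = random_dna(6000))
    map <- digest_reference(genome)
    targets <- map$frag_id[map$end - map$start >= 50]
    pd <- design_probes(map, genome, targets, probe_length = 50)
    top <- substring(genome["g"], pd$right_start + 1, pd$right_end)
    expect_identical(revcomp(pd$right_seq), unname(top))
    # probes lie within their fragment
    rows <- match(pd$frag_id, map$frag_id)
    expect_true(all(pd$left_start >= map$start[rows] & pd$right_end <= map$end[rows]))
  })
})

count_fixture <- function() {
  tibble(frag_id = rep(1:4, 2),
         sample = rep(c("s1", "s2"), each = 4),
         count = c(100, 200, 100, 100, 10, 20, 10, 10))
}

test_that("count normalization rescales each sample to the probed-set total", {
  norm <- normalize_counts(count_fixture())
  sums <- as.numeric(tapply(norm$count, norm$sample, sum))
  expect_equal(sums, c(1000, 1000), tolerance = 1e-6)
  # sample totalling 500 doubles at scale 1000
  one <- tibble(frag_id = 1:2, sample = "a", count = c(400, 100))
  expect_equal(normalize_counts(one)$count, c(800, 200))
  # a column already at the scale is unchanged; uniform counts split evenly
  flat <- tibble(frag_id = 1:4, sample = "a", count = rep(250, 4))
  expect_equal(normalize_counts(flat)$count, rep(250, 4))
  expect_error(normalize_counts(tibble(frag_id = 1, sample = "z", count = 0)),
               "zero total")
})

test_that("linearity against input mass recovers the true slope", {
  withr::with_seed(82, {
    masses <- rep(c(5, 2, 0.5), 2) # the assay's input series, duplicated
    sample_ids <- paste0("m", masses, letters[rep(1:2, each = 3)])
    truth_slope <- 100
    counts <- tidyr::expand_grid(frag_id = 1:6, sample = sample_ids) |>
      dplyr::mutate(mass = rep(masses, 6),
                    count = truth_slope / 6 * mass + rnorm(36, sd = 1)) |>
      dplyr::select(-"mass")
    samples <- tibble(sample = sample_ids, tissue = "ery",
                      input_mass = masses, replicate = rep(1:2, each = 3))
    lin <- linearity_check(counts, samples)
    tot <- glance(lin)
    expect_lt(abs(tot$slope - truth_slope), 3 * tot$slope_se)
    expect_gt(tot$r, 0.99)
    # per-probe fits agree with a direct lm oracle for one probe
    probe1 <- counts[counts$frag_id == 1, ]
    oracle <- lm(probe1$count ~ masses)
    got1 <- lin$per_probe[lin$per_probe$frag_id == 1, ]
    expect_equal(got1$slope, unname(coef(oracle)[2]), tolerance = 1e-12)
    # counts exactly proportional to mass: r = 1, intercept ~ 0
    exact <- counts; exact$count <- rep(masses, 6) * 20
    lin2 <- linearity_check(exact, samples)
    expect_equal(glance(lin2)$r, 1)
    expect_equal(glance(lin2)$intercept, 0, tolerance = 1e-9)
    # constant counts: slope 0
    const <- counts; const$count <- 50
    expect_equal(glance(linearity_check(const, samples))$slope, 0, tolerance = 1e-9)
    expect_error(linearity_check(counts, dplyr::mutate(samples, input_mass = 1)),
                 "distinct")
  })
})

test_that("comparison against a capture profile is closed-form Pearson", {
  withr::with_seed(83, {
    cmap <- digest_reference(c(cc = regular_chrom(130)))
    probed <- sample(cmap$frag_id, 120)
    p <- build_profile(tibble(read_id = "r1", viewpoint = "v", status = "informative",
                              capture_frag = 1L, reporters = list(2L)),
                       cmap, viewpoint = "v")
    p$value <- rpois(nrow(p), 20) + 1
    counts <- tibble(frag_id = probed, count = rpois(120, 50) + 1)
    cmp <- compare_to_capture(counts, p)
    keep <- match(probed, cmap$frag_id)
    expect_equal(cmp$r, oracle_pearson(counts$count / sum(counts$count),
                                       p$value[keep] / sum(p$value[keep])),
                 tolerance = 1e-12)
    # both vectors renormalized to the same total over the probed set
    expect_equal(sum(cmp$pairs$count), 1000)
    expect_equal(sum(cmp$pairs$capture), 1000)
    # identical restricted profiles: r = 1
    same <- tibble(frag_id = probed, count = p$value[keep])
    expect_equal(compare_to_capture(same, p)$r, 1)
    # constant side: zero variance is an error
    flat <- tibble(frag_id = probed, count = rep(3, 120))
    expect_error(compare_to_capture(flat, p), "variance")
  })
})

test_that("count-capture correlation rises with counting depth", {
  withr::with_seed(84, {
    cmap <- digest_reference(c(cc = regular_chrom(130)))
    probed <- cmap$frag_id[1:120]
    truth <- (1:120)^-0.5
    p <- build_profile(tibble(read_id = "r1", viewpoint = "v", status = "informative",
                              capture_frag = 1L, reporters = list(2L)),
                       cmap, viewpoint = "v")
    p$value[match(probed, cmap$frag_id)] <- truth
    r_at_depth <- function(depth) {
      counts <- tibble(frag_id = probed,
                       count = rpois(120, depth * truth / sum(truth)))
      compare_to_capture(counts, p)$r
    }
    r_low <- r_at_depth(200)
    r_high <- r_at_depth(50000)
    expect_gt(r_high, r_low)
    expect_gt(r_high, 0.99)
  })
})

test_that("differential counts mirror the profile subtraction arithmetic", {
  counts <- tibble(frag_id = rep(1:2, 4),
                   sample = rep(c("a1", "a2", "b1", "b2"), each = 2),
                   count = c(2, 5, 4, 5, 1, 5, 1, 5))
  d <- differential_counts(counts, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d$value[d$frag_id == 1], 2)
  expect_equal(d$se[d$frag_id == 1], 1)
  expect_equal(d$value[d$frag_id == 2], 0)
  # identical groups: zero everywhere
  d0 <- differential_counts(counts, c("a1", "a2"), c("a1", "a2"))
  expect_true(all(d0$value == 0))
  # single replicates: difference defined, SE 0
  d1 <- differential_counts(counts, "a1", "b1")
  expect_equal(d1$value[d1$frag_id == 1], 1)
  expect_true(all(d1$se == 0))
  expect_error(differential_counts(counts, character(0), "b1"), "sample")
})
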