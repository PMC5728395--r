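# The simulator is first-class code: its distributions and duplication model
# are checked against closed forms and independent multinomial draws.

regular_map <- digest_reference(c(c1 = regular_chrom(3))) # 3 x 100 bp fragments

test_that("interaction distribution follows decay, peaks and trans mass", {
  toy <- toy_fixture()
  vp <- locate_fragment(toy$map, "chrA", 65000, 65001)

  # t = 0: every trans fragment has probability exactly 0
  cfg <- sim_config(toy$map, list(v = vp), trans_frac = 0)
  d <- build_interaction_distribution(toy$map, cfg)
  expect_true(all(d$prob[!d$is_cis] == 0))
  expect_equal(sum(d$prob), 1)
  expect_equal(d$prob[d$frag_id == vp], 0) # viewpoint itself carries no mass

  # trans fragments share exactly t, uniformly
  cfg <- sim_config(toy$map, list(v = vp), trans_frac = 0.25)
  d <- build_interaction_distribution(toy$map, cfg)
  expect_equal(sum(d$prob[!d$is_cis]), 0.25)
  expect_equal(length(unique(d$prob[!d$is_cis])), 1L)

  # alpha -> 0 limit, no peaks: uniform over allowed cis fragments
  cfg <- sim_config(toy$map, list(v = vp), alpha = 1e-9, trans_frac = 0)
  d <- build_interaction_distribution(toy$map, cfg)
  nz <- d$prob[d$prob > 0]
  expect_lt(diff(range(nz)) / mean(nz), 1e-6)

  # exclusion-zone fragments carry zero probability
  excl <- abs((toy$map$start + toy$map$end) / 2 - 65000) < 900 & toy$map$chrom == "chrA"
  expect_true(all(d$prob[excl] == 0))
})

test_that("two cis fragments at distances d and 2d get probabilities 2:1", {
  # viewpoint = first 100 bp fragment; neighbours at midpoint distances 100, 200
  cfg <- sim_config(regular_map, list(v = regular_map$frag_id[1]),
                    alpha = 1, trans_frac = 0, exclusion_bp = 0)
  d <- build_interaction_distribution(regular_map, cfg)
  expect_equal(d$prob, c(0, 2 / 3, 1 / 3))
})

test_that("peak weight multiplies the decay weight by 1 + weight", {
  cfg <- sim_config(regular_map, list(v = regular_map$frag_id[1]),
                    peaks = tibble(frag_id = regular_map$frag_id[3], weight = 3),
                    alpha = 1, trans_frac = 0, exclusion_bp = 0)
  d <- build_interaction_distribution(regular_map, cfg)
  # weights 1/100 and 4/200 = 1/50: ratio 1:2
  expect_equal(d$prob, c(0, 1 / 3, 2 / 3))
})

test_that("breakpoint sampling matches its closed-form weights", {
  withr::with_seed(21, {
    # tagmentation with weight 1 is the sonication distribution
    seqs <- strrep("ACGT", 25)
    p1 <- table(factor(sample_breakpoints(seqs, "tagmentation", gc_weight = 1, n = 2e4),
                       levels = 1:99)) / 2e4
    expect_lt(max(abs(p1 - 1 / 99)), 3 * sqrt((1 / 99) * (98 / 99) / 2e4))

    # all-G sequence: uniform for any weight
    pg <- table(factor(sample_breakpoints(strrep("G", 50), "tagmentation",
                                          gc_weight = 7, n = 2e4),
                       levels = 1:49)) / 2e4
    expect_lt(max(abs(pg - 1 / 49)), 3 * sqrt((1 / 49) * (48 / 49) / 2e4))

    # empirical frequencies match the normalized weight vector within 3 SE
    s <- "ATGCATTGGC"
    w <- ifelse(strsplit(s, "")[[1]][1:9] %in% c("G", "C"), 3, 1)
    p <- w / sum(w)
    emp <- table(factor(sample_breakpoints(s, "tagmentation", gc_weight = 3, n = 1e5),
                        levels = 1:9)) / 1e5
    se <- sqrt(p * (1 - p) / 1e5)
    expect_true(all(abs(emp - p) <= 3 * se))
  })
})

test_that("PCR duplication follows the geometric law and wobble contract", {
  mol <- tibble(molecule_id = 1:2, chrom1 = "c1", start1 = c(100L, 500L),
                end1 = c(300L, 700L), chrom2 = "c1", start2 = c(1000L, 2000L),
                end2 = c(1150L, 2150L))

  # rho = 0: identity, no duplicates
  withr::with_seed(1, r0 <- apply_pcr_duplication(mol, 0, 0))
  expect_equal(nrow(r0), 2L)
  expect_false(any(r0$is_duplicate))
  expect_false(any(r0$wobbled))

  # epsilon = 1: every duplicate differs from its original by L1 1 or 2 on one end
  withr::with_seed(2, {
    r1 <- apply_pcr_duplication(mol[1, ], rho = 3, epsilon = 1)
    dup <- r1[r1$is_duplicate, ]
    d <- abs(dup$start1 - r1$start1[1]) + abs(dup$end2 - r1$end2[1])
    expect_true(all(d %in% c(1L, 2L)))
    expect_true(all(dup$umi_left_true == r1$start1[1] & dup$umi_right_true == r1$end2[1]))
  })

  # epsilon = 0: all reads of one molecule share an identical UMI pair
  withr::with_seed(3, {
    r2 <- apply_pcr_duplication(mol, rho = 2, epsilon = 0)
    per <- split(paste(r2$start1, r2$end2), r2$molecule_id)
    expect_true(all(vapply(per, function(k) length(unique(k)) == 1, logical(1))))
  })

  # mean reads per molecule ~ 1 + rho (3 SE of the geometric mean)
  withr::with_seed(4, {
    big <- mol[rep(1, 1e4), ]
    big$molecule_id <- 1:1e4
    r3 <- apply_pcr_duplication(big, rho = 1.5, epsilon = 0)
    m <- nrow(r3) / 1e4
    # Var(1+G) = rho(1+rho)
    expect_lt(abs(m - 2.5), 3 * sqrt(1.5 * 2.5 / 1e4))
  })
})

test_that("simulated libraries are deterministic and conserve records", {
  fx <- peak_fixture(2000, seed = 31, dup_rate = 1, wobble_prob = 0.1)
  lib1 <- simulate_library(fx$cfg)
  lib2 <- simulate_library(fx$cfg)
  expect_identical(lib1, lib2) # byte-identical given the same config + seed
  expect_identical(sort(unique(lib1$reads$read_id)), sort(lib1$truth$read_id))
  expect_equal(nrow(lib1$reads), 2L * nrow(lib1$truth))
  # every unique molecule appears >= 1 time; originals are never wobbled
  expect_true(all(!lib1$truth$wobbled[!lib1$truth$is_duplicate]))
  orig <- lib1$truth[!lib1$truth$is_duplicate, ]
  expect_equal(sort(unique(lib1$truth$molecule_id)), sort(orig$molecule_id))

  # rho = 0, eps = 0: reads equal molecules, no duplicate flags
  fx0 <- peak_fixture(1500, seed = 32)
  lib0 <- simulate_library(fx0$cfg)
  expect_equal(nrow(lib0$truth), fx0$cfg$n_molecules - lib0$n_skipped)
  expect_false(any(lib0$truth$is_duplicate))
})

test_that("reporter frequencies converge to the target distribution", {
  # compact locus so the irreducible multinomial sampling error at this depth
  # sits well below the bound (checked against an ideal draw below)
  genome <- simulate_genome(c(chrA = 30000, chrB = 10000), seed = 330)
  map <- digest_reference(genome)
  vp <- locate_fragment(map, "chrA", 15000, 15001)
  pk <- locate_fragment(map, "chrA", c(5000, 22000, 27000), c(5001, 22001, 27001))
  cfg <- sim_config(map, list(v = vp), peaks = tibble(frag_id = pk, weight = 50),
                    alpha = 1, trans_frac = 0.1, n_molecules = 5e4, dup_rate = 0,
                    wobble_prob = 0, seed = 33)
  lib <- simulate_library(cfg)
  dist <- build_interaction_distribution(map, cfg)
  emp <- tabulate(match(lib$truth$reporter_frag, dist$frag_id), nbins = nrow(dist))
  emp <- emp / sum(emp)
  tv <- sum(abs(emp - dist$prob)) / 2
  expect_lt(tv, 0.02)
  # threshold sanity: an ideal multinomial draw of the same size behaves alike
  withr::with_seed(34, {
    ideal <- as.vector(stats::rmultinom(1, nrow(lib$truth), dist$prob))
  })
  tv_ideal <- sum(abs(ideal / sum(ideal) - dist$prob)) / 2
  expect_lt(tv_ideal, 0.02)
})

test_that("cis fraction of unique molecules converges to 1 - t", {
  fx <- cistrans_fixture(trans_frac = 0.3, n_molecules = 8000, seed = 35)
  mols <- fx$lib$truth[!fx$lib$truth$is_duplicate, ]
  expect_lt(abs(mean(mols$is_cis) - 0.7), 3 * sqrt(0.3 * 0.7 / nrow(mols)))
})

test_that("configuration validation rejects out-of-range parameters", {
  toy <- toy_fixture()
  vp <- toy$map$frag_id[10]
  expect_error(sim_config(toy$map, list(v = 10^7)), "absent")
  expect_error(sim_config(toy$map, list(v = vp), trans_frac = 1.2), "trans_frac")
  expect_error(sim_config(toy$map, list(v = vp), n_molecules = 0), "n_molecules")
  expect_error(sim_config(toy$map, list(v = vp), gc_weight = 0.5), "gc_weight")
  expect_error(sim_config(toy$map, list(v = vp), breakpoint_model = "tagmentation"),
               "genome")
})
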