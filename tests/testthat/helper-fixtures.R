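# Fixtures are generated in code; oracles here are intentionally brute-force
# and independent of the implementation paths they check.

suppressPackageStartupMessages({
  library(tibble)
  library(dplyr)
})

# --- oracles -----------------------------------------------------------------

# Brute-force digestion: test every position for a motif occurrence.
oracle_fragment_bounds <- function(seq, motif) {
  seq <- toupper(seq); motif <- toupper(motif)
  L <- nchar(seq); k <- nchar(motif)
  cuts <- integer(0)
  if (k <= L) {
    for (p in 0:(L - k)) {
      if (substr(seq, p + 1, p + k) == motif) cuts <- c(cuts, p)
    }
  }
  starts <- sort(unique(c(0L, cuts)))
  ends <- c(starts[-1], L)
  keep <- ends > starts
  cbind(start = starts[keep], end = ends[keep])
}

# All-pairs + connected-components dedup oracle (igraph does the components).
oracle_cluster_count <- function(umis, max_wobble) {
  n <- nrow(umis)
  if (n <= 1) return(n)
  same <- outer(umis$umi_lchrom, umis$umi_lchrom, "==") &
    outer(umis$umi_rchrom, umis$umi_rchrom, "==")
  d <- abs(outer(umis$umi_left, umis$umi_left, "-")) +
    abs(outer(umis$umi_right, umis$umi_right, "-"))
  adj <- same & d <= max_wobble
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  igraph::components(g)$no
}

# Two-pass textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Truncated sliding window mean, straight from the definition.
oracle_window <- function(x, window) {
  h <- (window - 1) / 2
  vapply(seq_along(x), function(i) {
    mean(x[max(1, i - h):min(length(x), i + h)])
  }, numeric(1))
}

# --- fixture builders --------------------------------------------------------

random_umi_set <- function(n, n_chrom = 2, coord_range = 60) {
  tibble(
    read_id = sprintf("u%04d", seq_len(n)),
    umi_lchrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    umi_left = sample.int(coord_range, n, replace = TRUE),
    umi_rchrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    umi_right = sample.int(coord_range, n, replace = TRUE)
  )
}

umi_reads <- function(left, right, lchrom = "chr1", rchrom = lchrom) {
  tibble(read_id = sprintf("r%03d", seq_along(left)),
         umi_lchrom = lchrom, umi_left = left,
         umi_rchrom = rchrom, umi_right = right)
}

# Regular toy chromosome: `n` fragments of `size` bp each (motif at the start
# of every fragment except the first, whose leading cut is at position 0).
regular_chrom <- function(n, size = 100) {
  paste(rep(paste0("GATC", strrep("A", size - 4)), n), collapse = "")
}

# Two-chromosome toy locus used across tests.
toy_fixture <- function(seed = 7) {
  genome <- simulate_genome(c(chrA = 130000, chrB = 50000), seed = seed)
  map <- digest_reference(genome)
  list(genome = genome, map = map)
}

# ~500-fragment map with a mid-chromosome viewpoint and three planted
# enhancer-like peaks.
peak_fixture <- function(n_molecules, seed, dup_rate = 0, wobble_prob = 0) {
  toy <- toy_fixture()
  map <- toy$map
  vp_pos <- 65000
  vp <- locate_fragment(map, "chrA", vp_pos, vp_pos + 1)
  peak_pos <- vp_pos + c(12000, 20000, 35000)
  peak_ids <- locate_fragment(map, "chrA", peak_pos, peak_pos + 1)
  cfg <- sim_config(map, viewpoints = list(vpA = vp), genome = toy$genome,
                    peaks = tibble(frag_id = peak_ids, weight = 50),
                    alpha = 1, trans_frac = 0.1, n_molecules = n_molecules,
                    dup_rate = dup_rate, wobble_prob = wobble_prob, seed = seed)
  list(map = map, genome = toy$genome, cfg = cfg, viewpoint = vp, peaks = peak_ids)
}

# Sparse multiplexed design: 48 single-fragment viewpoints on 12 x 2 Mb
# chromosomes, shallow decay; coordinate-UMI space is far from saturated.
sparse_fixture_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lens <- setNames(rep(2e6, 12), paste0("chr", 1:12))
      genome <- simulate_genome(lens, seed = 424242)
      cache <<- digest_reference(genome)
    }
    cache
  }
})

sparse_fixture <- function(n_molecules = 5000, wobble_prob = 0, dup_rate = 1,
                           seed = 5) {
  map <- sparse_fixture_map()
  vps <- unlist(lapply(unique(map$chrom), function(cm) {
    f <- map$frag_id[map$chrom == cm]
    f[round(seq(0.2, 0.8, length.out = 4) * length(f))]
  }))
  cfg <- sim_config(map, viewpoints = as.integer(vps), alpha = 0.3,
                    trans_frac = 0.3, n_molecules = n_molecules,
                    dup_rate = dup_rate, wobble_prob = wobble_prob, seed = seed)
  lib <- simulate_library(cfg)
  cls <- classify_reads(lib$reads, map, sim_targets(cfg))
  list(map = map, cfg = cfg, lib = lib,
       informative = cls[cls$status == "informative", ])
}

# Two equal chromosomes for cis/trans recovery at a chosen trans fraction.
cistrans_fixture <- function(trans_frac, n_molecules = 10000, seed = 1) {
  genome <- simulate_genome(c(chrA = 150000, chrB = 150000), seed = 99)
  map <- digest_reference(genome)
  vp <- locate_fragment(map, "chrA", 75000, 75001)
  cfg <- sim_config(map, viewpoints = list(vpA = vp), alpha = 0.3,
                    trans_frac = trans_frac, n_molecules = n_molecules,
                    dup_rate = 0, wobble_prob = 0, seed = seed)
  lib <- simulate_library(cfg)
  cls <- classify_reads(lib$reads, map, sim_targets(cfg))
  list(map = map, cfg = cfg, lib = lib,
       informative = cls[cls$status == "informative", ])
}

# Small GC-rich locus where the coordinate-UMI space is appreciably occupied,
# so breakpoint clustering translates into UMI collisions.
gcrich_collision_rate <- function(n_molecules, model, seed, gc_weight = 5) {
  genome <- simulate_genome(c(chrG = 30000), gc = 0.6, seed = 777)
  map <- digest_reference(genome)
  vp <- locate_fragment(map, "chrG", 15000, 15001)
  cfg <- sim_config(map, viewpoints = list(vpG = vp), genome = genome,
                    alpha = 0.3, trans_frac = 0, n_molecules = n_molecules,
                    dup_rate = 0, wobble_prob = 0,
                    breakpoint_model = model, gc_weight = gc_weight, seed = seed)
  umi_collision_rate(simulate_library(cfg)$truth)
}
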