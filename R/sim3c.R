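# Synthetic 3C/Capture-C library generator with exhaustive ground truth.
# Mechanism mirrors the wet-lab order of events: ligation of a viewpoint
# fragment to a reporter fragment drawn from a specified interaction
# distribution, shearing of the junction molecule (sonication or GC-biased
# tagmentation), then PCR duplication with occasional "wobbly" UMI ends.

#' Generate a random reference genome
#'
#' Bases are drawn independently at the requested GC content; useful for
#' building toy fragment maps of any size in tests and simulations.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc GC content in `[0, 1]` (default 0.42, mammalian-like).
#' @param seed Optional seed; when given the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return Named character vector of sequences.
#' @export
simulate_genome <- function(chrom_lengths, gc = 0.42, seed = NULL) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop_invalid("`chrom_lengths` must be named")
  }
  check_number(gc, "gc", 0, 1)
  draw <- function() vapply(chrom_lengths, random_dna, character(1), gc = gc)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulation configuration
#'
#' Bundles and validates everything [simulate_library()] needs. Viewpoints are
#' given as named groups of fragment ids (one group per captured promoter;
#' duplicated-gene promoters form one group whose members must share a
#' chromosome). A bare integer vector is treated as independent
#' single-fragment groups.
#'
#' @param map A [digest_reference()] fragment map.
#' @param viewpoints Named list of integer fragment-id vectors, or an integer
#'   vector (each id its own group).
#' @param genome Genome sequences; required for the tagmentation breakpoint
#'   model (base composition drives the bias) and for FASTQ export.
#' @param peaks Optional tibble with columns `frag_id`, `weight` (>= 0):
#'   enhancer-like cis enrichment multiplying the decay weight by `1 + weight`.
#' @param alpha Cis distance-decay exponent (> 0).
#' @param trans_frac Fraction `t` of unique molecules that are trans (on a
#'   different chromosome than their viewpoint), shared uniformly across all
#'   trans fragments. Default 0.2, typical of a well-fixed library.
#' @param n_molecules Number of unique ligation molecules to simulate.
#' @param dup_rate Mean number of PCR duplicates per molecule (geometric law).
#' @param wobble_prob Probability that a duplicate has one UMI coordinate
#'   shifted by 1-2 bp (sequencing/mapping "wobble"). Default 0.05; the rate
#'   is not anchored to any measured value.
#' @param breakpoint_model `"sonication"` (uniform breakpoints) or
#'   `"tagmentation"` (G/C-weighted breakpoints).
#' @param gc_weight Relative weight (>= 1) of a G or C base under the
#'   tagmentation model; 1 reproduces sonication.
#' @param insert_mean,insert_sd,insert_range Sheared insert size model:
#'   normal, rounded, truncated to `insert_range` (defaults 200/30, [50, 500]).
#' @param exclusion_bp Half-width of the proximity-exclusion zone around each
#'   viewpoint fragment (default 1000 bp); excluded fragments get probability
#'   zero so simulated truth matches what the analysis can see.
#' @param seed Integer seed; identical configurations give byte-identical
#'   libraries.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(map, viewpoints, genome = NULL, peaks = NULL,
                       alpha = 1, trans_frac = 0.2, n_molecules = 10000,
                       dup_rate = 1, wobble_prob = 0.05,
                       breakpoint_model = c("sonication", "tagmentation"),
                       gc_weight = 3, insert_mean = 200, insert_sd = 30,
                       insert_range = c(50, 500), exclusion_bp = 1000,
                       seed = 1L) {
  check_fragment_map(map)
  breakpoint_model <- match.arg(breakpoint_model)
  if (is.numeric(viewpoints)) {
    viewpoints <- setNames(as.list(as.integer(viewpoints)),
                           paste0("vp", as.integer(viewpoints)))
  }
  if (!is.list(viewpoints) || length(viewpoints) == 0 ||
      is.null(names(viewpoints)) || any(names(viewpoints) == "")) {
    stop_invalid("`viewpoints` must be a named list of fragment-id vectors")
  }
  for (g in names(viewpoints)) {
    ids <- as.integer(viewpoints[[g]])
    rows <- match(ids, map$frag_id)
    if (anyNA(rows)) stop_invalid(sprintf("viewpoint group '%s' has ids absent from the map", g))
    if (length(unique(map$chrom[rows])) != 1L) {
      stop_invalid(sprintf("viewpoint group '%s' spans chromosomes", g))
    }
    viewpoints[[g]] <- ids
  }
  if (!is.null(peaks)) {
    check_columns(peaks, c("frag_id", "weight"), "peaks")
    if (any(peaks$weight < 0)) stop_invalid("peak weights must be >= 0")
    if (!all(peaks$frag_id %in% map$frag_id)) stop_invalid("peak fragment ids absent from map")
  }
  check_number(alpha, "alpha", min = 1e-9)
  check_number(trans_frac, "trans_frac", 0, 1)
  n_molecules <- check_count(n_molecules, "n_molecules", min = 1L)
  check_number(dup_rate, "dup_rate", min = 0)
  check_number(wobble_prob, "wobble_prob", 0, 1)
  check_number(gc_weight, "gc_weight", min = 1)
  check_number(insert_mean, "insert_mean", min = 1)
  check_number(insert_sd, "insert_sd", min = 0)
  if (length(insert_range) != 2 || insert_range[1] < 2 || diff(insert_range) < 0) {
    stop_invalid("`insert_range` must be c(lo, hi) with 2 <= lo <= hi")
  }
  check_number(exclusion_bp, "exclusion_bp", min = 0)
  if (breakpoint_model == "tagmentation" && is.null(genome)) {
    stop_invalid("the tagmentation model needs `genome` for base composition")
  }
  if (!is.null(genome)) genome <- as_genome(genome)
  structure(list(
    map = map, viewpoints = viewpoints, genome = genome, peaks = peaks,
    alpha = alpha, trans_frac = trans_frac, n_molecules = n_molecules,
    dup_rate = dup_rate, wobble_prob = wobble_prob,
    breakpoint_model = breakpoint_model, gc_weight = gc_weight,
    insert_mean = insert_mean, insert_sd = insert_sd,
    insert_range = as.numeric(insert_range), exclusion_bp = exclusion_bp,
    seed = as.integer(seed)), class = "sim_config")
}

#' Viewpoint target table of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `group`, `frag_id`, ready for
#'   [classify_reads()].
#' @export
sim_targets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  purrr::imap_dfr(config$viewpoints, function(ids, g) tibble(group = g, frag_id = ids))
}

#' True interaction distribution for one viewpoint group
#'
#' Cis fragment `i` receives unnormalized weight `(1 + peak_i) * d_i^-alpha`,
#' where `d_i` is the midpoint distance to the nearest viewpoint member,
#' floored at the viewpoint fragment length to avoid the singularity at zero.
#' Trans fragments share total mass `trans_frac` uniformly. Viewpoint members
#' and fragments inside the exclusion zone get probability zero. The vector
#' sums to one.
#'
#' @param map A fragment map (must match `config$map`).
#' @param config A [sim_config()].
#' @param group Viewpoint group name; default the first group.
#' @return Tibble with columns `frag_id`, `chrom`, `prob`, `is_cis`.
#' @export
build_interaction_distribution <- function(map, config, group = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_fragment_map(map)
  group <- group %||% names(config$viewpoints)[1]
  ids <- config$viewpoints[[group]]
  if (is.null(ids)) stop_invalid(sprintf("unknown viewpoint group '%s'", group))
  vp <- map[match(ids, map$frag_id), ]
  vp_chrom <- vp$chrom[1]
  vp_mid <- (vp$start + vp$end) / 2
  floor_d <- mean(vp$end - vp$start)

  mid <- (map$start + map$end) / 2
  cis <- map$chrom == vp_chrom
  excluded <- rep(FALSE, nrow(map))
  for (k in seq_len(nrow(vp))) {
    excluded <- excluded | (map$chrom == vp_chrom &
      map$start < vp$end[k] + config$exclusion_bp &
      map$end > vp$start[k] - config$exclusion_bp)
  }
  is_vp <- map$frag_id %in% ids

  d <- rep(Inf, nrow(map))
  for (m in vp_mid) d <- pmin(d, abs(mid - m))
  peak_w <- rep(0, nrow(map))
  if (!is.null(config$peaks)) {
    hit <- match(map$frag_id, config$peaks$frag_id)
    peak_w[!is.na(hit)] <- config$peaks$weight[hit[!is.na(hit)]]
  }
  w_cis <- ifelse(cis & !excluded & !is_vp,
                  (1 + peak_w) * pmax(d, floor_d)^(-config$alpha), 0)
  n_trans <- sum(!cis)
  t <- config$trans_frac
  prob <- numeric(nrow(map))
  cis_total <- sum(w_cis)
  if (t < 1) {
    if (cis_total == 0) stop_data("all cis weights are zero (everything excluded?)")
    prob[cis & !excluded & !is_vp] <- w_cis[cis & !excluded & !is_vp] / cis_total * (1 - t)
  }
  if (t > 0) {
    if (n_trans == 0) stop_data("trans_frac > 0 but the map has no trans fragments")
    prob[!cis] <- t / n_trans
  }
  if (sum(prob) == 0) stop_data("interaction distribution is identically zero")
  tibble(frag_id = map$frag_id, chrom = map$chrom, prob = prob, is_cis = cis)
}

#' Sample shear breakpoints within a sequence
#'
#' Positions index the bond after each base, `1 .. nchar(sequence) - 1`.
#' Sonication draws uniformly; tagmentation weights a position by `gc_weight`
#' when the base at that position is G or C and by 1 otherwise.
#'
#' @param sequence A DNA string of length >= 2.
#' @param model `"sonication"` or `"tagmentation"`.
#' @param gc_weight G/C weight (>= 1), tagmentation only.
#' @param n Number of positions to draw.
#' @return Integer vector of breakpoint positions.
#' @export
sample_breakpoints <- function(sequence, model = c("sonication", "tagmentation"),
                               gc_weight = 3, n = 1) {
  model <- match.arg(model)
  len <- nchar(sequence)
  if (len < 2) stop_invalid("`sequence` must have length >= 2")
  pos <- seq_len(len - 1L)
  if (model == "sonication" || gc_weight == 1) {
    return(sample(pos, n, replace = TRUE))
  }
  bases <- strsplit(toupper(sequence), "")[[1]][pos]
  w <- ifelse(bases %in% c("G", "C"), gc_weight, 1)
  sample(pos, n, replace = TRUE, prob = w)
}

# Integer draws from a normal truncated to [lo, hi] (inverse-CDF, vectorized).
rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(as.integer(pmin(pmax(round(mean), lo), hi)), n))
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  as.integer(pmin(pmax(round(qnorm(u, mean, sd)), lo), hi))
}

# Per-fragment tagmentation weight cache: weight of cutting at each bond.
frag_gc_weights <- function(seq, w) {
  b <- strsplit(seq, "")[[1]]
  ifelse(b %in% c("G", "C"), w, 1)
}

#' Simulate a Capture-C library with ground truth
#'
#' For each unique molecule: a viewpoint group (uniform) and member fragment
#' (uniform within group), a reporter from [build_interaction_distribution()],
#' an insert spanning the ligation junction with a size from the truncated
#' normal model and ends placed by the configured breakpoint model; the
#' molecule is emitted as two aligned slices (viewpoint side then reporter
#' side). PCR duplication and UMI wobble are applied by
#' [apply_pcr_duplication()], and records are shuffled. Identical
#' configurations (including seed) give byte-identical output.
#'
#' Molecules whose fragment pair cannot hold the minimum insert size are
#' skipped and counted in `n_skipped`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim3c_library`: `reads` (slice records: `read_id`,
#'   `slice_index`, `chrom`, `start`, `end`, `strand`), `truth` (one row per
#'   emitted read: molecule id, group, reporter fragment, cis flag, duplicate
#'   and wobble flags, true UMI pair), `config`, `n_requested`, `n_skipped`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_library_impl(config))
}

simulate_library_impl <- function(config) {
  map <- config$map
  n <- config$n_molecules
  groups <- names(config$viewpoints)
  grp <- sample(groups, n, replace = TRUE)
  # viewpoint member per molecule
  vp_frag <- integer(n)
  rep_frag <- integer(n)
  for (g in groups) {
    idx <- which(grp == g)
    if (length(idx) == 0) next
    members <- config$viewpoints[[g]]
    vp_frag[idx] <- if (length(members) == 1) members else sample(members, length(idx), replace = TRUE)
    dist <- build_interaction_distribution(map, config, g)
    rep_frag[idx] <- sample(dist$frag_id, length(idx), replace = TRUE, prob = dist$prob)
  }
  vrow <- match(vp_frag, map$frag_id)
  rrow <- match(rep_frag, map$frag_id)
  vchrom <- map$chrom[vrow]; vstart <- map$start[vrow]; vend <- map$end[vrow]
  rchrom <- map$chrom[rrow]; rstart <- map$start[rrow]
  Lv <- vend - vstart
  Lr <- map$end[rrow] - rstart

  lo <- config$insert_range[1]; hi <- config$insert_range[2]
  S <- rtrunc_norm_int(n, config$insert_mean, config$insert_sd, lo, hi)
  cap <- pmin(hi, Lv + Lr)
  feasible <- cap >= lo
  redo <- which(feasible & S > cap)
  # redraw within the locally feasible size range (bounded-retry equivalent)
  for (i in redo) {
    S[i] <- rtrunc_norm_int(1, config$insert_mean, config$insert_sd, lo, cap[i])
  }
  keep <- which(feasible)
  n_skipped <- n - length(keep)

  lmin <- pmax(1L, S - Lr)
  lmax <- pmin(Lv, S - 1L)
  ell <- integer(n)
  if (config$breakpoint_model == "sonication") {
    u <- runif(n)
    ell <- lmin + pmin(floor(u * (lmax - lmin + 1)), lmax - lmin)
  } else {
    seqs <- fragment_sequences(map, config$genome)
    cache <- new.env(parent = emptyenv())
    wts <- function(fid) {
      key <- as.character(fid)
      if (is.null(cache[[key]])) cache[[key]] <- frag_gc_weights(seqs[fid], config$gc_weight)
      cache[[key]]
    }
    for (i in keep) {
      lr <- lmin[i]:lmax[i]
      # weight both ends: first retained viewpoint base and last retained reporter base
      wv <- wts(vp_frag[i])[Lv[i] - lr + 1L]
      wr <- wts(rep_frag[i])[S[i] - lr]
      ell[i] <- if (length(lr) == 1) lr else sample(lr, 1, prob = wv * wr)
    }
  }

  left <- vstart + Lv - ell
  right <- rstart + (S - ell)
  molecules <- tibble(
    molecule_id = seq_len(n), group = grp,
    vp_frag = vp_frag, reporter_frag = rep_frag,
    is_cis = rchrom == vchrom,
    chrom1 = vchrom, start1 = left, end1 = vend,
    chrom2 = rchrom, start2 = rstart, end2 = right
  )[keep, ]

  reads <- apply_pcr_duplication(molecules, config$dup_rate, config$wobble_prob)
  reads <- reads[sample(nrow(reads)), ]
  reads$read_id <- sprintf("r%07d", seq_len(nrow(reads)))

  chrom_lengths <- attr(map, "chrom_lengths")
  if (!is.null(chrom_lengths)) { # wobble must not push a slice off the chromosome
    reads$start1 <- pmax(reads$start1, 0L)
    reads$end2 <- pmin(reads$end2, unname(chrom_lengths[reads$chrom2]))
  }

  slices <- tibble(
    read_id = rep(reads$read_id, each = 2),
    slice_index = rep(1:2, nrow(reads)),
    chrom = as.vector(rbind(reads$chrom1, reads$chrom2)),
    start = as.vector(rbind(reads$start1, reads$start2)),
    end = as.vector(rbind(reads$end1, reads$end2)),
    strand = "+"
  )
  truth <- tibble(
    read_id = reads$read_id, molecule_id = reads$molecule_id,
    group = reads$group, reporter_frag = reads$reporter_frag,
    is_cis = reads$is_cis, is_duplicate = reads$is_duplicate,
    wobbled = reads$wobbled,
    umi_lchrom = reads$chrom1, umi_left_true = reads$umi_left_true,
    umi_rchrom = reads$chrom2, umi_right_true = reads$umi_right_true
  )
  structure(list(reads = slices, truth = truth, config = config,
                 n_requested = n, n_skipped = n_skipped),
            class = "sim3c_library")
}

#' Apply PCR duplication and UMI wobble to unique molecules
#'
#' Each molecule is emitted `1 + G` times with `G ~ Geometric(mean rho)`.
#' Each duplicate independently, with probability `epsilon`, has exactly one
#' UMI coordinate (left or right end) shifted by +/-1 or +/-2 bp, uniformly
#' over the eight combinations; originals are never wobbled.
#'
#' @param molecules Tibble of unique molecules (as built by
#'   [simulate_library()]): slice coordinates `chrom1/start1/end1`,
#'   `chrom2/start2/end2` plus any bookkeeping columns.
#' @param rho Mean duplicates per molecule (>= 0).
#' @param epsilon Wobble probability per duplicate.
#' @return Tibble with one row per emitted read: the molecule columns plus
#'   `is_duplicate`, `wobbled` and the true (pre-wobble) UMI pair
#'   `umi_left_true` / `umi_right_true`.
#' @export
apply_pcr_duplication <- function(molecules, rho, epsilon) {
  check_columns(molecules, c("chrom1", "start1", "end1", "chrom2", "start2", "end2"),
                "molecules")
  check_number(rho, "rho", min = 0)
  check_number(epsilon, "epsilon", 0, 1)
  n <- nrow(molecules)
  g <- if (rho > 0) rgeom(n, 1 / (1 + rho)) else rep(0L, n)
  idx <- rep(seq_len(n), g + 1L)
  reads <- molecules[idx, ]
  reads$is_duplicate <- duplicated(idx)
  reads$umi_left_true <- reads$start1
  reads$umi_right_true <- reads$end2
  wob <- reads$is_duplicate & runif(nrow(reads)) < epsilon
  reads$wobbled <- wob
  nw <- sum(wob)
  if (nw > 0) {
    combo <- sample.int(8L, nw, replace = TRUE)
    shift <- c(-2L, -1L, 1L, 2L)[(combo - 1L) %% 4L + 1L]
    left_end <- combo <= 4L
    wl <- which(wob)[left_end]
    wr <- which(wob)[!left_end]
    reads$start1[wl] <- pmin(pmax(reads$start1[wl] + shift[left_end], 0L),
                             reads$end1[wl] - 1L)
    reads$end2[wr] <- pmax(reads$end2[wr] + shift[!left_end],
                           reads$start2[wr] + 1L)
  }
  reads
}

#' Fraction of unique molecules lost to coordinate-UMI collisions
#'
#' Two distinct molecules that happen to shear at identical coordinates are
#' indistinguishable from PCR duplicates and collapse to one UMI; this is the
#' mechanism by which base-biased tagmentation breakpoints cost complexity at
#' high input. Computed from the simulation truth: one minus the number of
#' distinct true UMI keys (per viewpoint group) over the number of unique
#' molecules.
#'
#' @param truth Truth table of a [simulate_library()] result.
#' @return A single number in `[0, 1]`.
#' @export
umi_collision_rate <- function(truth) {
  check_columns(truth, c("molecule_id", "group", "umi_lchrom", "umi_left_true",
                         "umi_rchrom", "umi_right_true"), "truth")
  mols <- dplyr::distinct(truth, .data$molecule_id, .keep_all = TRUE)
  key <- paste(mols$group, mols$umi_lchrom, mols$umi_left_true,
               mols$umi_rchrom, mols$umi_right_true)
  1 - length(unique(key)) / nrow(mols)
}
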