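# Hybridization-based (NanoString-style) junction counting: probe design
# against restriction-fragment ends, per-sample count normalization,
# input-linearity QC, comparison with capture profiles, and differential
# count profiles.

#' Design fragment-end reporter probes
#'
#' For each targeted restriction fragment: the left-end probe is the
#' top-strand sequence of the first `probe_length` bp of the fragment, and the
#' right-end probe is the bottom strand of the last `probe_length` bp (the
#' reverse complement of the genomic top strand over that interval), so a
#' denatured junction molecule can be captured from either fragment end.
#' Fragments shorter than `probe_length` are skipped and listed in the
#' `skipped` attribute.
#'
#' @param map A fragment map.
#' @param genome The genome the map was digested from.
#' @param targets Integer vector of target fragment ids.
#' @param probe_length Probe length in nt (default 50).
#' @return Tibble of class `probe_design`: `frag_id`, `chrom`, left probe
#'   coordinates/strand/sequence, right probe coordinates/strand/sequence.
#' @export
design_probes <- function(map, genome, targets, probe_length = 50) {
  check_fragment_map(map)
  genome <- as_genome(genome)
  probe_length <- check_count(probe_length, "probe_length", min = 1L)
  rows <- match(targets, map$frag_id)
  if (anyNA(rows)) stop_data("some target fragment ids are absent from the map")
  frag <- map[rows, ]
  short <- frag$end - frag$start < probe_length
  skipped <- frag$frag_id[short]
  frag <- frag[!short, ]
  top <- substring(genome[frag$chrom], frag$start + 1L, frag$start + probe_length)
  right_top <- substring(genome[frag$chrom], frag$end - probe_length + 1L, frag$end)
  out <- tibble(
    frag_id = frag$frag_id, chrom = frag$chrom,
    left_start = frag$start, left_end = frag$start + probe_length,
    left_strand = "+", left_seq = unname(top),
    right_start = frag$end - probe_length, right_end = frag$end,
    right_strand = "-", right_seq = revcomp(unname(right_top))
  )
  structure(out, skipped = skipped, probe_length = probe_length,
            class = c("probe_design", class(tibble())))
}

check_counts <- function(counts, name = "counts") {
  check_columns(counts, c("frag_id", "sample", "count"), name)
  if (any(counts$count < 0)) stop_data("counts must be non-negative")
  as_tibble(counts)
}

#' Normalize a count table per sample
#'
#' Scales each sample's counts so that its total over the probed fragments
#' equals `scale` (default 1000, the conventional probed-set total). The
#' instrument only sees probed fragments, so the normalization total is over
#' the probed set.
#'
#' @param counts Long count tibble: `frag_id`, `sample`, `count`.
#' @param scale Target per-sample total (default 1000).
#' @return The tibble with `count` rescaled; attribute `scale` records the
#'   constant.
#' @export
normalize_counts <- function(counts, scale = 1000) {
  counts <- check_counts(counts)
  check_number(scale, "scale", min = 1e-12)
  totals <- tapply(counts$count, counts$sample, sum)
  if (any(totals <= 0)) {
    stop_data(paste("sample(s) with zero total counts:",
                    paste(names(totals)[totals <= 0], collapse = ", ")))
  }
  counts$count <- counts$count * scale / as.vector(totals[counts$sample])
  structure(counts, scale = scale)
}

#' Linearity of counts against input mass
#'
#' Ordinary least squares of raw counts on input library mass, per sample
#' group (tissue) — for the total count over all probes and per probe. A
#' quantitative, amplification-free assay should be linear through the origin.
#'
#' @param counts Raw long count tibble (`frag_id`, `sample`, `count`).
#' @param samples Sample metadata: `sample`, `tissue`, `input_mass` (same mass
#'   unit throughout, e.g. micrograms); >= 3 samples with >= 2 distinct masses
#'   per tissue.
#' @return Object of class `cstring_linearity`: list with `total` (per-tissue
#'   slope/intercept/r of the total-count regression) and `per_probe`
#'   (the same per fragment). Supports [tidy()], [glance()], [autoplot()].
#' @export
linearity_check <- function(counts, samples) {
  counts <- check_counts(counts)
  check_columns(samples, c("sample", "tissue", "input_mass"), "samples")
  df <- dplyr::inner_join(counts, as_tibble(samples), by = "sample")
  if (nrow(df) == 0) stop_data("no overlap between counts and sample metadata")
  n_mass <- tapply(samples$input_mass, samples$tissue, function(x) length(unique(x)))
  if (any(n_mass < 2)) stop_data("need >= 2 distinct input masses per tissue")

  ols <- function(mass, y) {
    fit <- lm(y ~ mass)
    r <- if (sd(y) == 0) 0 else cor(mass, y)
    # exactly-linear input triggers lm's perfect-fit warning; the SE is then 0
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])
    tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
           slope_se = se, r = r)
  }
  totals <- df |>
    dplyr::group_by(.data$tissue, .data$sample, .data$input_mass) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  total <- totals |>
    dplyr::group_by(.data$tissue) |>
    dplyr::reframe(ols(.data$input_mass, .data$count))
  per_probe <- df |>
    dplyr::group_by(.data$tissue, .data$frag_id) |>
    dplyr::reframe(ols(.data$input_mass, .data$count))
  structure(list(total = total, per_probe = per_probe, data = totals),
            class = "cstring_linearity")
}

#' @export
tidy.cstring_linearity <- function(x, ...) x$per_probe

#' @export
glance.cstring_linearity <- function(x, ...) x$total

#' Compare a count column with a capture interaction profile
#'
#' Restricts the capture profile to the probed fragments, renormalizes both
#' vectors to the same total over that set (making them commensurable), and
#' reports the Pearson correlation together with the aligned value pairs.
#'
#' @param counts Normalized counts for one sample (`frag_id`, `count`; a long
#'   table may be given together with `sample`).
#' @param profile An `interaction_profile` (raw or normalized).
#' @param sample Sample id when `counts` holds several samples.
#' @param scale Common total for both vectors (default 1000).
#' @return Object of class `cstring_capture_comparison`: list with `r` and
#'   `pairs` (tibble `frag_id`, `count`, `capture`). Supports [tidy()] /
#'   [glance()].
#' @export
compare_to_capture <- function(counts, profile, sample = NULL, scale = 1000) {
  check_columns(counts, c("frag_id", "count"), "counts")
  check_profile(profile, "profile", kind = c("raw", "normalized", "windowed"))
  counts <- as_tibble(counts)
  if (!is.null(sample)) counts <- counts[counts$sample == sample, ]
  if (anyDuplicated(counts$frag_id)) {
    stop_invalid("`counts` must hold one sample (use `sample =` to select)")
  }
  rows <- match(counts$frag_id, profile$frag_id)
  if (anyNA(rows)) stop_data("probed fragments missing from the capture profile")
  if (nrow(counts) < 2) stop_data("need >= 2 overlapping fragments")
  cap <- profile$value[rows]
  if (sum(counts$count) <= 0 || sum(cap) <= 0) stop_data("zero totals over the probed set")
  cs <- counts$count * scale / sum(counts$count)
  cp <- cap * scale / sum(cap)
  if (sd(cs) == 0 || sd(cp) == 0) stop_data("zero variance over the probed set")
  pairs <- tibble(frag_id = counts$frag_id, count = cs, capture = cp)
  structure(list(r = cor(cs, cp), pairs = pairs, scale = scale),
            class = "cstring_capture_comparison")
}

#' @export
tidy.cstring_capture_comparison <- function(x, ...) x$pairs

#' @export
glance.cstring_capture_comparison <- function(x, ...) {
  tibble(r = x$r, n_fragments = nrow(x$pairs), scale = x$scale)
}

#' @export
print.cstring_capture_comparison <- function(x, ...) {
  cat(sprintf("<cstring_capture_comparison> r = %.4f over %d probed fragments\n",
              x$r, nrow(x$pairs)))
  invisible(x)
}

#' Differential count profile between two sample groups
#'
#' Per fragment: mean(A) - mean(B) of normalized counts, with standard error
#' `sqrt(SE_A^2 + SE_B^2)` (SE of the replicate mean, 0 for single
#' replicates) — the same arithmetic as [differential_profile()].
#'
#' @param counts Normalized long count tibble.
#' @param samples_a,samples_b Character vectors of sample ids in each group.
#' @return Tibble: `frag_id`, `value`, `se`.
#' @export
differential_counts <- function(counts, samples_a, samples_b) {
  counts <- check_counts(counts)
  if (length(samples_a) == 0 || length(samples_b) == 0) {
    stop_invalid("each group needs >= 1 sample")
  }
  wide <- function(ids) {
    sub <- counts[counts$sample %in% ids, ]
    if (length(setdiff(ids, sub$sample)) > 0) stop_data("unknown sample id(s)")
    m <- tidyr::pivot_wider(sub, id_cols = "frag_id", names_from = "sample",
                            values_from = "count")
    list(frag_id = m$frag_id, mat = as.matrix(m[-1]))
  }
  a <- wide(samples_a); b <- wide(samples_b)
  if (!identical(a$frag_id, b$frag_id)) stop_data("probe sets differ between groups")
  tibble(frag_id = a$frag_id,
         value = rowMeans(a$mat) - rowMeans(b$mat),
         se = sqrt(se_of_mean(a$mat)^2 + se_of_mean(b$mat)^2))
}
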