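# Library-quality statistics: cis/trans composition, replicate correlation,
# fragments per read, and qPCR-derived digestion efficiency / mass.

#' Percentage of unique interactions detected in cis
#'
#' Counted per reporter-fragment event on post-deduplication informative
#' reads: an event is cis when the reporter's chromosome equals the read's
#' viewpoint chromosome.
#'
#' @param reads Retained classified reads (with `capture_frag` and
#'   `reporters`).
#' @param map The fragment map.
#' @return Percentage in `[0, 100]`. Zero interactions is an error.
#' @export
cis_fraction <- function(reads, map) {
  check_columns(reads, c("capture_frag", "reporters"), "reads")
  check_fragment_map(map)
  k <- lengths(reads$reporters)
  events <- unlist(reads$reporters, use.names = FALSE)
  if (length(events) == 0) stop_data("no unique interactions to classify as cis/trans")
  vp_chrom <- map$chrom[match(rep(reads$capture_frag, k), map$frag_id)]
  rep_chrom <- map$chrom[match(events, map$frag_id)]
  100 * mean(rep_chrom == vp_chrom)
}

#' Pearson correlation between two interaction profiles
#'
#' Standard product-moment correlation over the (optionally restricted)
#' per-fragment value vectors, as used to compare replicates.
#'
#' @param a,b `interaction_profile`s on the same map.
#' @param fragments Optional fragment-id set to restrict to (default: all).
#' @return Pearson r.
#' @export
replicate_correlation <- function(a, b, fragments = NULL) {
  check_profile(a, "a"); check_profile(b, "b")
  check_same_map(a, b)
  va <- a$value; vb <- b$value
  if (!is.null(fragments)) {
    keep <- a$frag_id %in% fragments
    if (sum(keep) < 2) stop_data("fewer than 2 fragments after restriction")
    va <- va[keep]; vb <- vb[keep]
  }
  if (sd(va) == 0 || sd(vb) == 0) stop_data("zero variance: correlation undefined")
  cor(va, vb)
}

#' Detected restriction fragments per read
#'
#' @param reads Classified reads (column `n_slices`).
#' @return List with `mean` (arithmetic mean slices per read) and `histogram`
#'   (tibble `n_slices`, `n_reads`).
#' @export
fragments_per_read <- function(reads) {
  check_columns(reads, "n_slices", "reads")
  if (nrow(reads) == 0) stop_data("no reads")
  tab <- table(reads$n_slices)
  list(mean = mean(reads$n_slices),
       histogram = tibble(n_slices = as.integer(names(tab)),
                          n_reads = as.integer(tab)))
}

pull_ct <- function(table, sample, assay, template) {
  rows <- table$sample == sample & table$assay == assay & table$template == template
  if (!any(rows)) {
    stop_data(sprintf("missing Ct for sample '%s', assay '%s', template '%s'",
                      sample, assay, template))
  }
  mean(table$ct[rows])
}

#' Digestion efficiency from 3C-library qPCR
#'
#' Compares the Ct of a primer pair spanning a restriction/ligation site with
#' a genomic-control pair, on the 3C library and on undigested genomic DNA
#' (which calibrates primer-pair differences):
#' `ddCt = (Ct_site - Ct_control)_3C - (Ct_site - Ct_control)_genomic`, and
#' `efficiency = 100 * (1 - eff^-ddCt)` clipped to `[0, 100]`. A perfectly
#' doubling assay (`eff = 2`) is assumed by default; the paper names the Ct
#' comparison but not the arithmetic, so this formula is a declared
#' convention.
#'
#' @param table qPCR tibble with columns `sample`, `assay`
#'   (`"junction-site"` / `"genomic-control"`), `template` (`"3C"` /
#'   `"genomic"`), `ct`.
#' @param sample Sample id to evaluate.
#' @param amp_efficiency Per-cycle amplification factor (default 2).
#' @return Digestion efficiency as a percentage.
#' @export
digestion_efficiency <- function(table, sample, amp_efficiency = 2) {
  check_columns(table, c("sample", "assay", "template", "ct"), "table")
  check_number(amp_efficiency, "amp_efficiency", min = 1 + 1e-9)
  if (any(table$ct <= 0)) stop_data("Ct values must be positive")
  d_3c <- pull_ct(table, sample, "junction-site", "3C") -
    pull_ct(table, sample, "genomic-control", "3C")
  d_g <- pull_ct(table, sample, "junction-site", "genomic") -
    pull_ct(table, sample, "genomic-control", "genomic")
  ddct <- d_3c - d_g
  min(max(100 * (1 - amp_efficiency^(-ddct)), 0), 100)
}

#' Quantify DNA mass against a qPCR standard curve
#'
#' Fits Ct against `log2(mass)` by ordinary least squares (slope -1 is the
#' ideal doubling assay) and inverts the line at the sample Ct.
#'
#' @param standards Tibble with columns `mass_ng`, `ct` (>= 2 distinct
#'   masses).
#' @param sample_ct Ct value(s) of the sample(s) to quantify.
#' @return Object of class `qpcr_mass_fit`: list with `mass_ng` (estimated
#'   masses), `slope`, `intercept`, `r_squared` and the standards used.
#'   Supports [tidy()] and [glance()].
#' @export
quantify_mass <- function(standards, sample_ct) {
  check_columns(standards, c("mass_ng", "ct"), "standards")
  if (length(unique(standards$mass_ng)) < 2) {
    stop_data("standard curve needs >= 2 distinct masses")
  }
  if (any(standards$mass_ng <= 0)) stop_data("standard masses must be positive")
  fit <- lm(ct ~ log2(mass_ng), data = standards)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope == 0) stop_data("degenerate standard curve")
  r2 <- if (sd(standards$ct) == 0) 1 else cor(standards$ct, fitted(fit))^2
  structure(list(mass_ng = 2^((sample_ct - intercept) / slope),
                 slope = slope, intercept = intercept, r_squared = r2,
                 standards = as_tibble(standards), sample_ct = sample_ct),
            class = "qpcr_mass_fit")
}

#' @export
tidy.qpcr_mass_fit <- function(x, ...) {
  tibble(sample_ct = x$sample_ct, mass_ng = x$mass_ng)
}

#' @export
glance.qpcr_mass_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n_standards = nrow(x$standards))
}

#' @export
print.qpcr_mass_fit <- function(x, ...) {
  cat(sprintf("<qpcr_mass_fit> slope %.3f cycles/log2(ng), r^2 %.4f\n",
              x$slope, x$r_squared))
  cat("estimated mass (ng):", format(x$mass_ng, digits = 4), "\n")
  invisible(x)
}

#' @importFrom stats fitted
NULL
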