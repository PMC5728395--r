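# Per-restriction-fragment interaction profiles: build from unique reads,
# pool duplicated-promoter viewpoints, normalize to a genome-wide total,
# smooth with fragment-count windows, and subtract conditions.

new_interaction_profile <- function(values, map, viewpoint, kind, total_raw,
                                    norm_constant = NA_real_, window = NA_integer_,
                                    replicate = NA_character_,
                                    viewpoint_chrom = NA_character_) {
  structure(as_tibble(values),
            map_fingerprint = map_fingerprint(map),
            viewpoint = viewpoint, kind = kind, total_raw = total_raw,
            norm_constant = norm_constant, window = window,
            replicate = replicate, viewpoint_chrom = viewpoint_chrom,
            class = c("interaction_profile", class(tibble())))
}

map_fingerprint <- function(map) {
  if (is.null(map)) return(NULL)
  c(n = nrow(map), sum_end = sum(as.numeric(map$end)), nchrom = length(unique(map$chrom)))
}

check_profile <- function(p, name = "profile", kind = NULL) {
  if (!inherits(p, "interaction_profile")) {
    stop_invalid(sprintf("`%s` must be an interaction_profile", name))
  }
  if (!is.null(kind) && !attr(p, "kind") %in% kind) {
    stop_invalid(sprintf("`%s` must be of kind %s (got '%s')", name,
                         paste(kind, collapse = "/"), attr(p, "kind")))
  }
  invisible(p)
}

check_same_map <- function(a, b) {
  if (!identical(attr(a, "map_fingerprint"), attr(b, "map_fingerprint"))) {
    stop_data("profiles were built on different fragment maps")
  }
}

#' Profile metadata accessors
#'
#' @param p An `interaction_profile`.
#' @return `profile_kind()`: one of `"raw"`, `"normalized"`, `"windowed"`,
#'   `"differential"`; `profile_total()`: total raw interactions.
#' @export
profile_kind <- function(p) attr(p, "kind")

#' @rdname profile_kind
#' @export
profile_total <- function(p) attr(p, "total_raw")

#' Build a raw interaction profile from unique reads
#'
#' The value at fragment `f` is the number of retained informative reads
#' reporting `f`; a read with reporters in `k` distinct fragments contributes
#' one interaction to each. The profile is dense over the fragment map;
#' viewpoint and excluded fragments carry zero by construction (they are
#' never reporters).
#'
#' @param reads Post-deduplication classified reads (the `retained` element of
#'   a [filter_duplicates()] result), informative status only.
#' @param map The fragment map the reads were classified on.
#' @param viewpoint Viewpoint group of the profile; defaults to the single
#'   group present in `reads`. Reads from a different group are an error.
#' @param replicate Optional replicate label stored in the metadata.
#' @return An `interaction_profile` tibble (`frag_id`, `chrom`, `start`,
#'   `end`, `value`) of kind `"raw"`.
#' @export
build_profile <- function(reads, map, viewpoint = NULL, replicate = NA_character_) {
  check_columns(reads, c("read_id", "viewpoint", "reporters"), "reads")
  check_fragment_map(map)
  groups <- unique(reads$viewpoint[!is.na(reads$viewpoint)])
  viewpoint <- viewpoint %||% (if (length(groups) == 1) groups else
    stop_invalid("`viewpoint` must be given when reads span several groups"))
  if (!all(groups %in% viewpoint)) {
    stop_data(sprintf("reads contain viewpoint group(s) other than '%s'", viewpoint))
  }
  reads <- reads[!is.na(reads$viewpoint) & reads$viewpoint %in% viewpoint, ]
  events <- unlist(reads$reporters, use.names = FALSE)
  counts <- tabulate(match(events, map$frag_id), nbins = nrow(map))
  vp_chrom <- NA_character_
  if ("capture_frag" %in% names(reads) && nrow(reads) > 0) {
    vp_chrom <- map$chrom[match(reads$capture_frag[1], map$frag_id)]
  }
  values <- tibble(frag_id = map$frag_id, chrom = map$chrom,
                   start = map$start, end = map$end, value = as.numeric(counts))
  new_interaction_profile(values, map, viewpoint, "raw", total_raw = sum(counts),
                          replicate = replicate, viewpoint_chrom = vp_chrom)
}

#' Pool raw profiles of duplicated-promoter viewpoints
#'
#' Element-wise sum of raw member profiles on the same map (composite profile
#' of a viewpoint group whose members cannot be distinguished, e.g. the
#' duplicated alpha- or beta-globin promoters); totals add.
#'
#' @param ... Raw `interaction_profile`s, or a single list of them.
#' @param viewpoint Label for the pooled profile (default: joined member
#'   labels).
#' @return A raw `interaction_profile`.
#' @export
pool_profiles <- function(..., viewpoint = NULL) {
  profiles <- rlang::list2(...)
  if (length(profiles) == 1 && is.list(profiles[[1]]) &&
      !inherits(profiles[[1]], "interaction_profile")) {
    profiles <- profiles[[1]]
  }
  if (length(profiles) == 0) stop_invalid("nothing to pool")
  purrr::walk(profiles, check_profile, kind = "raw")
  purrr::walk(profiles[-1], check_same_map, b = profiles[[1]])
  value <- Reduce(`+`, purrr::map(profiles, "value"))
  out <- profiles[[1]]
  out$value <- value
  vp <- viewpoint %||% paste(unique(purrr::map_chr(profiles, attr, "viewpoint")),
                             collapse = "+")
  new_interaction_profile(out, NULL, vp, "raw",
                          total_raw = sum(purrr::map_dbl(profiles, attr, "total_raw")),
                          viewpoint_chrom = attr(profiles[[1]], "viewpoint_chrom")) |>
    (\(p) { attr(p, "map_fingerprint") <- attr(profiles[[1]], "map_fingerprint"); p })()
}

#' Normalize a raw profile to a genome-wide total
#'
#' Every value is multiplied by `scale / total`, where the total counts all
#' interactions genome-wide (cis and trans), so the normalized profile sums to
#' `scale` (default 100 000, the conventional genome-wide total for Capture-C
#' tracks). `cis_only = TRUE` instead scales by the cis total alone, for
#' sensitivity analysis.
#'
#' @param profile A raw `interaction_profile`.
#' @param scale Target total (default `1e5`).
#' @param cis_only Use only cis interactions in the denominator.
#' @return An `interaction_profile` of kind `"normalized"`. Normalizing an
#'   already-normalized profile at the same scale is the identity.
#' @export
normalize_profile <- function(profile, scale = 1e5, cis_only = FALSE) {
  check_profile(profile, kind = c("raw", "normalized"))
  check_number(scale, "scale", min = 1e-12)
  check_flag(cis_only, "cis_only")
  total <- if (cis_only) {
    vp_chrom <- attr(profile, "viewpoint_chrom")
    if (is.na(vp_chrom)) stop_invalid("cis_only normalization needs a viewpoint chromosome")
    sum(profile$value[profile$chrom == vp_chrom])
  } else {
    sum(profile$value)
  }
  if (total <= 0) stop_data("cannot normalize a profile with zero total interactions")
  out <- profile
  out$value <- profile$value * scale / total
  new_interaction_profile(out, NULL, attr(profile, "viewpoint"), "normalized",
                          total_raw = attr(profile, "total_raw"),
                          norm_constant = scale,
                          replicate = attr(profile, "replicate"),
                          viewpoint_chrom = attr(profile, "viewpoint_chrom")) |>
    (\(p) { attr(p, "map_fingerprint") <- attr(profile, "map_fingerprint"); p })()
}

# Truncated running mean over a vector (window = 2h+1), via cumulative sums.
running_mean_truncated <- function(x, h) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Window a profile over adjacent restriction fragments
#'
#' Smooths each chromosome with a centred running mean over an odd number of
#' fragments (the routine 4C-style windowed representation). Windows are
#' truncated at chromosome edges (the mean uses the available fragments) and
#' never span chromosomes. The window unit is fragments, not bp, because the
#' restriction fragment is the method's resolution unit.
#'
#' @param profile An `interaction_profile` (any kind except differential).
#' @param window Odd window size in fragments (default 5); 1 is the identity.
#' @return An `interaction_profile` of kind `"windowed"`.
#' @export
window_profile <- function(profile, window = 5) {
  check_profile(profile, kind = c("raw", "normalized", "windowed"))
  window <- check_count(window, "window", min = 1L)
  if (window %% 2L == 0L) stop_invalid("`window` must be odd")
  h <- (window - 1L) %/% 2L
  out <- profile
  for (cm in unique(profile$chrom)) {
    i <- which(profile$chrom == cm)
    out$value[i] <- running_mean_truncated(profile$value[i], h)
  }
  new_interaction_profile(out, NULL, attr(profile, "viewpoint"), "windowed",
                          total_raw = attr(profile, "total_raw"),
                          norm_constant = attr(profile, "norm_constant"),
                          window = window,
                          replicate = attr(profile, "replicate"),
                          viewpoint_chrom = attr(profile, "viewpoint_chrom")) |>
    (\(p) { attr(p, "map_fingerprint") <- attr(profile, "map_fingerprint"); p })()
}

# standard error of the replicate mean; 0 for a single replicate
se_of_mean <- function(mat) {
  k <- ncol(mat)
  if (k == 1) return(rep(0, nrow(mat)))
  apply(mat, 1, sd) / sqrt(k)
}

#' Differential interaction profile between two conditions
#'
#' Per fragment: `mean(A) - mean(B)` over normalized replicate profiles, with
#' standard error `sqrt(SE_A^2 + SE_B^2)` where each SE is the standard error
#' of the replicate mean (0 for a single replicate). Subtracting the inactive
#' condition highlights tissue-specific interactions.
#'
#' @param a,b Lists of normalized `interaction_profile` replicates (a single
#'   profile is accepted).
#' @return An `interaction_profile` of kind `"differential"` with columns
#'   `value` and `se`.
#' @export
differential_profile <- function(a, b) {
  as_list <- function(x) if (inherits(x, "interaction_profile")) list(x) else x
  a <- as_list(a); b <- as_list(b)
  if (length(a) == 0 || length(b) == 0) stop_invalid("each group needs >= 1 replicate")
  purrr::walk(c(a, b), check_profile, kind = "normalized")
  purrr::walk(c(a, b)[-1], check_same_map, b = a[[1]])
  ma <- do.call(cbind, purrr::map(a, "value"))
  mb <- do.call(cbind, purrr::map(b, "value"))
  out <- as_tibble(a[[1]])[c("frag_id", "chrom", "start", "end")]
  out$value <- rowMeans(ma) - rowMeans(mb)
  out$se <- sqrt(se_of_mean(ma)^2 + se_of_mean(mb)^2)
  new_interaction_profile(out, NULL, paste0(attr(a[[1]], "viewpoint"), " (diff)"),
                          "differential", total_raw = NA_real_,
                          viewpoint_chrom = attr(a[[1]], "viewpoint_chrom")) |>
    (\(p) { attr(p, "map_fingerprint") <- attr(a[[1]], "map_fingerprint"); p })()
}

#' Mean of normalized replicate profiles
#'
#' Per-fragment mean and standard error across replicates, computed after
#' per-replicate normalization (as in composite figure tracks).
#'
#' @param profiles List of normalized `interaction_profile`s.
#' @return An `interaction_profile` of kind `"normalized"` with an `se`
#'   column.
#' @export
mean_profile <- function(profiles) {
  if (inherits(profiles, "interaction_profile")) profiles <- list(profiles)
  purrr::walk(profiles, check_profile, kind = "normalized")
  purrr::walk(profiles[-1], check_same_map, b = profiles[[1]])
  m <- do.call(cbind, purrr::map(profiles, "value"))
  out <- as_tibble(profiles[[1]])[c("frag_id", "chrom", "start", "end")]
  out$value <- rowMeans(m)
  out$se <- se_of_mean(m)
  new_interaction_profile(out, NULL, attr(profiles[[1]], "viewpoint"), "normalized",
                          total_raw = mean(purrr::map_dbl(profiles, attr, "total_raw")),
                          norm_constant = attr(profiles[[1]], "norm_constant"),
                          viewpoint_chrom = attr(profiles[[1]], "viewpoint_chrom")) |>
    (\(p) { attr(p, "map_fingerprint") <- attr(profiles[[1]], "map_fingerprint"); p })()
}
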