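# Turn aligned read slices into classified Capture-C interactions: capture
# (viewpoint) slices, reporter slices and excluded (proximity-zone) slices.

#' Resolve target intervals to viewpoint fragment ids
#'
#' @param map A fragment map.
#' @param targets Tibble with columns `chrom`, `start`, `end`, `group`
#'   (e.g. from [read_targets_bed()]), or already-resolved with columns
#'   `group`, `frag_id`.
#' @return Tibble with columns `group`, `frag_id` (one row per member
#'   fragment, deduplicated).
#' @export
resolve_targets <- function(map, targets) {
  check_fragment_map(map)
  if (all(c("group", "frag_id") %in% names(targets))) {
    return(dplyr::distinct(as_tibble(targets)[c("group", "frag_id")]))
  }
  check_columns(targets, c("chrom", "start", "end", "group"), "targets")
  fid <- locate_fragment(map, targets$chrom, targets$start, targets$end)
  if (anyNA(fid)) stop_data("some target intervals cannot be placed on the fragment map")
  dplyr::distinct(tibble(group = targets$group, frag_id = fid))
}

#' Default proximity-exclusion intervals for viewpoint groups
#'
#' The viewpoint fragment(s) extended by `flank` bp on each side. Ligation
#' events in this zone are dominated by uninformative proximity ligation and
#' are not counted as reporters.
#'
#' @param map A fragment map.
#' @param targets Resolved targets (`group`, `frag_id`).
#' @param flank Half-width in bp (default 1000).
#' @return Tibble with columns `group`, `chrom`, `start`, `end`.
#' @export
default_exclusion <- function(map, targets, flank = 1000) {
  targets <- resolve_targets(map, targets)
  rows <- match(targets$frag_id, map$frag_id)
  tibble(group = targets$group,
         chrom = map$chrom[rows],
         start = pmax(map$start[rows] - flank, 0),
         end = map$end[rows] + flank)
}

#' Classify read slices into capture, reporter and excluded roles
#'
#' Each slice is placed on the fragment map by its midpoint. Slices on a
#' viewpoint group's target fragments are capture slices; for a read captured
#' by exactly one group, slices overlapping that group's exclusion intervals
#' are excluded, and the remaining slices are reporters (unique fragment ids,
#' one interaction per fragment per read). Reads hitting targets of two or
#' more distinct groups are `double-capture`; reads without a capture slice
#' are `no-capture`; captured reads without a reporter are `no-reporter`;
#' the rest are `informative`. Reads containing a slice that cannot be placed
#' on the map are dropped and recorded in the `dropped` attribute.
#'
#' @param slices Tibble of aligned slices: `read_id`, `slice_index`, `chrom`,
#'   `start`, `end` (0-based half-open), optional `strand`.
#' @param map A fragment map.
#' @param targets Viewpoint targets (see [resolve_targets()]).
#' @param exclusion Optional exclusion intervals (`group`, `chrom`, `start`,
#'   `end`); defaults to [default_exclusion()] with `exclusion_bp`.
#' @param exclusion_bp Flank for the default exclusion zone (default 1000 bp).
#' @return Tibble of class `classified_reads`, one row per read: `read_id`,
#'   `viewpoint`, `status`, `n_slices`, `n_capture`, `n_excluded`,
#'   `capture_frag` (first capture fragment), `reporters` (list column of
#'   fragment ids) and the coordinate-UMI pair (`umi_lchrom`, `umi_left`,
#'   `umi_rchrom`, `umi_right`). Attribute `dropped` lists dropped reads.
#' @export
classify_reads <- function(slices, map, targets, exclusion = NULL, exclusion_bp = 1000) {
  check_columns(slices, c("read_id", "slice_index", "chrom", "start", "end"), "slices")
  check_fragment_map(map)
  targets <- resolve_targets(map, targets)
  if (is.null(exclusion)) exclusion <- default_exclusion(map, targets, exclusion_bp)
  check_columns(exclusion, c("group", "chrom", "start", "end"), "exclusion")

  slices <- dplyr::arrange(as_tibble(slices), .data$read_id, .data$slice_index)
  frag <- locate_fragment(map, slices$chrom, slices$start, slices$end)

  bad <- unique(slices$read_id[is.na(frag)])
  dropped <- tibble(read_id = bad, reason = "slice not locatable on fragment map")
  if (length(bad) > 0) {
    keep <- !(slices$read_id %in% bad)
    slices <- slices[keep, ]
    frag <- frag[keep]
  }
  if (nrow(slices) == 0) {
    out <- tibble(read_id = character(), viewpoint = character(), status = character(),
                  n_slices = integer(), n_capture = integer(), n_excluded = integer(),
                  capture_frag = integer(), reporters = list(),
                  umi_lchrom = character(), umi_left = numeric(),
                  umi_rchrom = character(), umi_right = numeric())
    return(structure(out, dropped = dropped, class = c("classified_reads", class(tibble()))))
  }

  # group membership lookup by fragment id (a fragment belongs to <= 1 group)
  group_of <- rep(NA_character_, max(map$frag_id))
  group_of[targets$frag_id] <- targets$group
  slice_grp <- group_of[frag]
  is_capture <- !is.na(slice_grp)

  rid <- factor(slices$read_id, levels = unique(slices$read_id))
  nread <- nlevels(rid)
  iread <- as.integer(rid)

  # distinct captured groups per read
  cap_pairs <- unique(data.frame(i = iread[is_capture], g = slice_grp[is_capture]))
  ngroups <- tabulate(cap_pairs$i, nbins = nread)
  viewpoint <- rep(NA_character_, nread)
  one <- ngroups[cap_pairs$i] == 1L
  viewpoint[cap_pairs$i[one]] <- cap_pairs$g[one]

  # exclusion: only meaningful for reads with a single viewpoint group
  read_vp_of_slice <- viewpoint[iread]
  is_excluded <- rep(FALSE, nrow(slices))
  for (k in seq_len(nrow(exclusion))) {
    hit <- !is_capture &
      !is.na(read_vp_of_slice) & read_vp_of_slice == exclusion$group[k] &
      slices$chrom == exclusion$chrom[k] &
      slices$start < exclusion$end[k] & slices$end > exclusion$start[k]
    is_excluded <- is_excluded | hit
  }

  is_reporter <- !is_capture & !is_excluded & !is.na(read_vp_of_slice)
  rep_pairs <- unique(data.frame(i = iread[is_reporter], f = frag[is_reporter]))
  reporters <- rep(list(integer(0)), nread)
  if (nrow(rep_pairs) > 0) {
    split_rep <- split(rep_pairs$f, rep_pairs$i)
    reporters[as.integer(names(split_rep))] <- split_rep
  }

  n_slices_all <- tabulate(iread, nbins = nread)
  first_idx <- cumsum(n_slices_all) - n_slices_all + 1L
  last_idx <- cumsum(n_slices_all)
  cap_first <- rep(NA_integer_, nread)
  capi <- which(is_capture & !is.na(read_vp_of_slice))
  if (length(capi) > 0) {
    firsts <- capi[!duplicated(iread[capi])]
    cap_first[iread[firsts]] <- frag[firsts]
  }

  n_slices <- n_slices_all
  n_capture <- tabulate(iread[is_capture], nbins = nread)
  n_excluded <- tabulate(iread[is_excluded], nbins = nread)
  n_reporters <- lengths(reporters)

  status <- dplyr::case_when(
    ngroups >= 2L ~ "double-capture",
    ngroups == 0L ~ "no-capture",
    n_reporters == 0L ~ "no-reporter",
    TRUE ~ "informative"
  )

  out <- tibble(
    read_id = levels(rid),
    viewpoint = viewpoint,
    status = status,
    n_slices = n_slices,
    n_capture = n_capture,
    n_excluded = n_excluded,
    capture_frag = cap_first,
    reporters = reporters,
    umi_lchrom = slices$chrom[first_idx],
    umi_left = slices$start[first_idx],
    umi_rchrom = slices$chrom[last_idx],
    umi_right = slices$end[last_idx]
  )
  structure(out, dropped = dropped, class = c("classified_reads", class(tibble())))
}
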