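# Stringent coordinate-UMI duplicate filtering. The two sheared-molecule end
# coordinates of a read act as two independent UMIs; reads whose UMI pairs are
# identical, or differ by one or two base shifts ("wobble" from sequencing or
# mapping error), are treated as PCR duplicates of one molecule.

#' Extract coordinate-UMI keys from read slices
#'
#' The left UMI is the 5'-most mapped coordinate of the first slice, the right
#' UMI the 3'-most coordinate of the last slice (half-open end), in read order
#' rather than genomic order. Single-slice reads use that slice's two ends.
#'
#' @param slices Slice tibble (`read_id`, `slice_index`, `chrom`, `start`,
#'   `end`).
#' @return Tibble with one row per read: `read_id`, `umi_lchrom`, `umi_left`,
#'   `umi_rchrom`, `umi_right`.
#' @export
extract_umi <- function(slices) {
  check_columns(slices, c("read_id", "slice_index", "chrom", "start", "end"), "slices")
  slices <- dplyr::arrange(as_tibble(slices), .data$read_id, .data$slice_index)
  rid <- factor(slices$read_id, levels = unique(slices$read_id))
  n <- tabulate(as.integer(rid), nbins = nlevels(rid))
  first <- cumsum(n) - n + 1L
  last <- cumsum(n)
  tibble(read_id = levels(rid),
         umi_lchrom = slices$chrom[first], umi_left = slices$start[first],
         umi_rchrom = slices$chrom[last], umi_right = slices$end[last])
}

#' L1 distance between two coordinate-UMI keys
#'
#' Infinite when either end's chromosome differs; otherwise
#' `|delta left| + |delta right|`. Vectorized (recycled) over rows.
#'
#' @param a,b Tibbles/lists with fields `umi_lchrom`, `umi_left`,
#'   `umi_rchrom`, `umi_right`.
#' @return Numeric vector of distances (may contain `Inf`).
#' @export
umi_distance <- function(a, b) {
  same <- a$umi_lchrom == b$umi_lchrom & a$umi_rchrom == b$umi_rchrom
  d <- abs(a$umi_left - b$umi_left) + abs(a$umi_right - b$umi_right)
  ifelse(same, d, Inf)
}

# Single-linkage clustering of UMI keys: two keys link iff their L1 distance
# is <= max_wobble (chromosome pairs must match). Near-linear, not all-pairs:
# exact keys are collapsed first, then for every coordinate offset (dl, dr)
# with 0 < |dl| + |dr| <= max_wobble the shifted key is looked up in a hash,
# which enumerates exactly the neighbour edges; union-find merges them. The
# all-pairs comparison exists only in the test oracle.
umi_cluster <- function(lchrom, left, rchrom, right, max_wobble) {
  n <- length(left)
  if (n == 0) return(integer(0))
  exact_key <- paste(lchrom, left, rchrom, right, sep = "\r")
  uidx <- which(!duplicated(exact_key))
  keystr <- exact_key[uidx]
  key_of <- match(exact_key, keystr)
  m <- length(uidx)
  if (max_wobble == 0 || m == 1) return(key_of)

  ul <- left[uidx]; ur <- right[uidx]
  ulc <- lchrom[uidx]; urc <- rchrom[uidx]

  # half of the L1 ball (lexicographically positive offsets): each neighbour
  # pair is found exactly once
  offs <- list()
  for (dl in 0:max_wobble) {
    drs <- if (dl == 0) seq_len(max_wobble) else -(max_wobble - dl):(max_wobble - dl)
    for (dr in drs) offs[[length(offs) + 1L]] <- c(dl, dr)
  }

  ei <- integer(0); ej <- integer(0)
  for (off in offs) {
    cand <- match(paste(ulc, ul + off[1], urc, ur + off[2], sep = "\r"), keystr)
    hit <- which(!is.na(cand))
    ei <- c(ei, hit)
    ej <- c(ej, cand[hit])
  }

  parent <- seq_len(m)
  find <- function(i) { # path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(ei)) {
    ri <- find(ei[k]); rj <- find(ej[k])
    if (ri != rj) {
      r <- min(ri, rj)
      parent[ri] <- r
      parent[rj] <- r
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  cluster_of_key <- match(roots, unique(roots))
  cluster_of_key[key_of]
}

#' Stringent wobble-tolerant duplicate filter
#'
#' Reads are grouped per viewpoint group (cis and trans together) into
#' single-linkage clusters: two reads link when their coordinate-UMI pairs are
#' at L1 distance `<= max_wobble` with matching chromosomes ("one or two
#' differences in the UMIs" for the default `max_wobble = 2`;
#' `max_wobble = 0` is the plain exact-coordinate filter). One representative
#' is retained per cluster: the read with the most exact-key copies, ties
#' broken by smallest (chromosome, left, right, read id). Setting
#' `drop_wobble_clusters = TRUE` instead removes every cluster that spans more
#' than one exact key (the stricter reading in which wobble matches are
#' excluded outright; pure exact-duplicate clusters still keep one
#' representative).
#'
#' @param reads A [classify_reads()] tibble (or any tibble with `read_id`,
#'   the four UMI columns, and optionally `viewpoint`).
#' @param max_wobble Maximum summed coordinate shift treated as a duplicate
#'   (default 2).
#' @param drop_wobble_clusters Drop wobble-linked clusters entirely instead of
#'   keeping a representative (default `FALSE`).
#' @return An object of class `dedup_result`: list with `retained` (the
#'   retained rows of `reads`), `clusters` (per read: cluster id, exact-copy
#'   count, retained flag) and `report` (counts, cluster-size histogram,
#'   per-viewpoint summary). Supports [tidy()], [glance()] and [autoplot()].
#' @export
filter_duplicates <- function(reads, max_wobble = 2, drop_wobble_clusters = FALSE) {
  check_columns(reads, c("read_id", "umi_lchrom", "umi_left", "umi_rchrom", "umi_right"),
                "reads")
  max_wobble <- check_count(max_wobble, "max_wobble", min = 0L)
  check_flag(drop_wobble_clusters, "drop_wobble_clusters")
  reads <- as_tibble(reads)
  vp <- if ("viewpoint" %in% names(reads)) reads$viewpoint else rep("all", nrow(reads))
  vp[is.na(vp)] <- "<none>"

  cluster <- integer(nrow(reads))
  offset <- 0L
  for (g in unique(vp)) {
    idx <- which(vp == g)
    cl <- umi_cluster(reads$umi_lchrom[idx], reads$umi_left[idx],
                      reads$umi_rchrom[idx], reads$umi_right[idx], max_wobble)
    cluster[idx] <- cl + offset
    offset <- offset + max(cl, 0L)
  }

  exact_key <- paste(vp, reads$umi_lchrom, reads$umi_left,
                     reads$umi_rchrom, reads$umi_right, sep = "\r")
  copies <- as.integer(table(exact_key)[exact_key])

  ord <- order(cluster, -copies, reads$umi_lchrom, reads$umi_left,
               reads$umi_right, reads$read_id)
  rep_idx <- ord[!duplicated(cluster[ord])]
  retained_flag <- logical(nrow(reads))
  retained_flag[rep_idx] <- TRUE
  if (drop_wobble_clusters) {
    nkey <- tapply(exact_key, cluster, function(k) length(unique(k)))
    wobbly <- as.integer(names(nkey)[nkey > 1])
    retained_flag[cluster %in% wobbly] <- FALSE
  }

  clusters <- tibble(read_id = reads$read_id, viewpoint = vp,
                     cluster = cluster, n_exact_copies = copies,
                     retained = retained_flag)
  sizes <- table(table(cluster))
  report <- list(
    n_reads = nrow(reads),
    n_retained = sum(retained_flag),
    n_clusters = length(unique(cluster)),
    max_wobble = max_wobble,
    drop_wobble_clusters = drop_wobble_clusters,
    cluster_sizes = tibble(size = as.integer(names(sizes)),
                           n_clusters = as.integer(sizes)),
    by_viewpoint = clusters |>
      dplyr::group_by(viewpoint = .data$viewpoint) |>
      dplyr::summarise(n_reads = dplyr::n(), n_retained = sum(.data$retained),
                       .groups = "drop"),
    truth = NULL # filled by dedup_truth_summary() on simulated input
  )
  structure(list(retained = reads[retained_flag, ], clusters = clusters,
                 report = report), class = "dedup_result")
}

#' Compare a dedup result against simulation truth
#'
#' @param result A [filter_duplicates()] result.
#' @param truth Truth table of the [simulate_library()] run the reads came
#'   from (possibly subset to the classified reads).
#' @return One-row tibble: unique molecules, distinct true UMI keys, retained
#'   reads, molecules lost to exact UMI collisions, and the retained/true
#'   ratio (the filter's conservatism: <= 1 when wobble merges genuine
#'   molecules).
#' @export
dedup_truth_summary <- function(result, truth) {
  stopifnot(inherits(result, "dedup_result"))
  truth <- truth[truth$read_id %in% result$clusters$read_id, ]
  mols <- dplyr::distinct(truth, .data$molecule_id, .keep_all = TRUE)
  key <- paste(mols$group, mols$umi_lchrom, mols$umi_left_true,
               mols$umi_rchrom, mols$umi_right_true)
  n_true <- nrow(mols)
  n_keys <- length(unique(key))
  tibble(n_true_molecules = n_true,
         n_distinct_true_umis = n_keys,
         n_retained = result$report$n_retained,
         n_lost_to_collisions = n_true - n_keys,
         retained_over_true = result$report$n_retained / n_true)
}

#' @export
tidy.dedup_result <- function(x, ...) x$clusters

#' @export
glance.dedup_result <- function(x, ...) {
  tibble(n_reads = x$report$n_reads, n_retained = x$report$n_retained,
         n_clusters = x$report$n_clusters, max_wobble = x$report$max_wobble,
         drop_wobble_clusters = x$report$drop_wobble_clusters)
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf("<dedup_result> %d reads -> %d retained (%d clusters, max_wobble = %d)\n",
              x$report$n_reads, x$report$n_retained, x$report$n_clusters,
              x$report$max_wobble))
  invisible(x)
}
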