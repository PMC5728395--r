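# In-silico restriction digestion: the fragment map is the coordinate system
# shared by every downstream profile.

# Canonicalize a genome to a named uppercase character vector.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet") || inherits(genome, "XStringSet")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome) || length(genome) == 0) {
    stop_invalid("`genome` must be a non-empty named character vector or DNAStringSet")
  }
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    stop_invalid("every chromosome in `genome` must be named")
  }
  if (anyDuplicated(names(genome))) stop_invalid("chromosome names must be unique")
  toupper(genome)
}

check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0) {
    stop_invalid("`motif` must be a single non-empty DNA string")
  }
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop_invalid("`motif` may only contain A, C, G, T")
  motif
}

# 0-based start positions of every (possibly overlapping) motif occurrence.
# fixed = TRUE so that N in the subject never matches the motif.
motif_starts <- function(sequence, motif) {
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence), fixed = TRUE)
  Biostrings::start(m) - 1L
}

#' Digest a reference genome into restriction fragments
#'
#' Scans each chromosome for the enzyme recognition motif (case-insensitively;
#' `N` bases in the genome never match) and cuts immediately before each
#' occurrence, so every internal fragment carries the motif at its 5' end.
#' Fragments tile each chromosome exactly in 0-based half-open coordinates.
#' A motif occurrence at position 0 produces no leading empty fragment, and a
#' chromosome without any occurrence yields a single whole-chromosome fragment.
#'
#' @param genome Named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`). Alphabet `A/C/G/T/N`, any case.
#' @param motif Recognition sequence, default `"GATC"` (DpnII).
#' @return A tibble of class `fragment_map` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `frag_id` (genome-wide, stable for a given
#'   genome + motif) and `frag_index` (ordinal within the chromosome).
#'   Chromosome lengths and the motif are kept in attributes
#'   `chrom_lengths` and `motif`.
#' @examples
#' digest_reference(c(chr1 = "AAGATCAAGATCAA"))
#' @export
digest_reference <- function(genome, motif = "GATC") {
  genome <- as_genome(genome)
  motif <- check_motif(motif)
  lens <- nchar(genome)
  if (all(lens == 0)) stop_invalid("`genome` contains only empty sequences")
  if (any(lens == 0)) {
    warn("dropping zero-length chromosome(s)")
    genome <- genome[lens > 0]
    lens <- lens[lens > 0]
  }
  per_chrom <- purrr::imap(genome, function(seq, chrom) {
    len <- nchar(seq)
    cuts <- if (nchar(motif) > len) integer(0) else motif_starts(seq, motif)
    starts <- sort(unique(c(0L, cuts)))
    ends <- c(starts[-1], len)
    keep <- ends > starts # suppress the empty fragment from a cut at 0
    tibble(chrom = chrom, start = starts[keep], end = ends[keep])
  })
  map <- dplyr::bind_rows(per_chrom)
  map$frag_id <- seq_len(nrow(map))
  map <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(frag_index = dplyr::row_number()) |>
    dplyr::ungroup()
  new_fragment_map(map, chrom_lengths = setNames(lens, names(genome)), motif = motif)
}

new_fragment_map <- function(map, chrom_lengths, motif = NA_character_) {
  map <- as_tibble(map)[c("chrom", "start", "end", "frag_id", "frag_index")]
  structure(map,
    chrom_lengths = chrom_lengths,
    motif = motif,
    class = c("fragment_map", class(tibble())))
}

check_fragment_map <- function(map, name = "map") {
  check_columns(map, c("chrom", "start", "end", "frag_id"), name)
  invisible(map)
}

# TRUE when two maps describe the same fragment partition.
same_map <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(a$chrom, b$chrom) &&
    identical(as.integer(a$start), as.integer(b$start)) &&
    identical(as.integer(a$end), as.integer(b$end)) &&
    identical(as.integer(a$frag_id), as.integer(b$frag_id))
}

#' Locate the fragment containing an interval's midpoint
#'
#' Assigns each query interval to the fragment containing its midpoint,
#' `floor((start + end) / 2)`. Vectorized over queries.
#'
#' @param map A [digest_reference()] fragment map.
#' @param chrom,start,end Query interval(s), 0-based half-open.
#' @return Integer vector of fragment ids; `NA` where the chromosome is absent
#'   from the map or the midpoint lies beyond the chromosome end.
#' @export
locate_fragment <- function(map, chrom, start, end) {
  check_fragment_map(map)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  if (length(start) != length(end) || length(chrom) != length(start)) {
    stop_invalid("`chrom`, `start` and `end` must have equal length")
  }
  if (any(start >= end)) stop_data("interval start must be < end")
  mid <- (as.numeric(start) + as.numeric(end)) %/% 2
  out <- rep(NA_integer_, length(mid))
  for (cm in unique(chrom)) {
    sel <- which(chrom == cm)
    rows <- which(map$chrom == cm)
    if (length(rows) == 0) next
    idx <- findInterval(mid[sel], map$start[rows])
    chrom_end <- map$end[rows[length(rows)]]
    ok <- idx >= 1 & mid[sel] < chrom_end
    out[sel[ok]] <- map$frag_id[rows[idx[ok]]]
  }
  out
}

#' Digest a read sequence in silico
#'
#' Splits a sequence at the same cut convention as [digest_reference()]: a cut
#' before each motif occurrence, no empty slices. The concatenation of the
#' returned slices always reproduces the input.
#'
#' @param sequence A single DNA string.
#' @param motif Recognition sequence, default `"GATC"`.
#' @return Character vector of slices, in read order.
#' @examples
#' digest_read("AATTGATCGG") # "AATT", "GATCGG"
#' @export
digest_read <- function(sequence, motif = "GATC") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0) {
    stop_invalid("`sequence` must be a single non-empty string")
  }
  motif <- check_motif(motif)
  seq <- toupper(sequence)
  cuts <- if (nchar(motif) > nchar(seq)) integer(0) else motif_starts(seq, motif)
  starts <- sort(unique(c(0L, cuts)))
  ends <- c(starts[-1], nchar(seq))
  keep <- ends > starts
  substring(seq, starts[keep] + 1L, ends[keep])
}

#' Extract the genomic sequence of each fragment
#'
#' @param map A fragment map.
#' @param genome The genome the map was digested from.
#' @return Character vector of fragment sequences, in `frag_id` order.
#' @export
fragment_sequences <- function(map, genome) {
  check_fragment_map(map)
  genome <- as_genome(genome)
  missing <- setdiff(unique(map$chrom), names(genome))
  if (length(missing) > 0) {
    stop_data(paste("genome lacks chromosome(s):", paste(missing, collapse = ", ")))
  }
  substring(genome[map$chrom], map$start + 1L, map$end)
}
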