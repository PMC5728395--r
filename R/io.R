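# Readers and writers for the formats the toolkit exchanges. Internal
# coordinates are 0-based half-open everywhere; BED and bedGraph share that
# convention, SAM is 1-based and converted on ingest. Writers produce
# canonical files that round-trip byte-identically through their readers.

read_tsv_strict <- function(path, col_names, col_types) {
  out <- tryCatch(
    readr::read_tsv(path, col_names = col_names, col_types = col_types,
                    progress = FALSE),
    error = function(e) stop_data(sprintf("%s: %s", path, conditionMessage(e)))
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop_data(sprintf("%s: malformed line %d (%s)", path, probs$row[1] +
                        (if (isTRUE(col_names)) 1L else 0L), probs$expected[1]))
  }
  out
}

#' Read / write genome FASTA
#'
#' @param path File path.
#' @param genome Named character vector of sequences.
#' @return `read_genome_fasta()`: named uppercase character vector.
#' @export
read_genome_fasta <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_genome(genome)), path)
  invisible(path)
}

#' Read / write a fragment map as BED4
#'
#' Columns: chrom, start, end, fragment id; sorted as produced by
#' [digest_reference()]. Chromosome lengths are recovered from the last
#' fragment of each chromosome.
#'
#' @param map A fragment map.
#' @param path File path.
#' @param motif Motif to record on the restored map (optional).
#' @export
write_fragment_map <- function(map, path) {
  check_fragment_map(map)
  readr::write_tsv(as_tibble(map)[c("chrom", "start", "end", "frag_id")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path, motif = NA_character_) {
  bed <- read_tsv_strict(path, col_names = c("chrom", "start", "end", "frag_id"),
                         col_types = "ciii")
  map <- bed |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(frag_index = dplyr::row_number()) |>
    dplyr::ungroup()
  lens <- tapply(map$end, map$chrom, max)
  new_fragment_map(map, chrom_lengths = lens[unique(map$chrom)], motif = motif)
}

#' Read a BED file of viewpoint targets
#'
#' BED4 whose name column is `group` or `group:member`; the group collects
#' duplicated-gene viewpoints that cannot be distinguished bioinformatically.
#'
#' @param path File path.
#' @return Tibble: `chrom`, `start`, `end`, `group`, `member`.
#' @export
read_targets_bed <- function(path) {
  bed <- read_tsv_strict(path, col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic")
  parts <- strsplit(bed$name, ":", fixed = TRUE)
  tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
         group = purrr::map_chr(parts, 1),
         member = purrr::map_chr(parts, \(p) p[length(p)]))
}

#' Read a BED file of exclusion intervals
#'
#' BED4 with the viewpoint group in the name column.
#'
#' @param path File path.
#' @return Tibble: `group`, `chrom`, `start`, `end`.
#' @export
read_exclusion_bed <- function(path) {
  bed <- read_tsv_strict(path, col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic")
  tibble(group = bed$name, chrom = bed$chrom, start = bed$start, end = bed$end)
}

#' Read / write aligned read slices (TSV dialect)
#'
#' Columns `read_id`, `slice_index`, `chrom`, `start`, `end`, `strand`;
#' 0-based half-open; slices of one read are grouped and ordered by
#' `slice_index`.
#'
#' @param slices Slice tibble.
#' @param path File path.
#' @export
write_slices <- function(slices, path) {
  check_columns(slices, c("read_id", "slice_index", "chrom", "start", "end", "strand"),
                "slices")
  readr::write_tsv(as_tibble(slices)[c("read_id", "slice_index", "chrom",
                                       "start", "end", "strand")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_slices
#' @export
read_slices <- function(path) {
  read_tsv_strict(path, col_names = TRUE,
                  col_types = readr::cols(read_id = "c", slice_index = "i",
                                          chrom = "c", start = "i", end = "i",
                                          strand = "c"))
}

#' Read aligned slices from a SAM file
#'
#' Each alignment record is one slice; records are grouped by query name and
#' ordered as they appear. SAM's 1-based positions are converted to the
#' internal 0-based half-open convention.
#'
#' @param path SAM file path (with header).
#' @param min_mapq Drop records below this mapping quality (default 0).
#' @return Slice tibble as from [read_slices()].
#' @export
read_slices_sam <- function(path, min_mapq = 0) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "mapq")))
  meta <- S4Vectors::mcols(ga)
  keep <- is.na(meta$mapq) | meta$mapq >= min_mapq
  ga <- ga[keep]
  qname <- S4Vectors::mcols(ga)$qname
  idx <- stats::ave(seq_along(qname), qname, FUN = seq_along)
  out <- tibble(read_id = qname, slice_index = as.integer(idx),
                chrom = as.character(GenomeInfoDb::seqnames(ga)),
                start = BiocGenerics::start(ga) - 1L,
                end = BiocGenerics::end(ga),
                strand = as.character(BiocGenerics::strand(ga)))
  dplyr::arrange(out, .data$read_id, .data$slice_index)
}

#' Write / read an interaction profile as bedGraph
#'
#' One track per profile; values formatted with at most six significant
#' digits. The track line records the viewpoint group and profile kind.
#'
#' @param profile An `interaction_profile`.
#' @param path File path.
#' @param name Track name (default `"<viewpoint> (<kind>)"`).
#' @export
write_bedgraph <- function(profile, path, name = NULL) {
  check_profile(profile)
  name <- name %||% sprintf("%s (%s)", attr(profile, "viewpoint"), attr(profile, "kind"))
  lines <- c(sprintf("track type=bedGraph name=\"%s\"", name),
             sprintf("%s\t%d\t%d\t%s", profile$chrom, as.integer(profile$start),
                     as.integer(profile$end),
                     formatC(profile$value, format = "g", digits = 6)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  is_track <- grepl("^(track|#)", lines)
  body <- lines[!is_track & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4)
  if (length(bad) > 0) {
    stop_data(sprintf("%s: malformed bedGraph line %d", path,
                      which(!is_track & nzchar(lines))[bad[1]]))
  }
  m <- do.call(rbind, fields)
  value <- suppressWarnings(as.numeric(m[, 4]))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(value) || anyNA(start) || anyNA(end)) {
    bad <- which(is.na(value) | is.na(start) | is.na(end))[1]
    stop_data(sprintf("%s: malformed bedGraph line %d", path,
                      which(!is_track & nzchar(lines))[bad]))
  }
  tibble(chrom = m[, 1], start = start, end = end, value = value)
}

#' Write / read a profile as tidy TSV
#'
#' Columns `frag_id`, `chrom`, `start`, `end`, `value` and, for differential
#' profiles, `se`.
#'
#' @param profile An `interaction_profile`.
#' @param path File path.
#' @export
write_profile_tsv <- function(profile, path) {
  check_profile(profile)
  readr::write_tsv(as_tibble(profile), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  read_tsv_strict(path, col_names = TRUE, col_types = readr::cols())
}

#' Read a qPCR table
#'
#' TSV with columns `sample`, `assay`, `template`, `ct` and optionally
#' `mass_ng`.
#'
#' @param path File path.
#' @export
read_qpcr <- function(path) {
  out <- read_tsv_strict(path, col_names = TRUE, col_types = readr::cols())
  check_columns(out, c("sample", "assay", "template", "ct"), "qPCR table")
  out
}

#' Read a probe count table with its sample sheet
#'
#' The count TSV is wide (`frag_id` plus one column per sample); the sample
#' sheet TSV has columns `sample`, `tissue`, `input_mass`, `replicate`.
#'
#' @param counts_path,samples_path File paths.
#' @return List with `counts` (long tibble `frag_id`, `sample`, `count`) and
#'   `samples` (metadata tibble).
#' @export
read_count_table <- function(counts_path, samples_path) {
  wide <- read_tsv_strict(counts_path, col_names = TRUE, col_types = readr::cols())
  check_columns(wide, "frag_id", "count table")
  counts <- tidyr::pivot_longer(wide, -"frag_id", names_to = "sample",
                                values_to = "count")
  samples <- read_tsv_strict(samples_path, col_names = TRUE, col_types = readr::cols())
  check_columns(samples, c("sample", "tissue", "input_mass"), "sample sheet")
  missing <- setdiff(unique(counts$sample), samples$sample)
  if (length(missing) > 0) {
    stop_data(paste("samples absent from sample sheet:", paste(missing, collapse = ", ")))
  }
  list(counts = counts, samples = samples)
}

#' Export simulated reads as FASTQ
#'
#' Reconstructs each read's sequence by concatenating its slice sequences
#' from the genome (interoperability export; the analysis itself consumes
#' aligned slices).
#'
#' @param slices Slice tibble.
#' @param genome Genome sequences.
#' @param path Output FASTQ path.
#' @export
write_reads_fastq <- function(slices, genome, path) {
  check_columns(slices, c("read_id", "slice_index", "chrom", "start", "end"), "slices")
  genome <- as_genome(genome)
  slices <- dplyr::arrange(as_tibble(slices), .data$read_id, .data$slice_index)
  piece <- substring(genome[slices$chrom], slices$start + 1L, slices$end)
  seqs <- tapply(piece, slices$read_id, paste0, collapse = "")
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}
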