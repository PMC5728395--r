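# Shared input checks and small helpers. Errors raised here are classed so the
# CLI can map validation problems to exit code 2 and data problems to 3.

stop_invalid <- function(msg) abort(msg, class = "threecap_invalid")
stop_data <- function(msg) abort(msg, class = "threecap_data")

check_flag <- function(x, name) {
  if (!rlang::is_bool(x)) stop_invalid(sprintf("`%s` must be TRUE or FALSE", name))
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_invalid(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) stop_invalid(sprintf("`%s` must be a whole number", name))
  invisible(as.integer(x))
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) stop_invalid(sprintf("`%s` must be a data frame", name))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_invalid(sprintf("`%s` is missing column(s): %s", name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Reverse complement of plain character DNA (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast random DNA string; bases drawn independently with the given GC content.
random_dna <- function(n, gc = 0.42) {
  codes <- utf8ToInt("ACGT")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(sample(codes, n, replace = TRUE, prob = p))
}
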