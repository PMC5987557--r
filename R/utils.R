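# internal helpers

# open a connection that transparently handles gzip by extension
open_input <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read file: ", path), class = "twindmr_io_error")
  }
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

open_output <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

# strip or add the "chr" prefix so that two inputs agree
normalize_chrom_names <- function(x) sub("^chr", "", x)

# a 0-based half-open interval tibble -> GRanges (1-based closed)
as_granges0 <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

is_count_string <- function(x) grepl("^[0-9]+$", x)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
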