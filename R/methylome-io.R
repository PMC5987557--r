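#' Construct a methylome tibble
#'
#' A methylome is a per-cytosine table of bisulfite read counts for one
#' sample. Coordinates are 0-based half-open throughout the package: each
#' cytosine occupies `[start, start + 1)`. On-disk cytosine reports use
#' 1-based positions and are converted on read/write.
#'
#' @param sites A data frame with columns `chrom` (character), `start`
#'   (0-based integer), `strand` (`"+"`/`"-"`), `context` (`"CG"`, `"CHG"`,
#'   `"CHH"`), `meth` and `unmeth` (non-negative integer read counts). An
#'   optional `tri` column carries the trinucleotide.
#' @param sample_id Label stored as the `sample_id` attribute.
#'
#' @return A tibble sorted by `(chrom, start, strand)` with class
#'   `twindmr_methylome`, carrying a `sample_id` attribute. Duplicate
#'   `(chrom, start, strand)` rows are an error.
#' @export
methylome <- function(sites, sample_id = "sample") {
  required <- c("chrom", "start", "strand", "context", "meth", "unmeth")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    abort(paste0("methylome is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(sites)
  if (!"tri" %in% names(out)) out$tri <- NA_character_
  out <- out[required_methylome_cols()]
  if (any(out$meth < 0 | out$unmeth < 0)) {
    abort("read counts must be non-negative")
  }
  if (any(out$start < 0)) abort("positions must be >= 0 (0-based)")
  if (!all(out$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  ord <- order(out$chrom, out$start, out$strand)
  if (is.unsorted(ord, strictly = FALSE) && !identical(ord, seq_len(nrow(out)))) {
    out <- out[ord, ]
  }
  key <- paste(out$chrom, out$start, out$strand)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate cytosine site: ", dup), class = "twindmr_dup_site")
  }
  attr(out, "sample_id") <- sample_id
  class(out) <- c("twindmr_methylome", class(out))
  out
}

required_methylome_cols <- function() {
  c("chrom", "start", "strand", "context", "meth", "unmeth", "tri")
}

#' @export
print.twindmr_methylome <- function(x, ...) {
  cat(sprintf("# methylome '%s': %d cytosines on %d chromosome(s)\n",
              attr(x, "sample_id") %||% "?", nrow(x),
              length(unique(x$chrom))))
  NextMethod()
}

#' Parse lines of a bismark-style cytosine report
#'
#' The cytosine (CX) report is a 7-column TSV: chromosome, 1-based position,
#' strand, methylated read count, unmethylated read count, context
#' (CG/CHG/CHH), trinucleotide.
#'
#' @param lines Character vector of report lines.
#' @param line_offset Added to indices in error messages (for chunked reads).
#' @return A tibble with one row per line and 0-based `start` coordinates.
#' @export
parse_cytosine_report <- function(lines, line_offset = 0L) {
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad)) {
    abort(sprintf("line %d: expected >= 6 tab-separated fields, got %d",
                  bad[1] + line_offset, nf[bad[1]]),
          class = "twindmr_parse_error")
  }
  m <- vapply(fields, function(f) f[1:6], character(6))
  pos_chr <- m[2, ]
  meth_chr <- m[4, ]
  unmeth_chr <- m[5, ]
  bad <- which(!(is_count_string(pos_chr) & is_count_string(meth_chr) &
                   is_count_string(unmeth_chr)))
  if (length(bad)) {
    abort(sprintf("line %d: position and counts must be non-negative integers: '%s'",
                  bad[1] + line_offset, lines[bad[1]]),
          class = "twindmr_parse_error")
  }
  pos <- as.integer(pos_chr)
  if (any(pos < 1L)) {
    bad <- which(pos < 1L)[1]
    abort(sprintf("line %d: position must be >= 1", bad + line_offset),
          class = "twindmr_parse_error")
  }
  tri <- vapply(fields, function(f) if (length(f) >= 7L) f[7] else NA_character_,
                character(1))
  tibble(
    chrom = m[1, ],
    start = pos - 1L,          # to 0-based
    strand = m[3, ],
    context = m[6, ],
    meth = as.integer(meth_chr),
    unmeth = as.integer(unmeth_chr),
    tri = tri
  )
}

#' Read a cytosine report into a methylome
#'
#' @param path Path to a (optionally gzipped) cytosine report TSV.
#' @param context_filter Contexts to keep (default `"CG"`); `NULL` keeps all.
#' @param min_depth Minimum read depth (`meth + unmeth`) to keep a site.
#' @param sample_id Sample label; defaults to the file name.
#' @param collapse_strands If `TRUE`, counts of minus-strand CG sites are
#'   added onto the plus-strand position of the symmetric CpG pair
#'   (position - 1). Default keeps each strand as its own site, which is what
#'   the report encodes.
#' @param normalize_chrom If `TRUE`, strip a leading `"chr"` from chromosome
#'   names.
#' @return A [methylome()] tibble. Unsorted input is sorted with a warning;
#'   duplicate sites are an error.
#' @export
read_cytosine_report <- function(path, context_filter = "CG", min_depth = 0L,
                                 sample_id = basename(path),
                                 collapse_strands = FALSE,
                                 normalize_chrom = FALSE) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(methylome(tibble(chrom = character(), start = integer(),
                            strand = character(), context = character(),
                            meth = integer(), unmeth = integer()),
                     sample_id = sample_id))
  }
  df <- parse_cytosine_report(lines)
  if (normalize_chrom) df$chrom <- normalize_chrom_names(df$chrom)
  if (collapse_strands) df <- collapse_cpg_strands(df)
  if (!is.null(context_filter)) df <- df[df$context %in% context_filter, ]
  df <- df[df$meth + df$unmeth >= min_depth, ]
  ord <- order(df$chrom, df$start, df$strand)
  if (!identical(ord, seq_len(nrow(df)))) {
    warn(paste0("input not sorted by (chrom, pos, strand); sorting: ", path))
  }
  methylome(df, sample_id = sample_id)
}

# sum minus-strand CG counts onto the plus-strand position of the pair
collapse_cpg_strands <- function(df) {
  cg_minus <- df$context == "CG" & df$strand == "-"
  df$start[cg_minus] <- df$start[cg_minus] - 1L
  df$strand[cg_minus] <- "+"
  df |>
    group_by(.data$chrom, .data$start, .data$strand, .data$context) |>
    summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
              tri = .data$tri[1], .groups = "drop")
}

#' Write a methylome as a cytosine report
#'
#' Inverse of [read_cytosine_report()]: 0-based `start` is written as a
#' 1-based position. Gzip output is selected by a `.gz` extension.
#'
#' @param sample A methylome tibble.
#' @param path Output path.
#' @export
write_cytosine_report <- function(sample, path) {
  con <- open_output(path)
  on.exit(close(con))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s",
                   sample$chrom, sample$start + 1L, sample$strand,
                   sample$meth, sample$unmeth, sample$context,
                   ifelse(is.na(sample$tri), "NNN", sample$tri))
  writeLines(lines, con)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with chromosome name and length.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = "ci", progress = FALSE)
  if (any(is.na(df$length)) || any(df$length <= 0)) {
    abort("chrom.sizes lengths must be positive integers")
  }
  df
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Tibble with `chrom` and `length`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(chrom_sizes[, c("chrom", "length")], path,
                   col_names = FALSE)
  invisible(path)
}
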