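#' Read transcript models from refFlat or BED12
#'
#' Both dialects use 0-based half-open coordinates, which is also the
#' package-internal convention, so no shifting occurs. Each row of the result
#' is one transcript; exon coordinates are kept in list-columns.
#'
#' refFlat columns: geneName, name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds (comma-separated lists).
#' BED12: chrom, start, end, name, score, strand, thickStart, thickEnd,
#' itemRgb, blockCount, blockSizes, blockStarts; thick bounds are taken as
#' the coding span and the name doubles as gene and transcript id.
#'
#' @param path Input file (optionally gzipped).
#' @param dialect `"refflat"` or `"bed12"`.
#' @return A tibble with columns `gene_name`, `transcript_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, and list-columns
#'   `exon_starts`, `exon_ends`. A transcript with `cds_start == cds_end` is
#'   non-coding.
#' @export
read_gene_models <- function(path, dialect = c("refflat", "bed12")) {
  dialect <- match.arg(dialect)
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- stringr::str_split(lines, "\t")
  parse_one <- if (dialect == "refflat") parse_refflat_row else parse_bed12_row
  models <- purrr::imap(fields, function(f, i) {
    tryCatch(parse_one(f), error = function(e) {
      abort(sprintf("%s record %d (%s): %s", dialect, i,
                    f[if (dialect == "refflat") 2 else 4] %||% "?",
                    conditionMessage(e)),
            class = "twindmr_model_error")
    })
  })
  out <- bind_rows(models)
  validate_gene_models(out)
  out
}

parse_refflat_row <- function(f) {
  if (length(f) < 11L) stop("expected 11 fields")
  exon_starts <- as.integer(strsplit(f[10], ",")[[1]])
  exon_ends <- as.integer(strsplit(f[11], ",")[[1]])
  n <- as.integer(f[9])
  if (length(exon_starts) != n || length(exon_ends) != n) {
    stop("exonCount does not match exon lists")
  }
  tibble(
    gene_name = f[1], transcript_id = f[2], chrom = f[3], strand = f[4],
    tx_start = as.integer(f[5]), tx_end = as.integer(f[6]),
    cds_start = as.integer(f[7]), cds_end = as.integer(f[8]),
    exon_starts = list(exon_starts), exon_ends = list(exon_ends)
  )
}

parse_bed12_row <- function(f) {
  if (length(f) < 12L) stop("expected 12 fields")
  chrom_start <- as.integer(f[2])
  n <- as.integer(f[10])
  sizes <- as.integer(strsplit(f[11], ",")[[1]])
  offsets <- as.integer(strsplit(f[12], ",")[[1]])
  if (length(sizes) != n || length(offsets) != n) {
    stop("blockCount does not match block lists")
  }
  exon_starts <- chrom_start + offsets
  exon_ends <- exon_starts + sizes
  tibble(
    gene_name = f[4], transcript_id = f[4], chrom = f[1], strand = f[6],
    tx_start = chrom_start, tx_end = as.integer(f[3]),
    cds_start = as.integer(f[7]), cds_end = as.integer(f[8]),
    exon_starts = list(exon_starts), exon_ends = list(exon_ends)
  )
}

#' Validate a gene-model tibble
#'
#' Checks transcript spans, exon ordering/containment and coding-span
#' containment; raises an error naming the first offending transcript.
#'
#' @param models Gene-model tibble as returned by [read_gene_models()].
#' @return The input, invisibly.
#' @export
validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    id <- models$transcript_id[i]
    fail <- function(msg) {
      abort(sprintf("invalid gene model '%s': %s", id, msg),
            class = "twindmr_model_error")
    }
    s <- models$tx_start[i]; e <- models$tx_end[i]
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    if (!(s < e)) fail("tx_start must be < tx_end")
    if (!(cs <= ce)) fail("cds_start must be <= cds_end")
    if (cs < s || ce > e) fail("coding span outside transcript span")
    if (length(es) != length(ee) || !length(es)) fail("empty or ragged exon list")
    if (any(ee <= es)) fail("exon end must exceed exon start")
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)])) {
      fail("exons must be sorted and non-overlapping")
    }
    if (es[1] < s || ee[length(ee)] > e) fail("exon outside transcript span")
  }
  invisible(models)
}

#' Write gene models in refFlat layout
#'
#' @param models Gene-model tibble.
#' @param path Output path.
#' @export
write_refflat <- function(models, path) {
  con <- open_output(path)
  on.exit(close(con))
  lines <- purrr::pmap_chr(models, function(gene_name, transcript_id, chrom,
                                            strand, tx_start, tx_end,
                                            cds_start, cds_end, exon_starts,
                                            exon_ends, ...) {
    sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
            gene_name, transcript_id, chrom, strand, tx_start, tx_end,
            cds_start, cds_end, length(exon_starts),
            paste0(paste(exon_starts, collapse = ","), ","),
            paste0(paste(exon_ends, collapse = ","), ","))
  })
  writeLines(lines, con)
  invisible(path)
}

#' Read a TF-binding-site BED track
#'
#' Expects BED with at least 4 columns (chrom, start, end, name); a 5th
#' numeric column is kept as `score`.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end`, `tf_name`, `score`.
#' @export
read_tfbs_bed <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- stringr::str_split(lines, "\t")
  if (any(lengths(fields) < 4L)) {
    abort("TFBS BED needs at least 4 columns (chrom, start, end, name)")
  }
  out <- tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = as.integer(vapply(fields, `[`, "", 2)),
    end = as.integer(vapply(fields, `[`, "", 3)),
    tf_name = vapply(fields, `[`, "", 4),
    score = vapply(fields, function(f) {
      if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_
    }, numeric(1))
  )
  if (any(out$start >= out$end)) abort("TFBS intervals must satisfy start < end")
  out
}

#' @rdname read_tfbs_bed
#' @param tfbs TFBS tibble.
#' @export
write_tfbs_bed <- function(tfbs, path) {
  con <- open_output(path)
  on.exit(close(con))
  score <- ifelse(is.na(tfbs$score %||% rep(NA_real_, nrow(tfbs))),
                  "0", format(tfbs$score, trim = TRUE))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", tfbs$chrom, tfbs$start,
                     tfbs$end, tfbs$tf_name, score), con)
  invisible(path)
}
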