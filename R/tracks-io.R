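#' Write DMRs as BED6+
#'
#' Columns: chrom, start, end, name (direction), score, strand (`.`), then
#' `n_cpgs`, `mean_s1`, `mean_s2`. The BED score is the Phred-scaled p-value
#' `min(1000, round(-10 * log10(p)))`.
#'
#' @param dmrs DMR tibble (0-based half-open `start`/`end`, `direction`,
#'   `p_value`, `n_cpgs`, `mean_s1`, `mean_s2`).
#' @param path Output path.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  con <- open_output(path)
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tdirection\tscore\tstrand\tn_cpgs\tmean_s1\tmean_s2",
             con)
  if (nrow(dmrs)) {
    score <- pmin(1000, round(-10 * log10(dmrs$p_value)))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%d\t%.6g\t%.6g",
                       dmrs$chrom, as.integer(dmrs$start),
                       as.integer(dmrs$end), dmrs$direction, as.integer(score),
                       as.integer(dmrs$n_cpgs), dmrs$mean_s1, dmrs$mean_s2),
               con)
  }
  invisible(path)
}

#' Read DMRs written by [write_dmrs_bed()]
#'
#' @param path BED6+ path.
#' @return Tibble with `chrom`, `start`, `end`, `direction`, `score`,
#'   `n_cpgs`, `mean_s1`, `mean_s2`.
#' @export
read_dmrs_bed <- function(path) {
  df <- readr::read_tsv(path, comment = "#",
                        col_names = c("chrom", "start", "end", "direction",
                                      "score", "strand", "n_cpgs",
                                      "mean_s1", "mean_s2"),
                        col_types = "ciicicidd", progress = FALSE)
  df[, setdiff(names(df), "strand")]
}

#' Read a clone-by-CpG binary methylation matrix
#'
#' Rows are sequenced clones, columns are CpG positions within the assayed
#' amplicon; entries are 1 (methylated), 0 (unmethylated) or NA (unread).
#' The first column holds the clone identifier; remaining column headers are
#' the CpG positions.
#'
#' @param path TSV path.
#' @return Tibble with a `clone` column and one integer column per CpG.
#' @export
read_clone_matrix <- function(path) {
  df <- readr::read_tsv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = c("", "NA", "."))
  names(df)[1] <- "clone"
  df[-1] <- lapply(df[-1], function(x) suppressWarnings(as.integer(x)))
  vals <- unlist(df[-1], use.names = FALSE)
  if (!all(vals %in% c(0L, 1L, NA))) {
    abort("clone matrix entries must be 0, 1 or missing")
  }
  if (nrow(df) < 1) abort("clone matrix needs at least one clone")
  df
}

#' @rdname read_clone_matrix
#' @param clones Clone tibble (`clone` + CpG position columns).
#' @export
write_clone_matrix <- function(clones, path) {
  readr::write_tsv(clones, path, na = "NA")
  invisible(path)
}

#' Read and write the cohort table
#'
#' Columns: `sample_id`, `group` (case/control), `expression` (relative
#' expression level, positive).
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_cohort <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  names(df)[1:3] <- c("sample_id", "group", "expression")
  if (!all(df$group %in% c("case", "control"))) {
    abort("cohort group must be 'case' or 'control'")
  }
  if (any(!is.na(df$expression) & df$expression <= 0)) {
    abort("expression values must be positive")
  }
  df
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}
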