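#' Per-CpG and per-sample means of a clone matrix
#'
#' Clone bisulfite sequencing yields, per sample, a clones x CpG binary
#' matrix (1 = methylated). The per-CpG mean is the column mean over
#' non-missing entries; the sample mean averages over all non-missing
#' entries of the matrix (so columns with more missing clones weigh less).
#'
#' @param clones Clone tibble from [read_clone_matrix()] (`clone` column
#'   plus one 0/1/NA column per CpG position).
#' @return List with `per_cpg` (tibble: `position`, `mean_methylation`,
#'   `n_clones`; a fully-missing column has `NA` mean) and `sample_mean`.
#' @export
clone_mean_profile <- function(clones) {
  mat <- as.matrix(clones[, setdiff(names(clones), "clone"), drop = FALSE])
  if (!nrow(mat) || !ncol(mat)) abort("clone matrix is empty")
  per_cpg <- tibble(
    position = suppressWarnings(as.numeric(colnames(mat))),
    mean_methylation = unname(colMeans(mat, na.rm = TRUE)),
    n_clones = unname(colSums(!is.na(mat)))
  )
  per_cpg$mean_methylation[per_cpg$n_clones == 0] <- NA_real_
  list(per_cpg = per_cpg,
       sample_mean = mean(mat, na.rm = TRUE))
}

#' Call a sample hypermethylated
#'
#' @param sample_mean Per-sample mean methylation (vectorized).
#' @param threshold Call threshold in `[0, 1]`; the call is strict
#'   (`sample_mean > threshold`).
#' @return Logical vector.
#' @export
call_hypermethylated <- function(sample_mean, threshold = 0.5) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  sample_mean > threshold
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by the probability-mass method: conditioning on the
#' margins, the p-value sums the hypergeometric probabilities of every table
#' whose probability does not exceed that of the observed table (with a
#' relative tolerance of 1e-7 for ties).
#'
#' @param table 2x2 matrix of non-negative counts (rows = group, columns =
#'   methylation call), or the count `a` with `b`, `c`, `d` given.
#' @param b,c,d Remaining cells when `table` is given as the scalar `a`.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- table
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    abort("degenerate margins: every row and column must be non-empty",
          class = "twindmr_degenerate_table")
  }
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson correlation between methylation and expression
#'
#' @param cohort Tibble with columns `mean_methylation` and `expression`;
#'   rows with either value missing are dropped.
#' @return One-row tibble with `r`, `p_value` (two-sided, t distribution on
#'   n - 2 df) and `n`.
#' @export
methylation_expression_correlation <- function(cohort) {
  ok <- stats::complete.cases(cohort[, c("mean_methylation", "expression")])
  x <- cohort$mean_methylation[ok]
  y <- cohort$expression[ok]
  if (length(x) < 3) {
    abort("need at least 3 complete records",
          class = "twindmr_undefined_correlation")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance; correlation undefined",
          class = "twindmr_undefined_correlation")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Validate a clinical cohort against a hypermethylation call
#'
#' Summarises each sample's clone matrix, calls hypermethylation, tabulates
#' the call against disease status, tests the association with Fisher's
#' exact test, and correlates methylation with expression.
#'
#' @param clone_matrices Named list of clone tibbles, names = sample ids.
#' @param cohort Cohort tibble (`sample_id`, `group`, `expression`).
#' @param threshold Hypermethylation threshold for `rule = "threshold"`.
#' @param rule `"threshold"` calls `mean > threshold`; `"max_control"`
#'   calls a sample hypermethylated when its mean exceeds the largest
#'   control mean.
#' @return Object of class `cohort_validation`: `samples` (per-sample means
#'   and calls), `table` (2x2: group x call), `fisher_p`, `correlation`
#'   (from [methylation_expression_correlation()]), `threshold`, `rule`.
#' @export
validate_cohort <- function(clone_matrices, cohort, threshold = 0.5,
                            rule = c("threshold", "max_control")) {
  rule <- match.arg(rule)
  missing_ids <- setdiff(cohort$sample_id, names(clone_matrices))
  if (length(missing_ids)) {
    abort(paste0("no clone matrix for sample(s): ",
                 paste(missing_ids, collapse = ", ")))
  }
  samples <- cohort |>
    mutate(mean_methylation = purrr::map_dbl(
      .data$sample_id, ~ clone_mean_profile(clone_matrices[[.x]])$sample_mean))
  cut_at <- if (rule == "max_control") {
    max(samples$mean_methylation[samples$group == "control"])
  } else {
    threshold
  }
  samples$hyper_call <- call_hypermethylated(samples$mean_methylation, cut_at)
  tab <- matrix(c(sum(samples$group == "case" & samples$hyper_call),
                  sum(samples$group == "case" & !samples$hyper_call),
                  sum(samples$group == "control" & samples$hyper_call),
                  sum(samples$group == "control" & !samples$hyper_call)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("hyper", "not_hyper")))
  fisher_p <- fisher_exact_two_sided(tab)
  correlation <- methylation_expression_correlation(samples)
  structure(list(samples = samples, table = tab, fisher_p = fisher_p,
                 correlation = correlation, threshold = cut_at, rule = rule),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation\n")
  print(x$table)
  cat(sprintf("Fisher exact p = %.4g\n", x$fisher_p))
  cat(sprintf("methylation-expression r = %.3f (p = %.3g, n = %d)\n",
              x$correlation$r, x$correlation$p_value, x$correlation$n))
  invisible(x)
}
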