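#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DMR scan
#'
#' @param x A `dmr_scan` from [call_dmrs()].
#' @param what `"dmrs"` (default) returns merged regions; `"windows"`
#'   returns every tested window.
#' @param ... Unused.
#' @return A tibble without list-columns.
#' @export
tidy.dmr_scan <- function(x, what = c("dmrs", "windows"), ...) {
  what <- match.arg(what)
  if (what == "dmrs") {
    x$dmrs |> select(!dplyr::any_of("positions"))
  } else {
    x$dmws |> select(!dplyr::any_of(c("positions", "levels_s1", "levels_s2")))
  }
}

#' @rdname tidy.dmr_scan
#' @export
glance.dmr_scan <- function(x, ...) {
  r <- x$report
  tibble(windows_tested = r$windows_tested,
         dmws_significant = r$dmws_significant,
         n_dmrs = r$n_dmrs, n_hyper = r$n_hyper, n_hypo = r$n_hypo)
}

#' Tidy a cohort validation
#'
#' @param x A `cohort_validation` from [validate_cohort()].
#' @param ... Unused.
#' @return `tidy()`: per-sample tibble with means and calls. `glance()`:
#'   one-row tibble with the 2x2 cell counts, Fisher p and the
#'   methylation-expression correlation.
#' @export
tidy.cohort_validation <- function(x, ...) {
  x$samples
}

#' @rdname tidy.cohort_validation
#' @export
glance.cohort_validation <- function(x, ...) {
  tibble(n_case = sum(x$table[1, ]), n_control = sum(x$table[2, ]),
         hyper_case = x$table[1, 1], hyper_control = x$table[2, 1],
         fisher_p = x$fisher_p, r = x$correlation$r,
         cor_p = x$correlation$p_value)
}

#' @rdname summarize_categories
#' @param x A `dmr_category_summary`.
#' @param ... Unused.
#' @export
tidy.dmr_category_summary <- function(x, ...) {
  x$by_category
}

#' @rdname summarize_categories
#' @export
glance.dmr_category_summary <- function(x, ...) {
  x$promoter
}
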