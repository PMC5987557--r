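#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the per-site methylation level distribution
#'
#' Somatic methylomes are strongly bimodal: most CpGs sit near 0 or 1.
#'
#' @param sample Methylome tibble.
#' @param bins Number of level bins.
#' @return A ggplot.
#' @export
plot_methylation_distribution <- function(sample, bins = 20L) {
  d <- methylation_distribution(sample, bins = bins)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                                  y = .data$prop)) +
    ggplot2::geom_col(width = 1 / bins, fill = "steelblue") +
    ggplot2::labs(x = "methylation level", y = "fraction of CpGs",
                  title = attr(sample, "sample_id")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of shared-site levels between two samples
#'
#' @param s1,s2 Methylome tibbles.
#' @param min_depth Depth required in both samples.
#' @return A ggplot annotated with the Pearson r.
#' @export
plot_sample_correlation <- function(s1, s2, min_depth = 10L) {
  shared <- shared_deep_sites(s1, s2, min_depth)
  r <- sample_correlation(s1, s2, min_depth)
  ggplot2::ggplot(shared, ggplot2::aes(.data$level_1, .data$level_2)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::annotate("text", x = 0.1, y = 0.97,
                      label = sprintf("r = %.4f", r), hjust = 0) +
    ggplot2::labs(x = attr(s1, "sample_id") %||% "sample 1",
                  y = attr(s2, "sample_id") %||% "sample 2") +
    ggplot2::theme_minimal()
}

#' @describeIn call_dmrs Window-level significance along the genome:
#'   -log10 p per tested window, significant windows highlighted, faceted
#'   by chromosome.
#' @param object A `dmr_scan`.
#' @param ... Unused.
#' @export
autoplot.dmr_scan <- function(object, ...) {
  d <- tidy(object, what = "windows")
  d$significant <- object$dmws$significant
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @describeIn summarize_categories Bar chart of category proportions per
#'   direction.
#' @param object A `dmr_category_summary`.
#' @export
autoplot.dmr_category_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_category,
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DMRs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Lollipop-style view of a clone methylation matrix
#'
#' @param clones Clone tibble ([read_clone_matrix()]).
#' @return A ggplot tile map (clones x CpGs; filled = methylated).
#' @export
plot_clone_matrix <- function(clones) {
  long <- clones |>
    tidyr::pivot_longer(!"clone", names_to = "position",
                        values_to = "methylated") |>
    mutate(position = as.numeric(.data$position))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$position),
                                     y = .data$clone,
                                     fill = factor(.data$methylated))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               na.value = "grey80", name = "methylated") +
    ggplot2::labs(x = "CpG position", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn validate_cohort Methylation-expression scatter coloured by
#'   group, with the fitted Pearson r in the title.
#' @param object A `cohort_validation`.
#' @param ... Unused.
#' @export
autoplot.cohort_validation <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(.data$mean_methylation, .data$expression,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = sprintf("r = %.3f (p = %.3g)",
                                  object$correlation$r,
                                  object$correlation$p_value),
                  x = "promoter methylation (sample mean)",
                  y = "relative expression") +
    ggplot2::theme_minimal()
}
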