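#' Parameters for sliding-window DMR calling
#'
#' Defaults reproduce the discovery settings: 100 bp windows advanced in
#' 50 bp steps along each chromosome, CpG sites covered by at least 10 reads
#' in both samples, a two-sided Wilcoxon rank-sum test per window with
#' p < 0.01, and rejection of windows with fewer than 5 usable CpGs or an
#' absolute window mean difference below 10 percentage points.
#'
#' @param window_size Window width in bp.
#' @param step Grid step in bp (`window_size >= step >= 1`).
#' @param min_depth Minimum read depth per site, required in both samples.
#' @param alpha Raw p-value threshold for a differentially methylated window.
#' @param min_cpgs Minimum usable CpG sites per retained window.
#' @param min_delta Minimum absolute difference of window mean levels.
#' @param test `"ranksum"` or `"signed_rank"` (see [window_test()]).
#' @param adjust If `"BH"`, apply Benjamini-Hochberg across tested windows
#'   before thresholding; `"none"` (default) thresholds raw p-values.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(window_size = 100L, step = 50L, min_depth = 10L,
                       alpha = 0.01, min_cpgs = 5L, min_delta = 0.10,
                       test = c("ranksum", "signed_rank"),
                       adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (!(window_size >= step && step >= 1)) {
    abort("require window_size >= step >= 1")
  }
  assert_scalar_number(alpha, "alpha", lo = 1e-300, hi = 1 - 1e-12)
  assert_scalar_number(min_delta, "min_delta", lo = 0, hi = 1)
  if (min_cpgs < 1) abort("min_cpgs must be >= 1")
  if (min_depth < 0) abort("min_depth must be >= 0")
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step), min_depth = as.integer(min_depth),
                 alpha = alpha, min_cpgs = as.integer(min_cpgs),
                 min_delta = min_delta, test = test, adjust = adjust),
            class = "dmr_params")
}

#' Per-site methylation level
#'
#' @param meth_count,unmeth_count Read counts; total depth must be positive.
#' @return `meth_count / (meth_count + unmeth_count)`, vectorized.
#' @export
methylation_level <- function(meth_count, unmeth_count) {
  depth <- meth_count + unmeth_count
  if (any(depth <= 0)) {
    abort("methylation level undefined at zero depth",
          class = "twindmr_zero_depth")
  }
  meth_count / depth
}

# sites covered >= min_depth in BOTH samples, CG context by default
shared_deep_sites <- function(s1, s2, min_depth, context = "CG") {
  a <- s1[s1$context %in% context & (s1$meth + s1$unmeth) >= min_depth,
          c("chrom", "start", "strand", "meth", "unmeth")]
  b <- s2[s2$context %in% context & (s2$meth + s2$unmeth) >= min_depth,
          c("chrom", "start", "strand", "meth", "unmeth")]
  inner_join(a, b, by = c("chrom", "start", "strand"),
             suffix = c("_1", "_2")) |>
    mutate(level_1 = .data$meth_1 / (.data$meth_1 + .data$unmeth_1),
           level_2 = .data$meth_2 / (.data$meth_2 + .data$unmeth_2)) |>
    arrange(.data$chrom, .data$start, .data$strand)
}

#' Paired per-site levels within one window
#'
#' Returns the methylation levels of CpG sites lying in `[start, end)` that
#' reach `min_depth` in both samples, in position order.
#'
#' @param s1,s2 Methylome tibbles.
#' @param chrom,start,end Window interval (0-based half-open).
#' @param min_depth Depth required in both samples.
#' @return List with numeric `levels_s1`, `levels_s2` and integer `positions`.
#' @export
window_sites <- function(s1, s2, chrom, start, end, min_depth = 10L) {
  shared <- shared_deep_sites(s1, s2, min_depth)
  hit <- shared$chrom == chrom & shared$start >= start & shared$start < end
  list(levels_s1 = shared$level_1[hit],
       levels_s2 = shared$level_2[hit],
       positions = shared$start[hit])
}

#' Scan the fixed window grid and test every covered window
#'
#' Windows start at multiples of `step` from coordinate 0 of each
#' chromosome; trailing windows that would extend past the chromosome end
#' are not emitted. Every window holding at least one shared deep CpG site
#' is tested; significance is decided downstream by [filter_dmws()].
#'
#' @param s1,s2 Methylome tibbles.
#' @param params [dmr_params()].
#' @param chrom_sizes Tibble with `chrom`, `length` covering all records.
#' @return Tibble of tested windows (DMWs): `chrom`, `start`, `end`,
#'   `n_cpgs`, `mean_s1`, `mean_s2`, `delta` (`mean_s1 - mean_s2`),
#'   `p_value`, plus list-columns `positions`, `levels_s1`, `levels_s2`.
#' @export
scan_windows <- function(s1, s2, params = dmr_params(), chrom_sizes) {
  shared <- shared_deep_sites(s1, s2, params$min_depth)
  missing_chr <- setdiff(unique(c(s1$chrom, s2$chrom)), chrom_sizes$chrom)
  if (length(missing_chr)) {
    abort(paste0("chrom_sizes missing: ", paste(missing_chr, collapse = ", ")))
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_cpgs = integer(), mean_s1 = double(), mean_s2 = double(),
                  delta = double(), p_value = double(),
                  positions = list(), levels_s1 = list(), levels_s2 = list())
  if (!nrow(shared)) return(empty)
  w <- params$window_size; st <- params$step
  len <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  # windows containing site s: indices i with i*st <= s < i*st + w
  i_max_site <- floor(shared$start / st)
  i_min_site <- pmax(0L, ceiling((shared$start - w + 1L) / st))
  i_last <- floor((len[shared$chrom] - w) / st)   # last full window
  i_max_site <- pmin(i_max_site, i_last)
  n_win <- pmax(0L, i_max_site - i_min_site + 1L)
  keep <- n_win > 0L
  site_rep <- rep(which(keep), n_win[keep])
  win_idx <- unlist(purrr::map2(i_min_site[keep], i_max_site[keep], seq),
                    use.names = FALSE)
  if (!length(site_rep)) return(empty)
  expanded <- tibble(chrom = shared$chrom[site_rep],
                     win = as.integer(win_idx),
                     pos = shared$start[site_rep],
                     l1 = shared$level_1[site_rep],
                     l2 = shared$level_2[site_rep])
  expanded |>
    group_by(.data$chrom, .data$win) |>
    summarise(n_cpgs = dplyr::n(),
              mean_s1 = mean(.data$l1), mean_s2 = mean(.data$l2),
              positions = list(.data$pos),
              levels_s1 = list(.data$l1), levels_s2 = list(.data$l2),
              .groups = "drop") |>
    mutate(start = .data$win * st, end = .data$start + w,
           delta = .data$mean_s1 - .data$mean_s2,
           p_value = purrr::map2_dbl(.data$levels_s1, .data$levels_s2,
                                     window_test, test = params$test)) |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "n_cpgs", "mean_s1", "mean_s2",
           "delta", "p_value", "positions", "levels_s1", "levels_s2")
}

#' Keep differentially methylated windows
#'
#' Retains windows with `p_value < alpha` AND `n_cpgs >= min_cpgs` AND
#' `|delta| >= min_delta`. With `adjust = "BH"` the threshold applies to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param dmws Output of [scan_windows()].
#' @param params [dmr_params()].
#' @return The retained subset, same columns.
#' @export
filter_dmws <- function(dmws, params = dmr_params()) {
  p <- if (params$adjust == "BH") stats::p.adjust(dmws$p_value, "BH") else dmws$p_value
  dmws[p < params$alpha &
         dmws$n_cpgs >= params$min_cpgs &
         abs(dmws$delta) >= params$min_delta, ]
}

#' Merge adjacent significant windows into DMRs
#'
#' Within each chromosome and direction (sign of `delta`), maximal runs of
#' windows that overlap or abut are unioned into one region. A merged DMR
#' reports the minimum constituent p-value, the number of constituent
#' windows, and means over the distinct CpG sites it covers.
#'
#' @param dmws Significant windows from [filter_dmws()] (list-columns
#'   required for site-level summaries).
#' @return DMR tibble: `chrom`, `start`, `end`, `direction` (`"hyper"` if
#'   sample 1 is higher), `n_windows`, `n_cpgs`, `p_value`, `mean_s1`,
#'   `mean_s2`, `delta`, and a `positions` list-column of distinct sites.
#' @export
merge_dmws <- function(dmws) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  direction = character(), n_windows = integer(),
                  n_cpgs = integer(), p_value = double(), mean_s1 = double(),
                  mean_s2 = double(), delta = double(), positions = list())
  if (!nrow(dmws)) return(empty)
  d <- dmws |>
    mutate(direction = ifelse(.data$delta >= 0, "hyper", "hypo")) |>
    arrange(.data$chrom, .data$direction, .data$start)
  # run id: new run when chrom/direction changes or a gap appears
  run_end <- cummax_by_group(d$end, paste(d$chrom, d$direction))
  new_run <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                 d$direction[-1] != d$direction[-nrow(d)] |
                 d$start[-1] > run_end[-nrow(d)])
  d$run <- cumsum(new_run)
  d |>
    group_by(.data$run) |>
    summarise(chrom = .data$chrom[1],
              start = min(.data$start), end = max(.data$end),
              direction = .data$direction[1],
              n_windows = dplyr::n(),
              p_value = min(.data$p_value),
              site_tbl = list({
                pos <- unlist(.data$positions)
                l1 <- unlist(.data$levels_s1)
                l2 <- unlist(.data$levels_s2)
                distinct(tibble(pos = pos, l1 = l1, l2 = l2))
              }),
              .groups = "drop") |>
    mutate(n_cpgs = purrr::map_int(.data$site_tbl, nrow),
           mean_s1 = purrr::map_dbl(.data$site_tbl, ~ mean(.x$l1)),
           mean_s2 = purrr::map_dbl(.data$site_tbl, ~ mean(.x$l2)),
           delta = .data$mean_s1 - .data$mean_s2,
           positions = purrr::map(.data$site_tbl, ~ sort(.x$pos))) |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "direction", "n_windows", "n_cpgs",
           "p_value", "mean_s1", "mean_s2", "delta", "positions")
}

# running maximum of x restarting whenever the group key changes
cummax_by_group <- function(x, key) {
  out <- x
  for (i in seq_along(x)[-1]) {
    if (key[i] == key[i - 1]) out[i] <- max(out[i - 1], x[i])
  }
  out
}

#' Call DMRs between two methylomes
#'
#' Composes [scan_windows()], [filter_dmws()] and [merge_dmws()] and keeps a
#' scan report of counts at each stage.
#'
#' @inheritParams scan_windows
#' @return An object of class `dmr_scan`: a list with `dmrs` (merged
#'   regions), `dmws` (all tested windows with a `significant` flag),
#'   `params`, and `report` (windows tested, significant windows, DMR count,
#'   hyper/hypo split).
#' @export
call_dmrs <- function(s1, s2, params = dmr_params(), chrom_sizes) {
  dmws <- scan_windows(s1, s2, params, chrom_sizes)
  sig <- filter_dmws(dmws, params)
  dmrs <- merge_dmws(sig)
  key <- paste(dmws$chrom, dmws$start)
  dmws$significant <- key %in% paste(sig$chrom, sig$start)
  report <- list(
    windows_tested = nrow(dmws),
    dmws_significant = nrow(sig),
    n_dmrs = nrow(dmrs),
    n_hyper = sum(dmrs$direction == "hyper"),
    n_hypo = sum(dmrs$direction == "hypo"),
    sample_1 = attr(s1, "sample_id") %||% "sample1",
    sample_2 = attr(s2, "sample_id") %||% "sample2"
  )
  structure(list(dmrs = dmrs, dmws = dmws, params = params, report = report),
            class = "dmr_scan")
}

#' @export
print.dmr_scan <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("DMR scan of %s vs %s\n",
                     "  windows tested:      %d\n",
                     "  significant windows: %d\n",
                     "  DMRs:                %d (%d hyper, %d hypo)\n"),
              r$sample_1, r$sample_2, r$windows_tested, r$dmws_significant,
              r$n_dmrs, r$n_hyper, r$n_hypo))
  invisible(x)
}

#' Between-sample correlation of CpG methylation levels
#'
#' Pearson correlation of per-site levels over CpGs reaching `min_depth` in
#' both samples; the study's replicate-similarity QC.
#'
#' @param s1,s2 Methylome tibbles.
#' @param min_depth Depth required in both samples.
#' @return Pearson r (scalar).
#' @export
sample_correlation <- function(s1, s2, min_depth = 10L) {
  shared <- shared_deep_sites(s1, s2, min_depth)
  if (nrow(shared) < 2) {
    abort("need at least 2 shared deep sites for a correlation",
          class = "twindmr_undefined_correlation")
  }
  if (sd(shared$level_1) == 0 || sd(shared$level_2) == 0) {
    abort("zero variance in methylation levels; correlation undefined",
          class = "twindmr_undefined_correlation")
  }
  cor(shared$level_1, shared$level_2)
}

#' Histogram of per-site methylation levels
#'
#' QC view of the genome-wide level distribution, which is strongly bimodal
#' in somatic methylomes (most CpGs fully methylated or unmethylated).
#' Bins follow the base-R histogram convention: first bin closed on the
#' left, all bins closed on the right.
#'
#' @param sample Methylome tibble; sites with zero depth are ignored.
#' @param bins Number of equal-width bins over `[0, 1]`.
#' @param context Contexts included (default CG).
#' @return Tibble with `bin_lower`, `bin_upper`, `count`, `prop`.
#' @export
methylation_distribution <- function(sample, bins = 10L, context = "CG") {
  covered <- sample[sample$context %in% context &
                      (sample$meth + sample$unmeth) > 0, ]
  if (!nrow(covered)) abort("no covered sites in the requested context")
  lev <- covered$meth / (covered$meth + covered$unmeth)
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- graphics::hist(lev, breaks = breaks, plot = FALSE)$counts
  tibble(bin_lower = breaks[-length(breaks)], bin_upper = breaks[-1],
         count = counts, prop = counts / sum(counts))
}
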