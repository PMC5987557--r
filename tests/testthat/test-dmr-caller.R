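test_that("methylation level is the methylated read fraction", {
  expect_equal(methylation_level(7, 3), 0.7)
  expect_equal(methylation_level(0, 12), 0)
  expect_equal(methylation_level(5, 0), 1)
  expect_equal(methylation_level(c(7, 0), c(3, 12)), c(0.7, 0))
  expect_error(methylation_level(0, 0), class = "twindmr_zero_depth")
})

test_that("window_sites keeps only sites deep in both samples", {
  s1 <- make_methylome(c(10, 20, 30, 40), meth = c(8, 9, 5, 9),
                       unmeth = c(2, 1, 5, 1), id = "a")
  s2 <- make_methylome(c(10, 20, 30, 50), meth = c(1, 2, 10, 3),
                       unmeth = c(9, 8, 0, 7), id = "b")
  got <- window_sites(s1, s2, "chr1", 0, 100, min_depth = 10)
  expect_equal(got$positions, c(10L, 20L, 30L))        # 40/50 in one sample only
  expect_equal(got$levels_s1, c(0.8, 0.9, 0.5))
  expect_equal(got$levels_s2, c(0.1, 0.2, 1.0))
  # depth exactly min_depth is included (">= 10" reading of 10X)
  boundary <- window_sites(s1, s2, "chr1", 0, 100, min_depth = 10)
  expect_true(10L %in% boundary$positions)
  # disjoint interval -> empty
  none <- window_sites(s1, s2, "chr1", 500, 600, min_depth = 1)
  expect_length(none$positions, 0)
})

test_that("rank-sum p-values match hand-derived exact values", {
  # fully separated 5 vs 5: only the two extreme assignments qualify
  expect_equal(window_test(rep(0, 5), rep(1, 5)), 2 / 252)
  # identical vectors: every assignment is as extreme
  expect_equal(window_test(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3)), 1)
  expect_equal(window_test(c(0.1, 0.2), c(0.1, 0.2), test = "signed_rank"), 1)
  # mid-rank case checked against the bitmask enumeration oracle
  x <- c(0.1, 0.2, 0.3); y <- c(0.2, 0.3, 0.4)
  expect_equal(window_test(x, y), oracle_ranksum_p(x, y))
  expect_error(window_test(numeric(0), numeric(0)), regexp = "non-empty")
})

test_that("exact rank-sum equals enumeration on random level sets", {
  set.seed(42)
  for (i in 1:120) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    # methylation-like levels with frequent ties
    pool <- round(runif(12), 1)
    x <- sample(pool, n1, replace = TRUE)
    y <- sample(pool, n2, replace = TRUE)
    expect_equal(window_test(x, y), oracle_ranksum_p(x, y),
                 info = sprintf("case %d", i))
  }
})

test_that("exact rank-sum agrees with wilcox.test on tie-free data", {
  set.seed(7)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- runif(n1); y <- runif(n2)     # continuous, ties a.s. absent
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))$p.value
    expect_equal(window_test(x, y), ref, tolerance = 1e-12)
  }
})

test_that("signed-rank variant matches wilcox.test on paired tie-free data", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- runif(n); y <- runif(n)
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               exact = TRUE))$p.value
    expect_equal(window_test(x, y, test = "signed_rank"), ref,
                 tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum uses the tie-corrected normal approximation", {
  set.seed(9)
  x <- round(runif(15), 1); y <- round(runif(15) + 0.2, 1)
  got <- window_test(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))$p.value
  expect_equal(got, ref, tolerance = 1e-9)
  # all-tied input is defined as p = 1
  expect_equal(window_test(rep(0.5, 20), rep(0.5, 20)), 1)
})

test_that("scan emits the fixed window grid and only covered windows", {
  # chromosome of length 250: full windows start at 0, 50, 100, 150
  s1 <- make_methylome(c(5, 60, 120, 240), meth = rep(10, 4),
                       unmeth = rep(10, 4))
  s2 <- make_methylome(c(5, 60, 120, 240), meth = rep(10, 4),
                       unmeth = rep(10, 4))
  dmws <- scan_windows(s1, s2, dmr_params(), small_chrom_sizes(250L))
  expect_true(all(dmws$start %% 50 == 0))
  expect_true(all(dmws$end - dmws$start == 100))
  expect_true(all(dmws$end <= 250))
  # site 240 only fits window [150, 250)
  expect_true(240 %in% dmws$positions[dmws$start == 150][[1]])
  # identical samples: all p-values 1, all deltas 0
  expect_true(all(dmws$p_value == 1))
  expect_true(all(dmws$delta == 0))
})

test_that("each site lands in every window containing it", {
  sim <- simulate_methylome_pair(simulation_config(
    seed = 21, n_chroms = 1, chrom_length = 20000, n_dmrs = 1))
  params <- dmr_params()
  dmws <- scan_windows(sim$sample1, sim$sample2, params, sim$chrom_sizes)
  shared <- window_sites(sim$sample1, sim$sample2, "chr1", 0, 20000,
                         min_depth = params$min_depth)
  for (k in seq_len(nrow(dmws))) {
    expected <- shared$positions[shared$positions >= dmws$start[k] &
                                   shared$positions < dmws$end[k]]
    expect_equal(dmws$positions[[k]], expected)
  }
  # and no window outside the emitted set contains a shared site
  starts_all <- seq(0, 20000 - 100, by = 50)
  uncovered <- setdiff(starts_all, dmws$start)
  for (st in sample(uncovered, min(20, length(uncovered)))) {
    expect_length(shared$positions[shared$positions >= st &
                                     shared$positions < st + 100], 0)
  }
})

test_that("the three retention gates flip independently at their boundaries", {
  params <- dmr_params()  # alpha 0.01, min_cpgs 5, min_delta 0.10
  keep <- make_dmw(p = 0.005, n = 6, delta = 0.25)
  expect_equal(nrow(filter_dmws(keep, params)), 1L)
  expect_equal(nrow(filter_dmws(make_dmw(p = 0.005, n = 6, delta = 0.05),
                                params)), 0L)   # |delta| below 10%
  expect_equal(nrow(filter_dmws(make_dmw(p = 0.005, n = 4, delta = 0.25),
                                params)), 0L)   # fewer than 5 CpGs
  expect_equal(nrow(filter_dmws(make_dmw(p = 0.02, n = 6, delta = 0.25),
                                params)), 0L)   # p above alpha
  # boundaries: p == alpha excluded, n == min_cpgs and |delta| == min_delta kept
  expect_equal(nrow(filter_dmws(make_dmw(p = 0.01, n = 6, delta = 0.25),
                                params)), 0L)
  expect_equal(nrow(filter_dmws(make_dmw(p = 0.005, n = 5, delta = 0.10),
                                params)), 1L)
  # hypomethylated windows pass on |delta|
  expect_equal(nrow(filter_dmws(make_dmw(p = 0.005, n = 5, delta = -0.3),
                                params)), 1L)
})

test_that("merging unions overlapping or abutting same-direction windows", {
  two <- dplyr::bind_rows(make_dmw(start = 0), make_dmw(start = 50))
  m <- merge_dmws(two)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 150L))
  expect_equal(m$n_windows, 2L)
  expect_equal(m$direction, "hyper")

  gap <- dplyr::bind_rows(make_dmw(start = 0), make_dmw(start = 150))
  expect_equal(nrow(merge_dmws(gap)), 2L)

  split_dir <- dplyr::bind_rows(make_dmw(start = 0, delta = 0.3),
                                make_dmw(start = 50, delta = -0.3))
  m2 <- merge_dmws(split_dir)
  expect_equal(nrow(m2), 2L)
  expect_setequal(m2$direction, c("hyper", "hypo"))

  # abutting windows join; distinct CpGs counted once
  ab <- dplyr::bind_rows(make_dmw(start = 0), make_dmw(start = 100))
  expect_equal(merge_dmws(ab)$n_cpgs, 10L)
  shared_sites <- dplyr::bind_rows(make_dmw(start = 0), make_dmw(start = 50))
  shared_sites$positions[[2]] <- shared_sites$positions[[1]]  # same 5 sites
  expect_equal(merge_dmws(shared_sites)$n_cpgs, 5L)
})

test_that("merge output equals the brute-force same-direction union oracle", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    wins <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_dmw(chrom = sample(c("chr1", "chr2"), 1),
               start = 50L * sample(0:20, 1),
               delta = sample(c(-0.3, 0.3), 1),
               p = runif(1, 1e-5, 0.009))
    }))
    wins <- wins[!duplicated(paste(wins$chrom, wins$start)), ]
    got <- merge_dmws(wins)
    ora <- oracle_merge_intervals(
      data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
                 direction = ifelse(wins$delta >= 0, "hyper", "hypo")))
    got_df <- as.data.frame(got[order(got$chrom, got$start, got$direction),
                                c("chrom", "start", "end", "direction")])
    ora <- ora[order(ora$chrom, ora$start, ora$direction), ]
    rownames(got_df) <- rownames(ora) <- NULL
    expect_equal(got_df, ora, info = sprintf("rep %d", rep))
    # DMR p is the minimum constituent p
    expect_true(all(got$p_value %in% wins$p_value))
    expect_equal(min(got$p_value), min(wins$p_value))
  }
})

test_that("swapping samples flips deltas and directions but not p-values", {
  sim <- simulate_methylome_pair(simulation_config(
    seed = 13, n_chroms = 1, chrom_length = 60000, n_dmrs = 4))
  params <- dmr_params()
  fwd <- call_dmrs(sim$sample1, sim$sample2, params, sim$chrom_sizes)
  rev <- call_dmrs(sim$sample2, sim$sample1, params, sim$chrom_sizes)
  expect_equal(rev$dmws$p_value, fwd$dmws$p_value)
  expect_equal(rev$dmws$delta, -fwd$dmws$delta)
  expect_equal(rev$dmrs$start, fwd$dmrs$start)
  expect_equal(rev$dmrs$direction,
               ifelse(fwd$dmrs$direction == "hyper", "hypo", "hyper"))
})

test_that("window and region counts are monotone in the thresholds", {
  sim <- simulate_methylome_pair(simulation_config(
    seed = 17, n_chroms = 1, chrom_length = 80000, n_dmrs = 6))
  dmws <- scan_windows(sim$sample1, sim$sample2, dmr_params(),
                       sim$chrom_sizes)
  n_at <- function(alpha = 0.01, min_cpgs = 5, min_delta = 0.1) {
    nrow(filter_dmws(dmws, dmr_params(alpha = alpha, min_cpgs = min_cpgs,
                                      min_delta = min_delta)))
  }
  expect_true(n_at(alpha = 0.001) <= n_at(alpha = 0.01))
  expect_true(n_at(alpha = 0.01) <= n_at(alpha = 0.05))
  expect_true(n_at(min_delta = 0.3) <= n_at(min_delta = 0.1))
  expect_true(n_at(min_cpgs = 8) <= n_at(min_cpgs = 5))
})

test_that("call_dmrs reconciles its report with its outputs", {
  sim <- simulate_methylome_pair(simulation_config(
    seed = 19, n_chroms = 2, chrom_length = 60000, n_dmrs = 6))
  scan <- call_dmrs(sim$sample1, sim$sample2, dmr_params(), sim$chrom_sizes)
  expect_equal(scan$report$windows_tested, nrow(scan$dmws))
  expect_equal(scan$report$dmws_significant, sum(scan$dmws$significant))
  expect_equal(scan$report$n_dmrs, nrow(scan$dmrs))
  expect_equal(scan$report$n_hyper + scan$report$n_hypo, scan$report$n_dmrs)
  # glance mirrors the report
  g <- glance(scan)
  expect_equal(g$n_dmrs, scan$report$n_dmrs)
  expect_equal(nrow(tidy(scan)), nrow(scan$dmrs))
})

test_that("disjoint coverage yields zero tested windows and zero DMRs", {
  s1 <- make_methylome(c(100, 200), meth = c(10, 10), unmeth = c(5, 5))
  s2 <- make_methylome(c(5000, 6000), meth = c(10, 10), unmeth = c(5, 5))
  scan <- call_dmrs(s1, s2, dmr_params(), small_chrom_sizes(10000L))
  expect_equal(scan$report$windows_tested, 0L)
  expect_equal(scan$report$n_dmrs, 0L)
})

test_that("sample correlation is Pearson r over shared deep sites", {
  s1 <- make_methylome(c(10, 20, 30, 40), meth = c(0, 10, 0, 10),
                       unmeth = c(10, 0, 10, 0))
  expect_equal(sample_correlation(s1, s1, 10), 1)
  flip <- make_methylome(c(10, 20, 30, 40), meth = c(10, 0, 10, 0),
                         unmeth = c(0, 10, 0, 10))
  expect_equal(sample_correlation(s1, flip, 10), -1)
  one_site <- make_methylome(10, 5, 5)
  expect_error(sample_correlation(one_site, one_site, 1),
               class = "twindmr_undefined_correlation")
  flat <- make_methylome(c(10, 20), c(5, 5), c(5, 5))
  expect_error(sample_correlation(flat, flat, 1),
               class = "twindmr_undefined_correlation")
})

test_that("level histograms follow the right-closed binning convention", {
  all_zero <- make_methylome(c(10, 20, 30), meth = c(0, 0, 0),
                             unmeth = c(5, 5, 5))
  d <- methylation_distribution(all_zero, bins = 10)
  expect_equal(d$count[1], 3L)
  expect_equal(sum(d$count[-1]), 0L)

  toy <- make_methylome(c(10, 20, 30), meth = c(0, 5, 10),
                        unmeth = c(10, 5, 0))
  d2 <- methylation_distribution(toy, bins = 2)
  expect_equal(d2$count, c(2L, 1L))   # levels 0, 0.5 | 1
})
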