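#' Configuration for the synthetic methylome generator
#'
#' The generator emulates the statistical structure of somatic RRBS data:
#' CpGs placed by a two-state (island/background) renewal process, a
#' strongly bimodal baseline level distribution (most CpGs near 0 or 1),
#' negative-binomial read depth, binomial sampling of methylated reads, and
#' planted differential regions of a fixed number of CpGs and a fixed true
#' mean difference.
#'
#' @param seed Integer seed; every generator is a pure function of its
#'   configuration.
#' @param n_chroms,chrom_length Genome shape (equal-length chromosomes).
#' @param cpg_rate Background CpG density (expected CpGs per bp outside
#'   islands).
#' @param island_gap_mean Mean gap between CpGs inside islands (bp, >= 2).
#' @param island_size_mean Mean number of CpGs per island.
#' @param island_prob Probability that a background gap opens an island.
#' @param mix_low_weight,mix_high_weight Weights of the near-0 and near-1
#'   mixture components of the baseline level (the remainder is a
#'   mid-range component).
#' @param beta_shape Shape of the extreme components (`Beta(1, beta_shape)`
#'   near 0, `Beta(beta_shape, 1)` near 1).
#' @param depth_mean,depth_dispersion Negative-binomial depth model
#'   (mean and size); depth 0 leaves a site uncovered.
#' @param n_dmrs Number of planted differential regions.
#' @param dmr_n_cpgs CpGs per planted region.
#' @param dmr_delta True within-region mean difference in `(0, 1]`.
#' @param direction_prob Probability a planted region is hypermethylated in
#'   sample 1.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 400000L,
                              cpg_rate = 0.01, island_gap_mean = 10,
                              island_size_mean = 15, island_prob = 0.02,
                              mix_low_weight = 0.4, mix_high_weight = 0.5,
                              beta_shape = 15, depth_mean = 30,
                              depth_dispersion = 5, n_dmrs = 50L,
                              dmr_n_cpgs = 10L, dmr_delta = 0.4,
                              direction_prob = 0.5) {
  if (dmr_delta <= 0 || dmr_delta > 1) abort("dmr_delta must be in (0, 1]")
  if (dmr_n_cpgs < 1) abort("dmr_n_cpgs must be >= 1")
  if (mix_low_weight + mix_high_weight > 1) {
    abort("mixture weights must sum to <= 1")
  }
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length), cpg_rate = cpg_rate,
              island_gap_mean = island_gap_mean,
              island_size_mean = island_size_mean, island_prob = island_prob,
              mix_low_weight = mix_low_weight,
              mix_high_weight = mix_high_weight, beta_shape = beta_shape,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              n_dmrs = as.integer(n_dmrs), dmr_n_cpgs = as.integer(dmr_n_cpgs),
              dmr_delta = dmr_delta, direction_prob = direction_prob)
  structure(cfg, class = "sim_config")
}

# draw a bimodal baseline level per site
draw_baseline_levels <- function(n, cfg) {
  comp <- sample(1:3, n, replace = TRUE,
                 prob = c(cfg$mix_low_weight, cfg$mix_high_weight,
                          1 - cfg$mix_low_weight - cfg$mix_high_weight))
  lev <- numeric(n)
  lev[comp == 1] <- rbeta(sum(comp == 1), 1, cfg$beta_shape)
  lev[comp == 2] <- rbeta(sum(comp == 2), cfg$beta_shape, 1)
  lev[comp == 3] <- rbeta(sum(comp == 3), 2, 2)
  lev
}

# island/background renewal process of CpG starts over [from, to)
draw_cpg_positions <- function(from, to, cfg) {
  pos <- integer(0)
  p <- from
  bg_gap_mean <- 1 / cfg$cpg_rate
  while (TRUE) {
    if (runif(1) < cfg$island_prob) {
      k <- 1L + rgeom(1, 1 / cfg$island_size_mean)
      gaps <- 2L + rgeom(k, 1 / (cfg$island_gap_mean - 1))
      sites <- p + cumsum(gaps)
      sites <- sites[sites < to]
      pos <- c(pos, sites)
      p <- if (length(sites)) sites[length(sites)] else p
    }
    p <- p + 2L + rgeom(1, 1 / bg_gap_mean)
    if (p >= to) break
    pos <- c(pos, p)
  }
  unique(pos)
}

#' Simulate a discordant methylome pair with planted DMRs
#'
#' Both samples share the same CpG positions and baseline true levels;
#' inside each planted region, sample 1's true level is the baseline
#' shifted by `+dmr_delta` (hyper) or sample 2's by the same amount (hypo),
#' so the true within-region difference is exactly `+/- dmr_delta`.
#' Within planted regions the baseline is drawn uniformly from
#' `[0.05, 1 - dmr_delta - 0.05]` so the shift never clips. Per-site read
#' depth is negative-binomial per sample; methylated counts are binomial in
#' the true level. All sites are plus-strand CG records.
#'
#' @param config [simulation_config()].
#' @return List with `sample1`, `sample2` (methylomes including uncovered
#'   sites), `truth` (list: `regions` tibble with `chrom`, `start`, `end`,
#'   `direction`, `delta`; `sites` tibble of per-site true levels), and
#'   `chrom_sizes`.
#' @export
simulate_methylome_pair <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  # reserve non-overlapping slots for planted regions, spread over chroms
  slot_len <- 2000L
  slots_per_chrom <- (cfg$chrom_length - 2L * slot_len) %/% (2L * slot_len)
  total_slots <- slots_per_chrom * cfg$n_chroms
  if (cfg$n_dmrs > total_slots) {
    abort("genome too small for the requested non-overlapping planted regions",
          class = "twindmr_sim_error")
  }
  slot_tbl <- tibble(
    chrom = rep(chroms, each = slots_per_chrom),
    slot = rep(seq_len(slots_per_chrom), cfg$n_chroms)
  )
  picked <- slot_tbl[sort(sample(nrow(slot_tbl), cfg$n_dmrs)), ]

  region_rows <- list(); site_rows <- list()
  for (ch in chroms) {
    anchors <- sort(slot_len + (picked$slot[picked$chrom == ch] - 1L) *
                      2L * slot_len)
    # planted sites: dmr_n_cpgs island-like CpGs from each anchor
    planted <- purrr::map(anchors, function(a) {
      gaps <- 2L + rgeom(cfg$dmr_n_cpgs, 1 / (cfg$island_gap_mean - 1))
      a + cumsum(gaps)
    })
    planted_spans <- purrr::map(planted, ~ c(.x[1], .x[length(.x)] + 1L))
    # background/island sites everywhere outside the planted spans
    bg <- draw_cpg_positions(0L, cfg$chrom_length, cfg)
    in_planted <- rep(FALSE, length(bg))
    for (sp in planted_spans) {
      in_planted <- in_planted | (bg >= sp[1] - 50L & bg < sp[2] + 50L)
    }
    bg <- bg[!in_planted]
    n_reg <- length(anchors)
    dirs <- ifelse(runif(n_reg) < cfg$direction_prob, "hyper", "hypo")
    base_hi <- max(0, 1 - cfg$dmr_delta - 0.05)
    base_lo <- min(0.05, base_hi)
    reg_base <- runif(n_reg, base_lo, base_hi)
    for (j in seq_len(n_reg)) {
      ps <- planted[[j]]
      base <- rep(reg_base[j], length(ps))
      t1 <- pmin(1, if (dirs[j] == "hyper") base + cfg$dmr_delta else base)
      t2 <- pmin(1, if (dirs[j] == "hyper") base else base + cfg$dmr_delta)
      site_rows[[length(site_rows) + 1]] <-
        tibble(chrom = ch, start = ps, true_s1 = t1, true_s2 = t2)
      region_rows[[length(region_rows) + 1]] <-
        tibble(chrom = ch, start = planted_spans[[j]][1],
               end = planted_spans[[j]][2], direction = dirs[j],
               delta = if (dirs[j] == "hyper") cfg$dmr_delta else -cfg$dmr_delta)
    }
    base_lev <- draw_baseline_levels(length(bg), cfg)
    site_rows[[length(site_rows) + 1]] <-
      tibble(chrom = ch, start = bg, true_s1 = base_lev, true_s2 = base_lev)
  }
  sites <- bind_rows(site_rows) |> arrange(.data$chrom, .data$start)
  regions <- if (length(region_rows)) {
    bind_rows(region_rows) |> arrange(.data$chrom, .data$start)
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           direction = character(), delta = double())
  }

  n <- nrow(sites)
  depth1 <- rnbinom(n, size = cfg$depth_dispersion, mu = cfg$depth_mean)
  depth2 <- rnbinom(n, size = cfg$depth_dispersion, mu = cfg$depth_mean)
  meth1 <- rbinom(n, depth1, sites$true_s1)
  meth2 <- rbinom(n, depth2, sites$true_s2)
  mk <- function(meth, depth, id) {
    methylome(tibble(chrom = sites$chrom, start = sites$start, strand = "+",
                     context = "CG", meth = meth, unmeth = depth - meth,
                     tri = "CGG"),
              sample_id = id)
  }
  list(sample1 = mk(meth1, depth1, "sample1"),
       sample2 = mk(meth2, depth2, "sample2"),
       truth = list(regions = regions, sites = sites),
       chrom_sizes = tibble(chrom = chroms,
                            length = rep(cfg$chrom_length, cfg$n_chroms)))
}

#' Simulate gene models, optionally coupled to planted regions
#'
#' Generates non-overlapping multi-exon transcripts with valid coding
#' structure. When `truth_regions` is supplied, the first
#' `n_promoter_coupled` regions each get a transcript whose TSS lies just
#' downstream of the region (on the plus strand), so the region falls in
#' the 2 kb upstream promoter flank.
#'
#' @param config [simulation_config()] (genome shape and seed).
#' @param n_genes Number of uncoupled genes to place.
#' @param truth_regions Optional truth-region tibble from
#'   [simulate_methylome_pair()].
#' @param n_promoter_coupled Number of truth regions to couple to promoters.
#' @return Gene-model tibble passing [validate_gene_models()].
#' @export
simulate_gene_models <- function(config, n_genes, truth_regions = NULL,
                                 n_promoter_coupled = 0L) {
  cfg <- config
  set.seed(cfg$seed + 101L)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  rows <- list()
  occupied <- tibble(chrom = character(), start = integer(), end = integer())
  overlaps_occupied <- function(ch, s, e) {
    any(occupied$chrom == ch & occupied$start < e & occupied$end > s)
  }
  make_gene <- function(name, ch, tx_start, strand) {
    n_ex <- sample(2:4, 1)
    ex_len <- sample(100:400, n_ex, replace = TRUE)
    in_len <- sample(200:1500, n_ex - 1, replace = TRUE)
    starts <- tx_start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    tx_end <- ends[n_ex]
    if (tx_end >= cfg$chrom_length) return(NULL)
    # coding span strictly inside the first/last exon to leave both UTRs
    cds_start <- starts[1] + sample(20:60, 1)
    cds_end <- ends[n_ex] - sample(20:60, 1)
    tibble(gene_name = name, transcript_id = paste0(name, ".1"), chrom = ch,
           strand = strand, tx_start = tx_start, tx_end = tx_end,
           cds_start = cds_start, cds_end = cds_end,
           exon_starts = list(as.integer(starts)),
           exon_ends = list(as.integer(ends)))
  }
  if (!is.null(truth_regions) && n_promoter_coupled > 0) {
    n_promoter_coupled <- min(n_promoter_coupled, nrow(truth_regions))
    for (i in seq_len(n_promoter_coupled)) {
      reg <- truth_regions[i, ]
      tss <- reg$end + sample(100:1200, 1)   # region inside [tss-2000, tss)
      g <- make_gene(sprintf("PROMG%03d", i), reg$chrom, as.integer(tss), "+")
      if (!is.null(g)) {
        rows[[length(rows) + 1]] <- g
        occupied <- bind_rows(occupied,
                              tibble(chrom = g$chrom, start = g$tx_start - 2000L,
                                     end = g$tx_end + 2000L))
      }
    }
  }
  attempts <- 0L
  while (length(rows) < n_genes + n_promoter_coupled && attempts < n_genes * 50L) {
    attempts <- attempts + 1L
    ch <- sample(chroms, 1)
    s <- sample.int(max(1L, cfg$chrom_length - 12000L), 1)
    strand <- sample(c("+", "-"), 1)
    g <- make_gene(sprintf("GENE%04d", length(rows) + 1L), ch, s, strand)
    if (is.null(g)) next
    if (overlaps_occupied(ch, g$tx_start - 2000L, g$tx_end + 2000L)) next
    rows[[length(rows) + 1]] <- g
    occupied <- bind_rows(occupied, tibble(chrom = ch, start = g$tx_start - 2000L,
                                           end = g$tx_end + 2000L))
  }
  out <- bind_rows(rows)
  if (nrow(out)) validate_gene_models(out)
  out
}

#' Simulate a TF-binding-site track
#'
#' @param config [simulation_config()].
#' @param tf_names Factor names, cycled over sites.
#' @param n_sites Number of intervals (6-20 bp each).
#' @param dmrs Optional interval tibble; with `enrichment > 1` sites land
#'   inside these intervals `enrichment`-fold more often than their genomic
#'   fraction.
#' @param enrichment Fold enrichment inside `dmrs`.
#' @return TFBS tibble (`chrom`, `start`, `end`, `tf_name`, `score`).
#' @export
simulate_tfbs <- function(config, tf_names, n_sites, dmrs = NULL,
                          enrichment = 1) {
  cfg <- config
  set.seed(cfg$seed + 202L)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  tf_name = character(), score = numeric())
  if (n_sites < 1) return(empty)
  genome_bp <- as.numeric(cfg$n_chroms) * cfg$chrom_length
  dmr_bp <- if (is.null(dmrs) || !nrow(dmrs)) 0 else sum(dmrs$end - dmrs$start)
  frac <- dmr_bp / genome_bp
  p_in <- min(1, enrichment * frac / (enrichment * frac + (1 - frac)))
  inside <- runif(n_sites) < p_in & dmr_bp > 0
  widths <- sample(6:20, n_sites, replace = TRUE)
  chrom <- character(n_sites); start <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    if (inside[i]) {
      j <- sample.int(nrow(dmrs), 1)
      chrom[i] <- dmrs$chrom[j]
      lo <- dmrs$start[j]
      hi <- max(lo + 1L, dmrs$end[j] - widths[i])
      start[i] <- sample(lo:hi, 1)
    } else {
      chrom[i] <- sample(chroms, 1)
      start[i] <- sample.int(cfg$chrom_length - widths[i], 1)
    }
  }
  tibble(chrom = chrom, start = as.integer(start),
         end = as.integer(start + widths),
         tf_name = rep_len(tf_names, n_sites),
         score = round(runif(n_sites, 300, 1000))) |>
    arrange(.data$chrom, .data$start)
}

#' Simulate the clinical validation cohort
#'
#' Emulates the validation arm: a small case/control cohort with >= 20
#' sequenced clones per sample over the assayed CpGs. Each affected case
#' draws clone entries Bernoulli(`case_level`); unaffected cases and
#' controls draw Bernoulli(`control_level`). Expression decreases
#' log-linearly in the realized sample mean methylation with lognormal
#' noise.
#'
#' @param config [simulation_config()] (seed source).
#' @param n_cases,n_controls Cohort sizes (study: 15 cases, 5 controls).
#' @param n_cpgs CpGs in the assayed amplicon.
#' @param n_clones Clones sequenced per sample (study: >= 20).
#' @param case_level,control_level Per-CpG methylation probabilities.
#' @param effect_penetrance Probability a case is affected (study: 12/15).
#' @param expr_intercept,expr_slope,expr_sdlog Expression model
#'   `exp(intercept - slope * mean_methylation + Normal(0, sdlog))`.
#' @return List with `clones` (named list of clone tibbles), `cohort`
#'   (tibble: `sample_id`, `group`, `expression`) and `truth` (per-sample
#'   affected flag).
#' @export
simulate_cohort <- function(config, n_cases = 15L, n_controls = 5L,
                            n_cpgs = 10L, n_clones = 20L, case_level = 0.8,
                            control_level = 0.1, effect_penetrance = 0.8,
                            expr_intercept = 1, expr_slope = 3,
                            expr_sdlog = 0.3) {
  cfg <- config
  set.seed(cfg$seed + 303L)
  ids <- c(sprintf("case%02d", seq_len(n_cases)),
           sprintf("ctrl%02d", seq_len(n_controls)))
  groups <- rep(c("case", "control"), c(n_cases, n_controls))
  affected <- ifelse(groups == "case", runif(n_cases + n_controls) <
                       effect_penetrance, FALSE)
  positions <- 101 + 13 * seq_len(n_cpgs)   # arbitrary amplicon coordinates
  clones <- list(); means <- numeric(length(ids))
  for (i in seq_along(ids)) {
    p <- if (affected[i]) case_level else control_level
    mat <- matrix(rbinom(n_clones * n_cpgs, 1L, p), nrow = n_clones)
    tbl <- as_tibble(mat, .name_repair = ~ as.character(positions))
    tbl <- bind_cols(tibble(clone = sprintf("clone%02d", seq_len(n_clones))),
                     tbl)
    clones[[ids[i]]] <- tbl
    means[i] <- mean(mat)
  }
  expression <- exp(expr_intercept - expr_slope * means +
                      rnorm(length(ids), 0, expr_sdlog))
  list(clones = clones,
       cohort = tibble(sample_id = ids, group = groups,
                       expression = expression),
       truth = tibble(sample_id = ids, affected = affected))
}
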