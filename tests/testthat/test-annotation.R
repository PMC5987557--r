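test_that("promoter-proximal DMRs are classified upstream with gene links", {
  # + strand gene with TSS at 10000: upstream flank [8000, 10000)
  gene <- make_gene(tx_start = 10000L, tx_end = 14000L,
                    cds_start = 10200L, cds_end = 13800L,
                    exon_starts = c(10000L, 13000L),
                    exon_ends = c(11000L, 14000L))
  dmr <- tibble::tibble(chrom = "chr1", start = 8900L, end = 9050L,
                        direction = "hyper")
  ann <- classify_dmrs(dmr, gene)
  expect_equal(as.character(ann$category), "upstream")
  expect_equal(nrow(ann$gene_links[[1]]), 1L)
  expect_equal(ann$gene_links[[1]]$gene_name, "G1")
  expect_equal(ann$gene_links[[1]]$tss, 10000L)
  # the linked TSS is within upstream_bp of the DMR (invariant)
  expect_true(ann$gene_links[[1]]$tss - ann$end[1] <= 2000)
})

test_that("DMRs far from any transcript are intergenic", {
  gene <- make_gene(tx_start = 10000L, tx_end = 14000L)
  dmr <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L,
                        direction = "hypo")
  ann <- classify_dmrs(dmr, gene)
  expect_equal(as.character(ann$category), "intergenic")
  expect_equal(nrow(ann$gene_links[[1]]), 0L)
  # empty annotation set behaves the same way
  ann2 <- classify_dmrs(dmr, gene[0, ])
  expect_equal(as.character(ann2$category), "intergenic")
})

test_that("priority resolves multi-feature overlaps promoter-first", {
  # DMR inside gene A's intron and within 2 kb upstream of gene B's TSS
  gene_a <- make_gene(gene = "A", tx = "A.1", tx_start = 1000L,
                      tx_end = 9000L, cds_start = 1200L, cds_end = 8800L,
                      exon_starts = c(1000L, 8000L),
                      exon_ends = c(1500L, 9000L))
  gene_b <- make_gene(gene = "B", tx = "B.1", tx_start = 6000L,
                      tx_end = 16000L, cds_start = 6200L, cds_end = 15800L,
                      exon_starts = c(6000L, 15000L),
                      exon_ends = c(7000L, 16000L))
  models <- dplyr::bind_rows(gene_a, gene_b)
  dmr <- tibble::tibble(chrom = "chr1", start = 4500L, end = 4700L,
                        direction = "hyper")
  ann <- classify_dmrs(dmr, models)
  expect_equal(as.character(ann$category), "upstream")
  expect_setequal(ann$gene_links[[1]]$gene_name, c("A", "B"))
  # the same DMR classified without gene B is intronic
  ann_a <- classify_dmrs(dmr, gene_a)
  expect_equal(as.character(ann_a$category), "intronic")
})

test_that("mirroring a gene to the minus strand mirrors its flanks", {
  plus <- make_gene(strand = "+", tx_start = 10000L, tx_end = 14000L,
                    cds_start = 10200L, cds_end = 13800L,
                    exon_starts = c(10000L, 13000L),
                    exon_ends = c(11000L, 14000L))
  minus <- plus
  minus$strand <- "-"
  before <- tibble::tibble(chrom = "chr1", start = 9000L, end = 9100L,
                           direction = "hyper")
  after <- tibble::tibble(chrom = "chr1", start = 14500L, end = 14600L,
                          direction = "hyper")
  expect_equal(as.character(classify_dmrs(before, plus)$category), "upstream")
  expect_equal(as.character(classify_dmrs(after, plus)$category), "downstream")
  expect_equal(as.character(classify_dmrs(before, minus)$category), "downstream")
  expect_equal(as.character(classify_dmrs(after, minus)$category), "upstream")
  # UTR labels swap too
  utr_left <- tibble::tibble(chrom = "chr1", start = 10050L, end = 10150L,
                             direction = "hyper")
  expect_equal(as.character(classify_dmrs(utr_left, plus)$category), "UTR5")
  expect_equal(as.character(classify_dmrs(utr_left, minus)$category), "UTR3")
})

test_that("classification agrees with an exhaustive feature-overlap oracle", {
  cfg <- simulation_config(seed = 23, n_chroms = 2, chrom_length = 100000)
  models <- simulate_gene_models(cfg, n_genes = 12)
  set.seed(24)
  dmrs <- tibble::tibble(
    chrom = sample(paste0("chr", 1:2), 80, replace = TRUE),
    start = as.integer(sample.int(99000, 80)),
    direction = sample(c("hyper", "hypo"), 80, replace = TRUE)
  )
  dmrs$end <- dmrs$start + as.integer(sample(50:400, 80, replace = TRUE))
  ann <- classify_dmrs(dmrs, models)
  feats <- gene_features(models, 2000, 2000)
  priority <- c("upstream", "UTR5", "exonic", "intronic", "UTR3",
                "downstream", "intergenic")
  hits <- oracle_overlap_pairs(dmrs, feats)
  for (i in seq_len(nrow(dmrs))) {
    ftypes <- feats$feature[hits[hits[, 1] == i, 2]]
    expected <- if (length(ftypes)) priority[priority %in% ftypes][1]
    else "intergenic"
    expect_equal(as.character(ann$category[i]), expected,
                 info = sprintf("dmr %d", i))
  }
})

test_that("category summaries count, normalise and deduplicate correctly", {
  gene <- make_gene(tx_start = 10000L, tx_end = 14000L)
  dmrs <- tibble::tibble(
    chrom = "chr1",
    start = c(8100L, 9500L, 100L, 300L, 500L, 700L, 900L, 1100L, 20000L, 20200L),
    direction = c("hyper", "hyper", rep("hypo", 8))
  )
  dmrs$end <- dmrs$start + 100L
  ann <- classify_dmrs(dmrs, gene)
  s <- summarize_categories(ann)
  hyper <- s$by_category[s$by_category$direction == "hyper", ]
  expect_equal(sum(hyper$prop), 1)
  expect_equal(hyper$n[hyper$category == "upstream"], 2L)
  # two upstream DMRs linking one gene's single TSS
  expect_equal(s$promoter$n_promoter_dmrs, 2L)
  expect_equal(s$promoter$n_tss, 1L)
  expect_equal(s$promoter$n_genes, 1L)
  expect_true(s$promoter$n_genes <= s$promoter$n_tss)

  # three transcripts of one gene sharing a promoter region
  iso <- dplyr::bind_rows(
    make_gene(gene = "M", tx = "M.1", tx_start = 10000L, tx_end = 14000L),
    make_gene(gene = "M", tx = "M.2", tx_start = 10100L, tx_end = 14000L,
              cds_start = 10200L, cds_end = 2800L + 10000L,
              exon_starts = c(10100L, 12000L), exon_ends = c(10500L, 14000L)),
    make_gene(gene = "M", tx = "M.3", tx_start = 10200L, tx_end = 14000L,
              cds_start = 10300L, cds_end = 12800L,
              exon_starts = c(10200L, 13000L), exon_ends = c(10600L, 14000L))
  )
  two_dmrs <- tibble::tibble(chrom = "chr1", start = c(9000L, 9400L),
                             end = c(9200L, 9600L),
                             direction = c("hyper", "hyper"))
  s2 <- summarize_categories(classify_dmrs(two_dmrs, iso))
  expect_equal(s2$promoter$n_promoter_dmrs, 2L)
  expect_equal(s2$promoter$n_tss, 3L)
  expect_equal(s2$promoter$n_genes, 1L)

  # empty input: zero counts, proportions absent
  s0 <- summarize_categories(classify_dmrs(two_dmrs[0, ], iso))
  expect_equal(s0$promoter$n_promoter_dmrs, 0L)
  expect_true(all(s0$by_category$n == 0))
  expect_true(all(is.na(s0$by_category$prop)))
})

test_that("TFBS hits require a shared base pair (half-open semantics)", {
  dmr <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                        direction = "hyper")
  tfbs <- tibble::tibble(chrom = "chr1", start = c(150L, 200L),
                         end = c(160L, 210L),
                         tf_name = c("GATA2", "NKX25"), score = c(800, 900))
  ov <- tfbs_in_dmrs(dmr, tfbs)
  expect_equal(ov$tf_names, "GATA2")          # bookended interval: no hit
  expect_equal(nrow(ov$hits), 1L)
  expect_equal(ov$per_dmr$tf_hits[[1]], "GATA2")
  # empty track
  ov0 <- tfbs_in_dmrs(dmr, tfbs[0, ])
  expect_equal(length(ov0$tf_names), 0L)
})

test_that("interval-tree TFBS overlap equals the quadratic oracle", {
  set.seed(25)
  dmrs <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 120, replace = TRUE),
    start = as.integer(sample.int(50000, 120)))
  dmrs$end <- dmrs$start + as.integer(sample(50:300, 120, replace = TRUE))
  dmrs$direction <- "hyper"
  tfbs <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 150, replace = TRUE),
    start = as.integer(sample.int(50000, 150)))
  tfbs$end <- tfbs$start + as.integer(sample(6:20, 150, replace = TRUE))
  tfbs$tf_name <- paste0("TF", sample(1:30, 150, replace = TRUE))
  tfbs$score <- 500
  got <- tfbs_in_dmrs(dmrs, tfbs)$hits
  ora <- oracle_overlap_pairs(dmrs, tfbs)
  got_pairs <- paste(got$dmr_index,
                     match(paste(got$tf_name, got$tfbs_start),
                           paste(tfbs$tf_name, tfbs$start)))
  ora_pairs <- paste(ora[, 1], ora[, 2])
  expect_setequal(got_pairs, ora_pairs)
})
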