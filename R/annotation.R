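#' Expand gene models into classified genomic features
#'
#' For every transcript, derives the strand-aware upstream and downstream
#' flanks, 5'/3' UTRs, coding exon portions (whole exons for non-coding
#' transcripts) and introns, all as 0-based half-open intervals clipped at
#' zero (and at chromosome ends when `chrom_sizes` is given).
#'
#' @param models Gene-model tibble ([read_gene_models()]).
#' @param upstream_bp,downstream_bp Flank widths in bp from the TSS /
#'   transcript end.
#' @param chrom_sizes Optional tibble (`chrom`, `length`) for upper clipping.
#' @return Tibble with `gene_name`, `transcript_id`, `chrom`, `strand`,
#'   `tss`, `feature`, `start`, `end`. The `tss` is the transcription start:
#'   `tx_start` on `+`, `tx_end` on `-` (half-open boundary coordinate).
#' @export
gene_features <- function(models, upstream_bp = 2000L, downstream_bp = 2000L,
                          chrom_sizes = NULL) {
  lens <- if (is.null(chrom_sizes)) NULL else
    setNames(chrom_sizes$length, chrom_sizes$chrom)
  rows <- purrr::pmap(models, function(gene_name, transcript_id, chrom,
                                       strand, tx_start, tx_end, cds_start,
                                       cds_end, exon_starts, exon_ends, ...) {
    plus <- strand == "+"
    tss <- if (plus) tx_start else tx_end
    feat <- list()
    add <- function(type, s, e) {
      s <- pmax(0L, as.integer(s)); e <- as.integer(e)
      if (!is.null(lens) && chrom %in% names(lens)) e <- pmin(e, lens[[chrom]])
      keep <- e > s
      if (any(keep)) {
        feat[[length(feat) + 1]] <<- tibble(feature = type,
                                            start = s[keep], end = e[keep])
      }
    }
    if (plus) {
      add("upstream", tx_start - upstream_bp, tx_start)
      add("downstream", tx_end, tx_end + downstream_bp)
    } else {
      add("upstream", tx_end, tx_end + upstream_bp)
      add("downstream", tx_start - downstream_bp, tx_start)
    }
    coding <- cds_start < cds_end
    if (coding) {
      add("exonic", pmax(exon_starts, cds_start), pmin(exon_ends, cds_end))
      left_s <- exon_starts; left_e <- pmin(exon_ends, cds_start)
      right_s <- pmax(exon_starts, cds_end); right_e <- exon_ends
      add(if (plus) "UTR5" else "UTR3", left_s, left_e)
      add(if (plus) "UTR3" else "UTR5", right_s, right_e)
    } else {
      add("exonic", exon_starts, exon_ends)
    }
    if (length(exon_starts) > 1) {
      add("intronic", exon_ends[-length(exon_ends)], exon_starts[-1])
    }
    bind_rows(feat) |>
      mutate(gene_name = gene_name, transcript_id = transcript_id,
             chrom = chrom, strand = strand, tss = tss)
  })
  bind_rows(rows) |>
    select("gene_name", "transcript_id", "chrom", "strand", "tss",
           "feature", "start", "end")
}

# the one-category-per-DMR priority, promoter first
CATEGORY_PRIORITY <- c("upstream", "UTR5", "exonic", "intronic", "UTR3",
                       "downstream", "intergenic")

#' Classify DMRs into seven genomic categories
#'
#' Each DMR is assigned exactly one of upstream, UTR5, exonic, intronic,
#' UTR3, downstream, intergenic. All features overlapping the DMR by at
#' least 1 bp are collected; the category is the highest-priority feature
#' type present (priority `upstream > UTR5 > exonic > intronic > UTR3 >
#' downstream > intergenic`), and every transcript contributing any
#' overlapping feature is recorded as a gene link.
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end`, ...).
#' @param models Gene-model tibble.
#' @param upstream_bp,downstream_bp Flank widths (bp); the upstream flank is
#'   the promoter proxy ("within 2 kb upstream of the TSS").
#' @param chrom_sizes Optional, for flank clipping.
#' @param priority Category priority order (highest first).
#' @return The input DMR tibble plus `category` and a `gene_links`
#'   list-column of tibbles (`gene_name`, `transcript_id`, `tss`,
#'   `relation`).
#' @export
classify_dmrs <- function(dmrs, models, upstream_bp = 2000L,
                          downstream_bp = 2000L, chrom_sizes = NULL,
                          priority = CATEGORY_PRIORITY) {
  out <- as_tibble(dmrs)
  empty_links <- tibble(gene_name = character(), transcript_id = character(),
                        tss = integer(), relation = character())
  if (!nrow(out)) {
    out$category <- character()
    out$gene_links <- list()
    return(out)
  }
  feats <- if (nrow(models)) {
    gene_features(models, upstream_bp, downstream_bp, chrom_sizes)
  } else {
    NULL
  }
  cats <- rep("intergenic", nrow(out))
  links <- rep(list(empty_links), nrow(out))
  if (!is.null(feats) && nrow(feats)) {
    hits <- GenomicRanges::findOverlaps(as_granges0(out), as_granges0(feats))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      hit_tbl <- tibble(dmr = qh,
                        feature = feats$feature[sh],
                        gene_name = feats$gene_name[sh],
                        transcript_id = feats$transcript_id[sh],
                        tss = feats$tss[sh])
      by_dmr <- split(hit_tbl, hit_tbl$dmr)
      for (nm in names(by_dmr)) {
        i <- as.integer(nm)
        h <- by_dmr[[nm]]
        present <- priority[priority %in% h$feature]
        cats[i] <- present[1]
        links[[i]] <- h |>
          distinct(.data$gene_name, .data$transcript_id, .data$tss,
                   relation = .data$feature)
      }
    }
  }
  out$category <- factor(cats, levels = CATEGORY_PRIORITY)
  out$gene_links <- links
  out
}

#' Summarise DMR categories and promoter associations
#'
#' @param annotated Output of [classify_dmrs()] with a `direction` column.
#' @return Object of class `dmr_category_summary`: list with `by_category`
#'   (direction x category counts and within-direction proportions) and
#'   `promoter` (distinct upstream DMRs, distinct TSSs linked through
#'   upstream features, distinct gene names).
#' @export
summarize_categories <- function(annotated) {
  by_cat <- annotated |>
    count(.data$direction, category = factor(.data$category,
                                             levels = CATEGORY_PRIORITY),
          .drop = FALSE, name = "n") |>
    group_by(.data$direction) |>
    mutate(prop = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_) |>
    ungroup()
  up <- annotated |> filter(.data$category == "upstream")
  upstream_links <- if (nrow(up)) {
    up |>
      tidyr::unnest("gene_links") |>
      filter(.data$relation == "upstream")
  } else {
    tibble(gene_name = character(), transcript_id = character(),
           tss = integer())
  }
  promoter <- tibble(
    n_promoter_dmrs = nrow(up),
    n_tss = nrow(distinct(upstream_links, .data$transcript_id, .data$tss)),
    n_genes = dplyr::n_distinct(upstream_links$gene_name)
  )
  structure(list(by_category = by_cat, promoter = promoter),
            class = "dmr_category_summary")
}

#' @export
print.dmr_category_summary <- function(x, ...) {
  cat("DMR category summary\n")
  print(tidyr::pivot_wider(x$by_category[, c("direction", "category", "n")],
                           names_from = "category", values_from = "n"))
  cat(sprintf("promoter DMRs: %d (%d TSSs, %d genes)\n",
              x$promoter$n_promoter_dmrs, x$promoter$n_tss,
              x$promoter$n_genes))
  invisible(x)
}

#' Overlap DMRs with TF-binding sites
#'
#' A binding site hits a DMR iff the half-open intervals share at least
#' 1 bp (bookended intervals do not overlap).
#'
#' @param dmrs DMR tibble.
#' @param tfbs TFBS tibble ([read_tfbs_bed()]).
#' @return List of class `tfbs_overlap`: `hits` (one row per DMR x TFBS
#'   overlap with both intervals and the factor name), `tf_names` (sorted
#'   distinct factors hit), and `per_dmr` (the input DMRs with a `tf_hits`
#'   list-column of factor names).
#' @export
tfbs_in_dmrs <- function(dmrs, tfbs) {
  dmrs <- as_tibble(dmrs)
  hits_tbl <- tibble(dmr_index = integer(), chrom = character(),
                     dmr_start = integer(), dmr_end = integer(),
                     tf_name = character(), tfbs_start = integer(),
                     tfbs_end = integer())
  if (nrow(dmrs) && nrow(tfbs)) {
    ov <- GenomicRanges::findOverlaps(as_granges0(dmrs), as_granges0(tfbs))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    hits_tbl <- tibble(dmr_index = qh, chrom = dmrs$chrom[qh],
                       dmr_start = dmrs$start[qh], dmr_end = dmrs$end[qh],
                       tf_name = tfbs$tf_name[sh],
                       tfbs_start = tfbs$start[sh], tfbs_end = tfbs$end[sh])
  }
  per_dmr <- dmrs
  per_dmr$tf_hits <- purrr::map(seq_len(nrow(dmrs)), function(i) {
    sort(unique(hits_tbl$tf_name[hits_tbl$dmr_index == i]))
  })
  structure(list(hits = hits_tbl,
                 tf_names = sort(unique(hits_tbl$tf_name)),
                 per_dmr = per_dmr),
            class = "tfbs_overlap")
}

#' @export
print.tfbs_overlap <- function(x, ...) {
  cat(sprintf("TFBS overlap: %d hits across %d DMRs, %d distinct TFs\n",
              nrow(x$hits), dplyr::n_distinct(x$hits$dmr_index),
              length(x$tf_names)))
  invisible(x)
}

#' Annotate DMRs with categories, gene links and TF hits
#'
#' Convenience wrapper combining [classify_dmrs()] and [tfbs_in_dmrs()].
#'
#' @inheritParams classify_dmrs
#' @param tfbs Optional TFBS tibble.
#' @return Annotated DMR tibble with `category`, `gene_links` and
#'   (when `tfbs` is given) `tf_hits` list-columns.
#' @export
annotate_dmrs <- function(dmrs, models, tfbs = NULL, upstream_bp = 2000L,
                          downstream_bp = 2000L, chrom_sizes = NULL) {
  ann <- classify_dmrs(dmrs, models, upstream_bp, downstream_bp, chrom_sizes)
  if (!is.null(tfbs)) {
    ann$tf_hits <- tfbs_in_dmrs(dmrs, tfbs)$per_dmr$tf_hits
  }
  ann
}
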