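#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> DMR calling -> annotation -> cohort
#' validation as one reproducible run. The configuration is a YAML file or
#' an equivalent nested list with sections:
#'
#' * `seed`: integer used for every stochastic stage.
#' * `simulate`: arguments of [simulation_config()] plus `n_genes`,
#'   `n_promoter_coupled`, `n_tfbs`, `tf_names`, and the [simulate_cohort()]
#'   arguments — or instead
#' * `inputs`: paths `sample1`, `sample2`, `chrom_sizes`, and optionally
#'   `genes` (+ `genes_dialect`), `tfbs`, `clones_dir`, `cohort`.
#' * `dmr`: arguments of [dmr_params()].
#' * `annotate`: `upstream_bp`, `downstream_bp`.
#' * `validate`: `threshold`, `rule`.
#'
#' Outputs written to `outdir`: simulated inputs (when simulating),
#' `dmrs.bed`, `annotated.tsv`, and `report.json`.
#'
#' @param config Path to a YAML config or a list.
#' @param outdir Output directory (created); overrides `config$outdir`.
#' @return The run report, invisibly as class `twindmr_report` (a list),
#'   also written as JSON. All counts in the report equal the corresponding
#'   module outputs.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  outdir <- outdir %||% cfg$outdir %||%
    abort("config must name an `outdir`", class = "twindmr_config_error")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "twindmr_pipeline_error")
    })
  }

  # ---- stage 1: obtain inputs --------------------------------------------
  sim_mode <- !is.null(cfg$simulate)
  if (sim_mode) {
    sim_cfg_args <- cfg$simulate[intersect(names(cfg$simulate),
                                           names(formals(simulation_config)))]
    sim_cfg_args$seed <- seed
    scfg <- do.call(simulation_config, sim_cfg_args)
    sim <- stage("simulate", simulate_methylome_pair(scfg))
    s1 <- sim$sample1; s2 <- sim$sample2
    chrom_sizes <- sim$chrom_sizes
    genes <- stage("simulate", simulate_gene_models(
      scfg, n_genes = cfg$simulate$n_genes %||% 30L,
      truth_regions = sim$truth$regions,
      n_promoter_coupled = cfg$simulate$n_promoter_coupled %||% 5L))
    tfbs <- stage("simulate", simulate_tfbs(
      scfg, tf_names = cfg$simulate$tf_names %||%
        c("GATA2", "NKX25", "ZIC3", "NR2F2", "TBX5", "HNF1", "IRF2", "P300"),
      n_sites = cfg$simulate$n_tfbs %||% 500L,
      dmrs = sim$truth$regions, enrichment = cfg$simulate$tfbs_enrichment %||% 5))
    coh_args <- cfg$simulate[intersect(names(cfg$simulate),
                                       setdiff(names(formals(simulate_cohort)),
                                               "config"))]
    cohort_sim <- stage("simulate", do.call(simulate_cohort,
                                            c(list(config = scfg), coh_args)))
    clone_matrices <- cohort_sim$clones
    cohort <- cohort_sim$cohort
    # persist the simulated inputs
    write_cytosine_report(s1, file.path(outdir, "sample1.CX.gz"))
    write_cytosine_report(s2, file.path(outdir, "sample2.CX.gz"))
    write_chrom_sizes(chrom_sizes, file.path(outdir, "chrom.sizes"))
    write_refflat(genes, file.path(outdir, "genes.refflat"))
    write_tfbs_bed(tfbs, file.path(outdir, "tfbs.bed"))
    readr::write_tsv(sim$truth$regions, file.path(outdir, "truth.bed"),
                     col_names = FALSE)
    clone_dir <- file.path(outdir, "clones")
    dir.create(clone_dir, showWarnings = FALSE)
    purrr::iwalk(clone_matrices,
                 ~ write_clone_matrix(.x, file.path(clone_dir,
                                                    paste0(.y, ".tsv"))))
    write_cohort(cohort, file.path(outdir, "cohort.tsv"))
  } else {
    inp <- cfg$inputs %||%
      abort("config needs a `simulate` or `inputs` section",
            class = "twindmr_config_error")
    for (f in c("sample1", "sample2", "chrom_sizes")) {
      if (is.null(inp[[f]])) {
        abort(paste0("config inputs missing required field: ", f),
              class = "twindmr_config_error")
      }
    }
    min_depth <- cfg$dmr$min_depth %||% 10L
    s1 <- stage("load", read_cytosine_report(inp$sample1, min_depth = 0L))
    s2 <- stage("load", read_cytosine_report(inp$sample2, min_depth = 0L))
    chrom_sizes <- stage("load", read_chrom_sizes(inp$chrom_sizes))
    genes <- if (!is.null(inp$genes)) {
      stage("load", read_gene_models(inp$genes,
                                     inp$genes_dialect %||% "refflat"))
    } else NULL
    tfbs <- if (!is.null(inp$tfbs)) stage("load", read_tfbs_bed(inp$tfbs))
    else NULL
    clone_matrices <- cohort <- NULL
    if (!is.null(inp$clones_dir) && !is.null(inp$cohort)) {
      cohort <- stage("load", read_cohort(inp$cohort))
      clone_matrices <- stage("load", purrr::map(
        setNames(cohort$sample_id, cohort$sample_id),
        ~ read_clone_matrix(file.path(inp$clones_dir, paste0(.x, ".tsv")))))
    }
  }

  # ---- stage 2: DMR calling ----------------------------------------------
  dmr_args <- cfg$dmr %||% list()
  params <- do.call(dmr_params, dmr_args[intersect(names(dmr_args),
                                                   names(formals(dmr_params)))])
  scan <- stage("call_dmrs", call_dmrs(s1, s2, params, chrom_sizes))
  write_dmrs_bed(scan$dmrs, file.path(outdir, "dmrs.bed"))

  # ---- stage 3: annotation -----------------------------------------------
  upstream_bp <- cfg$annotate$upstream_bp %||% 2000L
  downstream_bp <- cfg$annotate$downstream_bp %||% 2000L
  ann <- stage("annotate", classify_dmrs(
    scan$dmrs, genes %||% tibble(), upstream_bp, downstream_bp, chrom_sizes))
  cat_summary <- stage("annotate", summarize_categories(ann))
  tf_overlap <- if (!is.null(tfbs)) {
    stage("annotate", tfbs_in_dmrs(scan$dmrs, tfbs))
  } else NULL
  write_annotated_tsv(ann, tf_overlap, file.path(outdir, "annotated.tsv"))

  # ---- stage 4: cohort validation ----------------------------------------
  validation <- NULL
  if (!is.null(clone_matrices) && !is.null(cohort)) {
    validation <- stage("validate", validate_cohort(
      clone_matrices, cohort,
      threshold = cfg$validate$threshold %||% 0.5,
      rule = cfg$validate$rule %||% "threshold"))
  }

  # ---- report ------------------------------------------------------------
  report <- list(
    version = as.character(utils::packageVersion("twindmr")),
    seed = seed,
    parameters = unclass(params),
    counts = list(
      windows_tested = scan$report$windows_tested,
      dmws_significant = scan$report$dmws_significant,
      n_dmrs = scan$report$n_dmrs,
      n_hyper = scan$report$n_hyper,
      n_hypo = scan$report$n_hypo,
      categories = as.list(setNames(
        tapply(cat_summary$by_category$n, cat_summary$by_category$category,
               sum),
        levels(cat_summary$by_category$category))),
      n_promoter_dmrs = cat_summary$promoter$n_promoter_dmrs,
      n_promoter_tss = cat_summary$promoter$n_tss,
      n_promoter_genes = cat_summary$promoter$n_genes,
      n_tfs = if (is.null(tf_overlap)) NULL else length(tf_overlap$tf_names)
    ),
    validation = if (is.null(validation)) NULL else list(
      table = as.vector(validation$table),
      fisher_p = validation$fisher_p,
      correlation_r = validation$correlation$r,
      correlation_p = validation$correlation$p_value
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  structure(c(report, list(scan = scan, annotated = ann,
                           category_summary = cat_summary,
                           tf_overlap = tf_overlap,
                           validation = validation)),
            class = "twindmr_report")
}

#' @export
print.twindmr_report <- function(x, ...) {
  cat(sprintf("twindmr run (seed %s)\n", x$seed))
  cat(sprintf("  windows tested %d; significant %d; DMRs %d (%d hyper / %d hypo)\n",
              x$counts$windows_tested, x$counts$dmws_significant,
              x$counts$n_dmrs, x$counts$n_hyper, x$counts$n_hypo))
  cat(sprintf("  promoter DMRs %d (%d TSSs, %d genes)",
              x$counts$n_promoter_dmrs, x$counts$n_promoter_tss,
              x$counts$n_promoter_genes))
  if (!is.null(x$counts$n_tfs)) cat(sprintf("; distinct TFs %d", x$counts$n_tfs))
  cat("\n")
  if (!is.null(x$validation)) {
    cat(sprintf("  validation: Fisher p = %.4g, meth-expr r = %.3f\n",
                x$validation$fisher_p, x$validation$correlation_r))
  }
  invisible(x)
}

# flat TSV of annotated DMRs; list columns collapsed with semicolons
write_annotated_tsv <- function(ann, tf_overlap, path) {
  flat <- ann |>
    mutate(gene_links = purrr::map_chr(.data$gene_links, function(g) {
      if (!nrow(g)) return("")
      paste(sprintf("%s|%s|%d|%s", g$gene_name, g$transcript_id, g$tss,
                    g$relation), collapse = ";")
    }))
  if (!is.null(tf_overlap)) {
    flat$tf_hits <- purrr::map_chr(tf_overlap$per_dmr$tf_hits,
                                   paste, collapse = ";")
  }
  flat$positions <- NULL
  readr::write_tsv(flat, path)
  invisible(path)
}
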