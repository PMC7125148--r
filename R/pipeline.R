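.pipeline_defaults <- list(
  # input paths (NULL when simulating)
  peaks = NULL, genes = NULL, loops = NULL, peak_counts = NULL,
  gene_counts = NULL, samples = NULL, motifs = NULL, gene_sets = NULL,
  simulate = FALSE, sim = list(),
  # stage parameters (defaults match the published analysis thresholds)
  window_bp = 5000L, alpha = 0.05, fdr_target = 0.20, min_abs_r = 0.4,
  lfc_class_threshold = 0.5, tf_fdr = 0.001, min_count = 2L,
  min_fraction = 0.10, promoter_window = 2500L, min_set = 3L, max_set = 80L,
  # permutation count must put the attainable BH floor below tf_fdr:
  # min padj ~ (n_tested/n_sig)/(n_permutations + 1)
  crd_rule = "any_pair", n_permutations = 5000L, min_sites = 10L,
  cyclic_loess = FALSE, restrict_to_differential = TRUE,
  covariates = c("batch", "sex", "mutation"),
  seed = 1L)

#' Build a pipeline configuration
#'
#' Defaults encode the analysis thresholds used throughout the package:
#' 5 kb anchor windows, correlation alpha 0.05, TF-link empirical FDR
#' 0.20 with a 0.4 absolute-correlation floor, fold-change classification
#' at 0.5, TF-activity FDR 0.001, expression filter (2 reads, 10% of
#' samples), 2.5 kb promoter window and gene-set size bounds 3-80.
#' Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults (see
#'   `crdgrn:::.pipeline_defaults`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.pipeline_defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.pipeline_defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

# deterministic per-stage seed derived from the root seed
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage) %% 2147483647L
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}

#' Run the full analysis pipeline
#'
#' Executes normalize, differential, CRD calling, enhancer-gene linking,
#' TF activity, TF-peak linking, network assembly and (when gene sets are
#' available) enrichment on either a simulated cohort
#' (`config$simulate = TRUE`) or user-supplied files, writing every
#' intermediate table, a summary and a log into `out_dir`.  Outputs
#' contain no timestamps, so re-running with the same configuration and
#' seed reproduces the run directory byte-identically.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly; the summary is written to
#'   `summary.tsv` and the log to `run_log.txt`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    note("stage: ", name)
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      stop("missing input for ", what, ": ",
           if (is.null(path)) "(not configured)" else path)
    }
    path
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               null = "null")
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  note("crdgrn version: ",
       as.character(utils::packageVersion("crdgrn")))
  note("seed: ", config$seed)
  note("config md5: ", unname(tools::md5sum(cfg_path)))

  ## ---- inputs ------------------------------------------------------------
  data <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      sim_args <- config$sim
      if (is.null(sim_args$seed)) sim_args$seed <- .stage_seed(config$seed, 0L)
      ds <- generate_cohort(do.call(sim_config, sim_args))
      write_dataset(ds, file.path(out_dir, "data"))
      ds
    } else {
      list(peaks = read_intervals(need(config$peaks, "peaks")),
           genes = read_intervals(need(config$genes, "genes")),
           loops = read_loops(need(config$loops, "loops")),
           peak_counts = read_matrix(need(config$peak_counts, "peak counts")),
           gene_counts = read_matrix(need(config$gene_counts, "gene counts")),
           samples = read_sample_table(need(config$samples, "sample table")),
           motifs = utils::read.delim(need(config$motifs, "motif annotation"),
                                      sep = "\t", stringsAsFactors = FALSE,
                                      colClasses = "character"),
           gene_sets = if (is.null(config$gene_sets)) NULL else
             read_gene_sets(need(config$gene_sets, "gene sets")))
    }
  })
  covariates <- intersect(config$covariates, names(data$samples))

  ## ---- normalize ---------------------------------------------------------
  norm <- stage("normalize", {
    pk_sf <- size_factors(data$peak_counts)
    g_sf <- size_factors(data$gene_counts)
    pk <- normalize_log(data$peak_counts, pk_sf,
                        cyclic_loess = isTRUE(config$cyclic_loess))
    ge <- normalize_log(data$gene_counts, g_sf)
    write_matrix(pk, file.path(out_dir, "peak_log2.tsv"))
    write_matrix(ge, file.path(out_dir, "gene_log2.tsv"))
    list(pk = pk, ge = ge)
  })

  expressed <- stage("filter", {
    keep <- filter_expressed(data$gene_counts, config$min_count,
                             config$min_fraction)
    note("expressed genes: ", length(keep), " / ", nrow(data$gene_counts))
    keep
  })
  expr_mat <- norm$ge[expressed, , drop = FALSE]

  ## ---- differential ------------------------------------------------------
  peak_diff <- stage("diff", {
    d <- differential_features(norm$pk, data$samples, covariates)
    .write_tsv(d[, c("feature_id", "mean_signal", "log2fc", "stat", "pvalue",
                     "padj")], file.path(out_dir, "peak_differential.tsv"))
    d
  })
  gene_diff <- stage("diff-genes", {
    d <- differential_features(expr_mat, data$samples, covariates)
    .write_tsv(d[, c("feature_id", "mean_signal", "log2fc", "stat", "pvalue",
                     "padj")], file.path(out_dir, "gene_differential.tsv"))
    d
  })
  labels <- classify_fold_changes(
    stats::setNames(peak_diff$log2fc, peak_diff$feature_id),
    config$lfc_class_threshold)

  ## ---- CRDs --------------------------------------------------------------
  crds <- stage("crd", {
    cc <- call_crds(data$loops, norm$pk, data$peaks, config$window_bp,
                    config$alpha, config$crd_rule)
    .write_tsv(cc[, c("loop_id", "is_crd", "best_peak_a", "best_peak_b", "r",
                      "pvalue", "n_pairs_tested")],
               file.path(out_dir, "crds.tsv"))
    write_loops(data$loops[data$loops$id %in% cc$loop_id[cc$is_crd], ,
                           drop = FALSE], file.path(out_dir, "crds.bedpe"))
    coord <- crd_coordination_fractions(cc[cc$is_crd, , drop = FALSE], labels)
    .write_tsv(coord, file.path(out_dir, "crd_coordination.tsv"))
    cc
  })

  ## ---- enhancer-gene links ----------------------------------------------
  gene_links <- stage("link-genes", {
    gl <- link_enhancers_to_genes(crds, norm$pk, expr_mat, data$genes,
                                  data$peaks, config$alpha,
                                  config$promoter_window)
    .write_tsv(gl, file.path(out_dir, "enhancer_gene_links.tsv"))
    gl
  })

  ## ---- TF activity -------------------------------------------------------
  tf_universe <- sort(unique(data$motifs$tf_id))
  expressed_tfs <- intersect(tf_universe, expressed)
  tf_act <- stage("tf-activity", {
    ta <- tf_activity_significance(peak_diff, data$motifs, expressed_tfs,
                                   config$n_permutations,
                                   seed = .stage_seed(config$seed, 1L),
                                   fdr_threshold = config$tf_fdr,
                                   min_sites = config$min_sites)
    mode <- classify_tf_mode(expr_mat, norm$pk, data$motifs,
                             intersect(expressed_tfs, rownames(expr_mat)))
    ta <- merge(ta, mode[, c("tf_id", "mode")], by = "tf_id", all.x = TRUE)
    ta$mode[is.na(ta$mode)] <- "undetermined"
    ta <- ta[order(ta$tf_id), , drop = FALSE]
    .write_tsv(ta, file.path(out_dir, "tf_activity.tsv"))
    ta
  })

  ## ---- TF-peak links -----------------------------------------------------
  tf_links <- stage("link-tfs", {
    candidate <- sort(unique(unlist(crds$member_peaks[crds$is_crd],
                                    use.names = FALSE)))
    if (length(candidate) == 0L) {
      note("no CRD member peaks; TF linking over all peaks")
      candidate <- data$peaks$id
    }
    tl <- link_tfs_to_peaks(intersect(expressed_tfs, rownames(expr_mat)),
                            expr_mat, norm$pk, data$motifs, candidate,
                            config$fdr_target, config$min_abs_r)
    .write_tsv(tl, file.path(out_dir, "tf_peak_links.tsv"))
    tl
  })

  ## ---- GRN ---------------------------------------------------------------
  grn <- stage("grn", {
    g <- assemble_grn(tf_links, gene_links, tf_act,
                      restrict_to_differential =
                        isTRUE(config$restrict_to_differential),
                      fdr_threshold = config$tf_fdr, peak_diff = peak_diff,
                      lfc_threshold = config$lfc_class_threshold)
    export_grn(g, file.path(out_dir, "grn_edges.tsv"), "tsv")
    export_grn(g, file.path(out_dir, "grn.graphml"), "graphml")
    g
  })
  consistency <- consistency_fraction(grn, tf_act, peak_diff)
  ntf <- nearest_tss_fraction(gene_links, data$genes, data$peaks)

  ## ---- enrichment --------------------------------------------------------
  enr <- stage("enrich", {
    if (is.null(data$gene_sets) || nrow(grn$edges) == 0L) {
      note("enrichment skipped (no gene sets or empty network)")
      NULL
    } else {
      target <- intersect(unique(grn$edges$gene_id), expressed)
      e <- fisher_enrichment(target, data$gene_sets, expressed,
                             config$min_set, config$max_set)
      .write_tsv(e, file.path(out_dir, "enrichment.tsv"))
      e
    }
  })

  ## ---- summary -----------------------------------------------------------
  summary_df <- data.frame(
    metric = c("n_peaks", "n_genes", "n_loops", "n_expressed_genes",
               "n_diff_peaks_fdr05", "n_crds", "n_enh_gene_links",
               "n_diff_tfs", "n_tf_peak_links", "n_grn_tfs",
               "n_grn_targets", "n_grn_edges", "n_grn_tf_peak_gene_triples",
               "consistency_fraction", "nearest_tss_fraction"),
    value = c(nrow(data$peaks), nrow(data$genes), nrow(data$loops),
              length(expressed), sum(peak_diff$padj < 0.05),
              sum(crds$is_crd), nrow(gene_links),
              sum(tf_act$direction != "null"), nrow(tf_links),
              sum(grn$nodes$is_tf), sum(!grn$nodes$is_tf), nrow(grn$edges),
              sum(lengths(grn$edges$via_peaks)),
              round(as.numeric(consistency), 6),
              round(ntf, 6)),
    stringsAsFactors = FALSE)
  .write_tsv(summary_df, file.path(out_dir, "summary.tsv"))
  note("edges: ", nrow(grn$edges))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
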