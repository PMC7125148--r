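#' Configuration for the synthetic multi-omic cohort generator
#'
#' The generator lays non-overlapping loops on one synthetic chromosome,
#' plants a latent co-regulation factor in a fraction of loops (the true
#' CRDs), drives genes from enhancer peaks inside their loop, drives
#' motif-bearing peaks from TF expression latents with activator or
#' repressor sign, adds condition-dependent fold-changes to a fraction of
#' peaks and to the latents of differentially active TFs, and draws
#' negative-binomial counts.  All randomness flows from `seed`; identical
#' configurations give bit-identical outputs.
#'
#' Defaults emulate a two-condition cohort of 10 cases and 7 controls with
#' 200 loops (half of them CRDs), one gene with three enhancers per loop,
#' and 20 TFs of which a quarter are differentially active and a quarter
#' act as repressors.
#'
#' @param n_case,n_control samples per condition.
#' @param n_loops number of loops on the synthetic chromosome.
#' @param frac_crd_loops fraction of loops carrying the shared latent
#'   factor (true CRDs).
#' @param peaks_per_anchor peaks placed inside each loop anchor.
#' @param genes_per_loop genes placed inside each loop.
#' @param enh_per_gene enhancer peaks linked to each gene (chosen among
#'   the loop's interior peaks; links are planted only in CRD loops).
#' @param interior_peaks_per_loop interior (non-anchor) peaks per loop;
#'   must be at least `enh_per_gene`.
#' @param n_bg_peaks background peaks outside any loop.
#' @param n_tfs number of TFs (emitted as extra rows of the gene matrix).
#' @param frac_diff_tfs fraction of TFs with a condition shift in their
#'   expression latent (differentially active).
#' @param frac_repressor_tfs fraction of TFs acting with negative sign on
#'   their target peaks.
#' @param tf_targets_per_tf target peaks per TF (drawn from the interior
#'   peaks of CRD loops; no targets are planted when `tf_effect = 0` or
#'   no CRD loops exist).
#' @param tf_effect log2 signal units added to a target peak per unit of
#'   TF latent.
#' @param tf_activity_shift condition shift (latent units) of
#'   differentially active TFs.
#' @param motif_decoy_rate probability that a non-target peak carries a
#'   TF's motif (null foreground for the empirical FDR).
#' @param frac_diff_peaks fraction of peaks with a planted condition
#'   log2 fold-change.
#' @param diff_peak_lfc magnitude of the planted fold-change (sign random).
#' @param crd_factor_sd standard deviation (log2 units) of the per-loop
#'   latent factor.
#' @param enh_effect log2 expression units a gene gains per unit of a
#'   linked peak's latent component.
#' @param noise_sd,gene_noise_sd residual log2 noise of peaks and genes.
#' @param baseline_log2_range range of per-feature baseline log2 means.
#' @param sex_effect_sd,batch_effect_sd,mutation_effect_sd standard
#'   deviations of per-feature covariate coefficients (log2 units).
#' @param library_factor_sd log-scale spread of per-sample library factors.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param seed integer random seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_case = 10L, n_control = 7L,
                       n_loops = 200L, frac_crd_loops = 0.5,
                       peaks_per_anchor = 2L, genes_per_loop = 1L,
                       enh_per_gene = 3L, interior_peaks_per_loop = 3L,
                       n_bg_peaks = 200L,
                       n_tfs = 20L, frac_diff_tfs = 0.25,
                       frac_repressor_tfs = 0.25,
                       tf_targets_per_tf = 15L, tf_effect = 2.0,
                       tf_activity_shift = 2.0, motif_decoy_rate = 0.03,
                       frac_diff_peaks = 0.1, diff_peak_lfc = 1.0,
                       crd_factor_sd = 1.0, enh_effect = 0.4,
                       noise_sd = 0.25, gene_noise_sd = 0.25,
                       baseline_log2_range = c(5, 8),
                       sex_effect_sd = 0.2, batch_effect_sd = 0.2,
                       mutation_effect_sd = 0.2,
                       library_factor_sd = 0.2,
                       nb_dispersion = 0.05, seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_loops = as.integer(n_loops), frac_crd_loops = frac_crd_loops,
              peaks_per_anchor = as.integer(peaks_per_anchor),
              genes_per_loop = as.integer(genes_per_loop),
              enh_per_gene = as.integer(enh_per_gene),
              interior_peaks_per_loop = as.integer(interior_peaks_per_loop),
              n_bg_peaks = as.integer(n_bg_peaks),
              n_tfs = as.integer(n_tfs), frac_diff_tfs = frac_diff_tfs,
              frac_repressor_tfs = frac_repressor_tfs,
              tf_targets_per_tf = as.integer(tf_targets_per_tf),
              tf_effect = tf_effect, tf_activity_shift = tf_activity_shift,
              motif_decoy_rate = motif_decoy_rate,
              frac_diff_peaks = frac_diff_peaks,
              diff_peak_lfc = diff_peak_lfc,
              crd_factor_sd = crd_factor_sd, enh_effect = enh_effect,
              noise_sd = noise_sd, gene_noise_sd = gene_noise_sd,
              baseline_log2_range = baseline_log2_range,
              sex_effect_sd = sex_effect_sd, batch_effect_sd = batch_effect_sd,
              mutation_effect_sd = mutation_effect_sd,
              library_factor_sd = library_factor_sd,
              nb_dispersion = nb_dispersion, seed = as.integer(seed))
  fr <- c("frac_crd_loops", "frac_diff_tfs", "frac_repressor_tfs",
          "motif_decoy_rate", "frac_diff_peaks")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$n_case < 2L || cfg$n_control < 2L) {
    stop("need >= 2 samples per condition")
  }
  if (cfg$enh_per_gene > cfg$interior_peaks_per_loop) {
    stop("enh_per_gene exceeds interior_peaks_per_loop: ",
         "cannot link more peaks per gene than a loop contains")
  }
  class(cfg) <- "sim_config"
  cfg
}

# ensure a categorical covariate has two levels even at small n
.two_level <- function(x, levels) {
  if (length(unique(x)) < 2L) x[1L] <- setdiff(levels, x[1L])[1L]
  x
}

#' Generate a synthetic multi-omic cohort with planted truth
#'
#' Implements the generative model described in [sim_config()].  The
#' returned list contains every input the analysis pipeline consumes plus
#' a `truth` list naming the planted CRD loops, differential peaks,
#' enhancer-gene links, TF-peak links (with sign) and differential TF
#' directions.
#'
#' @param config a [sim_config()] object.
#' @return List with elements `peaks`, `genes`, `loops`, `peak_counts`,
#'   `gene_counts`, `samples`, `motifs`, `gene_sets`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_case + cfg$n_control
  chrom <- "chrS"

  ## ---- samples and covariates -------------------------------------------
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    condition = c(rep("case", cfg$n_case), rep("control", cfg$n_control)),
    sex = .two_level(sample(c("F", "M"), n, replace = TRUE), c("F", "M")),
    mutation = .two_level(sample(c("none", "mut"), n, replace = TRUE),
                          c("none", "mut")),
    batch = .two_level(sample(c("b1", "b2"), n, replace = TRUE), c("b1", "b2")),
    stringsAsFactors = FALSE)
  is_case <- samples$condition == "case"

  ## ---- geometry: loops, peaks, genes ------------------------------------
  L <- cfg$n_loops
  loop_span <- 100000L; anchor_w <- 2000L; gap <- 20000L
  base <- (seq_len(L) - 1L) * (loop_span + gap)
  loops <- genomic_loops(rep(chrom, L), base, base + anchor_w,
                         base + loop_span - anchor_w, base + loop_span,
                         sprintf("loop_%03d", seq_len(L)))

  peak_w <- 500L
  pk_chrom <- character(0); pk_start <- integer(0)
  pk_loop <- character(0); pk_role <- character(0)
  a_off <- as.integer(round(seq(100L, anchor_w - peak_w - 100L,
                                length.out = cfg$peaks_per_anchor)))
  i_off <- as.integer(round(seq(0.25, 0.75,
                                length.out = cfg$interior_peaks_per_loop) *
                              loop_span))
  for (i in seq_len(L)) {
    st <- c(base[i] + a_off,
            base[i] + loop_span - anchor_w + a_off,
            base[i] + i_off)
    role <- c(rep("anchor1", cfg$peaks_per_anchor),
              rep("anchor2", cfg$peaks_per_anchor),
              rep("interior", cfg$interior_peaks_per_loop))
    pk_start <- c(pk_start, st)
    pk_loop <- c(pk_loop, rep(loops$id[i], length(st)))
    pk_role <- c(pk_role, role)
  }
  if (cfg$n_bg_peaks > 0L) {
    bg_gap <- sample.int(L, cfg$n_bg_peaks, replace = TRUE)
    bg_pos <- base[bg_gap] + loop_span + anchor_w +
      sample.int(gap - 2L * anchor_w - peak_w, cfg$n_bg_peaks, replace = TRUE)
    pk_start <- c(pk_start, sort(as.integer(bg_pos)))
    pk_loop <- c(pk_loop, rep(NA_character_, cfg$n_bg_peaks))
    pk_role <- c(pk_role, rep("background", cfg$n_bg_peaks))
  }
  P <- length(pk_start)
  peaks <- genomic_intervals(rep(chrom, P), pk_start, pk_start + peak_w,
                             sprintf("pk%05d", seq_len(P)))
  peak_loop <- stats::setNames(pk_loop, peaks$id)
  peak_role <- stats::setNames(pk_role, peaks$id)

  G <- L * cfg$genes_per_loop
  g_off <- as.integer(round(seq(0.35, 0.65, length.out = cfg$genes_per_loop) *
                              loop_span))
  gene_start <- as.integer(outer(g_off, base, "+"))
  gene_loop <- rep(loops$id, each = cfg$genes_per_loop)
  tf_ids <- if (cfg$n_tfs > 0L) sprintf("tf%02d", seq_len(cfg$n_tfs)) else character(0)
  tf_start <- max(base) + loop_span + gap + (seq_len(cfg$n_tfs) - 1L) * 5000L
  genes <- genomic_intervals(
    rep(chrom, G + cfg$n_tfs),
    c(gene_start, tf_start), c(gene_start, tf_start) + 1000L,
    c(sprintf("g%04d", seq_len(G)), tf_ids),
    strand = rep("+", G + cfg$n_tfs))
  gene_loop <- stats::setNames(c(gene_loop, rep(NA_character_, cfg$n_tfs)),
                               genes$id)

  ## ---- planted structure -------------------------------------------------
  n_crd <- round(cfg$frac_crd_loops * L)
  crd_loops <- sort(sample(loops$id, n_crd))
  in_crd_loop <- !is.na(peak_loop) & peak_loop %in% crd_loops

  # per-loop latent factor (CRD loops only)
  z <- matrix(0, nrow = L, ncol = n, dimnames = list(loops$id, samples$sample_id))
  if (n_crd > 0L) {
    z[crd_loops, ] <- stats::rnorm(n_crd * n, 0, cfg$crd_factor_sd)
  }

  # TF latents, signs and condition shifts
  x <- matrix(stats::rnorm(cfg$n_tfs * n), nrow = cfg$n_tfs, ncol = n,
              dimnames = if (cfg$n_tfs > 0L)
                list(tf_ids, samples$sample_id) else NULL)
  n_diff_tf <- round(cfg$frac_diff_tfs * cfg$n_tfs)
  diff_tfs <- if (n_diff_tf > 0L) sort(sample(tf_ids, n_diff_tf)) else character(0)
  tf_shift_dir <- stats::setNames(rep(0L, cfg$n_tfs), tf_ids)
  if (length(diff_tfs) > 0L && cfg$tf_activity_shift > 0) {
    tf_shift_dir[diff_tfs] <- sample(c(-1L, 1L), length(diff_tfs), replace = TRUE)
    x[diff_tfs, is_case] <- x[diff_tfs, is_case] +
      tf_shift_dir[diff_tfs] * cfg$tf_activity_shift
  }
  n_rep <- round(cfg$frac_repressor_tfs * cfg$n_tfs)
  rep_tfs <- if (n_rep > 0L) sort(sample(tf_ids, n_rep)) else character(0)
  tf_sign <- stats::setNames(ifelse(tf_ids %in% rep_tfs, -1L, 1L), tf_ids)

  # enhancer-gene links: planted in CRD loops only, among interior peaks
  enh_links <- NULL
  if (n_crd > 0L && cfg$enh_per_gene > 0L) {
    link_rows <- list()
    for (lid in crd_loops) {
      gpool <- names(gene_loop)[!is.na(gene_loop) & gene_loop == lid]
      ppool <- names(peak_loop)[!is.na(peak_loop) & peak_loop == lid &
                                  peak_role == "interior"]
      for (g in gpool) {
        sel <- sort(sample(ppool, cfg$enh_per_gene))
        link_rows[[length(link_rows) + 1L]] <-
          data.frame(gene_id = g, peak_id = sel, crd_loop_id = lid,
                     effect = cfg$enh_effect, stringsAsFactors = FALSE)
      }
    }
    enh_links <- do.call(rbind, link_rows)
  }
  if (is.null(enh_links)) {
    enh_links <- data.frame(gene_id = character(0), peak_id = character(0),
                            crd_loop_id = character(0), effect = numeric(0),
                            stringsAsFactors = FALSE)
  }

  # TF target peaks: interior peaks of CRD loops (so every target is some
  # gene's enhancer); planted only when the TF effect is non-zero
  tf_links <- data.frame(tf_id = character(0), peak_id = character(0),
                         sign = integer(0), stringsAsFactors = FALSE)
  target_pool <- peaks$id[in_crd_loop & peak_role == "interior"]
  if (cfg$tf_effect > 0 && cfg$n_tfs > 0L && length(target_pool) > 0L) {
    # disjoint target sets: each enhancer is driven by at most one TF, so
    # planted regulator-enhancer correlations are not diluted by stacked
    # latent drives
    k <- min(cfg$tf_targets_per_tf,
             max(1L, length(target_pool) %/% cfg$n_tfs))
    shuffled <- sample(target_pool)
    tf_links <- do.call(rbind, lapply(seq_along(tf_ids), function(j) {
      sel <- shuffled[((j - 1L) * k + 1L):(j * k)]
      data.frame(tf_id = tf_ids[j], peak_id = sort(sel),
                 sign = tf_sign[[tf_ids[j]]], stringsAsFactors = FALSE)
    }))
  }

  # motif annotation: true targets plus decoy occurrences elsewhere
  motif_rows <- list()
  for (tf in tf_ids) {
    targets <- tf_links$peak_id[tf_links$tf_id == tf]
    others <- setdiff(peaks$id, targets)
    decoys <- others[stats::runif(length(others)) < cfg$motif_decoy_rate]
    ids <- sort(c(targets, decoys))
    if (length(ids) > 0L) {
      motif_rows[[tf]] <- data.frame(tf_id = tf, peak_id = ids,
                                     stringsAsFactors = FALSE)
    }
  }
  motifs <- if (length(motif_rows) > 0L) do.call(rbind, motif_rows) else
    data.frame(tf_id = character(0), peak_id = character(0),
               stringsAsFactors = FALSE)
  rownames(motifs) <- NULL

  # differential peaks
  n_diff_pk <- round(cfg$frac_diff_peaks * P)
  diff_peaks <- data.frame(peak_id = character(0), log2fc = numeric(0),
                           stringsAsFactors = FALSE)
  if (n_diff_pk > 0L && cfg$diff_peak_lfc > 0) {
    ids <- sort(sample(peaks$id, n_diff_pk))
    diff_peaks <- data.frame(
      peak_id = ids,
      log2fc = sample(c(-1, 1), n_diff_pk, replace = TRUE) * cfg$diff_peak_lfc,
      stringsAsFactors = FALSE)
  }

  ## ---- log2 signal -------------------------------------------------------
  cov_design <- cbind(sex = as.numeric(samples$sex == "M"),
                      batch = as.numeric(samples$batch == "b2"),
                      mutation = as.numeric(samples$mutation == "mut"))
  cov_sds <- c(cfg$sex_effect_sd, cfg$batch_effect_sd, cfg$mutation_effect_sd)
  draw_cov <- function(nfeat) {
    coefs <- matrix(stats::rnorm(nfeat * 3L, 0, rep(cov_sds, each = nfeat)),
                    nrow = nfeat)
    coefs %*% t(cov_design)
  }

  # latent component of each peak: loop factor plus TF drive
  latent <- matrix(0, nrow = P, ncol = n,
                   dimnames = list(peaks$id, samples$sample_id))
  has_loop <- !is.na(peak_loop)
  latent[has_loop, ] <- z[peak_loop[has_loop], , drop = FALSE]
  if (nrow(tf_links) > 0L) {
    for (i in seq_len(nrow(tf_links))) {
      latent[tf_links$peak_id[i], ] <- latent[tf_links$peak_id[i], ] +
        tf_links$sign[i] * cfg$tf_effect * x[tf_links$tf_id[i], ]
    }
  }

  pk_base <- stats::runif(P, cfg$baseline_log2_range[1L],
                          cfg$baseline_log2_range[2L])
  pk_log2 <- pk_base + latent + draw_cov(P) +
    matrix(stats::rnorm(P * n, 0, cfg$noise_sd), nrow = P)
  if (nrow(diff_peaks) > 0L) {
    pk_log2[diff_peaks$peak_id, is_case] <-
      pk_log2[diff_peaks$peak_id, is_case] + diff_peaks$log2fc
  }

  GT <- G + cfg$n_tfs
  g_base <- stats::runif(GT, cfg$baseline_log2_range[1L],
                         cfg$baseline_log2_range[2L])
  g_log2 <- g_base + draw_cov(GT) +
    matrix(stats::rnorm(GT * n, 0, cfg$gene_noise_sd), nrow = GT)
  dimnames(g_log2) <- list(genes$id, samples$sample_id)
  if (nrow(enh_links) > 0L) {
    for (i in seq_len(nrow(enh_links))) {
      g_log2[enh_links$gene_id[i], ] <- g_log2[enh_links$gene_id[i], ] +
        enh_links$effect[i] * latent[enh_links$peak_id[i], ]
    }
  }
  if (cfg$n_tfs > 0L) {
    g_log2[tf_ids, ] <- g_log2[tf_ids, ] + x
  }

  ## ---- counts ------------------------------------------------------------
  lib <- exp(stats::rnorm(n, 0, cfg$library_factor_sd))
  lib <- lib / exp(mean(log(lib)))
  draw_counts <- function(log2sig) {
    mu <- sweep(2^log2sig, 2L, lib, "*")
    m <- matrix(stats::rnbinom(length(mu), size = 1 / cfg$nb_dispersion,
                               mu = mu), nrow = nrow(mu))
    dimnames(m) <- dimnames(log2sig)
    attr(m, "kind") <- "raw_counts"
    m
  }
  peak_counts <- draw_counts(pk_log2)
  gene_counts <- draw_counts(g_log2)

  ## ---- auxiliary gene sets (for the enrichment stage) --------------------
  set_sizes <- pmin(pmax(3L, stats::rpois(10L, 15L)), 80L)
  gene_sets <- stats::setNames(lapply(set_sizes, function(k) {
    sort(sample(genes$id, min(k, nrow(genes))))
  }), sprintf("set_%02d", seq_along(set_sizes)))
  attr(gene_sets, "description") <- stats::setNames(
    rep("synthetic gene set", length(gene_sets)), names(gene_sets))

  tf_activity_truth <- data.frame(
    tf_id = tf_ids,
    direction = ifelse(tf_shift_dir == 0L, "null",
                       ifelse(tf_shift_dir * tf_sign > 0L, "case-up",
                              "control-up")),
    stringsAsFactors = FALSE)

  truth <- list(crd_loops = crd_loops, diff_peaks = diff_peaks,
                enh_gene_links = enh_links, tf_peak_links = tf_links,
                tf_activity = tf_activity_truth)

  list(peaks = peaks, genes = genes, loops = loops,
       peak_counts = peak_counts, gene_counts = gene_counts,
       samples = samples, motifs = motifs, gene_sets = gene_sets,
       peak_loop = peak_loop, peak_role = peak_role, gene_loop = gene_loop,
       truth = truth, config = cfg)
}

#' Write a simulated cohort to disk
#'
#' Emits `peaks.bed`, `genes.bed`, `loops.bedpe`, `peak_counts.tsv`,
#' `gene_counts.tsv`, `samples.tsv`, `motifs.tsv`, `gene_sets.gmt`,
#' `truth/*.tsv` and a `manifest.json` recording the configuration
#' (including the seed).
#'
#' @param dataset result of [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_intervals(dataset$peaks, p("peaks.bed"))
  write_intervals(dataset$genes, p("genes.bed"))
  write_loops(dataset$loops, p("loops.bedpe"))
  write_matrix(dataset$peak_counts, p("peak_counts.tsv"))
  write_matrix(dataset$gene_counts, p("gene_counts.tsv"))
  write_sample_table(dataset$samples, p("samples.tsv"))
  utils::write.table(dataset$motifs, p("motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  write_gene_sets(dataset$gene_sets, p("gene_sets.gmt"))
  writeLines(dataset$truth$crd_loops, file.path(tdir, "crd_loops.txt"))
  for (nm in c("diff_peaks", "enh_gene_links", "tf_peak_links", "tf_activity")) {
    utils::write.table(dataset$truth[[nm]], file.path(tdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  }
  manifest <- unclass(dataset$config)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(p(c("peaks.bed", "genes.bed", "loops.bedpe", "peak_counts.tsv",
                 "gene_counts.tsv", "samples.tsv", "motifs.tsv",
                 "gene_sets.gmt", "manifest.json")),
             file.path(tdir, c("crd_loops.txt", "diff_peaks.tsv",
                               "enh_gene_links.tsv", "tf_peak_links.tsv",
                               "tf_activity.tsv")))
  invisible(files)
}

# canonical string key for a call/truth entry (id vector or data frame)
.recovery_keys <- function(x, key_cols = NULL) {
  if (is.data.frame(x)) {
    if (is.null(key_cols)) key_cols <- names(x)
    do.call(paste, c(unname(x[key_cols]), sep = "\r"))
  } else {
    as.character(x)
  }
}

#' Precision, recall and F1 of calls against planted truth
#'
#' Conventions: precision is 1 when there are no calls, recall is 1 when
#' the truth is empty, and F1 is 0 when precision + recall is 0.
#'
#' @param calls character vector of ids, or a data frame whose `key_cols`
#'   jointly identify a call.
#' @param truth same shape as `calls`.
#' @param key_cols columns identifying an entry when data frames are
#'   given (defaults to the columns shared by both tables).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
evaluate_recovery <- function(calls, truth, key_cols = NULL) {
  if (is.data.frame(calls) && is.data.frame(truth) && is.null(key_cols)) {
    key_cols <- intersect(names(calls), names(truth))
  }
  ck <- unique(.recovery_keys(calls, key_cols))
  tk <- unique(.recovery_keys(truth, key_cols))
  hit <- length(intersect(ck, tk))
  precision <- if (length(ck) == 0L) 1 else hit / length(ck)
  recall <- if (length(tk) == 0L) 1 else hit / length(tk)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}
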