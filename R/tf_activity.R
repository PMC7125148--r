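# motif annotation helpers: a data frame (tf_id, peak_id[, motif_id])
.motif_split <- function(motifs) {
  if (!all(c("tf_id", "peak_id") %in% names(motifs))) {
    stop("motif annotation needs columns 'tf_id' and 'peak_id'")
  }
  split(motifs, motifs$tf_id)
}

#' Differential TF activity scores
#'
#' For each expressed TF, activity is the mean log2 fold-change over its
#' motif-bearing peaks minus the mean log2 fold-change over all peaks
#' (the genome-wide background).  With a `motif_id` column, activity is
#' computed per motif and aggregated by a site-count-weighted mean.  TFs
#' with fewer than `min_sites` motif peaks are reported with status
#' `undetermined` (activity still shown when at least one site exists).
#'
#' @param diff differential table from [differential_features()] for the
#'   peak matrix.
#' @param motifs motif annotation data frame (`tf_id`, `peak_id`, optional
#'   `motif_id`).
#' @param expressed_tfs TF ids that pass the expression filter; others are
#'   excluded.
#' @param min_sites minimum motif-bearing peaks for a determined score
#'   (default 10).
#' @return Data frame with columns `tf_id`, `n_sites`, `activity`,
#'   `status` (`ok`/`undetermined`).
#' @export
tf_activity_scores <- function(diff, motifs, expressed_tfs, min_sites = 10L) {
  lfc <- stats::setNames(diff$log2fc, diff$feature_id)
  genome_mean <- mean(lfc)
  by_tf <- .motif_split(motifs)
  tfs <- intersect(expressed_tfs, names(by_tf))
  missing_tfs <- setdiff(expressed_tfs, names(by_tf))
  if (length(missing_tfs) > 0L) {
    warning("tf_activity_scores: no motif peaks for ",
            paste(missing_tfs, collapse = ", "))
  }
  rows <- lapply(tfs, function(tf) {
    ann <- by_tf[[tf]]
    ann <- ann[ann$peak_id %in% names(lfc), , drop = FALSE]
    sites <- unique(ann$peak_id)
    n_sites <- length(sites)
    if (n_sites == 0L) {
      return(data.frame(tf_id = tf, n_sites = 0L, activity = NA_real_,
                        status = "undetermined", stringsAsFactors = FALSE))
    }
    if ("motif_id" %in% names(ann) && length(unique(ann$motif_id)) > 1L) {
      per <- tapply(seq_len(nrow(ann)), ann$motif_id, function(ix) {
        pk <- unique(ann$peak_id[ix])
        c(mean(lfc[pk]), length(pk))
      })
      means <- vapply(per, `[[`, 0, 1L)
      ns <- vapply(per, `[[`, 0, 2L)
      act <- sum(means * ns) / sum(ns) - genome_mean
    } else {
      act <- mean(lfc[sites]) - genome_mean
    }
    data.frame(tf_id = tf, n_sites = n_sites, activity = act,
               status = if (n_sites >= min_sites) "ok" else "undetermined",
               stringsAsFactors = FALSE)
  })
  if (length(missing_tfs) > 0L) {
    rows <- c(rows, list(
      data.frame(tf_id = missing_tfs, n_sites = 0L, activity = NA_real_,
                 status = "undetermined", stringsAsFactors = FALSE)))
  }
  if (length(rows) == 0L) {
    return(data.frame(tf_id = character(0), n_sites = integer(0),
                      activity = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$tf_id), , drop = FALSE]
}

#' Permutation significance of TF activity
#'
#' For each TF the null distribution of activity is obtained by drawing
#' `n_permutations` random peak sets of the same size (uniformly, without
#' replacement, from all peaks) and recomputing the score.  The p-value
#' uses the add-one estimator
#' `(1 + #\{|null| >= |observed|\}) / (1 + n_permutations)`, so its floor
#' is `1 / (n_permutations + 1)`.  BH-adjusted p-values at or below
#' `fdr_threshold` assign the direction (`case-up` when activity > 0,
#' `control-up` when < 0); everything else is `null`.
#'
#' @inheritParams tf_activity_scores
#' @param n_permutations number of null draws (>= 100; default 1000).
#' @param seed integer seed for the permutation null.
#' @param fdr_threshold BH threshold for calling a direction
#'   (default 0.001).
#' @return The score table with added `pvalue`, `padj`, `direction`.
#' @export
tf_activity_significance <- function(diff, motifs, expressed_tfs,
                                     n_permutations = 1000L, seed = 1L,
                                     fdr_threshold = 0.001,
                                     min_sites = 10L) {
  stopifnot(n_permutations >= 100L)
  scores <- tf_activity_scores(diff, motifs, expressed_tfs, min_sites)
  lfc <- stats::setNames(diff$log2fc, diff$feature_id)
  genome_mean <- mean(lfc)
  P <- length(lfc)
  set.seed(seed)
  pvals <- rep(NA_real_, nrow(scores))
  for (i in seq_len(nrow(scores))) {
    k <- scores$n_sites[i]
    if (k == 0L || is.na(scores$activity[i])) next
    if (k > P) stop("TF ", scores$tf_id[i], " has more sites than peaks")
    null_act <- vapply(seq_len(n_permutations), function(b) {
      mean(lfc[sample.int(P, k)]) - genome_mean
    }, 0)
    pvals[i] <- (1 + sum(abs(null_act) >= abs(scores$activity[i]))) /
      (1 + n_permutations)
  }
  scores$pvalue <- pvals
  scores$padj <- NA_real_
  tested <- !is.na(pvals)
  scores$padj[tested] <- stats::p.adjust(pvals[tested], method = "BH")
  scores$direction <- "null"
  sig <- tested & !is.na(scores$padj) & scores$padj <= fdr_threshold
  scores$direction[sig & scores$activity > 0] <- "case-up"
  scores$direction[sig & scores$activity < 0] <- "control-up"
  scores
}

#' Classify TFs as activators or repressors
#'
#' Correlates each TF's expression with the log2 signal of its
#' motif-bearing peaks across samples.  The TF is an `activator` when the
#' median correlation exceeds `+r_mode`, a `repressor` below `-r_mode`,
#' otherwise `undetermined`.  When the annotation distinguishes motifs
#' and two motifs give decided aggregates of opposite sign, the TF is
#' flagged `mixed-evidence`.
#'
#' @param expr_matrix log2-normalized gene matrix containing TF rows.
#' @param peak_matrix log2-normalized peak matrix.
#' @param motifs motif annotation data frame.
#' @param tfs TF ids to classify (default: all TFs present in both the
#'   annotation and the expression matrix).
#' @param r_mode decision threshold on the median correlation
#'   (default 0.1).
#' @return Data frame with columns `tf_id`, `median_r`, `mode`.
#' @export
classify_tf_mode <- function(expr_matrix, peak_matrix, motifs, tfs = NULL,
                             r_mode = 0.1) {
  common <- intersect(colnames(expr_matrix), colnames(peak_matrix))
  if (length(common) < 3L) stop("need >= 3 shared samples")
  by_tf <- .motif_split(motifs)
  if (is.null(tfs)) tfs <- intersect(names(by_tf), rownames(expr_matrix))
  rows <- lapply(tfs, function(tf) {
    if (!tf %in% rownames(expr_matrix)) {
      stop("TF ", tf, " absent from expression matrix")
    }
    ann <- by_tf[[tf]]
    pk <- intersect(unique(ann$peak_id), rownames(peak_matrix))
    if (length(pk) == 0L) {
      return(data.frame(tf_id = tf, median_r = NA_real_,
                        mode = "undetermined", stringsAsFactors = FALSE))
    }
    e <- expr_matrix[tf, common]
    r <- as.numeric(stats::cor(e, t(peak_matrix[pk, common, drop = FALSE])))
    med <- stats::median(r, na.rm = TRUE)
    mode <- if (is.na(med) || abs(med) <= r_mode) "undetermined"
      else if (med > r_mode) "activator" else "repressor"
    if ("motif_id" %in% names(ann) && length(unique(ann$motif_id)) > 1L) {
      motif_med <- tapply(seq_len(nrow(ann)), ann$motif_id, function(ix) {
        mk <- intersect(unique(ann$peak_id[ix]), rownames(peak_matrix))
        if (length(mk) == 0L) return(NA_real_)
        stats::median(as.numeric(stats::cor(
          e, t(peak_matrix[mk, common, drop = FALSE]))), na.rm = TRUE)
      })
      decided <- motif_med[!is.na(motif_med) & abs(motif_med) > r_mode]
      if (length(decided) >= 2L && min(decided) < 0 && max(decided) > 0) {
        mode <- "mixed-evidence"
      }
    }
    data.frame(tf_id = tf, median_r = med, mode = mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enrichment of a known-TF list among differentially active TFs
#'
#' At each threshold of the grid, the set of differentially active TFs is
#' `padj <= threshold` (for `by = "padj"`) or `|activity| >= threshold`
#' (for `by = "activity"`), and a one-sided Fisher's exact test asks
#' whether known TFs are over-represented in it.
#'
#' @param activity_table table from [tf_activity_significance()].
#' @param known_tfs character vector of known TF ids (ids not tested are
#'   dropped with a warning).
#' @param thresholds numeric grid.
#' @param by `"padj"` or `"activity"`.
#' @return Data frame with columns `threshold`, `n_active`, `n_known_active`,
#'   `odds_ratio`, `pvalue` (odds ratio `NA` when the active set is empty).
#' @export
known_tf_enrichment <- function(activity_table, known_tfs,
                                thresholds = c(0.1, 0.05, 0.01, 0.001),
                                by = c("padj", "activity")) {
  by <- match.arg(by)
  tested <- activity_table[!is.na(activity_table$activity), , drop = FALSE]
  missing_tfs <- setdiff(known_tfs, tested$tf_id)
  if (length(missing_tfs) > 0L) {
    warning("known_tf_enrichment: dropping untested TF(s): ",
            paste(missing_tfs, collapse = ", "))
  }
  known <- tested$tf_id %in% known_tfs
  rows <- lapply(thresholds, function(th) {
    active <- if (by == "padj") !is.na(tested$padj) & tested$padj <= th
      else abs(tested$activity) >= th
    if (!any(active)) {
      return(data.frame(threshold = th, n_active = 0L, n_known_active = 0L,
                        odds_ratio = NA_real_, pvalue = NA_real_,
                        stringsAsFactors = FALSE))
    }
    a <- sum(known & active); b <- sum(known & !active)
    c_ <- sum(!known & active); d <- sum(!known & !active)
    ft <- .fisher_row(a, b, c_, d, "greater")
    data.frame(threshold = th, n_active = sum(active),
               n_known_active = a,
               odds_ratio = ft$odds_ratio, pvalue = ft$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
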