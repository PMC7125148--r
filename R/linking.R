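#' Link enhancers to genes within CRDs
#'
#' For every (gene, peak) pair sharing a CRD — genes assigned by
#' TSS-within-loop-span, peaks being the loop's member peaks — computes
#' the Pearson correlation between log2 expression and log2 peak signal
#' across the shared samples and retains pairs with `r > 0` and
#' `pvalue < alpha`.  Each retained link is annotated with whether the
#' peak lies within `promoter_window` of the gene's TSS and whether the
#' gene is the peak's nearest TSS.
#'
#' @param crds CRD table from [call_crds()].
#' @param peak_matrix log2-normalized peak matrix.
#' @param expr_matrix log2-normalized gene matrix (already filtered for
#'   expression).
#' @param genes gene interval data frame.
#' @param peaks peak interval data frame.
#' @param alpha significance level (default 0.05).
#' @param promoter_window promoter proximity window in bp (default 2500).
#' @param crd_only use only loops called CRD (default `TRUE`; set `FALSE`
#'   to apply the same rule to every loop in `crds`, e.g. for the
#'   non-CRD comparison).
#' @param min_samples minimum shared samples (default 5).
#' @return Data frame with columns `gene_id`, `peak_id`, `crd_loop_id`,
#'   `r`, `pvalue`, `is_promoter_proximal`, `nearest_tss_flag`; the number
#'   of pairs skipped for missing matrix rows is attached as attribute
#'   `n_skipped`.
#' @export
link_enhancers_to_genes <- function(crds, peak_matrix, expr_matrix, genes,
                                    peaks, alpha = 0.05,
                                    promoter_window = 2500L,
                                    crd_only = TRUE, min_samples = 5L) {
  common <- intersect(colnames(peak_matrix), colnames(expr_matrix))
  if (length(common) < min_samples) {
    stop("fewer than ", min_samples, " shared samples between matrices")
  }
  use <- if (crd_only) crds[crds$is_crd, , drop = FALSE] else crds
  tss <- gene_tss(genes)
  nearest <- nearest_tss(peaks, genes)
  n_samp <- length(common)
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(use))) {
    span_genes <- genes$id[genes$chrom == use$chrom[i] &
                             tss[genes$id] >= use$start[i] &
                             tss[genes$id] < use$end[i]]
    g_ok <- intersect(span_genes, rownames(expr_matrix))
    p_ok <- intersect(use$member_peaks[[i]], rownames(peak_matrix))
    n_skipped <- n_skipped +
      (length(span_genes) - length(g_ok)) * length(use$member_peaks[[i]]) +
      length(g_ok) * (length(use$member_peaks[[i]]) - length(p_ok))
    if (length(g_ok) == 0L || length(p_ok) == 0L) next
    pm <- t(peak_matrix[p_ok, common, drop = FALSE])
    for (g in g_ok) {
      r <- as.numeric(stats::cor(expr_matrix[g, common], pm))
      p <- .cor_pvalue(r, n_samp)
      keep <- !is.na(r) & r > 0 & p < alpha
      if (!any(keep)) next
      pk <- p_ok[keep]
      pidx <- match(pk, peaks$id)
      d <- ifelse(tss[g] >= peaks$start[pidx] & tss[g] < peaks$end[pidx], 0L,
                  pmin(abs(tss[g] - peaks$start[pidx]),
                       abs(tss[g] - (peaks$end[pidx] - 1L))))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, peak_id = pk, crd_loop_id = use$loop_id[i],
        r = r[keep], pvalue = p[keep],
        is_promoter_proximal = d <= promoter_window,
        nearest_tss_flag = nearest[pk] == g,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(0), peak_id = character(0),
               crd_loop_id = character(0), r = numeric(0), pvalue = numeric(0),
               is_promoter_proximal = logical(0), nearest_tss_flag = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Null p-value sample from randomized gene-peak pairings
#'
#' Draws pairs of a gene from one CRD and a peak from a different CRD
#' (uniformly) and returns the correlation p-values — a QC null that
#' should be approximately uniform.
#'
#' @inheritParams link_enhancers_to_genes
#' @param n_draws number of random pairs (>= 100).
#' @param seed integer seed.
#' @return Numeric vector of `n_draws` p-values.
#' @export
randomized_link_null <- function(crds, peak_matrix, expr_matrix, genes,
                                 n_draws = 1000L, seed = 1L) {
  stopifnot(n_draws >= 100L)
  use <- crds[crds$is_crd, , drop = FALSE]
  if (nrow(use) < 2L) stop("randomized_link_null needs >= 2 CRDs")
  common <- intersect(colnames(peak_matrix), colnames(expr_matrix))
  tss <- gene_tss(genes)
  gene_of_crd <- lapply(seq_len(nrow(use)), function(i) {
    intersect(genes$id[genes$chrom == use$chrom[i] &
                         tss[genes$id] >= use$start[i] &
                         tss[genes$id] < use$end[i]],
              rownames(expr_matrix))
  })
  peak_of_crd <- lapply(use$member_peaks, intersect, rownames(peak_matrix))
  ok_g <- which(lengths(gene_of_crd) > 0L)
  ok_p <- which(lengths(peak_of_crd) > 0L)
  if (length(ok_g) == 0L || length(ok_p) == 0L) {
    stop("no CRD with usable genes/peaks")
  }
  set.seed(seed)
  n_samp <- length(common)
  p <- numeric(n_draws)
  seen <- character(0)   # distinct pairs, so the QC sample has no ties
  for (b in seq_len(n_draws)) {
    for (attempt in seq_len(1000L)) {
      ig <- ok_g[sample.int(length(ok_g), 1L)]
      ip <- ok_p[sample.int(length(ok_p), 1L)]
      if (ig == ip) next
      g <- gene_of_crd[[ig]][sample.int(length(gene_of_crd[[ig]]), 1L)]
      pk <- peak_of_crd[[ip]][sample.int(length(peak_of_crd[[ip]]), 1L)]
      key <- paste(g, pk)
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    r <- stats::cor(expr_matrix[g, common], peak_matrix[pk, common])
    p[b] <- .cor_pvalue(r, n_samp)
  }
  p
}

#' Distribution of linked enhancers per gene
#'
#' For a set of genes, the fraction with k = 0, 1, 2, ... retained links.
#'
#' @param links link table from [link_enhancers_to_genes()].
#' @param gene_ids universe of genes (genes without links count in k = 0).
#' @return Data frame with columns `k`, `n_genes`, `fraction` (fractions
#'   sum to 1).
#' @export
enhancers_per_gene <- function(links, gene_ids) {
  k <- table(factor(links$gene_id[links$gene_id %in% gene_ids],
                    levels = gene_ids))
  tab <- table(as.integer(k))
  data.frame(k = as.integer(names(tab)), n_genes = as.integer(tab),
             fraction = as.integer(tab) / length(gene_ids),
             stringsAsFactors = FALSE)
}

#' Empirical FDR curve for one TF
#'
#' Correlates the TF's expression with every candidate peak's signal and,
#' over the stepwise grid of observed correlation values, counts the
#' foreground (motif-bearing) and background (motif-free) peaks passing
#' each threshold.  The FDR at a threshold is
#' `n_background / (n_background + n_foreground)` (0 when the denominator
#' is 0).  For `direction = "positive"` a peak passes when `r >= t`; for
#' `"negative"` when `r <= t`.
#'
#' @param tf_id TF identifier (must be a row of `expr_matrix`).
#' @param expr_matrix log2-normalized gene matrix.
#' @param peak_matrix log2-normalized peak matrix.
#' @param motifs motif annotation data frame.
#' @param candidate_peaks peak ids forming the candidate pool.
#' @param direction `"positive"` or `"negative"`.
#' @return Data frame with columns `tf_id`, `direction`, `threshold`,
#'   `n_fg`, `n_bg`, `fdr`, ordered by increasing `|threshold|`.
#' @export
empirical_fdr_curve <- function(tf_id, expr_matrix, peak_matrix, motifs,
                                candidate_peaks,
                                direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  r <- .tf_candidate_cor(tf_id, expr_matrix, peak_matrix, candidate_peaks)
  fg_ids <- motifs$peak_id[motifs$tf_id == tf_id]
  is_fg <- names(r) %in% fg_ids
  if (!any(is_fg) || all(is_fg)) {
    stop("empirical_fdr_curve: TF ", tf_id,
         " needs non-empty foreground and background in the candidate pool")
  }
  ord <- if (direction == "positive") order(r) else order(-r)
  r_s <- r[ord]; fg_s <- is_fg[ord]
  # passing counts at threshold r_s[i]: elements i..N (r >= t or r <= t)
  n_tot <- length(r_s)
  n_fg_pass <- rev(cumsum(rev(fg_s)))
  n_pass <- n_tot - seq_len(n_tot) + 1L
  n_bg_pass <- n_pass - n_fg_pass
  # one row per distinct threshold; the first of tied values carries the
  # full passing count (ties pass their own threshold)
  keep <- !duplicated(r_s)
  thr <- r_s[keep]; nf <- n_fg_pass[keep]; nb <- n_bg_pass[keep]
  fdr <- ifelse(nf + nb == 0L, 0, nb / (nf + nb))
  out <- data.frame(tf_id = tf_id, direction = direction, threshold = thr,
                    n_fg = nf, n_bg = nb, fdr = fdr, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.tf_candidate_cor <- function(tf_id, expr_matrix, peak_matrix,
                              candidate_peaks, min_samples = 5L) {
  if (!tf_id %in% rownames(expr_matrix)) {
    stop("TF ", tf_id, " absent from expression matrix")
  }
  cand <- intersect(candidate_peaks, rownames(peak_matrix))
  common <- intersect(colnames(expr_matrix), colnames(peak_matrix))
  if (length(common) < min_samples) {
    stop("fewer than ", min_samples, " shared samples")
  }
  r <- as.numeric(stats::cor(expr_matrix[tf_id, common],
                             t(peak_matrix[cand, common, drop = FALSE])))
  ok <- !is.na(r)
  stats::setNames(r[ok], cand[ok])
}

#' Link TFs to target peaks at an empirical FDR
#'
#' Per TF and direction, the correlation threshold is the smallest
#' `|r|` on the empirical FDR curve with `fdr <= fdr_target` (no such
#' threshold means no links in that direction); motif-bearing candidate
#' peaks beyond it are retained and links with `|r| < min_abs_r` are then
#' removed.  The link sign is the sign of the correlation.
#'
#' @param tf_ids TF identifiers (TFs absent from `expr_matrix` are
#'   skipped with a message).
#' @inheritParams empirical_fdr_curve
#' @param fdr_target empirical FDR target (default 0.20).
#' @param min_abs_r minimum absolute correlation kept (default 0.4).
#' @return Data frame with columns `tf_id`, `peak_id`, `r`, `sign`,
#'   `direction`, `r_threshold_used`, `fdr_at_threshold`.
#' @export
link_tfs_to_peaks <- function(tf_ids, expr_matrix, peak_matrix, motifs,
                              candidate_peaks, fdr_target = 0.20,
                              min_abs_r = 0.4) {
  rows <- list()
  for (tf in tf_ids) {
    if (!tf %in% rownames(expr_matrix)) {
      message("link_tfs_to_peaks: skipping ", tf,
              " (absent from expression matrix)")
      next
    }
    r <- .tf_candidate_cor(tf, expr_matrix, peak_matrix, candidate_peaks)
    fg_ids <- motifs$peak_id[motifs$tf_id == tf]
    if (!any(names(r) %in% fg_ids) || all(names(r) %in% fg_ids)) next
    for (dir in c("positive", "negative")) {
      curve <- empirical_fdr_curve(tf, expr_matrix, peak_matrix, motifs,
                                   candidate_peaks, dir)
      okc <- curve[curve$fdr <= fdr_target, , drop = FALSE]
      okc <- if (dir == "positive") okc[okc$threshold > 0, , drop = FALSE]
        else okc[okc$threshold < 0, , drop = FALSE]
      if (nrow(okc) == 0L) next
      thr <- okc$threshold[which.min(abs(okc$threshold))]
      fdr_at <- okc$fdr[which.min(abs(okc$threshold))]
      pass <- if (dir == "positive") r >= thr else r <= thr
      keep <- pass & names(r) %in% fg_ids & abs(r) >= min_abs_r
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        tf_id = tf, peak_id = names(r)[keep], r = unname(r[keep]),
        sign = ifelse(r[keep] > 0, 1L, -1L), direction = dir,
        r_threshold_used = thr, fdr_at_threshold = fdr_at,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(tf_id = character(0), peak_id = character(0), r = numeric(0),
               sign = integer(0), direction = character(0),
               r_threshold_used = numeric(0), fdr_at_threshold = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fraction of links pointing at the peak's nearest TSS
#'
#' @param links enhancer-gene link table.
#' @param genes gene interval data frame.
#' @param peaks peak interval data frame.
#' @return Fraction in `[0, 1]`, or `NA` for an empty link set.
#' @export
nearest_tss_fraction <- function(links, genes, peaks) {
  if (nrow(links) == 0L) return(NA_real_)
  nearest <- nearest_tss(peaks, genes)
  mean(nearest[links$peak_id] == links$gene_id, na.rm = TRUE)
}
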