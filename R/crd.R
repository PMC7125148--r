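#' Pearson correlation with a closed-form two-sided p-value
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Exposed so every correlation in the pipeline shares one definition.
#'
#' @param a,b numeric vectors of equal length (n >= 3).
#' @return `list(r, pvalue, n)`.
#' @export
pearson_test <- function(a, b) {
  n <- length(a)
  stopifnot(n == length(b), n >= 3L)
  r <- stats::cor(a, b)
  if (is.na(r)) return(list(r = NA_real_, pvalue = NA_real_, n = n))
  if (abs(r) >= 1) return(list(r = r, pvalue = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, pvalue = 2 * stats::pt(-abs(t), n - 2), n = n)
}

# vectorized two-sided p for a vector of correlations
.cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  rr <- pmin(pmax(r[ok], -1), 1)
  p[ok] <- ifelse(abs(rr) >= 1, 0,
                  2 * stats::pt(-abs(rr) * sqrt((n - 2) / (1 - rr^2)), n - 2))
  p
}

#' Correlations between peaks at opposite anchors of a loop
#'
#' One record per pair of (peak near anchor 1) x (peak near anchor 2),
#' excluding identical peaks, using the normalized log2 signal across
#' samples.  Pairs involving a zero-variance peak are skipped (the count
#' is attached as attribute `n_skipped`).
#'
#' @param loop single-row loop data frame.
#' @param peak_matrix log2-normalized peak matrix.
#' @param peaks peak interval data frame.
#' @param window_bp anchor window (default 5000).
#' @return Data frame with columns `loop_id`, `peak_a`, `peak_b`, `r`,
#'   `pvalue`, `n`.
#' @export
anchor_pair_correlations <- function(loop, peak_matrix, peaks,
                                     window_bp = 5000L) {
  stopifnot(ncol(peak_matrix) >= 3L)
  near <- peaks_in_anchor_windows(loop, peaks, window_bp)
  a <- intersect(near$anchor1, rownames(peak_matrix))
  b <- intersect(near$anchor2, rownames(peak_matrix))
  empty <- data.frame(loop_id = character(0), peak_a = character(0),
                      peak_b = character(0), r = numeric(0),
                      pvalue = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE)
  if (length(a) == 0L || length(b) == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  grid <- expand.grid(peak_a = a, peak_b = b, stringsAsFactors = FALSE)
  grid <- grid[grid$peak_a != grid$peak_b, , drop = FALSE]
  if (nrow(grid) == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  n <- ncol(peak_matrix)
  sda <- apply(peak_matrix[grid$peak_a, , drop = FALSE], 1L, stats::sd)
  sdb <- apply(peak_matrix[grid$peak_b, , drop = FALSE], 1L, stats::sd)
  usable <- sda > 0 & sdb > 0
  n_skipped <- sum(!usable)
  grid <- grid[usable, , drop = FALSE]
  r <- vapply(seq_len(nrow(grid)), function(i) {
    stats::cor(peak_matrix[grid$peak_a[i], ], peak_matrix[grid$peak_b[i], ])
  }, 0)
  out <- data.frame(loop_id = loop$id, peak_a = grid$peak_a,
                    peak_b = grid$peak_b, r = r,
                    pvalue = .cor_pvalue(r, n), n = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Call chromatin regulatory domains
#'
#' A CRD is a loop whose anchor-proximal peaks co-vary positively across
#' samples.  Under the default `any_pair` rule a loop is a CRD when at
#' least one anchor pair has `r > 0` and `pvalue < alpha`; `all_pairs`
#' requires every tested pair to qualify; `max_r` tests only the pair
#' with the largest correlation.  Since the p-value is two-sided and only
#' positive correlations qualify, a single null pair is called at rate
#' `alpha / 2`.
#'
#' @param loops loop data frame.
#' @param peak_matrix log2-normalized peak matrix.
#' @param peaks peak interval data frame.
#' @param window_bp anchor window (default 5000).
#' @param alpha significance level (default 0.05).
#' @param rule decision rule (see above).
#' @return Data frame with columns `loop_id`, `chrom`, `start`, `end`,
#'   `is_crd`, `best_peak_a`, `best_peak_b`, `r`, `pvalue`,
#'   `n_pairs_tested` and a `member_peaks` list column (all peaks within
#'   the loop span `[start1, end2)`).
#' @export
call_crds <- function(loops, peak_matrix, peaks, window_bp = 5000L,
                      alpha = 0.05, rule = c("any_pair", "all_pairs", "max_r")) {
  rule <- match.arg(rule)
  rows <- vector("list", nrow(loops))
  members <- vector("list", nrow(loops))
  for (i in seq_len(nrow(loops))) {
    loop <- loops[i, , drop = FALSE]
    pc <- anchor_pair_correlations(loop, peak_matrix, peaks, window_bp)
    if (rule == "max_r" && nrow(pc) > 0L) {
      pc <- pc[order(-pc$r, pc$peak_a, pc$peak_b), , drop = FALSE][1L, ,
                                                                   drop = FALSE]
    }
    qualifying <- pc[pc$r > 0 & pc$pvalue < alpha, , drop = FALSE]
    is_crd <- switch(rule,
                     any_pair = nrow(qualifying) > 0L,
                     max_r = nrow(qualifying) > 0L,
                     all_pairs = nrow(pc) > 0L && nrow(qualifying) == nrow(pc))
    best <- if (nrow(qualifying) > 0L) {
      qualifying[order(-qualifying$r, qualifying$peak_a, qualifying$peak_b),
                 , drop = FALSE][1L, , drop = FALSE]
    } else NULL
    rows[[i]] <- data.frame(
      loop_id = loop$id, chrom = loop$chrom, start = loop$start1,
      end = loop$end2, is_crd = is_crd,
      best_peak_a = if (is.null(best)) NA_character_ else best$peak_a,
      best_peak_b = if (is.null(best)) NA_character_ else best$peak_b,
      r = if (is.null(best)) NA_real_ else best$r,
      pvalue = if (is.null(best)) NA_real_ else best$pvalue,
      n_pairs_tested = nrow(pc), stringsAsFactors = FALSE)
    members[[i]] <- .overlapping_ids(peaks, loop$chrom, loop$start1, loop$end2)
  }
  out <- do.call(rbind, rows)
  out$member_peaks <- members
  rownames(out) <- NULL
  out
}

#' Summary statistics of a loop set and its CRD calls
#'
#' @param crds CRD table from [call_crds()].
#' @param loops loop data frame.
#' @return One-row data frame: loop and CRD counts, CRD fraction, span
#'   mean/median (bp), and mean peaks per loop.
#' @export
crd_summary <- function(crds, loops) {
  spans <- loop_spans(loops)
  n_loops <- nrow(loops)
  data.frame(
    n_loops = n_loops,
    n_crds = if (n_loops == 0L) 0L else sum(crds$is_crd),
    crd_fraction = if (n_loops == 0L) 0 else sum(crds$is_crd) / n_loops,
    mean_span_bp = if (n_loops == 0L) 0 else mean(spans),
    median_span_bp = if (n_loops == 0L) 0 else stats::median(spans),
    mean_peaks_per_loop = if (n_loops == 0L) 0 else
      mean(lengths(crds$member_peaks)),
    stringsAsFactors = FALSE)
}
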