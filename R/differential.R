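#' Median-of-ratios size factors
#'
#' DESeq-style estimator: the reference profile is the per-feature
#' geometric mean across samples, computed on the features that are
#' positive in every sample; each sample's factor is the median over those
#' features of the count-to-reference ratio.  Factors are rescaled to
#' geometric mean 1 so that relative library sizes, not an arbitrary
#' overall scale, are identified.
#'
#' @param counts raw count matrix (features x samples).
#' @return Positive numeric vector of per-sample factors (geometric mean
#'   1), named by sample.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("size_factors needs >= 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no feature with all-positive counts; add a pseudo-count to the ",
         "matrix or supply factors manually")
  }
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  lf <- apply(lc - ref, 2L, stats::median)
  lf <- lf - mean(lf)                     # geometric mean 1
  stats::setNames(exp(lf), colnames(counts))
}

#' Log2 normalization of a count matrix
#'
#' `log2(count / factor + pseudo_count)`.  With `cyclic_loess = TRUE` a
#' pairwise cyclic loess trend removal (via [limma::normalizeCyclicLoess()])
#' is applied to the log matrix afterwards, removing residual
#' intensity-dependent biases between samples.
#'
#' @param counts raw count matrix.
#' @param factors per-sample size factors; estimated with [size_factors()]
#'   when `NULL`.
#' @param pseudo_count added before the log (default 1).
#' @param cyclic_loess apply cyclic loess refinement (default `FALSE`).
#' @return Log2-normalized matrix with attribute `kind = "log_normalized"`.
#' @export
normalize_log <- function(counts, factors = NULL, pseudo_count = 1,
                          cyclic_loess = FALSE) {
  if (is.null(factors)) factors <- size_factors(counts)
  factors <- factors[colnames(counts)]
  if (anyNA(factors) || any(factors <= 0)) {
    stop("size factors must be positive and cover every sample")
  }
  m <- log2(sweep(counts, 2L, factors, "/") + pseudo_count)
  if (cyclic_loess) {
    m <- limma::normalizeCyclicLoess(m, method = "pairs")
    dimnames(m) <- dimnames(counts)
  }
  attr(m, "kind") <- "log_normalized"
  m
}

#' Filter lowly expressed features
#'
#' Keeps features with at least `min_count` reads in at least
#' `ceiling(min_fraction * n_samples)` samples (the defaults keep genes
#' with two or more reads in at least 10% of samples).
#'
#' @param counts raw count matrix.
#' @param min_count minimum count (default 2).
#' @param min_fraction minimum fraction of samples (default 0.10).
#' @return Character vector of retained feature ids.
#' @export
filter_expressed <- function(counts, min_count = 2, min_fraction = 0.10) {
  stopifnot(min_count >= 0, min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(counts))
  rownames(counts)[rowSums(counts >= min_count) >= need]
}

# design matrix for ~ covariates + condition; condition coded 0/1 with
# "control" as reference so the coefficient is case minus control
.build_design <- function(samples, covariates, condition_col = "condition") {
  cond <- samples[[condition_col]]
  lev <- sort(unique(cond))
  if (length(lev) != 2L || any(table(cond) < 2L)) {
    stop("condition must have exactly two levels with >= 2 samples each")
  }
  ref <- if ("control" %in% lev) "control" else lev[1L]
  fml <- stats::reformulate(c(covariates, condition_col))
  df <- samples
  df[[condition_col]] <- stats::relevel(factor(cond), ref = ref)
  for (cv in covariates) df[[cv]] <- factor(df[[cv]])
  X <- stats::model.matrix(fml, df)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Per-feature differential analysis with covariates
#'
#' Fits an ordinary least-squares linear model of the log2-normalized
#' signal on covariates plus condition for every feature.  The condition
#' coefficient is the log2 fold-change (positive = higher in case), its t
#' statistic is tested two-sided on the residual degrees of freedom, and
#' p-values are Benjamini-Hochberg adjusted across features.  Features
#' with zero residual variance get p-value 1 and are flagged.
#'
#' @param normmat log2-normalized matrix (features x samples).
#' @param samples sample table with a `condition` column (levels `case`
#'   and `control`) and the covariate columns.
#' @param covariates character vector of covariate column names fitted
#'   before condition (may be empty).
#' @return Data frame with columns `feature_id`, `mean_signal`, `log2fc`,
#'   `stat`, `pvalue`, `padj`, `zero_variance`.
#' @export
differential_features <- function(normmat, samples,
                                  covariates = character(0)) {
  stopifnot(identical(colnames(normmat), samples$sample_id) ||
              all(samples$sample_id %in% colnames(normmat)))
  normmat <- normmat[, samples$sample_id, drop = FALSE]
  X <- .build_design(samples, covariates)
  n <- nrow(X); p <- ncol(X)
  df_res <- n - p
  if (df_res < 1L) stop("no residual degrees of freedom")
  Y <- t(normmat)                               # samples x features
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)                 # p x features
  res <- Y - X %*% B
  rss <- colSums(res^2)
  s2 <- rss / df_res
  j <- p                                        # condition is the last column
  se <- sqrt(s2 * XtXi[j, j])
  lfc <- B[j, ]
  zero_var <- s2 < 1e-12
  stat <- ifelse(zero_var, 0, lfc / se)
  pval <- ifelse(zero_var, 1, 2 * stats::pt(-abs(lfc / se), df_res))
  out <- data.frame(feature_id = rownames(normmat),
                    mean_signal = rowMeans(normmat),
                    log2fc = as.numeric(lfc),
                    stat = as.numeric(stat),
                    pvalue = as.numeric(pval),
                    padj = stats::p.adjust(pval, method = "BH"),
                    zero_variance = as.logical(zero_var),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify log2 fold-changes
#'
#' Labels are `case-up` for values strictly above the threshold,
#' `control-up` strictly below its negative, and `unchanged` otherwise
#' (boundary values inclusive).
#'
#' @param log2fc numeric vector of log2 fold-changes.
#' @param threshold positive classification threshold (default 0.5).
#' @return Character vector of labels, preserving names.
#' @export
classify_fold_changes <- function(log2fc, threshold = 0.5) {
  stopifnot(threshold > 0)
  out <- rep("unchanged", length(log2fc))
  out[log2fc > threshold] <- "case-up"
  out[log2fc < -threshold] <- "control-up"
  names(out) <- names(log2fc)
  out
}

#' Per-CRD fold-change coordination fractions
#'
#' For each CRD, the fractions of member peaks classified case-up,
#' control-up and unchanged (summing to 1).  CRDs without labelled member
#' peaks are excluded with a warning.
#'
#' @param crds CRD table from [call_crds()] (uses `loop_id` and the
#'   `member_peaks` list column).
#' @param labels named label vector from [classify_fold_changes()].
#' @return Data frame with columns `loop_id`, `n_peaks`, `frac_case_up`,
#'   `frac_control_up`, `frac_unchanged`.
#' @export
crd_coordination_fractions <- function(crds, labels) {
  rows <- lapply(seq_len(nrow(crds)), function(i) {
    lab <- labels[intersect(crds$member_peaks[[i]], names(labels))]
    if (length(lab) == 0L) return(NULL)
    data.frame(loop_id = crds$loop_id[i], n_peaks = length(lab),
               frac_case_up = mean(lab == "case-up"),
               frac_control_up = mean(lab == "control-up"),
               frac_unchanged = mean(lab == "unchanged"),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0L) {
    warning("crd_coordination_fractions: excluded ", dropped,
            " CRD(s) without labelled member peaks")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(loop_id = character(0), n_peaks = integer(0),
                      frac_case_up = numeric(0), frac_control_up = numeric(0),
                      frac_unchanged = numeric(0), stringsAsFactors = FALSE)
  }
  out
}
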