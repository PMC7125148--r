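# 2x2 Fisher test row: exact p via fisher.test, sample odds ratio
# a*d/(b*c).  Zero handling: a zero table margin carries no information
# (OR 1, p 1); a zero denominator cell with informative margins is
# reported as Inf; other zero cells get the Haldane-Anscombe 0.5
# correction.  Table layout: rows = set membership, cols = target
# membership, `a` = in both.
.fisher_row <- function(a, b, c_, d, alternative) {
  p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                          alternative = alternative)$p.value
  if (a + b == 0L || c_ + d == 0L || a + c_ == 0L || b + d == 0L) {
    or <- 1
  } else if (b == 0L || c_ == 0L) {
    or <- Inf
  } else if (a == 0L || d == 0L) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  list(odds_ratio = or, pvalue = p)
}

#' Fisher's-exact gene-set enrichment
#'
#' For every set, members are intersected with the background, sets whose
#' intersected size falls outside `[min_set, max_set]` are skipped, and a
#' one-sided (enrichment) Fisher's exact test is computed on the 2x2
#' table of target membership by set membership over the background.
#' The odds ratio is the sample odds ratio (with a Haldane-Anscombe 0.5
#' correction when a cell is zero; infinite enrichment is reported as
#' `Inf`).  P-values are BH-adjusted across tested sets.
#'
#' @param target gene ids of interest (must be a subset of `background`).
#' @param sets gene-set collection from [read_gene_sets()] (named list).
#' @param background gene ids forming the statistical universe (e.g. all
#'   expressed genes).
#' @param min_set,max_set set-size bounds after background intersection
#'   (defaults 3 and 80).
#' @return Data frame with columns `set_name`, `n_hits`, `n_target`,
#'   `n_set_in_background`, `n_background`, `odds_ratio`, `pvalue`, `padj`.
#' @export
fisher_enrichment <- function(target, sets, background, min_set = 3L,
                              max_set = 80L) {
  target <- unique(target); background <- unique(background)
  stray <- setdiff(target, background)
  if (length(stray) > 0L) {
    stop("target genes missing from background: ",
         paste(utils::head(stray, 5L), collapse = ", "),
         if (length(stray) > 5L) ", ..." else "")
  }
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(unique(sets[[nm]]), background)
    if (length(members) < min_set || length(members) > max_set) next
    a <- length(intersect(members, target))
    b <- length(members) - a
    c_ <- length(target) - a
    d <- length(background) - length(members) - c_
    ft <- .fisher_row(a, b, c_, d, "greater")
    rows[[length(rows) + 1L]] <- data.frame(
      set_name = nm, n_hits = a, n_target = length(target),
      n_set_in_background = length(members), n_background = length(background),
      odds_ratio = ft$odds_ratio, pvalue = ft$pvalue, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(set_name = character(0), n_hits = integer(0),
               n_target = integer(0), n_set_in_background = integer(0),
               n_background = integer(0), odds_ratio = numeric(0),
               pvalue = numeric(0), stringsAsFactors = FALSE)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

#' Assign peaks their majority-overlap chromatin state
#'
#' Each peak gets the state whose annotation intervals cover the largest
#' number of its bases; ties go to the lexicographically first state
#' label; peaks with no overlap get `"none"`.
#'
#' @param peaks peak interval data frame.
#' @param states interval data frame with an extra `state` column.
#' @return Character vector of state labels named by peak id.
#' @export
assign_peak_states <- function(peaks, states) {
  if (nrow(states) == 0L) stop("empty state annotation")
  labels <- sort(unique(states$state))
  out <- rep("none", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    hit <- states$chrom == peaks$chrom[i] & states$start < peaks$end[i] &
      states$end > peaks$start[i]
    if (!any(hit)) next
    ov <- pmin(states$end[hit], peaks$end[i]) -
      pmax(states$start[hit], peaks$start[i])
    by_state <- tapply(ov, factor(states$state[hit], levels = labels), sum)
    by_state[is.na(by_state)] <- 0
    out[i] <- labels[which.max(by_state)]   # first maximum = lexicographic tie
  }
  stats::setNames(out, peaks$id)
}

#' Chromatin-state enrichment of a peak subset
#'
#' Per state, a two-sided Fisher's exact test of query membership by
#' state membership over all peaks (two-sided so depletion is reportable),
#' BH-adjusted across states.
#'
#' @param query_peaks peak ids of interest (e.g. differential peaks).
#' @param all_peaks peak interval data frame (the universe).
#' @param states state annotation (see [assign_peak_states()]).
#' @return Data frame with columns `state`, `n_hits`, `n_query`,
#'   `n_state`, `n_total`, `odds_ratio`, `pvalue`, `padj`.
#' @export
state_overlap_enrichment <- function(query_peaks, all_peaks, states) {
  lab <- assign_peak_states(all_peaks, states)
  in_query <- all_peaks$id %in% query_peaks
  rows <- lapply(sort(unique(lab)), function(st) {
    in_state <- lab == st
    a <- sum(in_state & in_query)
    b <- sum(in_state & !in_query)
    c_ <- sum(!in_state & in_query)
    d <- sum(!in_state & !in_query)
    ft <- .fisher_row(a, b, c_, d, "two.sided")
    data.frame(state = st, n_hits = a, n_query = sum(in_query),
               n_state = sum(in_state), n_total = length(lab),
               odds_ratio = ft$odds_ratio, pvalue = ft$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}
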