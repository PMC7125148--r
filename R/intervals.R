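#' Genomic intervals and loops
#'
#' Intervals are plain data frames in 0-based, half-open coordinates
#' (`start` inclusive, `end` exclusive), the native convention of BED and
#' BEDPE.  An interval set has columns `chrom`, `start`, `end`, `id` and
#' optionally `strand` (`"+"`, `"-"` or `"."`; genes only).  A loop set has
#' columns `chrom`, `start1`, `end1`, `start2`, `end2`, `id` with
#' `end1 <= start2` (ordered, non-overlapping anchors on one chromosome).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param id character vector of unique feature identifiers; generated as
#'   `"chrom:start-end"` when `NULL`.
#' @param strand optional strand vector (`"+"`, `"-"`, `"."`).
#' @return A data frame of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL, strand = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end)) {
    stop("interval coordinates must be integers")
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad) > 0L) {
    stop("invalid interval (need 0 <= start < end) at record ", bad[1L])
  }
  if (is.null(id)) {
    id <- sprintf("%s:%d-%d", chrom, start, end)
  }
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate interval id: ", id[anyDuplicated(id)])
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    id = id, stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", "."))) {
      stop("strand must be one of '+', '-', '.'")
    }
    out$strand <- strand
  }
  rownames(out) <- NULL
  out
}

#' Construct a loop set from anchor coordinates
#'
#' Anchors are stored left-to-right; records whose anchors overlap after
#' ordering are invalid.
#'
#' @param chrom chromosome name per loop.
#' @param start1,end1 first (left) anchor coordinates.
#' @param start2,end2 second (right) anchor coordinates.
#' @param id unique loop identifiers; `"loop_<i>"` when `NULL`.
#' @return A data frame of loops.
#' @export
genomic_loops <- function(chrom, start1, end1, start2, end2, id = NULL) {
  start1 <- as.integer(start1); end1 <- as.integer(end1)
  start2 <- as.integer(start2); end2 <- as.integer(end2)
  if (is.null(id)) id <- sprintf("loop_%d", seq_along(chrom))
  swap <- start1 > start2
  if (any(swap)) {
    tmp_s <- start1[swap]; tmp_e <- end1[swap]
    start1[swap] <- start2[swap]; end1[swap] <- end2[swap]
    start2[swap] <- tmp_s; end2[swap] <- tmp_e
  }
  bad <- which(start1 < 0L | start1 >= end1 | start2 >= end2 | end1 > start2)
  if (length(bad) > 0L) {
    stop("invalid loop (anchors must be ordered and non-overlapping) at record ",
         bad[1L])
  }
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate loop id: ", id[anyDuplicated(id)])
  data.frame(chrom = as.character(chrom), start1 = start1, end1 = end1,
             start2 = start2, end2 = end2, id = id, stringsAsFactors = FALSE)
}

#' Loop spans in base pairs
#'
#' Span is `end2 - start1` (outer extent of the anchor pair).
#'
#' @param loops a loop data frame.
#' @return Integer vector of spans, named by loop id.
#' @export
loop_spans <- function(loops) {
  stats::setNames(loops$end2 - loops$start1, loops$id)
}

# which peaks overlap the half-open window [wstart, wend) on `chrom`
.overlapping_ids <- function(peaks, chrom, wstart, wend) {
  hit <- peaks$chrom == chrom & peaks$start < wend & peaks$end > wstart
  peaks$id[hit]
}

#' Peaks near the two anchors of a loop
#'
#' A peak is "near" an anchor when it overlaps the anchor extended by
#' `window_bp` on both sides, i.e. the half-open window
#' `[anchor.start - window_bp, anchor.end + window_bp)`.  The default 5 kb
#' window matches the anchor neighbourhood used for CRD detection.  A peak
#' may appear in both lists when the windows overlap.
#'
#' @param loop a single-row loop data frame.
#' @param peaks an interval data frame of peaks.
#' @param window_bp non-negative window extension in bp (default 5000).
#' @return `list(anchor1 = <peak ids>, anchor2 = <peak ids>)`.
#' @export
peaks_in_anchor_windows <- function(loop, peaks, window_bp = 5000L) {
  stopifnot(nrow(loop) == 1L, window_bp >= 0L)
  list(
    anchor1 = .overlapping_ids(peaks, loop$chrom,
                               loop$start1 - window_bp, loop$end1 + window_bp),
    anchor2 = .overlapping_ids(peaks, loop$chrom,
                               loop$start2 - window_bp, loop$end2 + window_bp)
  )
}

#' Transcription start sites of a gene set
#'
#' TSS is `start` for `"+"` or `"."` strand and `end - 1` for `"-"` strand
#' (the last covered base, in 0-based coordinates).
#'
#' @param genes gene interval data frame (optional `strand` column).
#' @return Integer vector of TSS positions named by gene id.
#' @export
gene_tss <- function(genes) {
  strand <- if ("strand" %in% names(genes)) genes$strand else rep(".", nrow(genes))
  tss <- ifelse(strand == "-", genes$end - 1L, genes$start)
  stats::setNames(as.integer(tss), genes$id)
}

#' Nearest TSS for each peak
#'
#' Distance is measured from the peak midpoint `(start + end) / 2` to each
#' TSS on the same chromosome; ties are broken by lexicographic gene id so
#' the assignment is deterministic.  Peaks on a chromosome without genes
#' get `NA`.
#'
#' @param peaks peak interval data frame.
#' @param genes gene interval data frame.
#' @return Character vector of gene ids, named by peak id (`NA` when no
#'   gene shares the peak's chromosome).
#' @export
nearest_tss <- function(peaks, genes) {
  tss <- gene_tss(genes)
  out <- rep(NA_character_, nrow(peaks))
  mid <- (peaks$start + peaks$end) / 2
  for (chr in unique(peaks$chrom)) {
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0L) next
    # lexicographic order so the first minimum wins ties
    gi <- gi[order(genes$id[gi])]
    gt <- tss[gi]
    pi <- which(peaks$chrom == chr)
    d <- abs(outer(mid[pi], gt, "-"))
    out[pi] <- genes$id[gi][apply(d, 1L, which.min)]
  }
  stats::setNames(out, peaks$id)
}
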