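#' Assemble a TF-to-gene regulatory network
#'
#' Composes TF-to-peak and enhancer-to-gene links through shared peaks:
#' an edge (TF, gene) exists iff at least one peak carries both link
#' types; `via_peaks` collects all such peaks.  The edge sign is the
#' majority sign of the TF-to-peak correlations over the via peaks (ties
#' give 0, "mixed").  With `restrict_to_differential = TRUE` only TFs
#' with `padj <= fdr_threshold` in the activity table are kept.
#'
#' @param tf_links TF-peak link table from [link_tfs_to_peaks()].
#' @param gene_links enhancer-gene link table from
#'   [link_enhancers_to_genes()].
#' @param tf_activity activity table from [tf_activity_significance()]
#'   (optional; required for restriction and edge directions).
#' @param restrict_to_differential keep only differentially active TFs.
#' @param fdr_threshold activity padj threshold used for restriction
#'   (default 0.001).
#' @param peak_diff optional differential table for the peak matrix; used
#'   to annotate each edge's `target_direction` (majority
#'   [classify_fold_changes()] label over via peaks).
#' @param lfc_threshold fold-change classification threshold
#'   (default 0.5).
#' @return A `grn` object: list with `edges` (data frame with a
#'   `via_peaks` list column), `nodes` and `params`.
#' @export
assemble_grn <- function(tf_links, gene_links, tf_activity = NULL,
                         restrict_to_differential = FALSE,
                         fdr_threshold = 0.001, peak_diff = NULL,
                         lfc_threshold = 0.5) {
  tfl <- tf_links
  if (restrict_to_differential) {
    if (is.null(tf_activity)) {
      stop("restrict_to_differential requires a TF activity table")
    }
    keep_tfs <- tf_activity$tf_id[!is.na(tf_activity$padj) &
                                    tf_activity$padj <= fdr_threshold]
    tfl <- tfl[tfl$tf_id %in% keep_tfs, , drop = FALSE]
  }
  merged <- merge(tfl[, c("tf_id", "peak_id", "sign")],
                  gene_links[, c("gene_id", "peak_id")], by = "peak_id")
  edges <- data.frame(tf_id = character(0), gene_id = character(0),
                      edge_sign = integer(0), tf_direction = character(0),
                      target_direction = character(0),
                      stringsAsFactors = FALSE)
  edges$via_peaks <- list()
  if (nrow(merged) > 0L) {
    key <- paste(merged$tf_id, merged$gene_id, sep = "\r")
    sp <- split(seq_len(nrow(merged)), key)
    tf_dir <- if (!is.null(tf_activity)) {
      stats::setNames(tf_activity$direction, tf_activity$tf_id)
    } else NULL
    peak_lab <- if (!is.null(peak_diff)) {
      stats::setNames(classify_fold_changes(peak_diff$log2fc, lfc_threshold),
                      peak_diff$feature_id)
    } else NULL
    rows <- lapply(sp, function(ix) {
      via <- sort(unique(merged$peak_id[ix]))
      s <- merged$sign[ix][!duplicated(merged$peak_id[ix])]
      maj <- sum(s > 0) - sum(s < 0)
      tgt <- NA_character_
      if (!is.null(peak_lab)) {
        lab <- peak_lab[intersect(via, names(peak_lab))]
        if (length(lab) > 0L) {
          tt <- sort(table(lab), decreasing = TRUE)
          tgt <- names(tt)[1L]
        }
      }
      list(tf_id = merged$tf_id[ix[1L]], gene_id = merged$gene_id[ix[1L]],
           via_peaks = via,
           edge_sign = if (maj > 0L) 1L else if (maj < 0L) -1L else 0L,
           tf_direction = if (is.null(tf_dir)) NA_character_ else
             unname(tf_dir[merged$tf_id[ix[1L]]]),
           target_direction = tgt)
    })
    edges <- data.frame(
      tf_id = vapply(rows, `[[`, "", "tf_id"),
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      edge_sign = vapply(rows, `[[`, 0L, "edge_sign"),
      tf_direction = vapply(rows, `[[`, "", "tf_direction"),
      target_direction = vapply(rows, `[[`, "", "target_direction"),
      stringsAsFactors = FALSE)
    edges$via_peaks <- unname(lapply(rows, `[[`, "via_peaks"))
    edges <- edges[order(edges$tf_id, edges$gene_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- data.frame(
    id = c(unique(edges$tf_id), setdiff(unique(edges$gene_id),
                                        unique(edges$tf_id))),
    stringsAsFactors = FALSE)
  nodes$is_tf <- nodes$id %in% edges$tf_id
  structure(list(edges = edges, nodes = nodes,
                 params = list(restrict_to_differential = restrict_to_differential,
                               fdr_threshold = fdr_threshold)),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("GRN:", sum(x$nodes$is_tf), "TFs,", sum(!x$nodes$is_tf),
      "target-only genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Fraction of direction-consistent network edges
#'
#' An edge is consistent when, for the majority of its via peaks,
#' `sign(TF activity) * edge_sign == sign(peak log2fc)` — i.e. the TF's
#' activity change, propagated through the sign of its binding
#' correlation, matches the direction of the chromatin change at the
#' target peak.  Edges with mixed sign (`edge_sign == 0`) or missing
#' activity/fold-change information are excluded from the denominator.
#'
#' @param grn a `grn` object.
#' @param tf_activity activity table (uses `tf_id`, `activity`).
#' @param peak_diff differential table for the peak matrix.
#' @return Fraction in `[0, 1]` (`NA` if no edge is evaluable), with the
#'   number of evaluated edges as attribute `n_evaluated`.
#' @export
consistency_fraction <- function(grn, tf_activity, peak_diff) {
  act <- stats::setNames(tf_activity$activity, tf_activity$tf_id)
  lfc <- stats::setNames(peak_diff$log2fc, peak_diff$feature_id)
  n_eval <- 0L; n_cons <- 0L
  for (i in seq_len(nrow(grn$edges))) {
    e <- grn$edges[i, ]
    a <- act[e$tf_id]
    if (is.na(a) || a == 0 || e$edge_sign == 0L) next
    via <- intersect(e$via_peaks[[1L]], names(lfc))
    via <- via[lfc[via] != 0]
    if (length(via) == 0L) next
    ok <- sign(a) * e$edge_sign == sign(lfc[via])
    n_eval <- n_eval + 1L
    if (mean(ok) > 0.5) n_cons <- n_cons + 1L
  }
  out <- if (n_eval == 0L) NA_real_ else n_cons / n_eval
  attr(out, "n_evaluated") <- n_eval
  out
}

#' Degree rankings of a network
#'
#' @param grn a `grn` object.
#' @param top_k optional cut after ranking.
#' @return List with `tfs` (tf_id, out_degree) and `targets` (gene_id,
#'   in_degree), each sorted by decreasing degree with lexicographic ties.
#' @export
degree_rankings <- function(grn, top_k = NULL) {
  e <- grn$edges
  if (nrow(e) == 0L) {
    return(list(tfs = data.frame(tf_id = character(0),
                                 out_degree = integer(0)),
                targets = data.frame(gene_id = character(0),
                                     in_degree = integer(0))))
  }
  out_deg <- table(e$tf_id)
  in_deg <- table(e$gene_id)
  tfs <- data.frame(tf_id = names(out_deg),
                    out_degree = as.integer(out_deg),
                    stringsAsFactors = FALSE)
  tfs <- tfs[order(-tfs$out_degree, tfs$tf_id), , drop = FALSE]
  tg <- data.frame(gene_id = names(in_deg), in_degree = as.integer(in_deg),
                   stringsAsFactors = FALSE)
  tg <- tg[order(-tg$in_degree, tg$gene_id), , drop = FALSE]
  if (!is.null(top_k)) {
    tfs <- utils::head(tfs, top_k)
    tg <- utils::head(tg, top_k)
  }
  rownames(tfs) <- NULL; rownames(tg) <- NULL
  list(tfs = tfs, targets = tg)
}

#' Seeded subnetwork extraction
#'
#' Induced subgraph on the seed nodes plus every node within
#' `neighborhood` undirected hops; edge attributes are preserved; seeds
#' with no edges remain as isolated nodes.
#'
#' @param grn a `grn` object.
#' @param seed_genes node ids (TFs or genes); seeds absent from the
#'   network are dropped with a warning.
#' @param neighborhood number of hops (default 1; 0 = seeds only).
#' @return A `grn` object.
#' @export
subnetwork <- function(grn, seed_genes, neighborhood = 1L) {
  stopifnot(neighborhood >= 0L)
  present <- intersect(seed_genes, grn$nodes$id)
  absent <- setdiff(seed_genes, grn$nodes$id)
  if (length(absent) > 0L) {
    warning("subnetwork: seed(s) absent from GRN: ",
            paste(absent, collapse = ", "))
  }
  keep <- present
  frontier <- present
  e <- grn$edges
  for (h in seq_len(neighborhood)) {
    nb <- c(e$gene_id[e$tf_id %in% frontier], e$tf_id[e$gene_id %in% frontier])
    frontier <- setdiff(nb, keep)
    if (length(frontier) == 0L) break
    keep <- c(keep, frontier)
  }
  sub_e <- e[e$tf_id %in% keep & e$gene_id %in% keep, , drop = FALSE]
  rownames(sub_e) <- NULL
  nodes <- data.frame(id = keep, stringsAsFactors = FALSE)
  nodes$is_tf <- nodes$id %in% grn$nodes$id[grn$nodes$is_tf]
  structure(list(edges = sub_e, nodes = nodes, params = grn$params),
            class = "grn")
}

#' Export a network
#'
#' Edge TSV columns: `tf`, `gene`, `via_peaks` (';'-joined), `edge_sign`,
#' `tf_direction`, `target_direction`.  GraphML (via igraph) carries node
#' and edge attributes; [import_grn()] reproduces the network.
#'
#' @param grn a `grn` object.
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_grn <- function(grn, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  ids <- c(grn$edges$tf_id, grn$edges$gene_id,
           unlist(grn$edges$via_peaks, use.names = FALSE))
  if (any(grepl(";", ids, fixed = TRUE))) {
    stop("identifiers must not contain ';'")
  }
  if (format == "tsv") {
    df <- data.frame(tf = grn$edges$tf_id, gene = grn$edges$gene_id,
                     via_peaks = vapply(grn$edges$via_peaks, paste, "",
                                        collapse = ";"),
                     edge_sign = grn$edges$edge_sign,
                     tf_direction = grn$edges$tf_direction,
                     target_direction = grn$edges$target_direction,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  } else {
    g <- .grn_to_igraph(grn)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.grn_to_igraph <- function(grn) {
  e <- grn$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$tf_id, to = e$gene_id,
               via_peaks = vapply(e$via_peaks, paste, "", collapse = ";"),
               edge_sign = e$edge_sign, tf_direction = e$tf_direction,
               target_direction = e$target_direction,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = grn$nodes$id, is_tf = grn$nodes$is_tf,
                          stringsAsFactors = FALSE))
  g
}

#' Import a network exported by [export_grn()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return A `grn` object.
#' @export
import_grn <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(tf = "character",
                                           gene = "character",
                                           via_peaks = "character",
                                           edge_sign = "integer",
                                           tf_direction = "character",
                                           target_direction = "character"))
    edges <- data.frame(tf_id = df$tf, gene_id = df$gene,
                        edge_sign = df$edge_sign,
                        tf_direction = df$tf_direction,
                        target_direction = df$target_direction,
                        stringsAsFactors = FALSE)
    edges$via_peaks <- strsplit(df$via_peaks, ";", fixed = TRUE)
    nodes <- data.frame(
      id = c(unique(edges$tf_id),
             setdiff(unique(edges$gene_id), unique(edges$tf_id))),
      stringsAsFactors = FALSE)
    nodes$is_tf <- nodes$id %in% edges$tf_id
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    vl <- igraph::as_data_frame(g, what = "vertices")
    edges <- data.frame(tf_id = el$from, gene_id = el$to,
                        edge_sign = as.integer(el$edge_sign),
                        tf_direction = el$tf_direction,
                        target_direction = el$target_direction,
                        stringsAsFactors = FALSE)
    edges$via_peaks <- strsplit(el$via_peaks, ";", fixed = TRUE)
    nodes <- data.frame(id = vl$name, is_tf = as.logical(vl$is_tf),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$tf_id, edges$gene_id),
                 c("tf_id", "gene_id", "edge_sign", "tf_direction",
                   "target_direction", "via_peaks"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = nodes, params = list()),
            class = "grn")
}
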