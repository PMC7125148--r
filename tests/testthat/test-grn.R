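toy_links <- function() {
  tf_links <- data.frame(
    tf_id = c("TF1", "TF1", "TF2"),
    peak_id = c("p1", "p2", "p2"),
    r = c(0.8, 0.7, -0.6), sign = c(1L, 1L, -1L),
    direction = c("positive", "positive", "negative"),
    r_threshold_used = 0.5, fdr_at_threshold = 0.1,
    stringsAsFactors = FALSE)
  gene_links <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    peak_id = c("p1", "p2", "p2"),
    crd_loop_id = "L1", r = 0.9, pvalue = 0.001,
    is_promoter_proximal = FALSE, nearest_tss_flag = TRUE,
    stringsAsFactors = FALSE)
  list(tf = tf_links, gene = gene_links)
}

test_that("edges are exactly the peak-mediated compositions", {
  l <- toy_links()
  g <- assemble_grn(l$tf, l$gene)
  got <- paste(g$edges$tf_id, g$edges$gene_id)
  expect_setequal(got, c("TF1 gA", "TF1 gB", "TF2 gA", "TF2 gB"))
  expect_equal(g$edges$via_peaks[[which(got == "TF1 gA")]], c("p1", "p2"))
  expect_equal(g$edges$via_peaks[[which(got == "TF2 gA")]], "p2")
  expect_equal(g$edges$edge_sign[got == "TF2 gB"], -1L)
  # a TF-peak link whose peak has no gene link produces no edge
  extra <- rbind(l$tf, data.frame(tf_id = "TF3", peak_id = "p9", r = 0.9,
                                  sign = 1L, direction = "positive",
                                  r_threshold_used = 0.5,
                                  fdr_at_threshold = 0.1))
  g2 <- assemble_grn(extra, l$gene)
  expect_false("TF3" %in% g2$edges$tf_id)
})

test_that("restriction to differential TFs only removes edges", {
  l <- toy_links()
  act <- data.frame(tf_id = c("TF1", "TF2"), activity = c(0.5, -0.2),
                    padj = c(1e-4, 0.5),
                    direction = c("case-up", "null"),
                    stringsAsFactors = FALSE)
  full <- assemble_grn(l$tf, l$gene, act)
  restr <- assemble_grn(l$tf, l$gene, act, restrict_to_differential = TRUE)
  expect_false("TF2" %in% restr$edges$tf_id)
  expect_true(all(paste(restr$edges$tf_id, restr$edges$gene_id) %in%
                    paste(full$edges$tf_id, full$edges$gene_id)))
  expect_equal(unique(restr$edges$tf_direction), "case-up")
})

test_that("consistency fraction counts direction-matched edges", {
  l <- toy_links()
  act <- data.frame(tf_id = c("TF1", "TF2"), activity = c(0.5, 0.3),
                    padj = 1e-4, direction = "case-up",
                    stringsAsFactors = FALSE)
  # TF1 (sign +, activity +) consistent iff target peak lfc > 0;
  # TF2 (sign -, activity +) consistent iff target peak lfc < 0
  pd <- data.frame(feature_id = c("p1", "p2"), log2fc = c(1, 1))
  g <- assemble_grn(l$tf, l$gene, act)
  cf <- consistency_fraction(g, act, pd)
  # TF1 edges (2) consistent; TF2 edges (2) inconsistent
  expect_equal(as.numeric(cf), 0.5)
  expect_equal(attr(cf, "n_evaluated"), 4L)
  all_pos <- consistency_fraction(
    assemble_grn(l$tf[l$tf$tf_id == "TF1", ], l$gene, act), act, pd)
  expect_equal(as.numeric(all_pos), 1)
})

test_that("degree rankings are stable with lexicographic ties", {
  g <- assemble_grn(toy_links()$tf, toy_links()$gene)
  dr <- degree_rankings(g)
  expect_equal(dr$tfs$out_degree, c(2L, 2L))
  expect_equal(dr$tfs$tf_id, c("TF1", "TF2"))   # tie broken by id
  expect_equal(sum(dr$tfs$out_degree), nrow(g$edges))
  expect_equal(sum(dr$targets$in_degree), nrow(g$edges))
  empty <- assemble_grn(toy_links()$tf[0, ], toy_links()$gene)
  expect_equal(nrow(degree_rankings(empty)$tfs), 0L)
})

test_that("subnetwork extraction respects the hop neighbourhood", {
  g <- assemble_grn(toy_links()$tf, toy_links()$gene)
  s0 <- subnetwork(g, "gA", neighborhood = 0L)
  expect_equal(nrow(s0$edges), 0L)
  expect_equal(s0$nodes$id, "gA")
  s1 <- subnetwork(g, "gA", neighborhood = 1L)
  expect_setequal(s1$nodes$id, c("gA", "TF1", "TF2"))
  # edges among included nodes are retained (TF-gB excluded with gB)
  expect_setequal(paste(s1$edges$tf_id, s1$edges$gene_id),
                  c("TF1 gA", "TF2 gA"))
  s2 <- subnetwork(g, "gA", neighborhood = 2L)
  expect_equal(nrow(s2$edges), 4L)
  expect_warning(subnetwork(g, c("gA", "nope")), "nope")
})

test_that("exports round-trip through TSV and GraphML", {
  l <- toy_links()
  act <- data.frame(tf_id = c("TF1", "TF2"), activity = c(0.5, -0.2),
                    padj = 1e-4, direction = c("case-up", "control-up"),
                    stringsAsFactors = FALSE)
  pd <- data.frame(feature_id = c("p1", "p2"), log2fc = c(1, -0.2))
  g <- assemble_grn(l$tf, l$gene, act, peak_diff = pd)
  for (fmt in c("tsv", "graphml")) {
    f <- withr::local_tempfile()
    export_grn(g, f, fmt)
    back <- import_grn(f, fmt)
    expect_equal(back$edges[, c("tf_id", "gene_id", "edge_sign")],
                 g$edges[, c("tf_id", "gene_id", "edge_sign")])
    expect_equal(back$edges$via_peaks, g$edges$via_peaks)
    expect_equal(back$edges$tf_direction, g$edges$tf_direction)
    expect_setequal(back$nodes$id, g$nodes$id)
  }
  bad <- g
  bad$edges$via_peaks[[1L]] <- "has;semicolon"
  f <- withr::local_tempfile()
  expect_error(export_grn(bad, f, "tsv"), ";")
})

test_that("assembled networks keep referential integrity on real runs", {
  ds <- small_cohort()
  pk <- normalize_log(ds$peak_counts)
  ge <- normalize_log(ds$gene_counts)
  expr <- ge[filter_expressed(ds$gene_counts), , drop = FALSE]
  crds <- call_crds(ds$loops, pk, ds$peaks)
  gl <- link_enhancers_to_genes(crds, pk, expr, ds$genes, ds$peaks)
  cand <- sort(unique(unlist(crds$member_peaks[crds$is_crd])))
  tfs <- intersect(sort(unique(ds$motifs$tf_id)), rownames(expr))
  tl <- link_tfs_to_peaks(tfs, expr, pk, ds$motifs, cand)
  g <- assemble_grn(tl, gl)
  tf_key <- paste(tl$tf_id, tl$peak_id)
  gene_key <- paste(gl$gene_id, gl$peak_id)
  for (i in seq_len(nrow(g$edges))) {
    via <- g$edges$via_peaks[[i]]
    expect_true(all(paste(g$edges$tf_id[i], via) %in% tf_key))
    expect_true(all(paste(g$edges$gene_id[i], via) %in% gene_key))
  }
  expect_setequal(g$nodes$id, c(g$edges$tf_id, g$edges$gene_id))
})
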