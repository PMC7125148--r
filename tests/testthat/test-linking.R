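test_that("within-CRD gene linking recovers planted enhancers", {
  ds <- small_cohort()
  pk <- normalize_log(ds$peak_counts)
  ge <- normalize_log(ds$gene_counts)
  expr <- ge[filter_expressed(ds$gene_counts), , drop = FALSE]
  crds <- call_crds(ds$loops, pk, ds$peaks)
  links <- link_enhancers_to_genes(crds, pk, expr, ds$genes, ds$peaks)
  expect_true(all(links$r > 0))
  expect_true(all(links$pvalue < 0.05))
  rec <- evaluate_recovery(links[, c("gene_id", "peak_id")],
                           ds$truth$enh_gene_links[, c("gene_id", "peak_id")])
  expect_gte(rec["recall"], 0.7)
  # recovered planted links are strongly correlated
  key <- paste(links$gene_id, links$peak_id)
  tkey <- paste(ds$truth$enh_gene_links$gene_id,
                ds$truth$enh_gene_links$peak_id)
  expect_gt(median(links$r[key %in% tkey]), 0.6)

  # tightening alpha never adds links
  strict <- link_enhancers_to_genes(crds, pk, expr, ds$genes, ds$peaks,
                                    alpha = 0.01)
  expect_true(all(paste(strict$gene_id, strict$peak_id) %in% key))

  # genes whose TSS lies outside every CRD loop acquire no links
  tf_genes <- grep("^tf", rownames(expr), value = TRUE)
  expect_false(any(links$gene_id %in% tf_genes))
})

test_that("negative correlations are excluded by the sign rule", {
  set.seed(5)
  n <- 17L
  z <- rnorm(n)
  pk <- rbind(pos = z + rnorm(n, 0, 0.3), neg = -z + rnorm(n, 0, 0.3))
  colnames(pk) <- sprintf("s%02d", 1:n)
  ge <- matrix(z, 1, dimnames = list("g1", colnames(pk)))
  peaks <- genomic_intervals("chr1", c(100, 40000), c(600, 40500),
                             c("pos", "neg"))
  genes <- genomic_intervals("chr1", 50000, 51000, "g1", strand = "+")
  crds <- data.frame(loop_id = "L1", chrom = "chr1", start = 0L,
                     end = 100000L, is_crd = TRUE, stringsAsFactors = FALSE)
  crds$member_peaks <- list(c("pos", "neg"))
  links <- link_enhancers_to_genes(crds, pk, ge, genes, peaks)
  expect_equal(links$peak_id, "pos")
  expect_false("neg" %in% links$peak_id)
})

test_that("randomized gene-peak pairings give uniform p-values", {
  ds <- generate_cohort(null_cohort_config(n_loops = 800L, seed = 19L))
  pk <- normalize_log(ds$peak_counts)
  ge <- normalize_log(ds$gene_counts)
  expr <- ge[filter_expressed(ds$gene_counts), , drop = FALSE]
  crds <- call_crds(ds$loops, pk, ds$peaks)
  p1 <- randomized_link_null(crds, pk, expr, ds$genes, n_draws = 400L,
                             seed = 2L)
  expect_length(p1, 400L)
  expect_uniform_pvalues(p1)
  p2 <- randomized_link_null(crds, pk, expr, ds$genes, n_draws = 400L,
                             seed = 2L)
  expect_identical(p1, p2)
})

test_that("enhancers-per-gene distribution sums to one and bins correctly", {
  links <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                      peak_id = sprintf("p%d", 1:4))
  tab <- enhancers_per_gene(links, c("g1", "g2", "g3"))
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$n_genes[tab$k == 3], 1L)
  expect_equal(tab$n_genes[tab$k == 0], 1L)

  # genes in CRDs accumulate more linked enhancers than genes in plain loops
  ds <- small_cohort()
  pk <- normalize_log(ds$peak_counts)
  ge <- normalize_log(ds$gene_counts)
  expr <- ge[filter_expressed(ds$gene_counts), , drop = FALSE]
  crds <- call_crds(ds$loops, pk, ds$peaks)
  crd_links <- link_enhancers_to_genes(crds, pk, expr, ds$genes, ds$peaks)
  non <- crds[!crds$is_crd, , drop = FALSE]
  non_links <- link_enhancers_to_genes(non, pk, expr, ds$genes, ds$peaks,
                                       crd_only = FALSE)
  gene_loop <- ds$gene_loop[!is.na(ds$gene_loop)]
  crd_genes <- names(gene_loop)[gene_loop %in% crds$loop_id[crds$is_crd]]
  non_genes <- names(gene_loop)[gene_loop %in% non$loop_id]
  mean_k <- function(links, genes) {
    tab <- enhancers_per_gene(links, genes)
    sum(tab$k * tab$fraction)
  }
  expect_gt(mean_k(crd_links, crd_genes), mean_k(non_links, non_genes))
})

test_that("empirical FDR curve counts match brute-force enumeration", {
  ds <- small_cohort()
  pk <- normalize_log(ds$peak_counts)
  ge <- normalize_log(ds$gene_counts)
  crds <- call_crds(ds$loops, pk, ds$peaks)
  cand <- sort(unique(unlist(crds$member_peaks[crds$is_crd])))
  tf <- sort(unique(ds$motifs$tf_id))[1L]
  common <- colnames(pk)
  r <- as.numeric(cor(ge[tf, common], t(pk[cand, common])))
  names(r) <- cand
  is_fg <- cand %in% ds$motifs$peak_id[ds$motifs$tf_id == tf]
  for (dir in c("positive", "negative")) {
    curve <- empirical_fdr_curve(tf, ge, pk, ds$motifs, cand, dir)
    oracle <- fdr_curve_oracle(r, is_fg, dir)
    expect_equal(curve$threshold, oracle$threshold, tolerance = 1e-12)
    expect_equal(curve$n_fg, oracle$n_fg)
    expect_equal(curve$n_bg, oracle$n_bg)
    expect_equal(curve$fdr, oracle$fdr, tolerance = 1e-12)
    # counts never increase as the threshold tightens
    expect_true(all(diff(curve$n_fg) <= 0))
    expect_true(all(diff(curve$n_bg) <= 0))
  }
})

test_that("FDR arithmetic follows the stated formula at the boundaries", {
  # 8 foreground and 2 background passing -> FDR 0.2
  e <- c(rep(2, 8), rep(-2, 12), 0.5, 0.6)
  set.seed(10)
  n <- 20L
  x <- rnorm(n)
  pk <- t(sapply(e, function(b) b * x + rnorm(n, 0, 0.05)))
  rownames(pk) <- sprintf("p%02d", seq_along(e))
  colnames(pk) <- sprintf("s%02d", 1:n)
  ge <- matrix(x, 1, dimnames = list("tfZ", colnames(pk)))
  motifs <- data.frame(tf_id = "tfZ", peak_id = sprintf("p%02d", 1:8))
  curve <- empirical_fdr_curve("tfZ", ge, pk, motifs, rownames(pk),
                               "positive")
  # thresholds passing the 8 strong foreground and the 2 moderate
  # background peaks: fdr = 2 / (8 + 2)
  hi <- curve[curve$n_fg == 8 & curve$n_bg == 2, ]
  expect_true(nrow(hi) > 0)
  expect_equal(unique(hi$fdr), 0.2)
  # the tightest threshold passes only the top (foreground) peak: fdr 0
  expect_equal(curve$fdr[nrow(curve)], 0)
  expect_equal(curve$n_bg[nrow(curve)], 0L)
  expect_error(empirical_fdr_curve("tfZ", ge, pk,
                                   data.frame(tf_id = "tfZ",
                                              peak_id = rownames(pk)),
                                   rownames(pk), "positive"),
               "foreground and background")
})

test_that("TF-peak linking honours FDR target and the 0.4 floor", {
  ds <- small_cohort()
  pk <- normalize_log(ds$peak_counts)
  ge <- normalize_log(ds$gene_counts)
  expr <- ge[filter_expressed(ds$gene_counts), , drop = FALSE]
  crds <- call_crds(ds$loops, pk, ds$peaks)
  cand <- sort(unique(unlist(crds$member_peaks[crds$is_crd])))
  tfs <- intersect(sort(unique(ds$motifs$tf_id)), rownames(expr))
  links <- link_tfs_to_peaks(tfs, expr, pk, ds$motifs, cand)
  expect_true(all(abs(links$r) >= 0.4))
  expect_true(all(abs(links$r) >= abs(links$r_threshold_used) - 1e-12))
  expect_true(all(links$fdr_at_threshold <= 0.20))
  expect_equal(links$sign, ifelse(links$r > 0, 1L, -1L))
  # every link points at a motif-bearing peak
  key <- paste(ds$motifs$tf_id, ds$motifs$peak_id)
  expect_true(all(paste(links$tf_id, links$peak_id) %in% key))
  # monotone in the FDR target
  tight <- link_tfs_to_peaks(tfs, expr, pk, ds$motifs, cand,
                             fdr_target = 0.05)
  expect_true(all(paste(tight$tf_id, tight$peak_id) %in%
                    paste(links$tf_id, links$peak_id)))
  # determinism
  again <- link_tfs_to_peaks(tfs, expr, pk, ds$motifs, cand)
  expect_identical(links, again)
})

test_that("a planted activator is recovered at bounded realized FDR", {
  # single strongly planted TF: 50 targets, decoy rate 0.1
  ds <- generate_cohort(sim_config(n_loops = 120L, n_tfs = 1L,
                                   frac_repressor_tfs = 0,
                                   frac_diff_tfs = 0,
                                   interior_peaks_per_loop = 3L,
                                   tf_targets_per_tf = 50L,
                                   motif_decoy_rate = 0.1, seed = 77L))
  pk <- normalize_log(ds$peak_counts)
  ge <- normalize_log(ds$gene_counts)
  crds <- call_crds(ds$loops, pk, ds$peaks)
  cand <- sort(unique(unlist(crds$member_peaks[crds$is_crd])))
  links <- link_tfs_to_peaks("tf01", ge, pk, ds$motifs, cand)
  expect_gt(nrow(links), 0L)
  expect_true(all(links$sign == 1L))
  rec <- evaluate_recovery(links[, c("tf_id", "peak_id")],
                           ds$truth$tf_peak_links[, c("tf_id", "peak_id")])
  expect_lte(1 - rec["precision"], 0.3)
})

test_that("nearest-TSS fraction counts links to the closest gene", {
  genes <- genomic_intervals("chr1", c(1000, 90000), c(2000, 91000),
                             c("gA", "gB"), strand = c("+", "+"))
  peaks <- genomic_intervals("chr1", c(1500, 2500, 3500, 80000),
                             c(1600, 2600, 3600, 80100),
                             sprintf("p%d", 1:4))
  links <- data.frame(gene_id = c("gA", "gA", "gB", "gB"),
                      peak_id = sprintf("p%d", 1:4))
  # p1-p3 nearest gA, p4 nearest gB: links 1,2 and 4 point at the nearest
  expect_equal(nearest_tss_fraction(links, genes, peaks), 0.75)
  expect_true(is.na(nearest_tss_fraction(links[0, ], genes, peaks)))
})
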