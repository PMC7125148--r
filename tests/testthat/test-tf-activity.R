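toy_diff <- function(lfc) {
  data.frame(feature_id = names(lfc), log2fc = unname(lfc),
             stringsAsFactors = FALSE)
}

test_that("activity is the motif-peak mean relative to the genome mean", {
  lfc <- c(p1 = 1.0, p2 = 0.5, p3 = 0.0, p4 = -0.5)
  motifs <- data.frame(tf_id = "tfA", peak_id = c("p1", "p2"))
  sc <- tf_activity_scores(toy_diff(lfc), motifs, "tfA", min_sites = 1L)
  expect_equal(sc$activity, 0.75 - 0.25)   # motif mean minus genome mean
  expect_equal(sc$n_sites, 2L)

  # motif mean equal to the genome mean gives activity 0
  motifs0 <- data.frame(tf_id = "tfA", peak_id = c("p1", "p4"))
  expect_equal(tf_activity_scores(toy_diff(lfc), motifs0, "tfA",
                                  min_sites = 1L)$activity, 0)

  # TFs outside the expressed set are excluded
  sc2 <- tf_activity_scores(toy_diff(lfc), motifs, character(0))
  expect_equal(nrow(sc2), 0L)

  # below min_sites the score is flagged undetermined
  sc3 <- tf_activity_scores(toy_diff(lfc), motifs, "tfA", min_sites = 10L)
  expect_equal(sc3$status, "undetermined")
})

test_that("activity decomposes as the site-weighted mean of subsets", {
  set.seed(3)
  lfc <- setNames(rnorm(200), sprintf("p%03d", 1:200))
  s1 <- sprintf("p%03d", 1:30)
  s2 <- sprintf("p%03d", 61:80)
  d <- toy_diff(lfc)
  a1 <- tf_activity_scores(d, data.frame(tf_id = "t", peak_id = s1), "t")$activity
  a2 <- tf_activity_scores(d, data.frame(tf_id = "t", peak_id = s2), "t")$activity
  au <- tf_activity_scores(d, data.frame(tf_id = "t", peak_id = c(s1, s2)),
                           "t")$activity
  expect_equal(au, (30 * a1 + 20 * a2) / 50, tolerance = 1e-12)
})

test_that("permutation p-values bound zero activity and planted effects", {
  set.seed(4)
  lfc <- setNames(rnorm(300), sprintf("p%03d", 1:300))
  d <- toy_diff(lfc)
  # a TF whose motif set is the whole genome has activity exactly 0
  motifs <- data.frame(tf_id = "t0", peak_id = names(lfc))
  ta <- tf_activity_significance(d, motifs, "t0", n_permutations = 199L,
                                 seed = 1L, min_sites = 1L)
  expect_equal(ta$activity, 0)
  expect_gte(ta$pvalue, 0.5)

  expect_error(tf_activity_significance(d, motifs, "t0",
                                        n_permutations = 10L), "100")
})

test_that("planted differential TFs are detected with correct sign", {
  ds <- small_cohort()
  pk <- normalize_log(ds$peak_counts)
  pd <- differential_features(pk, ds$samples, c("batch", "sex", "mutation"))
  tfs <- sort(unique(ds$motifs$tf_id))
  ta <- tf_activity_significance(pd, ds$motifs, tfs, n_permutations = 1000L,
                                 seed = 7L, fdr_threshold = 0.01)
  truth <- setNames(ds$truth$tf_activity$direction, ds$truth$tf_activity$tf_id)
  planted <- ta$tf_id[truth[ta$tf_id] != "null"]
  # planted shifts dominate the permutation null ...
  expect_true(all(ta$pvalue[ta$tf_id %in% planted] <= 2 / 1001))
  # ... with the planted direction ...
  expect_equal(ta$direction[ta$tf_id %in% planted],
               unname(truth[planted]))
  # ... and larger activity magnitude than every undriven TF (whose
  # chance condition contrast produces only modest target shifts)
  expect_equal(sort(ta$tf_id[order(-abs(ta$activity))][seq_along(planted)]),
               sort(planted))
})

test_that("permutation p-values are valid on null cohorts", {
  ds <- generate_cohort(null_cohort_config(n_loops = 300L, n_tfs = 50L,
                                           seed = 13L))
  pk <- normalize_log(ds$peak_counts)
  pd <- differential_features(pk, ds$samples, c("batch", "sex", "mutation"))
  ta <- tf_activity_significance(pd, ds$motifs,
                                 sort(unique(ds$motifs$tf_id)),
                                 n_permutations = 200L, seed = 3L)
  expect_gte(sum(!is.na(ta$pvalue)), 50L)
  for (alpha in c(0.01, 0.05)) {
    expect_lte(mean(ta$pvalue <= alpha, na.rm = TRUE),
               alpha + 2 / sqrt(200))
  }
  expect_uniform_pvalues(ta$pvalue[!is.na(ta$pvalue)])
})

test_that("label swap negates TF activities exactly", {
  ds <- small_cohort()
  pk <- normalize_log(ds$peak_counts)
  pd <- differential_features(pk, ds$samples, c("batch", "sex", "mutation"))
  flipped <- ds$samples
  flipped$condition <- ifelse(flipped$condition == "case", "control", "case")
  pd2 <- differential_features(pk, flipped, c("batch", "sex", "mutation"))
  tfs <- sort(unique(ds$motifs$tf_id))
  a1 <- tf_activity_scores(pd, ds$motifs, tfs)
  a2 <- tf_activity_scores(pd2, ds$motifs, tfs)
  expect_equal(a2$activity, -a1$activity, tolerance = 1e-9)
})

test_that("activator/repressor classification follows the planted sign", {
  ds <- small_cohort()
  pk <- normalize_log(ds$peak_counts)
  ge <- normalize_log(ds$gene_counts)
  truth <- ds$truth$tf_peak_links
  signs <- tapply(truth$sign, truth$tf_id, unique)
  modes <- classify_tf_mode(ge, pk, ds$motifs, names(signs))
  got <- setNames(modes$mode, modes$tf_id)
  expect_true(all(got[names(signs)[signs == 1L]] == "activator"))
  expect_true(all(got[names(signs)[signs == -1L]] == "repressor"))
  expect_error(classify_tf_mode(ge[, 1:2], pk[, 1:2], ds$motifs), "3")
})

test_that("motifs with significant opposite aggregates give mixed evidence", {
  set.seed(8)
  n <- 20L
  e <- rnorm(n)
  pk <- rbind(up1 = e + rnorm(n, 0, 0.1), up2 = e + rnorm(n, 0, 0.1),
              dn1 = -e + rnorm(n, 0, 0.1), dn2 = -e + rnorm(n, 0, 0.1))
  colnames(pk) <- sprintf("s%02d", 1:n)
  ge <- matrix(e, nrow = 1, dimnames = list("tfX", colnames(pk)))
  motifs <- data.frame(tf_id = "tfX",
                       peak_id = c("up1", "up2", "dn1", "dn2"),
                       motif_id = c("m1", "m1", "m2", "m2"))
  expect_equal(classify_tf_mode(ge, pk, motifs)$mode, "mixed-evidence")
})

test_that("known-TF enrichment matches the hypergeometric oracle", {
  # 8 of 10 known TFs active; 100 of 500 others active
  act <- data.frame(
    tf_id = sprintf("t%03d", 1:510),
    activity = 1,
    padj = c(rep(0.0005, 8), rep(0.5, 2), rep(0.0005, 100), rep(0.5, 400)),
    stringsAsFactors = FALSE)
  known <- sprintf("t%03d", 1:10)
  enr <- known_tf_enrichment(act, known, thresholds = 0.001)
  expect_equal(enr$n_active, 108L)
  expect_equal(enr$n_known_active, 8L)
  expect_equal(enr$odds_ratio, (8 * 400) / (2 * 100))
  expect_equal(enr$pvalue, hyper_tail_oracle(8, 2, 100, 400),
               tolerance = 1e-9)

  # proportionally distributed known TFs give OR near 1
  act2 <- act
  act2$padj <- rep(c(0.0005, rep(0.5, 4)), 102)
  enr2 <- known_tf_enrichment(act2, act2$tf_id[1:50], thresholds = 0.001)
  expect_lt(abs(log(enr2$odds_ratio)), log(2.5))

  # known set equal to the active set: infinite enrichment
  act3 <- data.frame(tf_id = sprintf("t%d", 1:20), activity = 1,
                     padj = c(rep(1e-4, 5), rep(0.9, 15)))
  enr3 <- known_tf_enrichment(act3, sprintf("t%d", 1:5), thresholds = 0.001)
  expect_true(is.infinite(enr3$odds_ratio))
  expect_warning(known_tf_enrichment(act3, c("t1", "zz"), thresholds = 0.5),
                 "untested")
})
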