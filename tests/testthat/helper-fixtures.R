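# Small cohorts shared across test files.  Generated once per test run;
# everything is seeded so results are stable.

small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- generate_cohort(sim_config(n_loops = 60L, n_bg_peaks = 60L,
                                          n_tfs = 8L, seed = 42L))
    }
    memo
  }
})

null_cohort_config <- function(n_loops = 400L, n_per_group = 10L,
                               n_tfs = 20L, seed = 11L) {
  sim_config(n_case = n_per_group, n_control = n_per_group,
             n_loops = n_loops, frac_crd_loops = 0,
             peaks_per_anchor = 1L, genes_per_loop = 1L,
             enh_per_gene = 1L, interior_peaks_per_loop = 1L,
             n_bg_peaks = 50L, n_tfs = n_tfs, frac_diff_tfs = 0,
             frac_repressor_tfs = 0.25, tf_effect = 0,
             tf_activity_shift = 0, frac_diff_peaks = 0,
             sex_effect_sd = 0, batch_effect_sd = 0,
             mutation_effect_sd = 0, seed = seed)
}

# independent Benjamini-Hochberg oracle: sorted n*p/rank, cumulative
# minimum from the largest p downwards
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in seq(n, 1L)) {
    running <- min(running, n * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

# one-sided (enrichment) Fisher p by direct hypergeometric tail summation
hyper_tail_oracle <- function(a, b, c_, d) {
  K <- a + b          # set size
  n <- a + c_         # target size
  N <- a + b + c_ + d
  ks <- a:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# brute-force empirical FDR curve: loop over thresholds, count directly
fdr_curve_oracle <- function(r, is_fg, direction) {
  thr <- sort(unique(r), decreasing = (direction == "negative"))
  do.call(rbind, lapply(thr, function(t) {
    pass <- if (direction == "positive") r >= t else r <= t
    nf <- sum(pass & is_fg); nb <- sum(pass & !is_fg)
    data.frame(threshold = t, n_fg = nf, n_bg = nb,
               fdr = if (nf + nb == 0L) 0 else nb / (nf + nb))
  }))
}

expect_uniform_pvalues <- function(p, alpha = 0.01) {
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, alpha)
}
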