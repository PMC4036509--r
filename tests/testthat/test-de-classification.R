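make_table <- function(padj_G, padj_N, padj_GxN) {
  n <- length(padj_G)
  tab <- data.frame(probe_id = sprintf("p%02d", seq_len(n)),
                    T_G = 0, p_G = padj_G, T_N = 0, p_N = padj_N,
                    T_GxN = 0, p_GxN = padj_GxN,
                    padj_G = padj_G, padj_N = padj_N, padj_GxN = padj_GxN,
                    stringsAsFactors = FALSE)
  class(tab) <- c("contrast_table", "data.frame")
  tab
}

test_that("declaration uses a strict inequality at alpha", {
  tab <- make_table(c(0.05, 0.049999), 1, 1)
  cls <- classify_de(tab, alpha = 0.05)
  expect_identical(cls$flags$declared_G, c(FALSE, TRUE))
  expect_error(classify_de(tab, alpha = 0), "alpha")
  expect_error(classify_de(tab, alpha = 1), "alpha")
})

test_that("the Venn partition matches hand enumeration and sums to the union", {
  # G only x2, N only x1, G-and-N x1
  tab <- make_table(padj_G = c(0.01, 0.01, 1, 0.01, 1),
                    padj_N = c(1, 1, 0.01, 0.01, 1),
                    padj_GxN = c(1, 1, 1, 1, 1))
  v <- classify_de(tab)$venn
  expect_equal(v$cells$G_only, 2)
  expect_equal(v$cells$N_only, 1)
  expect_equal(v$cells$G_N, 1)
  expect_equal(v$cells$GxN_only + v$cells$G_GxN + v$cells$N_GxN +
                 v$cells$G_N_GxN, 0)
  expect_equal(v$union, 4)
  expect_equal(v$totals[["G"]], 3)
  expect_equal(v$totals[["N"]], 2)

  # all adjusted p at 1: empty classification
  v0 <- classify_de(make_table(rep(1, 4), rep(1, 4), rep(1, 4)))$venn
  expect_equal(v0$union, 0)
})

test_that("disjoint cells always partition the union on random tables", {
  set.seed(303)
  for (i in 1:20) {
    tab <- make_table(runif(50), runif(50), runif(50))
    v <- classify_de(tab, alpha = 0.5)$venn
    expect_equal(Reduce(`+`, v$cells), v$union)
    expect_equal(v$cells$G_only + v$cells$G_N + v$cells$G_GxN +
                   v$cells$G_N_GxN, unname(v$totals["G"]))
  }
})

test_that("declared sets are nested as alpha grows", {
  set.seed(7)
  tab <- make_table(runif(200), runif(200), runif(200))
  alphas <- c(0.01, 0.05, 0.2, 0.8)
  prev <- NULL
  for (a in alphas) {
    cur <- classify_de(tab, alpha = a)$flags
    if (!is.null(prev)) {
      expect_true(all(!prev$declared_G | cur$declared_G))
      expect_true(all(!prev$declared_N | cur$declared_N))
      expect_true(all(!prev$declared_GxN | cur$declared_GxN))
    }
    prev <- cur
  }
})

test_that("effect direction reproduces the published N-transporter pattern", {
  # cell means of an NRT2-family nitrate transporter probe set:
  # MUT-HN 5.13, MUT-LN 4.15, WT-HN 2.76, WT-LN 3.19
  m <- one_gene_matrix(rep(2.76, 2), rep(3.19, 2), rep(5.13, 2),
                       rep(4.15, 2))
  f <- fit_gene_anova(m)
  d <- effect_direction(f, "G")
  expect_equal(d$difference, 1.665, tolerance = 1e-12)
  expect_identical(d$direction, "up_in_MUT")
  expect_true(d$strong)
  expect_false(d$tie)
})

test_that("direction handles ties, weak effects and rejects the interaction", {
  m <- one_gene_matrix(c(4, 6), c(4, 6), c(4, 6), c(4, 6))
  f <- fit_gene_anova(m)
  d <- effect_direction(f, "G")
  expect_identical(d$direction, "down_in_MUT")
  expect_true(d$tie)
  expect_false(d$strong)

  m2 <- one_gene_matrix(rep(5, 2), rep(5, 2), rep(4.5, 2), rep(4.5, 2))
  d2 <- effect_direction(fit_gene_anova(m2), "G")
  expect_equal(d2$difference, -0.5)
  expect_identical(d2$direction, "down_in_MUT")
  expect_false(d2$strong)

  expect_error(effect_direction(f, "GxN"), "direction")
})

test_that("overlaps with external lists are exact set intersections", {
  rep_ <- overlap_with_lists(c("a", "b", "c"),
                             list(local = c("b", "c", "d"),
                                  systemic = c("c", "e")))
  expect_equal(unname(rep_$overlaps["local"]), 2)
  expect_equal(unname(rep_$overlaps["systemic"]), 1)
  expect_equal(rep_$pairwise["local", "systemic"], 1L)
  expect_equal(rep_$in_any, 2)  # "a" is in neither list

  empty <- overlap_with_lists(character(0), list(l = c("x", "y")))
  expect_equal(unname(empty$overlaps["l"]), 0)

  same <- overlap_with_lists(c("a", "b"), list(l = c("a", "b")))
  expect_equal(unname(same$overlaps["l"]), 2)
})

test_that("planted genotype effects are recovered with high sensitivity and controlled false positives", {
  cfg <- expression_sim_config(n_genes = 2000, prop_G = 0.05,
                               effect_size_G = 2, prop_N = 0, prop_GxN = 0,
                               noise_sd = 0.5, n_replicates = 3, seed = 185)
  sim <- simulate_expression(cfg)
  fit <- pooled_anova(sim$matrix, filter_threshold = -Inf, m = 2000)
  declared <- fit$classification$flags$declared_G
  planted <- sim$truth$has_G
  sens <- mean(declared[planted])
  expect_gt(sens, 0.9)
  # under Bonferroni the expected false-positive count is <= alpha = 0.05,
  # so more than one false positive would be wildly improbable
  fp <- sum(declared[!planted])
  expect_lte(fp, 1)
})
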